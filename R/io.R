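#' Describe one microarray sample
#'
#' Builds a one-row tibble of sample metadata for a single two-channel array.
#' The normalization batch is derived from the fraction: total-RNA arrays form
#' one batch, monosome- and polysome-associated arrays form a second
#' ("ribosomal") batch, because the intensity distributions of
#' ribosome-associated RNA differ from those of total RNA.
#'
#' @param fraction One of `"total"`, `"monosome"`, `"polysome"`.
#' @param temperature_c Culture temperature in degrees Celsius (30 or 42).
#' @param replicate Biological replicate number (positive integer).
#' @param sample_id Optional sample identifier; a default is composed from the
#'   other fields.
#' @return A one-row tibble with columns `sample_id`, `fraction`,
#'   `temperature_c`, `replicate`, `batch`.
#' @examples
#' array_sample("polysome", 42, 1)
#' @export
array_sample <- function(fraction, temperature_c, replicate, sample_id = NULL) {
  fraction <- match.arg(fraction, c("total", "monosome", "polysome"))
  temperature_c <- as.integer(temperature_c)
  if (!temperature_c %in% c(30L, 42L)) {
    abort("`temperature_c` must be 30 or 42")
  }
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) abort("`replicate` must be a positive integer")
  sample_id <- sample_id %||% sprintf("%s_%d_r%d", fraction, temperature_c, replicate)
  tibble::tibble(
    sample_id = sample_id,
    fraction = fraction,
    temperature_c = temperature_c,
    replicate = replicate,
    batch = derive_batch(fraction)
  )
}

#' Normalization batch implied by a fraction
#'
#' @param fraction Character vector of fractions.
#' @return `"total"` for total-RNA samples, `"ribosomal"` for monosome or
#'   polysome samples.
#' @export
derive_batch <- function(fraction) {
  ifelse(fraction == "total", "total", "ribosomal")
}

probe_table_columns <- c("probe_id", "gene_id", "is_control", "signal", "reference")

new_probe_table <- function(df, sample) {
  df <- tibble::as_tibble(df)
  structure(df, sample = sample, class = c("probe_table", class(df)))
}

#' Read a probe-level two-channel intensity table
#'
#' Reads one array's worth of probe measurements: the sample-channel processed
#' signal and the genomic-DNA reference-channel processed signal, with the
#' probe-to-gene mapping and control flags. Negative intensities are legal
#' (background subtraction in feature extraction can produce them) and are
#' handled downstream by [compute_log_ratios()].
#'
#' @param path Path to a tab-separated file with header columns `probe_id`,
#'   `gene_id`, `is_control`, `signal`, `reference`. `gene_id` may be empty for
#'   control or unmapped probes.
#' @param sample A one-row metadata tibble as returned by [array_sample()].
#' @return A `probe_table` tibble (row order preserved) carrying `sample` as an
#'   attribute.
#' @export
read_probe_table <- function(path, sample) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing <- setdiff(probe_table_columns, names(df))
  if (length(missing) > 0) {
    abort(paste0("missing column: ", paste(missing, collapse = ", ")))
  }
  df <- df[probe_table_columns]
  for (col in c("signal", "reference")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric %s value at row %d: '%s'", col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- x
  }
  df$is_control <- df$is_control %in% c("TRUE", "true", "1", "T", "yes")
  df$gene_id <- ifelse(is.na(df$gene_id) | df$gene_id == "", NA_character_, df$gene_id)
  if (anyDuplicated(df$probe_id)) abort("duplicate probe_id in probe table")
  validate_probe_table(df)
  new_probe_table(df, sample)
}

validate_probe_table <- function(df) {
  if (any(df$is_control & !is.na(df$gene_id))) {
    warn("control probes with non-empty gene_id; their gene_id is ignored")
  }
  invisible(df)
}

#' Read sample metadata for an experiment
#'
#' @param path Tab-separated file with columns `sample_id`, `fraction`,
#'   `temperature_c`, `replicate`.
#' @return A tibble with the four input columns plus the derived `batch`
#'   column. `(fraction, temperature_c, replicate)` must be unique.
#' @export
read_sample_meta <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    fraction = readr::col_character(),
    temperature_c = readr::col_integer(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  missing <- setdiff(c("sample_id", "fraction", "temperature_c", "replicate"), names(df))
  if (length(missing) > 0) abort(paste0("missing column: ", paste(missing, collapse = ", ")))
  bad <- setdiff(unique(df$fraction), c("total", "monosome", "polysome"))
  if (length(bad) > 0) abort(paste0("unknown fraction: ", paste(bad, collapse = ", ")))
  key <- paste(df$fraction, df$temperature_c, df$replicate)
  if (anyDuplicated(key)) abort("duplicate (fraction, temperature_c, replicate) in metadata")
  df$batch <- derive_batch(df$fraction)
  df
}

#' Extract coding-sequence records from a genome
#'
#' Reads a genome FASTA and its GFF3 annotation and returns one record per
#' protein-coding gene: the CDS in coding (5' to 3') orientation, the 50 nt
#' immediately upstream of the start codon on the coding strand, the encoded
#' protein, and a pseudogene flag. Minus-strand features are
#' reverse-complemented. Multi-part CDS features sharing a gene identifier are
#' concatenated in genomic order (an untested rarity in bacterial annotation).
#'
#' Genes whose CDS length is not a multiple of three, or whose start/stop
#' codons are non-canonical, are kept with a warning and flagged in the
#' `length_ok` column; upstream regions truncated at a contig edge trigger a
#' warning and are shorter than 50 nt.
#'
#' @param fasta_path Genome FASTA; sequence names must match GFF seqids.
#' @param gff_path GFF3 annotation with CDS features carrying a gene
#'   identifier (attribute `gene_id`, `locus_tag`, or `ID`). Pseudogenes are
#'   recognised from attribute `pseudo=true` or feature type `pseudogene`.
#' @param upstream Width of the upstream window (default 50 nt).
#' @return A tibble with columns `gene_id`, `seqid`, `start`, `end`, `strand`,
#'   `cds`, `upstream50`, `protein`, `is_pseudogene`, `length_ok`.
#' @export
read_genome <- function(fasta_path, gff_path, upstream = 50L) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff_path)
  ftype <- as.character(gff$type)
  keep <- ftype %in% c("CDS", "pseudogene")
  gff <- gff[keep]
  ftype <- ftype[keep]
  if (length(gff) == 0) abort("no CDS features in GFF")
  meta <- S4Vectors::mcols(gff)
  gid <- NULL
  for (cand in c("gene_id", "locus_tag", "ID")) {
    if (cand %in% names(meta) && !all(is.na(meta[[cand]]))) {
      gid <- as.character(meta[[cand]])
      break
    }
  }
  if (is.null(gid)) abort("CDS features carry no usable gene identifier")
  pseudo_attr <- if ("pseudo" %in% names(meta)) {
    tolower(as.character(meta$pseudo)) %in% "true"
  } else rep(FALSE, length(gff))
  pseudo <- pseudo_attr | ftype == "pseudogene"

  feat <- tibble::tibble(
    gene_id = gid,
    seqid = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff),
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    is_pseudogene = pseudo
  )
  if (any(!feat$strand %in% c("+", "-"))) abort("CDS feature with undefined strand")

  recs <- feat |>
    dplyr::arrange(.data$seqid, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      seqid = .data$seqid[1],
      strand = .data$strand[1],
      is_pseudogene = any(.data$is_pseudogene),
      parts_start = list(.data$start),
      parts_end = list(.data$end),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    )

  extract_one <- function(seqid, strand, parts_start, parts_end) {
    if (!seqid %in% names(contigs)) abort(paste0("GFF seqid not in FASTA: ", seqid))
    contig <- contigs[[seqid]]
    pieces <- Biostrings::DNAStringSet(Map(function(s, e) {
      Biostrings::subseq(contig, s, e)
    }, parts_start, parts_end))
    cds <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (strand == "-") cds <- Biostrings::reverseComplement(cds)
    as.character(cds)
  }
  extract_upstream <- function(seqid, strand, start, end) {
    contig <- contigs[[seqid]]
    len <- length(contig)
    if (strand == "+") {
      lo <- start - upstream
      if (lo < 1) {
        warn(sprintf("upstream region truncated at contig edge near position %d", start))
        lo <- 1
      }
      if (start == 1) return("")
      as.character(Biostrings::subseq(contig, lo, start - 1))
    } else {
      hi <- end + upstream
      if (hi > len) {
        warn(sprintf("upstream region truncated at contig edge near position %d", end))
        hi <- len
      }
      if (end == len) return("")
      as.character(Biostrings::reverseComplement(Biostrings::subseq(contig, end + 1, hi)))
    }
  }

  cds <- purrr::pmap_chr(
    list(recs$seqid, recs$strand, recs$parts_start, recs$parts_end), extract_one)
  up <- purrr::pmap_chr(list(recs$seqid, recs$strand, recs$start, recs$end),
                        extract_upstream)

  length_ok <- nchar(cds) %% 3 == 0
  if (any(!length_ok)) {
    warn(sprintf("%d CDS with length not divisible by 3 (kept, flagged)", sum(!length_ok)))
  }
  starts <- substr(cds, 1, 3)
  if (any(length_ok & !starts %in% c("ATG", "GTG", "TTG"))) {
    warn("non-canonical start codon(s) present (records kept)")
  }
  stops <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (any(length_ok & !stops %in% c("TAA", "TAG", "TGA"))) {
    warn("non-canonical stop codon(s) present (records kept)")
  }

  protein <- translate_cds(cds)

  tibble::tibble(
    gene_id = recs$gene_id,
    seqid = recs$seqid,
    start = recs$start,
    end = recs$end,
    strand = recs$strand,
    cds = cds,
    upstream50 = up,
    protein = protein,
    is_pseudogene = recs$is_pseudogene,
    length_ok = length_ok
  ) |> dplyr::arrange(.data$gene_id)
}

# Standard-table translation of CDS strings, dropping the terminal stop.
translate_cds <- function(cds) {
  n_codon <- nchar(cds) %/% 3
  trimmed <- substr(cds, 1, n_codon * 3)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(trimmed),
                          if.fuzzy.codon = "solve")))
  sub("\\*$", "", aa)
}

#' Write a results table deterministically
#'
#' Writes any uniform record tibble as TSV with a fixed column order, `.` as
#' the decimal separator, and rows sorted by `gene_id` when that column is
#' present, so identical inputs always serialize byte-identically.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  if ("gene_id" %in% names(records)) {
    records <- dplyr::arrange(records, .data$gene_id)
  }
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}
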