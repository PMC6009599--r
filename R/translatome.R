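#' Translational-efficiency table
#'
#' Computes per-gene translational efficiency (TE) for every
#' (replicate, temperature) pair as the log2 ratio of a transcript's
#' abundance in one fraction to its abundance in another; with the default
#' fractions this is the classical polysome-to-total ratio. Because the GEM
#' already holds log2 values, the ratio is a subtraction.
#'
#' @param gem A gene-level `gem` containing both fractions for every
#'   (temperature, replicate).
#' @param numerator Fraction whose abundance forms the numerator
#'   (default `"polysome"`).
#' @param denominator Denominator fraction (default `"total"`). Setting
#'   `numerator = "monosome"`, `denominator = "polysome"` yields the
#'   monosome-vs-polysome partitioning contrast.
#' @return A tibble of class `te_table` with columns `gene_id`, `replicate`,
#'   `temperature_c`, `te` (log2 units), and attribute `contrast`.
#' @export
compute_te <- function(gem, numerator = "polysome", denominator = "total") {
  stopifnot(inherits(gem, "gem"))
  smp <- gem$samples
  pairs <- smp |>
    dplyr::filter(.data$fraction == numerator) |>
    dplyr::select(num_id = "sample_id", "temperature_c", "replicate")
  den <- smp |>
    dplyr::filter(.data$fraction == denominator) |>
    dplyr::select(den_id = "sample_id", "temperature_c", "replicate")
  pairs <- dplyr::full_join(pairs, den, by = c("temperature_c", "replicate"))
  bad <- !complete.cases(pairs)
  if (any(bad)) {
    miss <- pairs[bad, ][1, ]
    missing_frac <- if (is.na(miss$num_id)) numerator else denominator
    abort(sprintf("missing sample: fraction=%s, temperature=%d, replicate=%d",
                  missing_frac, miss$temperature_c, miss$replicate))
  }
  if (nrow(pairs) == 0) abort("no matching (temperature, replicate) pairs")
  vals <- gem$values
  out <- purrr::pmap(pairs, function(num_id, temperature_c, replicate, den_id) {
    tibble::tibble(
      gene_id = rownames(vals),
      replicate = replicate,
      temperature_c = temperature_c,
      te = unname(vals[, num_id] - vals[, den_id])
    )
  }) |> dplyr::bind_rows()
  structure(out, contrast = paste0(numerator, "/", denominator),
            class = c("te_table", class(out)))
}

# genes x replicates matrix of paired 42C - 30C differences from a long
# (gene_id, replicate, temperature_c, value) tibble
paired_fc_matrix <- function(df, value_col = "te") {
  wide <- df |>
    dplyr::select("gene_id", "replicate", "temperature_c", value = dplyr::all_of(value_col)) |>
    tidyr::pivot_wider(names_from = "temperature_c", values_from = "value")
  if (!all(c("30", "42") %in% names(wide))) abort("both temperatures (30, 42) required")
  wide$fc <- wide$`42` - wide$`30`
  m <- wide |>
    dplyr::select("gene_id", "replicate", "fc") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "fc")
  out <- as.matrix(m[-1])
  rownames(out) <- m$gene_id
  if (anyNA(out)) abort("incomplete replicate structure in fold-change matrix")
  out
}

#' Differential translational efficiency between temperatures
#'
#' Forms the per-replicate paired difference dTE = TE(42C) - TE(30C) for
#' every gene and tests it with [rank_products()].
#'
#' @param te A `te_table` from [compute_te()] containing both temperatures.
#' @inheritParams rank_products
#' @return An `rp_result` tibble.
#' @export
differential_te <- function(te, n_perm = 1000, seed = NULL) {
  rank_products(paired_fc_matrix(te, "te"), n_perm = n_perm, seed = seed)
}

#' Differential transcript abundance within one fraction
#'
#' Per-replicate paired log2 fold change (42C - 30C) of a single fraction's
#' abundance, tested with [rank_products()]. With `fraction = "total"` this
#' is the transcriptome contrast; `"polysome"`/`"monosome"` give the
#' ribosome-associated abundance contrasts.
#'
#' @param gem A gene-level `gem`.
#' @param fraction Fraction to contrast between temperatures.
#' @inheritParams rank_products
#' @return An `rp_result` tibble.
#' @export
differential_abundance <- function(gem, fraction = "total", n_perm = 1000, seed = NULL) {
  stopifnot(inherits(gem, "gem"))
  df <- tidy(gem) |>
    dplyr::filter(.data$fraction == !!fraction) |>
    dplyr::rename(gene_id = "feature_id")
  if (nrow(df) == 0) abort(sprintf("no samples for fraction '%s'", fraction))
  rank_products(paired_fc_matrix(df, "value"), n_perm = n_perm, seed = seed)
}

gene_class_levels <- c("potentiated", "te_up_t_unchanged", "te_up_t_down",
                       "te_down", "t_up_only", "t_down_only", "none")

#' Classify genes by their transcriptional and translational response
#'
#' Combines the significance calls for translational efficiency (TE) and
#' transcript abundance (T) into mutually exclusive response groups:
#' `potentiated` (TE up and T up), `te_up_t_down` (TE up despite reduced
#' transcription, e.g. the cold-shock protein family), `te_up_t_unchanged`
#' (TE up, transcription unchanged), `te_down`, and transcription-only
#' changes `t_up_only`/`t_down_only`; all remaining genes are `none`.
#'
#' @param genes Character vector of all gene ids to classify.
#' @param te_up,te_down,t_up,t_down Character vectors of gene ids called
#'   significant in each direction for TE and T at a common pfp threshold.
#' @return A tibble `gene_id`, `class` (factor), one row per input gene.
#' @export
classify_genes <- function(genes, te_up, te_down, t_up, t_down) {
  clash <- intersect(te_up, te_down)
  if (length(clash) > 0) {
    abort(sprintf("contradictory TE calls (up and down) for: %s",
                  paste(head(clash, 5), collapse = ", ")))
  }
  cls <- dplyr::case_when(
    genes %in% te_up & genes %in% t_up ~ "potentiated",
    genes %in% te_up & genes %in% t_down ~ "te_up_t_down",
    genes %in% te_up ~ "te_up_t_unchanged",
    genes %in% te_down ~ "te_down",
    genes %in% t_up ~ "t_up_only",
    genes %in% t_down ~ "t_down_only",
    TRUE ~ "none"
  )
  tibble::tibble(gene_id = genes,
                 class = factor(cls, levels = gene_class_levels))
}

#' Four-way Venn partition of gene sets
#'
#' Counts the genes in every intersection region of the supplied sets (all
#' 2^n - 1 membership patterns over the union). Region counts sum to the
#' size of the union.
#'
#' @param sets Named list of character vectors, e.g.
#'   `list(polysome_up = ..., te_up = ..., t_up = ..., t_down = ...)`.
#' @return A tibble with one logical membership column per set plus `count`.
#' @export
venn_partition <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == "")) abort("sets must be named")
  universe <- unique(unlist(sets))
  member <- purrr::map(sets, ~ universe %in% .x)
  pattern <- tidyr::expand_grid(!!!purrr::map(sets, ~ c(TRUE, FALSE))) |>
    dplyr::filter(dplyr::if_any(dplyr::everything()))
  memb_mat <- do.call(cbind, member)
  key <- apply(memb_mat, 1, paste, collapse = ".")
  pat_key <- apply(as.matrix(pattern), 1, paste, collapse = ".")
  counts <- table(key)
  pattern$count <- as.integer(counts[pat_key])
  pattern$count[is.na(pattern$count)] <- 0L
  pattern
}

#' Monosome-versus-polysome partitioning analysis
#'
#' Tests which transcripts shift between the monosome and polysome pools on
#' heat shock, then characterizes the significant genes. The contrast is the
#' per-replicate difference of differences
#' `[mono(42) - poly(42)] - [mono(30) - poly(30)]`, tested with rank
#' products. The report gives, for the significant genes (both directions
#' pooled): the fraction with ORF length < 1000 nt (with a one-tailed
#' Wilcoxon test that significant ORFs are shorter than the genome's), and
#' their mean total-RNA abundance versus the genome mean at each temperature
#' (one-tailed Wilcoxon, alternative: lower).
#'
#' @param gem A gene-level `gem` with monosome, polysome and total fractions.
#' @param orf_lengths Named numeric vector of ORF lengths in nucleotides
#'   (names = gene ids).
#' @param n_perm,seed Passed to [rank_products()].
#' @param threshold pfp significance cut-off.
#' @return A list with `rp` (the `rp_result`), `significant` (`up`/`down`
#'   gene id vectors), and `report` (a one-row tibble of the association
#'   statistics).
#' @export
monosome_partitioning <- function(gem, orf_lengths, n_perm = 1000, seed = NULL,
                                  threshold = 0.1) {
  te_mp <- compute_te(gem, numerator = "monosome", denominator = "polysome")
  rp <- differential_te(te_mp, n_perm = n_perm, seed = seed)
  sig <- call_significant(rp, threshold)
  sig_genes <- union(sig$up, sig$down)

  genes <- rp$gene_id
  missing_len <- setdiff(sig_genes, names(orf_lengths))
  if (length(missing_len) > 0) abort("ORF lengths missing for significant genes")
  len_sig <- orf_lengths[sig_genes]
  len_all <- orf_lengths[intersect(genes, names(orf_lengths))]

  total_means <- tidy(gem) |>
    dplyr::filter(.data$fraction == "total") |>
    dplyr::group_by(.data$feature_id, .data$temperature_c) |>
    dplyr::summarise(mean_abund = mean(.data$value), .groups = "drop")
  abund_report <- total_means |>
    dplyr::group_by(.data$temperature_c) |>
    dplyr::summarise(
      genome_mean = mean(.data$mean_abund),
      sig_mean = mean(.data$mean_abund[.data$feature_id %in% sig_genes]),
      wilcox_p = if (length(sig_genes) > 0) {
        wilcox.test(.data$mean_abund[.data$feature_id %in% sig_genes],
                    .data$mean_abund, alternative = "less", exact = FALSE)$p.value
      } else NA_real_,
      .groups = "drop"
    )

  report <- tibble::tibble(
    n_significant = length(sig_genes),
    frac_orf_lt_1000 = if (length(sig_genes) > 0) mean(len_sig < 1000) else NA_real_,
    length_wilcox_p = if (length(sig_genes) > 0) {
      wilcox.test(len_sig, len_all, alternative = "less", exact = FALSE)$p.value
    } else NA_real_,
    sig_mean_abund_30 = abund_report$sig_mean[abund_report$temperature_c == 30],
    genome_mean_abund_30 = abund_report$genome_mean[abund_report$temperature_c == 30],
    abund_wilcox_p_30 = abund_report$wilcox_p[abund_report$temperature_c == 30],
    sig_mean_abund_42 = abund_report$sig_mean[abund_report$temperature_c == 42],
    genome_mean_abund_42 = abund_report$genome_mean[abund_report$temperature_c == 42],
    abund_wilcox_p_42 = abund_report$wilcox_p[abund_report$temperature_c == 42]
  )
  list(rp = rp, significant = sig, report = report)
}
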