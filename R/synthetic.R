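#' Configuration for the synthetic-data generator
#'
#' Collects every parameter of the simulated study in one object. Defaults
#' mirror the design of the heat-shock polysome-profiling experiment the
#' pipeline targets: five biological replicates, three fractions (total,
#' monosome, polysome) at 30 and 42 degrees C, several probes per gene with
#' control probes and occasional negative processed signals, 74 genes with
#' enhanced translational efficiency split into potentiated /
#' transcription-unchanged / transcription-down groups, a composition-shifted
#' TE gene set (lower G+C, shorter proteins, characteristic amino-acid
#' enrichment, shifted start/stop codon usage) in a high-G+C background
#' genome, and a small monosome-shift group drawn from low-abundance, short
#' genes.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Biological replicates per condition.
#' @param probes_per_gene Probes targeting each gene's coding region.
#' @param control_probe_frac Control probes as a fraction of gene probes.
#' @param unmapped_probe_frac Non-control probes without a gene mapping.
#' @param neg_signal_frac Probability that a channel intensity is negated
#'   (emulating background-subtraction negatives).
#' @param noise_sd Biological noise SD per gene and sample, log2 units.
#' @param tech_sd Technical (per-probe, per-array) noise SD, log2 units.
#' @param probe_sd SD of per-probe affinity effects, log2 units.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 abundance law.
#' @param te_base_sd,mono_base_sd SD of per-gene baseline polysome/monosome
#'   loading offsets, log2 units.
#' @param ref_log2 Log2 intensity of the genomic-DNA reference channel.
#' @param groups Named integer vector of spiked group sizes: `potentiated`,
#'   `te_up_t_unchanged`, `te_up_t_down`, `t_up_only`, `t_down_only`,
#'   `te_down`, `mono_shift`.
#' @param delta_te,delta_t_up,delta_t_down,delta_te_down,delta_mono Spiked
#'   effect sizes in log2 units.
#' @param mono_low_abundance Log2 units subtracted from the baseline of
#'   monosome-shift genes (they come from the low-abundance stratum).
#' @param background_gc,te_set_gc Target coding G+C fraction of background
#'   genes and of the composition-shifted TE set.
#' @param length_meanlog,length_sdlog Log-normal protein-length law
#'   (codons) of background genes.
#' @param te_length_factor Multiplicative length factor for TE-set (and
#'   monosome-shift) genes.
#' @param min_codons Minimum protein length in codons.
#' @param gc_block Plant a G+C-rich 24-nt block at coding positions +52..+75
#'   in TE-set genes (a thermosensor-like feature).
#' @param pseudogene_frac Fraction of (background) genes flagged as
#'   pseudogenes.
#' @param start_freq_bg,start_freq_te Start-codon shares (ATG, GTG, TTG).
#' @param stop_freq_bg,stop_freq_te Stop-codon shares (TAA, TAG, TGA).
#' @param aa_freq_bg Background amino-acid frequencies (named, sums to 1).
#' @param aa_boost,aa_boost_factor,aa_deplete,aa_deplete_factor Amino acids
#'   enriched/depleted in the TE set and their multiplicative factors.
#' @param seed Default seed used by the simulators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_replicates = 5,
                       probes_per_gene = 3,
                       control_probe_frac = 0.05,
                       unmapped_probe_frac = 0.01,
                       neg_signal_frac = 0.01,
                       noise_sd = 0.3,
                       tech_sd = 0.1,
                       probe_sd = 0.25,
                       baseline_mean = 8,
                       baseline_sd = 1,
                       te_base_sd = 0.5,
                       mono_base_sd = 0.5,
                       ref_log2 = 10,
                       groups = c(potentiated = 15, te_up_t_unchanged = 40,
                                  te_up_t_down = 19, t_up_only = 30,
                                  t_down_only = 150, te_down = 3,
                                  mono_shift = 20),
                       delta_te = 1.5,
                       delta_t_up = 2,
                       delta_t_down = -1.5,
                       delta_te_down = -1.5,
                       delta_mono = 1.5,
                       mono_low_abundance = 1.5,
                       background_gc = 0.72,
                       te_set_gc = 0.62,
                       length_meanlog = log(250),
                       length_sdlog = 0.45,
                       te_length_factor = 0.6,
                       min_codons = 60,
                       gc_block = TRUE,
                       pseudogene_frac = 0.05,
                       start_freq_bg = c(ATG = 0.617, GTG = 0.351, TTG = 0.003),
                       start_freq_te = c(ATG = 0.657, GTG = 0.301, TTG = 0.041),
                       stop_freq_bg = c(TAA = 0.044, TAG = 0.174, TGA = 0.781),
                       stop_freq_te = c(TAA = 0.082, TAG = 0.150, TGA = 0.767),
                       aa_freq_bg = NULL,
                       aa_boost = c("E", "Q", "M", "V", "K", "I"),
                       aa_boost_factor = 1.6,
                       aa_deplete = c("A", "H", "L", "P", "W", "Y"),
                       aa_deplete_factor = 0.7,
                       seed = 1) {
  if (is.null(aa_freq_bg)) {
    # loosely actinobacteria-like usage (G+C-rich proteome)
    aa_freq_bg <- c(A = 0.120, R = 0.070, N = 0.020, D = 0.060, C = 0.006,
                    Q = 0.030, E = 0.060, G = 0.090, H = 0.020, I = 0.040,
                    L = 0.100, K = 0.020, M = 0.020, F = 0.030, P = 0.060,
                    S = 0.050, T = 0.060, W = 0.014, Y = 0.020, V = 0.080)
  }
  aa_freq_bg <- aa_freq_bg / sum(aa_freq_bg)
  cfg <- list(
    n_genes = n_genes, n_replicates = n_replicates,
    probes_per_gene = probes_per_gene,
    control_probe_frac = control_probe_frac,
    unmapped_probe_frac = unmapped_probe_frac,
    neg_signal_frac = neg_signal_frac,
    noise_sd = noise_sd, tech_sd = tech_sd, probe_sd = probe_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    te_base_sd = te_base_sd, mono_base_sd = mono_base_sd,
    ref_log2 = ref_log2,
    groups = groups,
    delta_te = delta_te, delta_t_up = delta_t_up, delta_t_down = delta_t_down,
    delta_te_down = delta_te_down, delta_mono = delta_mono,
    mono_low_abundance = mono_low_abundance,
    background_gc = background_gc, te_set_gc = te_set_gc,
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    te_length_factor = te_length_factor, min_codons = min_codons,
    gc_block = gc_block, pseudogene_frac = pseudogene_frac,
    start_freq_bg = start_freq_bg / sum(start_freq_bg),
    start_freq_te = start_freq_te / sum(start_freq_te),
    stop_freq_bg = stop_freq_bg / sum(stop_freq_bg),
    stop_freq_te = stop_freq_te / sum(stop_freq_te),
    aa_freq_bg = aa_freq_bg,
    aa_boost = aa_boost, aa_boost_factor = aa_boost_factor,
    aa_deplete = aa_deplete, aa_deplete_factor = aa_deplete_factor,
    seed = seed
  )
  if (sum(groups) > n_genes) abort("spiked group sizes exceed n_genes")
  structure(cfg, class = "sim_config")
}

te_classes <- c("potentiated", "te_up_t_unchanged", "te_up_t_down")

assign_gene_classes <- function(cfg) {
  classes <- rep("none", cfg$n_genes)
  idx <- sample.int(cfg$n_genes, sum(cfg$groups))
  classes[idx] <- rep(names(cfg$groups), cfg$groups)
  classes
}

# amino-acid frequency vector of the composition-shifted TE set
te_aa_freq <- function(cfg) {
  f <- cfg$aa_freq_bg
  f[cfg$aa_boost] <- f[cfg$aa_boost] * cfg$aa_boost_factor
  f[cfg$aa_deplete] <- f[cfg$aa_deplete] * cfg$aa_deplete_factor
  f / sum(f)
}

# Within-family codon weights proportional to w^(G+C count of the codon),
# with w solved so that the expected coding G+C equals `gc_target` given the
# amino-acid frequencies. Errors when the target is outside the range the
# amino-acid composition permits.
codon_distribution <- function(aa_freq, gc_target) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  fam <- split(sense, code[sense])
  gc_count <- vapply(sense, function(cd) {
    sum(strsplit(cd, "")[[1]] %in% c("G", "C"))
  }, numeric(1))
  expected_gc <- function(logw) {
    w <- exp(logw)
    per_aa <- vapply(names(fam), function(a) {
      cods <- fam[[a]]
      p <- w^gc_count[cods]
      sum(p / sum(p) * gc_count[cods])
    }, numeric(1))
    sum(aa_freq[names(fam)] * per_aa) / 3
  }
  lo <- expected_gc(-12)
  hi <- expected_gc(12)
  if (gc_target < lo || gc_target > hi) {
    abort(sprintf(
      "contradictory composition targets: G+C %.3f unreachable (range %.3f-%.3f) for the given amino-acid frequencies",
      gc_target, lo, hi))
  }
  logw <- uniroot(function(x) expected_gc(x) - gc_target, c(-12, 12))$root
  w <- exp(logw)
  probs <- lapply(fam, function(cods) {
    p <- w^gc_count[cods]
    setNames(p / sum(p), cods)
  })
  list(families = fam, probs = probs)
}

# sample interior codons for many genes at once; returns list of codon vectors
sample_codons <- function(n_per_gene, aa_freq, dist) {
  total <- sum(n_per_gene)
  aa <- sample(names(aa_freq), total, replace = TRUE, prob = aa_freq)
  codons <- character(total)
  for (a in unique(aa)) {
    sel <- which(aa == a)
    p <- dist$probs[[a]]
    codons[sel] <- sample(names(p), length(sel), replace = TRUE, prob = p)
  }
  split(codons, rep(seq_along(n_per_gene), n_per_gene))
}

random_dna <- function(n, gc) {
  if (n == 0) return("")
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate an annotated genome with a composition-shifted gene set
#'
#' Generates a single-contig genome whose genes are drawn codon by codon
#' from a G+C-parameterized codon distribution. Genes belonging to the TE
#' (translationally enhanced) set use a lower-G+C codon distribution, a
#' shorter length law, amino-acid targets enriched for E/Q/M/V/K/I and
#' depleted for A/H/L/P/W/Y, shifted start/stop codon shares, and (by
#' default) a G+C-rich block near coding position +63; their upstream
#' regions share the low G+C. Genes are separated by 100-bp intergenic
#' spacers (which carry the 50-bp upstream windows), placed on random
#' strands, and a fraction of background genes is flagged as pseudogenes.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`); fixed seed gives
#'   byte-identical output.
#' @return A list of class `sim_genome` with elements `genome` (a CDS record
#'   tibble as from [read_genome()]), `contig` (the chromosome sequence as a
#'   string), `truth` (per-gene class labels and TE-set membership) and
#'   `cfg`.
#' @export
simulate_genome <- function(cfg = sim_config(), seed = cfg$seed) {
  dist_bg <- codon_distribution(cfg$aa_freq_bg, cfg$background_gc)
  aa_te <- te_aa_freq(cfg)
  dist_te <- codon_distribution(aa_te, cfg$te_set_gc)

  with_seed(seed, {
    n <- cfg$n_genes
    gene_id <- sprintf("G%04d", seq_len(n))
    class <- assign_gene_classes(cfg)
    in_te_set <- class %in% te_classes
    short <- in_te_set | class == "mono_shift"
    eligible_pseudo <- which(!in_te_set & class != "mono_shift")
    is_pseudogene <- rep(FALSE, n)
    is_pseudogene[sample(eligible_pseudo,
                         round(cfg$pseudogene_frac * n))] <- TRUE

    n_codons <- pmax(round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog) *
                             ifelse(short, cfg$te_length_factor, 1)),
                     cfg$min_codons)

    interior <- vector("list", n)
    for (grp in list(list(sel = in_te_set, aa = aa_te, dist = dist_te),
                     list(sel = !in_te_set, aa = cfg$aa_freq_bg, dist = dist_bg))) {
      sel <- which(grp$sel)
      if (length(sel) > 0) {
        interior[sel] <- sample_codons(n_codons[sel] - 1, grp$aa, grp$dist)
      }
    }

    starts <- character(n)
    stops <- character(n)
    starts[in_te_set] <- sample(names(cfg$start_freq_te), sum(in_te_set),
                                replace = TRUE, prob = cfg$start_freq_te)
    starts[!in_te_set] <- sample(names(cfg$start_freq_bg), sum(!in_te_set),
                                 replace = TRUE, prob = cfg$start_freq_bg)
    stops[in_te_set] <- sample(names(cfg$stop_freq_te), sum(in_te_set),
                               replace = TRUE, prob = cfg$stop_freq_te)
    stops[!in_te_set] <- sample(names(cfg$stop_freq_bg), sum(!in_te_set),
                                replace = TRUE, prob = cfg$stop_freq_bg)

    if (cfg$gc_block) {
      gc_rich <- c("GGC", "GCC", "CGC", "CCG")
      for (i in which(in_te_set)) {
        # codons 17..24 of the interior = coding positions +52..+75, so the
        # planted block is centred near +63
        if (length(interior[[i]]) >= 24) {
          interior[[i]][17:24] <- sample(gc_rich, 8, replace = TRUE)
        }
      }
    }

    cds <- vapply(seq_len(n), function(i) {
      paste0(starts[i], paste(interior[[i]], collapse = ""), stops[i])
    }, character(1))

    gene_gc <- ifelse(in_te_set, cfg$te_set_gc, cfg$background_gc)
    upstream50 <- vapply(gene_gc, function(g) random_dna(50, g), character(1))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    # spacer i precedes gene i; 100 bp each, one trailing spacer at the end.
    # A plus-strand gene's upstream window is the last 50 bp of its leading
    # spacer; a minus-strand gene's is the first 50 bp of the following
    # spacer, reverse-complemented.
    spacers <- vapply(seq_len(n + 1), function(i) random_dna(100, cfg$background_gc),
                      character(1))
    for (i in seq_len(n)) {
      if (strand[i] == "+") {
        substr(spacers[i], 51, 100) <- upstream50[i]
      } else {
        substr(spacers[i + 1], 1, 50) <- revcomp_chr(upstream50[i])
      }
    }

    genomic <- ifelse(strand == "+", cds, vapply(cds, revcomp_chr, character(1)))
    pieces <- character(2 * n + 1)
    pieces[seq(1, 2 * n + 1, by = 2)] <- spacers
    pieces[seq(2, 2 * n, by = 2)] <- genomic
    contig <- paste(pieces, collapse = "")

    width <- nchar(genomic)
    start_pos <- as.integer(100 + cumsum(c(0, head(width, -1) + 100)) + 1)
    end_pos <- as.integer(start_pos + width - 1)

    genome <- tibble::tibble(
      gene_id = gene_id, seqid = "chr1",
      start = start_pos, end = end_pos, strand = strand,
      cds = cds, upstream50 = upstream50,
      protein = translate_cds(cds),
      is_pseudogene = is_pseudogene,
      length_ok = TRUE
    )
    truth <- tibble::tibble(gene_id = gene_id, class = class,
                            in_te_set = in_te_set,
                            is_pseudogene = is_pseudogene)
    structure(list(genome = genome, contig = contig, truth = truth, cfg = cfg),
              class = "sim_genome")
  })
}

#' Write a simulated genome as FASTA + GFF3
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param fasta_path,gff_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome_files <- function(sim, fasta_path, gff_path) {
  contig <- Biostrings::DNAStringSet(sim$contig)
  names(contig) <- "chr1"
  Biostrings::writeXStringSet(contig, fasta_path)
  g <- sim$genome
  attrs <- sprintf("ID=cds-%s;gene_id=%s%s", g$gene_id, g$gene_id,
                   ifelse(g$is_pseudogene, ";pseudo=true", ""))
  lines <- c("##gff-version 3",
             sprintf("##sequence-region chr1 1 %d", nchar(sim$contig)),
             sprintf("chr1\ttranslatomics\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     g$start, g$end, g$strand, attrs))
  writeLines(lines, gff_path)
  invisible(list(fasta = fasta_path, gff = gff_path))
}

#' Simulate a replicated two-channel microarray experiment
#'
#' Generates probe-level intensity tables for every combination of fraction
#' (total, monosome, polysome), temperature (30, 42) and biological
#' replicate, with known per-gene ground truth. Per-gene baseline log2
#' abundances are normal; spiked groups add their transcription (`delta_t`),
#' translational-efficiency (`delta_te`) and monosome-shift (`delta_mono`)
#' effects at 42 degrees C. Biological noise is drawn once per gene,
#' replicate and temperature and shared by the three fractions of that
#' culture: each biological replicate is one culture whose RNA is split into
#' the total, monosome and polysome pools, so culture-to-culture variation
#' moves the fractions together (and largely cancels from within-replicate
#' efficiency ratios), while technical noise is independent per probe and
#' array. Channel intensities are formed
#' as `reference = 2^(ref_log2 + probe effect + technical noise)` and
#' `signal = reference-scale x 2^(gene log-ratio)`; a fraction of channel
#' entries is negated to exercise the negative-value rules, and control and
#' unmapped probes are appended.
#'
#' @param cfg A [sim_config()].
#' @param genome Optional `sim_genome` whose gene ids, classes and TE-set
#'   membership are reused, tying expression truth to sequence truth.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return A list of class `sim_experiment`: `probe_tables` (named list of
#'   `probe_table` tibbles), `samples` (metadata tibble), `probe_map`,
#'   `truth` (per-gene class, effect sizes, baseline), and `cfg`.
#' @export
simulate_experiment <- function(cfg = sim_config(), genome = NULL,
                                seed = cfg$seed) {
  with_seed(seed, {
    n <- cfg$n_genes
    if (!is.null(genome)) {
      stopifnot(inherits(genome, "sim_genome"))
      if (nrow(genome$truth) != n) abort("genome and config disagree on n_genes")
      gene_id <- genome$truth$gene_id
      class <- genome$truth$class
    } else {
      gene_id <- sprintf("G%04d", seq_len(n))
      class <- assign_gene_classes(cfg)
    }
    delta_t <- dplyr::case_when(
      class %in% c("potentiated", "t_up_only") ~ cfg$delta_t_up,
      class %in% c("te_up_t_down", "t_down_only") ~ cfg$delta_t_down,
      TRUE ~ 0
    )
    delta_te <- dplyr::case_when(
      class %in% te_classes ~ cfg$delta_te,
      class == "te_down" ~ cfg$delta_te_down,
      TRUE ~ 0
    )
    delta_mono <- ifelse(class == "mono_shift", cfg$delta_mono, 0)

    baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd) -
      ifelse(class == "mono_shift", cfg$mono_low_abundance, 0)
    te_base <- rnorm(n, 0, cfg$te_base_sd)
    mono_base <- rnorm(n, 0, cfg$mono_base_sd)

    samples <- tidyr::expand_grid(
      fraction = c("total", "monosome", "polysome"),
      temperature_c = c(30L, 42L),
      replicate = seq_len(cfg$n_replicates)
    ) |>
      purrr::pmap(array_sample) |>
      dplyr::bind_rows()

    # culture-level biological noise: one draw per gene x replicate x
    # temperature, shared across the three fractions of that culture
    bio <- array(rnorm(n * cfg$n_replicates * 2, 0, cfg$noise_sd),
                 dim = c(n, cfg$n_replicates, 2),
                 dimnames = list(NULL, NULL, c("30", "42")))

    expr_value <- function(fraction, temperature_c, replicate) {
      hot <- temperature_c == 42L
      total <- baseline + hot * delta_t
      mu <- switch(fraction,
                   total = total,
                   polysome = total + te_base + hot * delta_te,
                   monosome = total + mono_base + hot * delta_mono)
      mu + bio[, replicate, as.character(temperature_c)]
    }

    n_gene_probes <- n * cfg$probes_per_gene
    probe_map <- tibble::tibble(
      probe_id = sprintf("P%06d", seq_len(n_gene_probes)),
      gene_id = rep(gene_id, each = cfg$probes_per_gene)
    )
    n_unmapped <- round(cfg$unmapped_probe_frac * n_gene_probes)
    n_ctrl <- round(cfg$control_probe_frac * n_gene_probes)
    unmapped_ids <- if (n_unmapped > 0) sprintf("U%05d", seq_len(n_unmapped)) else character(0)
    ctrl_ids <- if (n_ctrl > 0) sprintf("CTRL%05d", seq_len(n_ctrl)) else character(0)
    probe_effect <- rnorm(n_gene_probes + n_unmapped, 0, cfg$probe_sd)

    gene_idx <- rep(seq_len(n), each = cfg$probes_per_gene)
    probe_tables <- vector("list", nrow(samples))
    names(probe_tables) <- samples$sample_id
    for (s in seq_len(nrow(samples))) {
      mu <- expr_value(samples$fraction[s], samples$temperature_c[s],
                       samples$replicate[s])
      ratio <- (mu - cfg$baseline_mean)[gene_idx]
      ratio_un <- rnorm(n_unmapped, 0, 1)
      all_ratio <- c(ratio, ratio_un)
      n_main <- n_gene_probes + n_unmapped
      ref <- 2^(cfg$ref_log2 + probe_effect + rnorm(n_main, 0, cfg$tech_sd))
      sig <- ref * 2^(all_ratio + rnorm(n_main, 0, cfg$tech_sd))
      ctrl_ref <- 2^rnorm(n_ctrl, cfg$ref_log2, 1)
      ctrl_sig <- 2^rnorm(n_ctrl, cfg$ref_log2, 1)
      signal <- c(sig, ctrl_sig)
      reference <- c(ref, ctrl_ref)
      if (cfg$neg_signal_frac > 0) {
        # background subtraction produces negatives at the dim end of the
        # intensity distribution, so negation targets low-intensity entries
        negate_low <- function(x) {
          m <- length(x)
          n_flip <- round(cfg$neg_signal_frac * m)
          if (n_flip == 0) return(x)
          cand <- which(x <= stats::quantile(x, min(1, 5 * cfg$neg_signal_frac)))
          flip <- sample(cand, min(n_flip, length(cand)))
          x[flip] <- -x[flip]
          x
        }
        signal <- negate_low(signal)
        reference <- negate_low(reference)
      }
      tb <- tibble::tibble(
        probe_id = c(probe_map$probe_id, unmapped_ids, ctrl_ids),
        gene_id = c(probe_map$gene_id, rep(NA_character_, n_unmapped + n_ctrl)),
        is_control = c(rep(FALSE, n_main), rep(TRUE, n_ctrl)),
        signal = signal,
        reference = reference
      )
      probe_tables[[s]] <- new_probe_table(tb, samples[s, ])
    }

    truth <- tibble::tibble(
      gene_id = gene_id, class = class,
      in_te_set = class %in% te_classes,
      delta_t = delta_t, delta_te = delta_te, delta_mono = delta_mono,
      baseline = baseline
    )
    structure(list(probe_tables = probe_tables, samples = samples,
                   probe_map = probe_map, truth = truth, cfg = cfg),
              class = "sim_experiment")
  })
}

#' Write a simulated experiment to disk
#'
#' Emits one probe TSV per array under `dir/probes/`, plus `meta.tsv`,
#' `probemap.tsv` and `truth.tsv`.
#'
#' @param sim A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment_files <- function(sim, dir) {
  dir.create(file.path(dir, "probes"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(sim$probe_tables)) {
    readr::write_tsv(tibble::as_tibble(sim$probe_tables[[nm]]),
                     file.path(dir, "probes", paste0(nm, ".tsv")), progress = FALSE)
  }
  readr::write_tsv(sim$samples[c("sample_id", "fraction", "temperature_c", "replicate")],
                   file.path(dir, "meta.tsv"), progress = FALSE)
  readr::write_tsv(sim$probe_map, file.path(dir, "probemap.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
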