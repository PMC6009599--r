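#' @keywords internal
#' @noRd
NULL

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 59 informative sense codons: stops excluded, single-codon families
# (ATG/Met, TGG/Trp) excluded because their usage is fully constrained
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  fam <- tibble::tibble(codon = names(gc), aa = unname(gc))
  fam <- fam[fam$aa != "*", ]
  sizes <- table(fam$aa)
  fam[fam$aa %in% names(sizes[sizes > 1]), ]
}

subset_genome <- function(genome, gene_set) {
  if (is.null(gene_set)) return(genome)
  missing <- setdiff(gene_set, genome$gene_id)
  if (length(missing) > 0) {
    abort(sprintf("gene set members absent from genome: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  genome[match(gene_set, genome$gene_id), ]
}

gc_percent <- function(x) {
  x <- x[nchar(x) > 0]
  if (length(x) == 0) return(numeric(0))
  s <- Biostrings::DNAStringSet(x)
  100 * as.numeric(Biostrings::letterFrequency(s, "GC")) / Biostrings::width(s)
}

# per-gene codon count matrix over the CDS interior (start and stop excluded)
codon_count_matrix <- function(cds) {
  n_codon <- nchar(cds) %/% 3
  interior <- substr(cds, 4, pmax(3, (n_codon - 1) * 3))
  interior[n_codon < 3] <- ""
  m <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(interior), step = 3)
  rownames(m) <- NULL
  m
}

aa_count_matrix <- function(protein) {
  s <- Biostrings::AAStringSet(protein)
  m <- Biostrings::letterFrequency(s, aa_alphabet)
  colnames(m) <- aa_alphabet
  rownames(m) <- NULL
  m
}

new_null_comparison <- function(statistic, observed, null_values, n_sets, seed,
                                extra = NULL) {
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  if (!is.finite(null_sd) || null_sd == 0) {
    warn(sprintf("degenerate null distribution for '%s' (sd = 0)", statistic[1]))
    z <- NA_real_
  } else {
    z <- (observed - null_mean) / null_sd
  }
  out <- tibble::tibble(
    statistic = statistic,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    significant = !is.na(z) & abs(z) > 2,
    direction = dplyr::case_when(
      is.na(z) | abs(z) <= 2 ~ "none",
      z > 2 ~ "higher",
      TRUE ~ "lower"
    ),
    n_sets = n_sets,
    seed = seed %||% NA_integer_
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, class = c("null_comparison", class(out)))
}

# column-wise null: observed row vector vs matrix of per-set row vectors
null_comparison_vec <- function(statistics, observed, null_matrix, n_sets, seed,
                                extra = NULL) {
  null_mean <- colMeans(null_matrix)
  null_sd <- apply(null_matrix, 2, stats::sd)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  if (any(null_sd == 0)) {
    warn("degenerate null distribution (sd = 0) for some statistics")
  }
  out <- tibble::tibble(
    statistic = statistics,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    significant = !is.na(z) & abs(z) > 2,
    direction = dplyr::case_when(
      is.na(z) | abs(z) <= 2 ~ "none",
      z > 2 ~ "higher",
      TRUE ~ "lower"
    ),
    n_sets = n_sets,
    seed = seed %||% NA_integer_
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, extra)
  structure(out, class = c("null_comparison", class(out)))
}

#' Draw random gene sets from the genome
#'
#' Samples `n_sets` sets of `set_size` genes, uniformly without replacement
#' within each set and independently across sets, from all protein-coding
#' genes excluding pseudogenes. These random sets form the null distribution
#' against which a significant gene set's composition statistics are
#' compared.
#'
#' @param genome CDS record tibble (see [read_genome()]).
#' @param set_size Genes per set.
#' @param n_sets Number of sets (default 1000).
#' @param seed Integer seed for reproducibility.
#' @return A list of `n_sets` character vectors of gene ids.
#' @export
sample_random_sets <- function(genome, set_size, n_sets = 1000, seed = NULL) {
  eligible <- genome$gene_id[!genome$is_pseudogene]
  if (set_size > length(eligible)) {
    abort(sprintf("set_size (%d) exceeds eligible gene count (%d)",
                  set_size, length(eligible)))
  }
  with_seed(seed, purrr::map(seq_len(n_sets), ~ sample(eligible, set_size)))
}

#' Protein length of a gene set versus resampled null
#'
#' Compares the total amino-acid residue count of a gene set against the
#' null distribution of total residues over random same-size gene sets
#' (flagging |z| > 2), and additionally tests with a one-tailed Wilcoxon
#' rank-sum test whether the set's per-protein lengths are shorter than the
#' genome-wide lengths.
#'
#' @param sig_set Character vector of gene ids.
#' @param genome CDS record tibble.
#' @param null_sets List of random gene-id sets (see [sample_random_sets()]).
#' @param seed Seed recorded in the output (provenance only).
#' @return A one-row `null_comparison` tibble with an extra `wilcox_p`
#'   column.
#' @export
protein_length_stats <- function(sig_set, genome, null_sets, seed = NULL) {
  if (length(sig_set) == 0) abort("empty gene set")
  len <- setNames(nchar(genome$protein), genome$gene_id)
  obs_len <- len[sig_set]
  if (anyNA(obs_len)) abort("gene set members absent from genome")
  null_totals <- vapply(null_sets, function(s) sum(len[s]), numeric(1))
  wp <- wilcox.test(unname(obs_len), unname(len), alternative = "less",
                    exact = FALSE)$p.value
  new_null_comparison("total_protein_residues", sum(obs_len), null_totals,
                      length(null_sets), seed,
                      extra = tibble::tibble(wilcox_p = wp))
}

#' Pooled amino-acid frequencies of a gene set
#'
#' Frequency of use of each amino acid per 100 residues, pooled over all
#' proteins of the set (total count of the residue divided by total residues,
#' times 100). Frequencies sum to 100.
#'
#' @param genome CDS record tibble.
#' @param gene_set Optional character vector restricting to a set; `NULL`
#'   uses all genes.
#' @return A tibble `aa`, `count`, `freq`.
#' @export
aa_frequency <- function(genome, gene_set = NULL) {
  g <- subset_genome(genome, gene_set)
  counts <- colSums(aa_count_matrix(g$protein))
  total <- sum(counts)
  if (total == 0) abort("no residues in gene set")
  tibble::tibble(aa = aa_alphabet, count = unname(counts),
                 freq = 100 * unname(counts) / total)
}

#' Amino-acid composition of a gene set versus resampled null
#'
#' Per-amino-acid pooled frequency (per 100 residues) of the set compared to
#' the null distribution over random gene sets; |z| > 2 flags a residue as
#' used significantly more (`higher`) or less (`lower`) often. An empirical
#' tail probability against the null sets is reported alongside.
#'
#' @inheritParams protein_length_stats
#' @return A 20-row `null_comparison` tibble (one per amino acid) with an
#'   `empirical_p` column.
#' @export
aa_frequency_stats <- function(sig_set, genome, null_sets, seed = NULL) {
  counts <- aa_count_matrix(genome$protein)
  rownames(counts) <- genome$gene_id
  freq_of <- function(s) {
    cs <- colSums(counts[s, , drop = FALSE])
    100 * cs / sum(cs)
  }
  obs <- freq_of(sig_set)
  null_m <- t(vapply(null_sets, freq_of, numeric(length(aa_alphabet))))
  emp <- vapply(seq_along(obs), function(i) {
    hi <- mean(null_m[, i] >= obs[i])
    lo <- mean(null_m[, i] <= obs[i])
    min(hi, lo)
  }, numeric(1))
  null_comparison_vec(aa_alphabet, unname(obs), null_m, length(null_sets), seed,
                      extra = tibble::tibble(empirical_p = emp))
}

#' Per-gene G+C content in three windows
#'
#' G+C percentage of (i) the 50 bp upstream of the start codon, (ii) the
#' first 50 coding bp, and (iii) the full coding sequence, for each gene of
#' a set. Genes with truncated upstream regions are flagged.
#'
#' @inheritParams aa_frequency
#' @return A tibble `gene_id`, `upstream50_gc`, `downstream50_gc`,
#'   `full_cds_gc`, `upstream_complete`.
#' @export
gc_windows <- function(genome, gene_set = NULL) {
  g <- subset_genome(genome, gene_set)
  up_gc <- rep(NA_real_, nrow(g))
  has_up <- nchar(g$upstream50) > 0
  up_gc[has_up] <- gc_percent(g$upstream50[has_up])
  tibble::tibble(
    gene_id = g$gene_id,
    upstream50_gc = up_gc,
    downstream50_gc = gc_percent(substr(g$cds, 1, 50)),
    full_cds_gc = gc_percent(g$cds),
    upstream_complete = nchar(g$upstream50) == 50
  )
}

#' G+C window composition of a gene set versus null and genome
#'
#' Set-mean G+C of the three windows of [gc_windows()] compared (i) to the
#' null distribution of set means over random gene sets (|z| > 2 rule) and
#' (ii) to the genome-wide per-gene values by one-tailed Welch t-tests
#' (alternative: the set is lower). Genes with incomplete upstream windows
#' are dropped from the upstream statistic with a warning.
#'
#' @inheritParams protein_length_stats
#' @return A 3-row `null_comparison` tibble with a `t_p` column.
#' @export
gc_window_stats <- function(sig_set, genome, null_sets, seed = NULL) {
  all_gc <- gc_windows(genome)
  if (any(!all_gc$upstream_complete)) {
    warn(sprintf("%d gene(s) with truncated upstream window dropped from upstream G+C",
                 sum(!all_gc$upstream_complete)))
  }
  cols <- c("upstream50_gc", "downstream50_gc", "full_cds_gc")
  set_mean <- function(s) {
    rows <- all_gc[match(s, all_gc$gene_id), ]
    c(mean(rows$upstream50_gc[rows$upstream_complete], na.rm = TRUE),
      mean(rows$downstream50_gc), mean(rows$full_cds_gc))
  }
  obs <- set_mean(sig_set)
  null_m <- t(vapply(null_sets, set_mean, numeric(3)))
  t_p <- vapply(seq_along(cols), function(i) {
    x <- all_gc[[cols[i]]][match(sig_set, all_gc$gene_id)]
    if (cols[i] == "upstream50_gc") x <- x[!is.na(x)]
    t.test(x, all_gc[[cols[i]]], alternative = "less")$p.value
  }, numeric(1))
  null_comparison_vec(cols, obs, null_m, length(null_sets), seed,
                      extra = tibble::tibble(t_p = t_p))
}

#' Positional G+C profile around the start codon
#'
#' Mean G+C fraction (as a percentage) in a sliding window of half-width
#' `half_window` centred at each position relative to the start codon.
#' Position +1 is the first base of the start codon, -1 the last upstream
#' base; there is no position 0. At each position, genes whose sequence does
#' not cover that position are excluded; windows are clipped at sequence
#' ends.
#'
#' @inheritParams aa_frequency
#' @param half_window Window half-width in nt (default 12, i.e. 25-nt
#'   windows).
#' @param positions Integer positions to profile (default -50..+300,
#'   excluding 0).
#' @return A tibble `position`, `gc` (mean percent), `n_genes`.
#' @export
gc_positional_profile <- function(genome, gene_set = NULL, half_window = 12,
                                  positions = setdiff(-50:300, 0)) {
  g <- subset_genome(genome, gene_set)
  positions <- positions[positions != 0]
  acc_sum <- numeric(length(positions))
  acc_n <- integer(length(positions))
  for (i in seq_len(nrow(g))) {
    seq_full <- paste0(g$upstream50[i], g$cds[i])
    n_up <- nchar(g$upstream50[i])
    L <- nchar(seq_full)
    is_gc <- strsplit(chartr("GCATN", "11000", seq_full), "")[[1]] == "1"
    cs <- c(0, cumsum(is_gc))
    # label -> index: upstream labels -n_up..-1 map to 1..n_up, coding +1.. to n_up+1..
    to_idx <- function(lab) ifelse(lab < 0, lab + n_up + 1, lab + n_up)
    p_idx <- to_idx(positions)
    covered <- p_idx >= 1 & p_idx <= L
    # a window bound falling on the nonexistent label 0 snaps inward
    lo <- pmax(to_idx(ifelse(positions - half_window == 0, 1, positions - half_window)), 1)
    hi <- pmin(to_idx(ifelse(positions + half_window == 0, -1, positions + half_window)), L)
    frac <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
    acc_sum[covered] <- acc_sum[covered] + 100 * frac[covered]
    acc_n[covered] <- acc_n[covered] + 1L
  }
  tibble::tibble(position = positions,
                 gc = ifelse(acc_n > 0, acc_sum / pmax(acc_n, 1L), NA_real_),
                 n_genes = acc_n)
}

#' Relative synonymous codon usage of a gene set
#'
#' RSCU of each sense codon, pooled over the coding sequences of the set:
#' the observed count of a codon divided by the mean count over its
#' synonymous family (1 = no bias within the family). Start and stop codons
#' are excluded from counting (their identity is constrained; stop-codon
#' choice is tabulated separately by [start_stop_usage()]), and the
#' single-codon families ATG (Met) and TGG (Trp) are omitted, leaving 59
#' codons.
#'
#' @inheritParams aa_frequency
#' @return A 59-row tibble `codon`, `aa`, `count`, `rscu`. Within each
#'   family with nonzero usage the RSCU values average to exactly 1.
#' @export
rscu <- function(genome, gene_set = NULL) {
  g <- subset_genome(genome, gene_set)
  fam <- codon_families()
  counts <- colSums(codon_count_matrix(g$cds))[fam$codon]
  fam$count <- unname(counts)
  fam |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(rscu = if (sum(.data$count) > 0) .data$count / mean(.data$count)
                  else NA_real_) |>
    dplyr::ungroup()
}

#' RSCU of a gene set versus resampled null
#'
#' Per-codon RSCU of the set compared against the null distribution of RSCU
#' over random gene sets; codons with |z| > 2 are flagged as used more
#' (`higher`) or less (`lower`) than expected.
#'
#' @inheritParams protein_length_stats
#' @return A 59-row `null_comparison` tibble with an `aa` column.
#' @export
rscu_stats <- function(sig_set, genome, null_sets, seed = NULL) {
  fam <- codon_families()
  counts <- codon_count_matrix(genome$cds)[, fam$codon, drop = FALSE]
  rownames(counts) <- genome$gene_id
  fam_idx <- split(seq_len(nrow(fam)), fam$aa)
  rscu_of <- function(s) {
    cs <- colSums(counts[s, , drop = FALSE])
    out <- numeric(length(cs))
    for (idx in fam_idx) {
      m <- mean(cs[idx])
      out[idx] <- if (m > 0) cs[idx] / m else NA_real_
    }
    out
  }
  obs <- rscu_of(sig_set)
  null_m <- t(vapply(null_sets, rscu_of, numeric(nrow(fam))))
  null_comparison_vec(fam$codon, obs, null_m, length(null_sets), seed,
                      extra = tibble::tibble(aa = fam$aa))
}

#' Start and stop codon usage of a gene set
#'
#' Percentage of genes using each start codon (ATG/GTG/TTG/other) and each
#' stop codon (TAA/TAG/TGA/other); percentages sum to 100 within each
#' category.
#'
#' @inheritParams aa_frequency
#' @return A tibble `category`, `codon`, `n`, `percent`.
#' @export
start_stop_usage <- function(genome, gene_set = NULL) {
  g <- subset_genome(genome, gene_set)
  starts <- substr(g$cds, 1, 3)
  stops <- substr(g$cds, nchar(g$cds) - 2, nchar(g$cds))
  tab <- function(x, canon, category) {
    x[!x %in% canon] <- "other"
    lv <- c(canon, if (any(x == "other")) "other")
    tt <- table(factor(x, levels = lv))
    tibble::tibble(category = category, codon = names(tt),
                   n = as.integer(tt), percent = 100 * as.integer(tt) / length(x))
  }
  dplyr::bind_rows(tab(starts, c("ATG", "GTG", "TTG"), "start"),
                   tab(stops, c("TAA", "TAG", "TGA"), "stop"))
}

#' Full sequence-composition battery for a significant gene set
#'
#' Runs the composition characterization of a significant gene set against
#' the genome: protein length, amino-acid frequencies, G+C windows and
#' positional profile, RSCU, and start/stop codon usage, each compared
#' against `n_sets` random same-size gene sets drawn from the protein-coding,
#' non-pseudogene fraction of the genome, with the |z| > 2 flagging rule and
#' the one-tailed Wilcoxon/t-tests.
#'
#' @param sig_set Character vector of gene ids.
#' @param genome CDS record tibble (see [read_genome()] /
#'   [simulate_genome()]).
#' @param n_sets Number of random sets (default 1000).
#' @param seed Integer seed for the random-set draw.
#' @param half_window Half-width of the positional G+C profile window.
#' @return An object of class `composition_battery`: a list with elements
#'   `length`, `aa`, `gc`, `rscu` (each a `null_comparison` tibble),
#'   `start_stop`, `start_stop_genome`, and `profile`.
#' @export
composition_battery <- function(sig_set, genome, n_sets = 1000, seed = NULL,
                                half_window = 12) {
  null_sets <- sample_random_sets(genome, length(sig_set), n_sets, seed)
  structure(list(
    length = protein_length_stats(sig_set, genome, null_sets, seed = seed),
    aa = aa_frequency_stats(sig_set, genome, null_sets, seed = seed),
    gc = suppressWarnings(gc_window_stats(sig_set, genome, null_sets, seed = seed)),
    rscu = rscu_stats(sig_set, genome, null_sets, seed = seed),
    start_stop = start_stop_usage(genome, sig_set),
    start_stop_genome = start_stop_usage(genome[!genome$is_pseudogene, ]),
    profile = gc_positional_profile(genome, sig_set, half_window = half_window),
    n_sets = n_sets,
    seed = seed
  ), class = "composition_battery")
}

#' @describeIn composition_battery All null-comparison rows bound into one
#'   tibble with a `panel` column.
#' @param x A `composition_battery`.
#' @param ... Unused.
#' @export
tidy.composition_battery <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$length), panel = "length"),
    dplyr::mutate(tibble::as_tibble(x$aa), panel = "aa"),
    dplyr::mutate(tibble::as_tibble(x$gc), panel = "gc"),
    dplyr::mutate(tibble::as_tibble(x$rscu), panel = "rscu")
  ) |> dplyr::relocate("panel")
}

#' @describeIn composition_battery Flag counts across the battery.
#' @export
glance.composition_battery <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_statistics = nrow(td),
    n_flagged = sum(td$significant),
    flag_rate = mean(td$significant),
    n_sets = x$n_sets,
    seed = x$seed %||% NA_integer_
  )
}

#' @describeIn composition_battery z-score overview plot of the battery.
#' @param object A `composition_battery`.
#' @export
autoplot.composition_battery <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$statistic, y = .data$z,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed") +
    ggplot2::facet_grid(. ~ .data$panel, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(higher = "red", lower = "blue",
                                          none = "grey70")) +
    ggplot2::labs(x = NULL, y = "z vs random sets") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}

#' Plot a positional G+C profile
#'
#' @param profile Tibble from [gc_positional_profile()] (optionally with a
#'   `set` column to draw several profiles).
#' @return A ggplot.
#' @export
plot_gc_profile <- function(profile) {
  aes <- if ("set" %in% names(profile)) {
    ggplot2::aes(x = .data$position, y = .data$gc, colour = .data$set)
  } else {
    ggplot2::aes(x = .data$position, y = .data$gc)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "position relative to start codon (nt)",
                  y = "mean G+C (%)") +
    ggplot2::theme_minimal()
}
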