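#' Run the full transcriptome/translatome analysis
#'
#' Chains every stage of the analysis on one experiment: GEM construction
#' ([build_gem()]), rank-products contrasts for total-RNA abundance,
#' polysome abundance and translational efficiency ([differential_abundance()],
#' [differential_te()]), gene classification ([classify_genes()]), the
#' four-way Venn partition ([venn_partition()]), monosome-vs-polysome
#' partitioning ([monosome_partitioning()]) when a monosome fraction is
#' present, and the sequence-composition battery ([composition_battery()])
#' when a genome is supplied. All stochastic stages are driven by `seed`.
#'
#' @param probe_tables Named list of `probe_table` objects (e.g. from
#'   [simulate_experiment()] or [read_probe_table()]).
#' @param samples Optional sample metadata overriding per-table attributes.
#' @param genome Optional CDS record tibble (from [read_genome()] or
#'   `simulate_genome()$genome`) enabling the composition battery and
#'   supplying ORF lengths.
#' @param pfp pfp significance cut-off (default 0.1).
#' @param n_perm Permutations per rank-products run.
#' @param n_sets Random sets for the composition battery.
#' @param seed Integer seed for permutations and random sets.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV ([write_results_table()]) together with a `manifest.tsv`
#'   of run parameters.
#' @return A list with elements `gem`, `rp_total`, `rp_polysome`, `rp_te`,
#'   `classes`, `venn`, and (when available) `monosome`, `composition`.
#' @export
run_heatshock_pipeline <- function(probe_tables, samples = NULL, genome = NULL,
                                   pfp = 0.1, n_perm = 1000, n_sets = 1000,
                                   seed = 1, out_dir = NULL) {
  gem <- build_gem(probe_tables, samples = samples)
  fractions <- unique(gem$samples$fraction)
  if (!all(c("total", "polysome") %in% fractions)) {
    abort("pipeline requires at least the total and polysome fractions")
  }
  rp_total <- differential_abundance(gem, "total", n_perm = n_perm, seed = seed)
  rp_poly <- differential_abundance(gem, "polysome", n_perm = n_perm, seed = seed + 1L)
  te <- compute_te(gem, "polysome", "total")
  rp_te <- differential_te(te, n_perm = n_perm, seed = seed + 2L)

  sig_t <- call_significant(rp_total, pfp)
  sig_p <- call_significant(rp_poly, pfp)
  sig_te <- call_significant(rp_te, pfp)
  classes <- classify_genes(rp_te$gene_id, sig_te$up, sig_te$down,
                            sig_t$up, sig_t$down)
  venn <- venn_partition(list(polysome_up = sig_p$up, te_up = sig_te$up,
                              t_up = sig_t$up, t_down = sig_t$down))

  result <- list(gem = gem, rp_total = rp_total, rp_polysome = rp_poly,
                 rp_te = rp_te, classes = classes, venn = venn)

  if ("monosome" %in% fractions) {
    orf_lengths <- if (!is.null(genome)) {
      setNames(nchar(genome$cds), genome$gene_id)
    } else {
      setNames(rep(NA_real_, nrow(rp_te)), rp_te$gene_id)
    }
    if (!all(is.na(orf_lengths))) {
      result$monosome <- monosome_partitioning(gem, orf_lengths,
                                               n_perm = n_perm,
                                               seed = seed + 3L,
                                               threshold = pfp)
    }
  }
  if (!is.null(genome) && length(sig_te$up) > 1) {
    result$composition <- composition_battery(sig_te$up, genome,
                                              n_sets = n_sets, seed = seed + 4L)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(tibble::as_tibble(rp_total), file.path(out_dir, "rp_total.tsv"))
    write_results_table(tibble::as_tibble(rp_poly), file.path(out_dir, "rp_polysome.tsv"))
    write_results_table(tibble::as_tibble(rp_te), file.path(out_dir, "rp_te.tsv"))
    write_results_table(dplyr::mutate(classes, class = as.character(class)),
                        file.path(out_dir, "classes.tsv"))
    readr::write_tsv(venn, file.path(out_dir, "venn.tsv"), progress = FALSE)
    if (!is.null(result$monosome)) {
      readr::write_tsv(result$monosome$report,
                       file.path(out_dir, "monosome_report.tsv"), progress = FALSE)
    }
    if (!is.null(result$composition)) {
      readr::write_tsv(tidy(result$composition),
                       file.path(out_dir, "composition.tsv"), progress = FALSE)
    }
    manifest <- tibble::tibble(
      key = c("pfp", "n_perm", "n_sets", "seed", "n_arrays", "n_genes"),
      value = as.character(c(pfp, n_perm, n_sets, seed,
                             ncol(gem$values), nrow(gem$values)))
    )
    readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  }
  result
}
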