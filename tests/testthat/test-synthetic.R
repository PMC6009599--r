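test_that("genome and experiment generation are deterministic under a seed", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg, seed = 20)
  g2 <- simulate_genome(cfg, seed = 20)
  expect_identical(g1$contig, g2$contig)
  expect_identical(g1$genome, g2$genome)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_genome_files(g1, file.path(d1, "g.fa"), file.path(d1, "g.gff3"))
  write_genome_files(g2, file.path(d2, "g.fa"), file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fa")), readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gff3")), readLines(file.path(d2, "g.gff3")))

  e1 <- simulate_experiment(cfg, seed = 21)
  e2 <- simulate_experiment(cfg, seed = 21)
  expect_identical(e1$probe_tables, e2$probe_tables)
  expect_identical(e1$truth, e2$truth)
})

test_that("simulated genomes hit their composition targets", {
  cfg <- sim_config(n_genes = 400,
                    groups = c(potentiated = 6, te_up_t_unchanged = 16,
                               te_up_t_down = 8, t_up_only = 8,
                               t_down_only = 30, te_down = 2, mono_shift = 8))
  sg <- simulate_genome(cfg, seed = 22)
  gw <- gc_windows(sg$genome)
  bg <- !sg$truth$in_te_set
  # realized background coding G+C within 1% of the 72% target
  bg_gc <- sum(nchar(sg$genome$cds[bg]) * gw$full_cds_gc[bg]) /
    sum(nchar(sg$genome$cds[bg])) / 100
  expect_lt(abs(bg_gc - 0.72), 0.01)
  te <- sg$truth$gene_id[sg$truth$in_te_set]
  te_gc <- mean(gw$full_cds_gc[match(te, gw$gene_id)]) / 100
  expect_lt(te_gc, 0.68)  # well below background (62% target + planted GC block)

  # all genes have canonical starts and stops and length divisible by 3
  expect_true(all(nchar(sg$genome$cds) %% 3 == 0))
  expect_true(all(substr(sg$genome$cds, 1, 3) %in% c("ATG", "GTG", "TTG")))
  stops <- substr(sg$genome$cds, nchar(sg$genome$cds) - 2, nchar(sg$genome$cds))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))

  # TE-set genes are markedly shorter on average
  len <- nchar(sg$genome$protein)
  expect_lt(mean(len[sg$truth$in_te_set]), 0.8 * mean(len[bg]))

  # pseudogenes exist and are never in the TE set
  expect_gt(sum(sg$truth$is_pseudogene), 0)
  expect_false(any(sg$truth$is_pseudogene & sg$truth$in_te_set))
})

test_that("an impossible G+C target is rejected", {
  # all-lysine proteins (AAA/AAG) cannot reach 72% G+C
  aa <- setNames(rep(1e-9, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  aa["K"] <- 1
  cfg <- small_cfg(aa_freq_bg = aa)
  expect_error(simulate_genome(cfg, seed = 1), "contradictory composition")
})

test_that("negative-signal injection fires the replacement rules at the set rate", {
  cfg <- small_cfg(neg_signal_frac = 0.02)
  se <- simulate_experiment(cfg, seed = 23)
  n_rep <- 0
  n_zero <- 0
  n_entries <- 0
  for (tb in se$probe_tables) {
    lr <- compute_log_ratios(tb)
    n_rep <- n_rep + attr(lr, "n_replaced")
    n_zero <- n_zero + attr(lr, "n_zeroed")
    n_entries <- n_entries + nrow(tb)
  }
  # each of the two channels is negated at ~2%; both-negative overlaps are rare
  rate <- (n_rep + 2 * n_zero) / (2 * n_entries)
  expect_gt(rate, 0.015)
  expect_lt(rate, 0.025)
})

test_that("a noiseless, spike-free experiment yields zero fold changes", {
  # controls and unmapped probes are also disabled: their intensities are
  # drawn per array, so arrays would no longer be exact replicas
  cfg <- small_cfg(noise_sd = 0, tech_sd = 0, neg_signal_frac = 0,
                   control_probe_frac = 0, unmapped_probe_frac = 0,
                   groups = c(potentiated = 0, te_up_t_unchanged = 0,
                              te_up_t_down = 0, t_up_only = 0,
                              t_down_only = 0, te_down = 0, mono_shift = 0))
  se <- simulate_experiment(cfg, seed = 24)
  gem <- build_gem(se$probe_tables)
  df <- tidy(gem) |>
    tidyr::pivot_wider(id_cols = c("feature_id", "fraction", "replicate"),
                       names_from = "temperature_c", values_from = "value")
  expect_lt(max(abs(df$`42` - df$`30`)), 1e-9)
})

test_that("spiked genes propagate through the pipeline to their classes", {
  cfg <- small_cfg()
  se <- simulate_experiment(cfg, seed = 25)
  gem <- build_gem(se$probe_tables)
  rp_te <- differential_te(compute_te(gem), n_perm = 400, seed = 26)
  rp_t <- differential_abundance(gem, "total", n_perm = 400, seed = 27)
  ste <- call_significant(rp_te, 0.1)
  st <- call_significant(rp_t, 0.1)
  cls <- classify_genes(rp_te$gene_id, ste$up, ste$down, st$up, st$down)
  truth <- se$truth
  pot <- truth$gene_id[truth$class == "potentiated"]
  expect_gt(mean(cls$class[match(pot, cls$gene_id)] == "potentiated"), 0.7)
  expect_equal(nrow(cls), cfg$n_genes)
})

test_that("written experiment files round-trip through the readers", {
  cfg <- small_cfg()
  se <- simulate_experiment(cfg, seed = 28)
  dir <- withr::local_tempdir()
  write_experiment_files(se, dir)
  meta <- read_sample_meta(file.path(dir, "meta.tsv"))
  expect_equal(meta$sample_id, se$samples$sample_id)
  nm <- se$samples$sample_id[7]
  back <- read_probe_table(file.path(dir, "probes", paste0(nm, ".tsv")),
                           se$samples[7, ])
  orig <- se$probe_tables[[nm]]
  expect_identical(back$signal, orig$signal)
  expect_identical(back$reference, orig$reference)
  expect_identical(back$gene_id, orig$gene_id)
  expect_identical(back$is_control, orig$is_control)
})
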