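test_that("log-ratio rules handle negatives per channel and per array", {
  # hand-constructed 5-probe table; expectations computed by hand from the
  # replacement rules (min positive signal = 1, min positive reference = 2)
  tb <- make_probe_table(tibble::tibble(
    probe_id = paste0("p", 1:5),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    is_control = FALSE,
    signal = c(8, -5, 1, 4, -2),
    reference = c(2, 4, 8, -7, -3)
  ))
  lr <- compute_log_ratios(tb)
  expect_equal(lr$log_ratio, c(
    log2(8 / 2),   # plain ratio
    log2(1 / 4),   # negative signal -> min positive signal (1)
    log2(1 / 8),
    log2(4 / 2),   # negative reference -> min positive reference (2)
    0              # both negative -> 0
  ))
  expect_equal(attr(lr, "n_replaced"), 2)
  expect_equal(attr(lr, "n_zeroed"), 1)
})

test_that("zero intensities are treated as negative-equivalent", {
  tb <- make_probe_table(tibble::tibble(
    probe_id = paste0("p", 1:3), gene_id = "g1", is_control = FALSE,
    signal = c(0, 4, 6), reference = c(2, 0, 3)
  ))
  lr <- compute_log_ratios(tb)
  expect_equal(lr$log_ratio[1], log2(4 / 2))  # min positive signal = 4
  expect_equal(lr$log_ratio[2], log2(4 / 2))  # min positive reference = 2
})

test_that("an all-negative channel is an error", {
  tb <- make_probe_table(tibble::tibble(
    probe_id = c("p1", "p2"), gene_id = "g1", is_control = FALSE,
    signal = c(-1, -2), reference = c(3, 4)
  ))
  expect_error(compute_log_ratios(tb), "signal")
})

test_that("median centering zeroes column medians and is idempotent", {
  m <- cbind(a1 = c(1, 2, 3), a2 = c(5, 5, 5), a3 = c(-2, 0, 7))
  rownames(m) <- paste0("p", 1:3)
  g <- gem_from_matrix(m)
  c1 <- median_center(g)
  expect_equal(unname(c1$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(c1$values[, 2]), c(0, 0, 0))
  expect_equal(unname(apply(c1$values, 2, median)), rep(0, 3))
  expect_equal(median_center(c1)$values, c1$values)
  expect_equal(c1$stage, "centered")
})

test_that("adding a constant to one array changes nothing after centering", {
  set.seed(1)
  m <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("p", 1:20), NULL))
  g1 <- median_center(gem_from_matrix(m))
  m2 <- m
  m2[, 2] <- m2[, 2] + 7.5
  g2 <- median_center(gem_from_matrix(m2))
  expect_equal(g1$values, g2$values)
})

test_that("scale normalization equalizes MADs to the batch geometric mean", {
  # two columns with MADs 1 and 4 -> both end at MAD 2
  x <- c(-2, -1, 0, 1, 2)
  m <- cbind(a1 = x, a2 = 4 * x)
  rownames(m) <- paste0("p", 1:5)
  g <- gem_from_matrix(m, stage = "raw") |> median_center() |> scale_normalize()
  mads <- apply(g$values, 2, function(v) median(abs(v - median(v))))
  expect_equal(unname(mads), c(2, 2))
  # overall spread preserved: geometric mean of MADs unchanged
  expect_equal(exp(mean(log(mads))), 2)

  # a single-column batch is left unchanged
  g1 <- gem_from_matrix(cbind(a1 = x), stage = "raw") |>
    median_center() |> scale_normalize()
  expect_equal(unname(g1$values[, 1]), x)
})

test_that("batches are normalized independently", {
  set.seed(2)
  m <- matrix(rnorm(80), 20, 4, dimnames = list(paste0("p", 1:20), NULL))
  fr <- c("total", "total", "polysome", "polysome")
  g <- gem_from_matrix(m, fractions = fr) |> median_center() |> scale_normalize()
  # perturb batch A (total) only; batch B output must be bit-identical
  m2 <- m
  m2[, 1] <- m2[, 1] * 3 + 1
  g2 <- gem_from_matrix(m2, fractions = fr) |> median_center() |> scale_normalize()
  expect_identical(g$values[, 3:4], g2$values[, 3:4])
})

test_that("a zero-MAD array is rejected by name", {
  m <- cbind(a1 = c(1, 2, 3, 4), a2 = rep(0, 4))
  rownames(m) <- paste0("p", 1:4)
  g <- median_center(gem_from_matrix(m))
  expect_error(scale_normalize(g), "a2")
})

test_that("control filtering and probe averaging collapse to one value per gene", {
  m <- matrix(c(1, 3, 2, 5, 9,
                0, 2, 4, 4, 9), ncol = 2)
  rownames(m) <- paste0("p", 1:5)
  samples <- dplyr::bind_rows(array_sample("total", 30, 1),
                              array_sample("total", 42, 1))
  feat <- tibble::tibble(
    probe_id = paste0("p", 1:5),
    gene_id = c("gA", "gA", "gB", NA, NA),   # p4 unmapped, p5 control
    is_control = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  g <- new_gem(m, samples, features = feat, stage = "normalized", level = "probe")
  out <- filter_and_average(g)
  expect_equal(nrow(out$values), 2)  # 5 probes: 1 control + 1 unmapped dropped
  expect_equal(unname(out$values["gA", 1]), 2)  # mean(1, 3)
  expect_equal(unname(out$values["gB", ]), c(2, 4))  # single probe: identity
  expect_equal(attr(out, "n_unmapped"), 1)
  expect_equal(out$level, "gene")
  expect_equal(out$stage, "normalized")
})

test_that("the assembled GEM honours its stage contracts on simulated data", {
  se <- simulate_experiment(small_cfg(), seed = 5)
  pg <- probe_gem(se$probe_tables) |> median_center() |> scale_normalize()
  expect_lt(max(abs(apply(pg$values, 2, median))), 1e-12)
  mads <- apply(pg$values, 2, function(v) median(abs(v - median(v))))
  for (b in unique(pg$samples$batch)) {
    bm <- mads[pg$samples$batch == b]
    expect_lt(max(abs(bm - bm[1])), 1e-9)
  }
  gene_gem <- filter_and_average(pg)
  expect_false(anyNA(gene_gem$values))
  expect_equal(sort(rownames(gene_gem$values)), sort(se$truth$gene_id))

  # determinism: identical inputs -> bit-identical GEM
  gem_a <- build_gem(se$probe_tables)
  gem_b <- build_gem(se$probe_tables)
  expect_identical(gem_a$values, gem_b$values)
})
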