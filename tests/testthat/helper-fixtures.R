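# Shared fixtures and independent oracles, built in code at test time.

# small, fast simulation settings used across tests
small_cfg <- function(n_genes = 200,
                      groups = c(potentiated = 4, te_up_t_unchanged = 6,
                                 te_up_t_down = 4, t_up_only = 4,
                                 t_down_only = 15, te_down = 2,
                                 mono_shift = 4),
                      ...) {
  sim_config(n_genes = n_genes, groups = groups, ...)
}

make_probe_table <- function(df, fraction = "total", temperature_c = 30,
                             replicate = 1) {
  sample <- array_sample(fraction, temperature_c, replicate)
  structure(tibble::as_tibble(df), sample = sample,
            class = c("probe_table", class(tibble::tibble())))
}

# a raw probe-level gem built directly from a ratio matrix
gem_from_matrix <- function(values, fractions = NULL, stage = "raw",
                            level = "probe") {
  n_arr <- ncol(values)
  fractions <- fractions %||% rep("total", n_arr)
  samples <- dplyr::bind_rows(purrr::map(seq_len(n_arr), function(i) {
    array_sample(fractions[i], 30, i, sample_id = paste0("a", i))
  }))
  if (is.null(rownames(values))) rownames(values) <- paste0("f", seq_len(nrow(values)))
  new_gem(values, samples, stage = stage, level = level)
}

# ---- independent oracle: exhaustive rank-product pfp ------------------------

# all n! permutations of 1..n, one per row (insertion construction)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    q <- p
    q[q >= i] <- q[q >= i] + 1L
    cbind(i, q, deparse.level = 0)
  }))
}

# pfp by enumeration of every within-column label permutation
exact_rp_pfp <- function(fc, direction) {
  n <- nrow(fc)
  k <- ncol(fc)
  sgn <- if (direction == "up") -fc else fc
  ranks <- apply(sgn, 2, rank, ties.method = "average")
  rp_obs <- exp(rowMeans(log(ranks)))
  P <- all_perms(n)
  combos <- as.matrix(expand.grid(rep(list(seq_len(nrow(P))), k)))
  pool <- numeric(nrow(combos) * n)
  for (i in seq_len(nrow(combos))) {
    m <- vapply(seq_len(k), function(j) ranks[P[combos[i, j], ], j], numeric(n))
    pool[((i - 1) * n + 1):(i * n)] <- exp(rowMeans(log(m)))
  }
  e <- vapply(rp_obs, function(v) sum(pool <= v + 1e-9), numeric(1)) / nrow(combos)
  rho <- rank(rp_obs, ties.method = "max")
  pfp <- e / rho
  ord <- order(rp_obs)
  pfp[ord] <- cummax(pfp[ord])
  pmin(pfp, 1)
}
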