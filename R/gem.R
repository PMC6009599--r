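#' Gene/probe expression matrix container
#'
#' A `gem` holds a features-by-samples matrix of log2(sample/reference)
#' values together with its sample metadata and a record of which
#' normalization stage it has reached (`raw`, `centered`, `normalized`).
#' The same container carries probe-level values before probe-to-gene
#' averaging (`level = "probe"`) and the final gene expression matrix
#' (`level = "gene"`).
#'
#' @param values Numeric matrix with feature rownames; columns follow `samples`.
#' @param samples Sample metadata tibble (one row per column of `values`),
#'   with columns `sample_id`, `fraction`, `temperature_c`, `replicate`,
#'   `batch`.
#' @param features Feature annotation tibble; for probe level it carries
#'   `probe_id`, `gene_id`, `is_control`.
#' @param stage One of `"raw"`, `"centered"`, `"normalized"`.
#' @param level `"probe"` or `"gene"`.
#' @return An object of class `gem`.
#' @export
new_gem <- function(values, samples, features = NULL,
                    stage = c("raw", "centered", "normalized"),
                    level = c("probe", "gene")) {
  stage <- match.arg(stage)
  level <- match.arg(level)
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  samples <- tibble::as_tibble(samples)
  if (ncol(values) != nrow(samples)) abort("one metadata row per matrix column required")
  if (anyNA(values)) abort("GEM values must not contain missing values")
  colnames(values) <- samples$sample_id
  structure(
    list(values = values, samples = samples, features = features,
         stage = stage, level = level),
    class = "gem"
  )
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %d %ss x %d arrays, stage=%s\n",
              nrow(x$values), x$level, ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.gem <- function(x) dim(x$values)

#' @export
as.matrix.gem <- function(x, ...) x$values

#' @describeIn new_gem Long-format view: one row per (feature, sample) with
#'   the sample metadata joined in.
#' @param x A `gem`.
#' @param ... Unused.
#' @export
tidy.gem <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id", values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' @describeIn new_gem One-row summary (dimensions, stage, level).
#' @export
glance.gem <- function(x, ...) {
  tibble::tibble(n_features = nrow(x$values), n_samples = ncol(x$values),
                 stage = x$stage, level = x$level)
}

#' Per-probe log2 ratios with negative-signal handling
#'
#' Forms log2(signal/reference) for every probe on one array. Probes where
#' exactly one channel is non-positive have that channel's value replaced by
#' the lowest positive value of the same channel's distribution on that array
#' before taking the ratio; probes where both channels are non-positive are
#' assigned a log2 ratio of 0. Zero intensities are treated like negatives
#' (the logarithm is undefined at 0). Replacement values are per-channel and
#' per-array because arrays have independent intensity scales.
#'
#' @param table A `probe_table` (see [read_probe_table()]).
#' @return The input tibble with a `log_ratio` column added; attributes
#'   `n_replaced` (entries that used the replacement rule) and `n_zeroed`
#'   (probes assigned ratio 0) record how often the rules fired.
#' @examples
#' pt <- tibble::tibble(probe_id = c("p1", "p2"), gene_id = c("g1", "g1"),
#'                      is_control = FALSE, signal = c(8, -5), reference = c(2, -3))
#' compute_log_ratios(pt)
#' @export
compute_log_ratios <- function(table) {
  if (nrow(table) == 0) abort("empty probe table")
  sig <- table$signal
  ref <- table$reference
  bad_sig <- sig <= 0
  bad_ref <- ref <= 0
  both <- bad_sig & bad_ref
  repl <- function(x, bad, channel) {
    if (!any(bad)) return(x)
    pos <- x[x > 0]
    if (length(pos) == 0) {
      abort(sprintf("all %s values non-positive: no replacement value exists", channel))
    }
    x[bad] <- min(pos)
    x
  }
  # replacement applies where exactly one channel is non-positive
  sig2 <- repl(sig, bad_sig & !both, "signal")
  ref2 <- repl(ref, bad_ref & !both, "reference")
  lr <- log2(sig2 / ref2)
  lr[both] <- 0
  out <- table
  out$log_ratio <- lr
  attr(out, "n_replaced") <- sum(bad_sig & !both) + sum(bad_ref & !both)
  attr(out, "n_zeroed") <- sum(both)
  attr(out, "sample") <- attr(table, "sample")
  out
}

#' Assemble a probe-level GEM from per-array probe tables
#'
#' Computes log ratios for each array ([compute_log_ratios()]) and binds them
#' into a probes-by-arrays matrix. All arrays must share an identical probe
#' set (one microarray platform).
#'
#' @param probe_tables A list of `probe_table` objects, each carrying its
#'   sample metadata attribute, or plain tibbles paired with `samples`.
#' @param samples Optional metadata tibble overriding the per-table
#'   attributes; rows must match `probe_tables` in order.
#' @return A `gem` at `level = "probe"`, `stage = "raw"`.
#' @export
probe_gem <- function(probe_tables, samples = NULL) {
  if (length(probe_tables) == 0) abort("no probe tables supplied")
  if (is.null(samples)) {
    samples <- purrr::map(probe_tables, ~ attr(.x, "sample"))
    if (any(purrr::map_lgl(samples, is.null))) {
      abort("probe tables lack sample metadata; supply `samples`")
    }
    samples <- dplyr::bind_rows(samples)
  }
  if (!"batch" %in% names(samples)) samples$batch <- derive_batch(samples$fraction)
  ref_ids <- probe_tables[[1]]$probe_id
  ratio_cols <- purrr::map(probe_tables, function(tb) {
    if (!identical(sort(tb$probe_id), sort(ref_ids))) {
      abort("arrays do not share an identical probe set")
    }
    lr <- compute_log_ratios(tb)
    lr$log_ratio[match(ref_ids, lr$probe_id)]
  })
  values <- do.call(cbind, ratio_cols)
  rownames(values) <- ref_ids
  features <- probe_tables[[1]][c("probe_id", "gene_id", "is_control")]
  new_gem(values, samples, features = features, stage = "raw", level = "probe")
}

#' Median-center each array
#'
#' Subtracts each column's median so that every array's log-ratio
#' distribution is centered at zero. Idempotent.
#'
#' @param gem A `gem` at stage `"raw"` (or `"centered"`, in which case the
#'   operation is a no-op up to numerical precision).
#' @return The `gem` at stage `"centered"`.
#' @export
median_center <- function(gem) {
  stopifnot(inherits(gem, "gem"))
  meds <- apply(gem$values, 2, median)
  gem$values <- sweep(gem$values, 2, meds, "-")
  gem$stage <- "centered"
  gem
}

#' Between-array scale normalization, in batches
#'
#' Equalizes the spread of the arrays within each normalization batch: every
#' column is divided by its median absolute deviation (MAD, without the
#' 1.4826 consistency factor -- only MAD ratios matter here) and multiplied by
#' the geometric mean of the batch's column MADs, so all arrays of a batch
#' end up with a common MAD while the batch's overall spread is preserved.
#' Batches are normalized independently: total-RNA arrays in one batch,
#' monosome/polysome arrays in the other, mirroring their different intensity
#' distributions.
#'
#' @param gem A `gem` at stage `"centered"`.
#' @param batches Optional character vector (one entry per array) overriding
#'   `gem$samples$batch`.
#' @return The `gem` at stage `"normalized"`.
#' @export
scale_normalize <- function(gem, batches = NULL) {
  stopifnot(inherits(gem, "gem"))
  if (gem$stage != "centered") abort("scale_normalize() expects a centered GEM")
  batches <- batches %||% gem$samples$batch
  if (length(batches) != ncol(gem$values)) abort("one batch label per array required")
  mads <- apply(gem$values, 2, function(x) median(abs(x - median(x))))
  if (any(mads == 0)) {
    abort(paste0("degenerate array (MAD = 0): ",
                 paste(colnames(gem$values)[mads == 0], collapse = ", ")))
  }
  for (b in unique(batches)) {
    idx <- which(batches == b)
    target <- gmean(mads[idx])
    gem$values[, idx] <- sweep(gem$values[, idx, drop = FALSE], 2,
                               target / mads[idx], "*")
  }
  gem$stage <- "normalized"
  gem
}

#' Filter control probes and average probes per gene
#'
#' Removes control probes, drops probes without a gene mapping (their count
#' is recorded in the `n_unmapped` attribute), and averages the remaining
#' probes of each gene into a single per-gene value per array, producing the
#' final gene expression matrix. The gene set is identical across arrays by
#' construction (single platform).
#'
#' @param gem A probe-level `gem` whose `features` carry `gene_id` and
#'   `is_control`.
#' @return A gene-level `gem` at the same stage, rows ordered by `gene_id`.
#' @export
filter_and_average <- function(gem) {
  stopifnot(inherits(gem, "gem"))
  if (gem$level != "probe") abort("filter_and_average() expects a probe-level GEM")
  feat <- gem$features
  if (is.null(feat)) abort("probe-level GEM lacks feature annotation")
  keep <- !feat$is_control & !is.na(feat$gene_id)
  n_unmapped <- sum(!feat$is_control & is.na(feat$gene_id))
  values <- gem$values[keep, , drop = FALSE]
  genes <- feat$gene_id[keep]
  summed <- rowsum(values, genes)
  counts <- as.vector(table(genes)[rownames(summed)])
  averaged <- summed / counts
  averaged <- averaged[order(rownames(averaged)), , drop = FALSE]
  out <- new_gem(averaged, gem$samples, features = NULL,
                 stage = gem$stage, level = "gene")
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build the normalized gene expression matrix
#'
#' Runs the full GEM construction in the fixed order: probe log2 ratios with
#' negative-value handling, per-array median centering, batched between-array
#' scale normalization, then control filtering and probe-to-gene averaging.
#'
#' @inheritParams probe_gem
#' @return A gene-level `gem` at stage `"normalized"`.
#' @seealso [compute_log_ratios()], [median_center()], [scale_normalize()],
#'   [filter_and_average()]
#' @export
build_gem <- function(probe_tables, samples = NULL) {
  probe_gem(probe_tables, samples = samples) |>
    median_center() |>
    scale_normalize() |>
    filter_and_average()
}
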