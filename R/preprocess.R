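#' Quantile-normalize intensity columns within sample groups
#'
#' Normalization is applied independently within each sample group (the
#' replicates of the same biological sample). Within a group, each column's
#' non-missing values are replaced by the mean of the order statistics
#' across that group's columns at the corresponding rank, so columns with
#' equal numbers of observations end up with identical value multisets.
#' Missing (`NA`) cells are masked out of the computation and stay missing.
#' When the group's columns carry unequal numbers of observations, the
#' reference distribution is built on the finest rank grid by linear
#' interpolation of the order statistics; tied values receive the mean of
#' the tied ranks' reference values. A group with a single replicate is
#' returned unchanged with a warning.
#'
#' @param mat Numeric matrix, proteins x replicates, `NA` = missing.
#' @param groups Character vector of group ids, one per column (or named by
#'   column name).
#' @return Matrix of the same shape with normalized non-missing values.
#' @export
quantile_normalize <- function(mat, groups) {
  stopifnot(is.matrix(mat))
  if (!is.null(names(groups))) groups <- groups[colnames(mat)]
  if (length(groups) != ncol(mat)) {
    abort("`groups` must supply one group id per column")
  }
  out <- mat
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) {
      warn(sprintf("sample group '%s' has a single replicate; left unchanged", g))
      next
    }
    obs <- lapply(cols, function(j) sort(mat[!is.na(mat[, j]), j]))
    n_obs <- lengths(obs)
    if (all(n_obs == 0L)) next
    n_grid <- max(n_obs)
    grid <- if (n_grid == 1L) 0.5 else seq(0, 1, length.out = n_grid)
    on_grid <- vapply(obs, function(v) {
      n <- length(v)
      if (n == 0L) return(rep(NA_real_, n_grid))
      if (n == n_grid) return(v)
      if (n == 1L) return(rep(v, n_grid))
      approx(seq(0, 1, length.out = n), v, xout = grid)$y
    }, numeric(n_grid))
    if (n_grid == 1L) on_grid <- matrix(on_grid, nrow = 1L)
    ref <- rowMeans(on_grid, na.rm = TRUE)
    for (idx in seq_along(cols)) {
      j <- cols[idx]
      keep <- !is.na(mat[, j])
      n <- n_obs[idx]
      if (n == 0L) next
      r <- rank(mat[keep, j], ties.method = "average")
      pos <- if (n == 1L) 0.5 else (r - 1) / (n - 1)
      out[keep, j] <- if (n_grid == 1L) ref else approx(grid, ref, xout = pos)$y
    }
  }
  out
}

#' Impute missing intensities with the within-sample-type minimum
#'
#' Each missing cell is replaced by the minimum observed value of that
#' protein across the replicates of its sample type (disease or control).
#' A protein with no observation at all in a sample type falls back to the
#' global dataset minimum, reported with a warning.
#'
#' @param mat Numeric matrix, proteins x replicates, `NA` = missing.
#' @param sample_types Character vector of sample-type ids, one per column
#'   (or named by column name).
#' @return Matrix with no `NA` cells (given at least one observed value in
#'   the dataset).
#' @export
impute_missing <- function(mat, sample_types) {
  stopifnot(is.matrix(mat))
  if (!is.null(names(sample_types))) sample_types <- sample_types[colnames(mat)]
  if (length(sample_types) != ncol(mat)) {
    abort("`sample_types` must supply one id per column")
  }
  if (all(is.na(mat))) abort("matrix has no observed values to impute from")
  global_min <- min(mat, na.rm = TRUE)
  out <- mat
  n_fallback <- 0L
  for (g in unique(sample_types)) {
    cols <- which(sample_types == g)
    block <- mat[, cols, drop = FALSE]
    row_min <- suppressWarnings(apply(block, 1L, min, na.rm = TRUE))
    fully_missing <- !is.finite(row_min)
    n_fallback <- n_fallback + sum(fully_missing & rowSums(is.na(block)) > 0)
    row_min[fully_missing] <- global_min
    miss <- is.na(block)
    block[miss] <- matrix(row_min, nrow(block), ncol(block))[miss]
    out[, cols] <- block
  }
  if (n_fallback > 0) {
    warn(sprintf(
      "%d protein/sample-type block(s) had no observation; filled with the global dataset minimum (%g)",
      n_fallback, global_min
    ))
  }
  out
}

#' Preprocess an AP-MS dataset for differential-connectivity analysis
#'
#' Applies, in order: quantile normalization of raw MS1 intensities within
#' each sample group ([quantile_normalize()]), minimal-intensity imputation
#' of missing values within each sample type ([impute_missing()]), and a
#' log10 transform. MS/MS spectral counts are copied through untransformed.
#' A zero intensity surviving imputation is replaced by half the smallest
#' positive value in the dataset before the log (reported with a warning).
#' The alternative impute-then-normalize order is available via `order`.
#'
#' @param dataset A [quant_dataset].
#' @param order `"normalize_impute"` (default) or `"impute_normalize"`.
#' @return A `processed_dataset`: the input plus a finite `log10_intensity`
#'   matrix and a logical `imputed` matrix flagging cells that were filled.
#' @examples
#' sim <- simulate_quant_dataset(sim_config(n_proteins = 40, seed = 2))
#' proc <- preprocess(sim$dataset)
#' range(proc$log10_intensity)
#' @export
preprocess <- function(dataset,
                       order = c("normalize_impute", "impute_normalize")) {
  stopifnot(inherits(dataset, "quant_dataset"))
  order <- match.arg(order)
  groups <- setNames(dataset$samples$sample_group, dataset$samples$replicate)
  types <- setNames(dataset$samples$condition, dataset$samples$replicate)
  imputed <- is.na(dataset$intensity)
  m <- dataset$intensity
  if (order == "normalize_impute") {
    m <- quantile_normalize(m, groups)
    m <- impute_missing(m, types)
  } else {
    m <- impute_missing(m, types)
    m <- quantile_normalize(m, setNames(rep("all", ncol(m)), colnames(m)))
  }
  zero <- m <= 0
  if (any(zero)) {
    half_min_pos <- min(m[m > 0]) / 2
    warn(sprintf("%d zero intensities replaced by %g before log10",
                 sum(zero), half_min_pos))
    m[zero] <- half_min_pos
  }
  out <- dataset
  out$log10_intensity <- log10(m)
  out$imputed <- imputed
  class(out) <- c("processed_dataset", "quant_dataset")
  out
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat(sprintf(
    "<processed_dataset> %d proteins x %d replicates; %d cells imputed (%.1f%%)\n",
    nrow(x$intensity), ncol(x$intensity), sum(x$imputed),
    100 * mean(x$imputed)
  ))
  invisible(x)
}
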