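#' AP-MS protein quantification dataset
#'
#' The carrier for a two-condition AP-MS experiment: an MS1 raw-intensity
#' matrix and an MS/MS spectral-count matrix (proteins in rows, replicates in
#' columns), plus a sample sheet describing each replicate. Missing
#' observations are encoded as `NA` in the matrices — never as zero, since
#' zero is a legal intensity after imputation.
#'
#' @param intensity Numeric matrix, proteins x replicates, non-negative,
#'   `NA` = not observed. Must carry rownames (protein accessions) and
#'   colnames (replicate labels).
#' @param spectral_counts Integer matrix of identical dimension and dimnames;
#'   `NA` = not observed.
#' @param samples Data frame with columns `replicate`, `condition`
#'   (`"disease"` or `"control"`) and `sample_group` (replicates of the same
#'   biological sample, the unit within which quantile normalization runs).
#'   Row order must match the matrix columns.
#' @return An object of class `quant_dataset`.
#' @seealso [simulate_quant_dataset()], [preprocess()], [tidy.quant_dataset()]
#' @export
quant_dataset <- function(intensity, spectral_counts, samples) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("`intensity` must be a numeric matrix")
  }
  if (!is.matrix(spectral_counts)) {
    abort("`spectral_counts` must be a matrix")
  }
  if (is.null(rownames(intensity)) || is.null(colnames(intensity))) {
    abort("`intensity` must have protein rownames and replicate colnames")
  }
  if (anyDuplicated(rownames(intensity))) {
    abort("duplicate protein ids in `intensity` rownames")
  }
  if (!identical(dim(intensity), dim(spectral_counts))) {
    abort("`intensity` and `spectral_counts` dimensions differ")
  }
  samples <- as_tibble(samples)
  required <- c("replicate", "condition", "sample_group")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    abort(paste0("`samples` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!identical(as.character(samples$replicate), colnames(intensity))) {
    abort("`samples$replicate` must match matrix colnames in order")
  }
  bad <- setdiff(unique(samples$condition), c("disease", "control"))
  if (length(bad)) {
    abort(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(intensity < 0, na.rm = TRUE)) {
    abort("`intensity` must be non-negative")
  }
  structure(
    list(
      intensity = intensity,
      spectral_counts = spectral_counts,
      samples = samples
    ),
    class = "quant_dataset"
  )
}

#' @export
print.quant_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$intensity))
  cat(sprintf(
    "<quant_dataset> %d proteins x %d replicates (%d disease, %d control); %d missing cells (%.1f%%)\n",
    nrow(x$intensity), ncol(x$intensity),
    sum(x$samples$condition == "disease"),
    sum(x$samples$condition == "control"),
    n_missing, 100 * n_missing / length(x$intensity)
  ))
  invisible(x)
}

#' @export
dim.quant_dataset <- function(x) dim(x$intensity)

protein_ids <- function(x) rownames(x$intensity)

#' Tidy an AP-MS dataset into a long tibble
#'
#' One row per protein x replicate cell, with intensity, spectral count,
#' missingness flag, and the replicate's condition and sample group.
#'
#' @param x A [quant_dataset].
#' @param ... Unused.
#' @return A tibble with columns `protein_id`, `replicate`, `condition`,
#'   `sample_group`, `intensity`, `spectral_count`, `missing`.
#' @method tidy quant_dataset
#' @export
tidy.quant_dataset <- function(x, ...) {
  long <- tibble(
    protein_id = rep(rownames(x$intensity), times = ncol(x$intensity)),
    replicate = rep(colnames(x$intensity), each = nrow(x$intensity)),
    intensity = as.vector(x$intensity),
    spectral_count = as.vector(x$spectral_counts)
  )
  long$missing <- is.na(long$intensity)
  dplyr::left_join(long, x$samples, by = "replicate") |>
    dplyr::select("protein_id", "replicate", "condition", "sample_group",
                  "intensity", "spectral_count", "missing")
}

#' @rdname tidy.quant_dataset
#' @method glance quant_dataset
#' @export
glance.quant_dataset <- function(x, ...) {
  tibble(
    n_proteins = nrow(x$intensity),
    n_replicates = ncol(x$intensity),
    n_disease = sum(x$samples$condition == "disease"),
    n_control = sum(x$samples$condition == "control"),
    frac_missing = mean(is.na(x$intensity))
  )
}
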