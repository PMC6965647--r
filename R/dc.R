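#' Two-sided Student's t-test p-value
#'
#' Classic pooled-variance two-sample t statistic with a two-sided p-value
#' from the t distribution on `length(x) + length(y) - 2` degrees of
#' freedom. When both samples have zero variance, the p-value is 1 for
#' equal means and the smallest representable positive double otherwise
#' (reported with a warning). Welch's unequal-variance form is available
#' via `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors with at least two values each.
#' @param var_equal Pool the variances (Student, default) or not (Welch).
#' @return A single p-value in `(0, 1]`.
#' @examples
#' student_t_two_sided(c(1, 2, 3), c(4, 5, 6))
#' @export
student_t_two_sided <- function(x, y, var_equal = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("both samples need at least two non-missing values")
  }
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(1)
    warn("zero variance in both samples with unequal means; returning the smallest positive p")
    return(.Machine$double.xmin)
  }
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  2 * pt(-abs(tstat), df)
}

#' Fold change between disease and control samples
#'
#' The ratio of disease over control mean signal. The default geometric
#' scale, `10^(mean(log10 disease) - mean(log10 control))`, matches a
#' t-test run on log10-transformed intensities; the arithmetic scale is the
#' plain ratio of linear means.
#'
#' @param disease,control Non-empty numeric vectors (positive under the
#'   geometric scale).
#' @param scale `"geometric_log10"` (default) or `"arithmetic"`.
#' @return A positive fold change; values > 1 mean higher signal in disease.
#' @export
fold_change <- function(disease, control,
                        scale = c("geometric_log10", "arithmetic")) {
  scale <- match.arg(scale)
  disease <- disease[!is.na(disease)]; control <- control[!is.na(control)]
  if (!length(disease) || !length(control)) abort("empty sample")
  if (scale == "geometric_log10") {
    if (any(disease <= 0) || any(control <= 0)) {
      abort("geometric fold change needs strictly positive values")
    }
    10^(mean(log10(disease)) - mean(log10(control)))
  } else {
    if (mean(control) == 0) abort("control mean is zero under arithmetic scale")
    mean(disease) / mean(control)
  }
}

# vectorized pooled-variance t over matrix rows; NA-aware.
# cross-checked against stats::t.test in the test suite.
row_t_pooled <- function(mat, idx_d, idx_c) {
  stat_block <- function(idx) {
    block <- mat[, idx, drop = FALSE]
    n <- rowSums(!is.na(block))
    mu <- rowMeans(block, na.rm = TRUE)
    v <- rowSums((block - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  d <- stat_block(idx_d); c_ <- stat_block(idx_c)
  ok <- d$n >= 2 & c_$n >= 2
  df <- d$n + c_$n - 2
  sp2 <- ((d$n - 1) * d$v + (c_$n - 1) * c_$v) / df
  tstat <- (d$mu - c_$mu) / sqrt(sp2 * (1 / d$n + 1 / c_$n))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- ok & d$v == 0 & c_$v == 0
  p[degenerate & d$mu == c_$mu] <- 1
  p[degenerate & d$mu != c_$mu] <- .Machine$double.xmin
  p[!ok] <- NA_real_
  list(p = unname(p), mean_d = unname(d$mu), mean_c = unname(c_$mu))
}

#' Run the differential-connectivity (DC) analysis
#'
#' Per-protein two-sided pooled-variance t-tests comparing disease against
#' control replicates: `raw_p`/`raw_fc` on the preprocessed log10
#' intensities and `sc_p`/`sc_fc` on the untransformed spectral counts.
#' Classification into DC pools is a separate step ([classify_dc()]).
#'
#' @param processed A `processed_dataset` from [preprocess()].
#' @param fc_scale Fold-change scale for `raw_fc` (see [fold_change()]).
#'   Spectral-count fold changes are always arithmetic ratios of mean
#'   counts; `sc_fc` is `NA` (undefined) when the control mean count is
#'   zero, and the `sc_fc_undefined` flag records it.
#' @return A `dc_tbl` tibble with one row per protein: `protein_id`,
#'   `raw_p`, `raw_fc`, `sc_p`, `sc_fc`, `sc_fc_undefined`.
#' @examples
#' sim <- simulate_quant_dataset(sim_config(n_proteins = 60, seed = 3))
#' dc <- run_dc(preprocess(sim$dataset))
#' dc
#' @export
run_dc <- function(processed, fc_scale = c("geometric_log10", "arithmetic")) {
  stopifnot(inherits(processed, "processed_dataset"))
  fc_scale <- match.arg(fc_scale)
  idx_d <- which(processed$samples$condition == "disease")
  idx_c <- which(processed$samples$condition == "control")
  if (length(idx_d) < 2L || length(idx_c) < 2L) {
    abort("need at least two replicates per condition")
  }
  raw <- row_t_pooled(processed$log10_intensity, idx_d, idx_c)
  raw_fc <- if (fc_scale == "geometric_log10") {
    10^(raw$mean_d - raw$mean_c)
  } else {
    lin <- 10^processed$log10_intensity
    unname(rowMeans(lin[, idx_d, drop = FALSE]) /
             rowMeans(lin[, idx_c, drop = FALSE]))
  }
  counts <- processed$spectral_counts
  sc <- row_t_pooled(counts, idx_d, idx_c)
  sc_mean_c <- rowMeans(counts[, idx_c, drop = FALSE], na.rm = TRUE)
  sc_mean_d <- rowMeans(counts[, idx_d, drop = FALSE], na.rm = TRUE)
  sc_fc <- unname(sc_mean_d / sc_mean_c)
  undefined <- !is.finite(sc_fc) | is.na(sc_mean_c) | unname(sc_mean_c) == 0
  sc_fc[undefined] <- NA_real_
  out <- tibble(
    protein_id = rownames(processed$intensity),
    raw_p = raw$p,
    raw_fc = raw_fc,
    sc_p = sc$p,
    sc_fc = sc_fc,
    sc_fc_undefined = undefined
  )
  class(out) <- c("dc_tbl", class(out))
  out
}

#' Threshold profiles for DC classification
#'
#' Named presets reproducing the dataset-specific selection rules:
#' * `network_human` — network map / iGSEA selection: `Raw.p <= 0.25`.
#' * `gsea_human` — human-brain GSEA input: `Raw.p <= 0.1`.
#' * `heatmap_human` — heatmap selection: `Raw.p <= 0.1`.
#' * `ipsc_neurons`, `mouse_PS19` — `Raw.p <= 0.25` or
#'   `SC.p <= 0.25 & SC.FC != 1`.
#' * `n2a` — `Raw.p <= 0.25`.
#'
#' @param name Preset name, or `"custom"` with the remaining arguments.
#' @param raw_p_max Intensity-branch p-value threshold.
#' @param use_sc_branch Allow passing through the spectral-count branch.
#' @param sc_p_max Spectral-count branch p-value threshold.
#' @param require_sc_fc_not_1 Require `SC.FC != 1` on the count branch (an
#'   undefined `SC.FC` — control mean count zero — counts as satisfied: a
#'   change from nothing to something).
#' @return A `threshold_profile` list.
#' @export
threshold_profile <- function(name = c("network_human", "gsea_human",
                                       "heatmap_human", "ipsc_neurons",
                                       "mouse_PS19", "n2a", "custom"),
                              raw_p_max = 0.25, use_sc_branch = FALSE,
                              sc_p_max = 0.25, require_sc_fc_not_1 = TRUE) {
  name <- match.arg(name)
  preset <- switch(
    name,
    network_human = list(raw_p_max = 0.25, use_sc_branch = FALSE),
    gsea_human = list(raw_p_max = 0.1, use_sc_branch = FALSE),
    heatmap_human = list(raw_p_max = 0.1, use_sc_branch = FALSE),
    ipsc_neurons = list(raw_p_max = 0.25, use_sc_branch = TRUE,
                        sc_p_max = 0.25, require_sc_fc_not_1 = TRUE),
    mouse_PS19 = list(raw_p_max = 0.25, use_sc_branch = TRUE,
                      sc_p_max = 0.25, require_sc_fc_not_1 = TRUE),
    n2a = list(raw_p_max = 0.25, use_sc_branch = FALSE),
    custom = list(raw_p_max = raw_p_max, use_sc_branch = use_sc_branch,
                  sc_p_max = sc_p_max,
                  require_sc_fc_not_1 = require_sc_fc_not_1)
  )
  defaults <- list(raw_p_max = raw_p_max, use_sc_branch = use_sc_branch,
                   sc_p_max = sc_p_max,
                   require_sc_fc_not_1 = require_sc_fc_not_1)
  prof <- utils::modifyList(defaults, preset)
  if (prof$raw_p_max <= 0 || prof$raw_p_max > 1 ||
      prof$sc_p_max <= 0 || prof$sc_p_max > 1) {
    abort("p-value thresholds must lie in (0, 1]")
  }
  structure(c(list(name = name), prof), class = "threshold_profile")
}

#' Classify proteins into DC pools
#'
#' A protein passes the active [threshold_profile()] if `raw_p <=
#' raw_p_max`, or — when the profile's spectral-count branch is enabled —
#' `sc_p <= sc_p_max` (and `sc_fc != 1` where required). Passing proteins
#' with `raw_fc > 1` are `disease_specific`, with `raw_fc < 1`
#' `control_specific`; everything else is `unclassified`.
#'
#' @param records A `dc_tbl` from [run_dc()].
#' @param profile A [threshold_profile()] or a preset name.
#' @return The input tibble with a `dc_class` column.
#' @export
classify_dc <- function(records, profile = "network_human") {
  if (is.character(profile)) profile <- threshold_profile(profile)
  stopifnot(inherits(profile, "threshold_profile"))
  raw_pass <- !is.na(records$raw_p) & records$raw_p <= profile$raw_p_max
  sc_pass <- rep(FALSE, nrow(records))
  if (profile$use_sc_branch) {
    sc_pass <- !is.na(records$sc_p) & records$sc_p <= profile$sc_p_max
    if (profile$require_sc_fc_not_1) {
      fc_ok <- is.na(records$sc_fc) | records$sc_fc != 1
      sc_pass <- sc_pass & fc_ok
    }
  }
  pass <- raw_pass | sc_pass
  cls <- rep("unclassified", nrow(records))
  cls[pass & !is.na(records$raw_fc) & records$raw_fc > 1] <- "disease_specific"
  cls[pass & !is.na(records$raw_fc) & records$raw_fc < 1] <- "control_specific"
  records$dc_class <- cls
  if (!inherits(records, "dc_tbl")) class(records) <- c("dc_tbl", class(records))
  records
}

#' Venn-region overlap counts of DC-protein sets across datasets
#'
#' Computes the exact counts of every region of the Venn partition over the
#' differentially connected proteins of several datasets (identified in a
#' shared, post-orthology accession space).
#'
#' @param sets A named list of classified `dc_tbl` tables (their
#'   `dc_class != "unclassified"` proteins are used) or of character
#'   vectors of protein ids.
#' @return A tibble with one row per non-empty dataset combination: a
#'   logical membership column per dataset, a `region` label
#'   (`"A&B"`-style, meaning exactly those datasets), and the exclusive
#'   `count` of proteins in that region.
#' @export
cross_dataset_overlap <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be a named list")
  }
  as_set <- function(x) {
    if (inherits(x, "data.frame")) {
      x <- x$protein_id[x$dc_class != "unclassified"]
    }
    unique(canonicalize_accession(x))
  }
  sets <- lapply(sets, as_set)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  sig <- if (length(universe)) {
    apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  } else {
    character()
  }
  combo_sig <- apply(combos, 1L, function(r) paste(as.integer(r),
                                                   collapse = ""))
  counts <- vapply(combo_sig, function(s) sum(sig == s), integer(1))
  out <- as_tibble(combos)
  out$region <- apply(combos, 1L, function(r) {
    paste(names(sets)[as.logical(r)], collapse = "&")
  })
  out$count <- unname(counts)
  out[order(rowSums(combos), out$region), ]
}

#' @method glance dc_tbl
#' @export
glance.dc_tbl <- function(x, ...) {
  cls <- if ("dc_class" %in% names(x)) x$dc_class else
    rep("unclassified", nrow(x))
  tibble(
    n_proteins = nrow(x),
    n_disease_specific = sum(cls == "disease_specific"),
    n_control_specific = sum(cls == "control_specific"),
    n_unclassified = sum(cls == "unclassified"),
    median_raw_fc = median(x$raw_fc, na.rm = TRUE)
  )
}

#' Write a DC table to TSV
#'
#' Columns follow the conventional field names `Raw.p`, `Raw.FC`, `SC.p`,
#' `SC.FC` plus `dc_class` when present.
#'
#' @param records A `dc_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dc_table <- function(records, path) {
  out <- tibble(
    protein_id = records$protein_id,
    Raw.p = records$raw_p,
    Raw.FC = records$raw_fc,
    SC.p = records$sc_p,
    SC.FC = records$sc_fc
  )
  if ("dc_class" %in% names(records)) out$dc_class <- records$dc_class
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a DC table from TSV
#'
#' Accepts a configurable column map so externally produced tables with
#' different headers can be ingested.
#'
#' @param path Input path.
#' @param col_map Named character vector mapping the canonical fields
#'   (`protein_id`, `raw_p`, `raw_fc`, `sc_p`, `sc_fc`) to the file's
#'   column names.
#' @return A `dc_tbl` tibble.
#' @export
read_dc_table <- function(path,
                          col_map = c(protein_id = "protein_id",
                                      raw_p = "Raw.p", raw_fc = "Raw.FC",
                                      sc_p = "SC.p", sc_fc = "SC.FC")) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(col_map[c("protein_id", "raw_p", "raw_fc")]),
                          names(tbl))
  if (length(missing_cols)) {
    abort(paste0("DC table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  get <- function(field) {
    nm <- col_map[[field]]
    if (!is.null(nm) && nm %in% names(tbl)) tbl[[nm]] else NA_real_
  }
  out <- tibble(
    protein_id = canonicalize_accession(tbl[[col_map[["protein_id"]]]]),
    raw_p = as.numeric(get("raw_p")),
    raw_fc = as.numeric(get("raw_fc")),
    sc_p = as.numeric(get("sc_p")),
    sc_fc = as.numeric(get("sc_fc"))
  )
  out$sc_fc_undefined <- is.na(out$sc_fc)
  if ("dc_class" %in% names(tbl)) out$dc_class <- tbl$dc_class
  class(out) <- c("dc_tbl", class(out))
  out
}
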