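#' Read and write AP-MS quantification tables
#'
#' A dataset is stored as three TSV files sharing a prefix:
#' `<prefix>_intensity.tsv` and `<prefix>_counts.tsv` (first column
#' `protein_id`, one column per replicate, blank or `NA` cells marking
#' unobserved entries) and a sample sheet `<prefix>_samples.tsv` with
#' columns `replicate`, `condition`, `sample_group`. A generator seed, when
#' supplied, is recorded in a `<prefix>_provenance.tsv` sidecar.
#'
#' @param prefix Path prefix for the three files.
#' @param dataset A [quant_dataset].
#' @param seed Optional integer recorded in the provenance sidecar.
#' @return `read_quant_dataset()` returns a [quant_dataset];
#'   `write_quant_dataset()` returns the written paths, invisibly.
#' @name quant_io
NULL

#' @rdname quant_io
#' @export
write_quant_dataset <- function(dataset, prefix, seed = NULL) {
  stopifnot(inherits(dataset, "quant_dataset"))
  paths <- c(
    intensity = paste0(prefix, "_intensity.tsv"),
    counts = paste0(prefix, "_counts.tsv"),
    samples = paste0(prefix, "_samples.tsv")
  )
  mat_to_tbl <- function(m) {
    dplyr::bind_cols(tibble(protein_id = rownames(m)), as_tibble(m))
  }
  readr::write_tsv(mat_to_tbl(dataset$intensity), paths["intensity"])
  readr::write_tsv(mat_to_tbl(dataset$spectral_counts), paths["counts"])
  readr::write_tsv(dataset$samples, paths["samples"])
  if (!is.null(seed)) {
    prov <- paste0(prefix, "_provenance.tsv")
    readr::write_tsv(tibble(key = "seed", value = as.integer(seed)), prov)
    paths <- c(paths, provenance = prov)
  }
  invisible(paths)
}

#' @rdname quant_io
#' @export
read_quant_dataset <- function(prefix) {
  read_mat <- function(path) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
    if (anyDuplicated(tbl$protein_id)) {
      abort(paste0("duplicate protein ids in ", path))
    }
    vals <- tbl[setdiff(names(tbl), "protein_id")]
    non_num <- names(vals)[!vapply(vals, is.numeric, logical(1))]
    if (length(non_num)) {
      abort(paste0("non-numeric cells in column(s) ",
                   paste(non_num, collapse = ", "), " of ", path))
    }
    m <- as.matrix(vals)
    rownames(m) <- tbl$protein_id
    m
  }
  intensity <- read_mat(paste0(prefix, "_intensity.tsv"))
  counts <- read_mat(paste0(prefix, "_counts.tsv"))
  samples <- readr::read_tsv(paste0(prefix, "_samples.tsv"),
                             show_col_types = FALSE)
  unlabelled <- setdiff(colnames(intensity), samples$replicate)
  if (length(unlabelled)) {
    abort(paste0("replicate(s) without a condition label: ",
                 paste(unlabelled, collapse = ", ")))
  }
  samples <- samples[match(colnames(intensity), samples$replicate), ]
  quant_dataset(intensity, counts, samples)
}

#' Read and write gene-set collections (GMT)
#'
#' Standard GMT: one term per line — term id, description, then members,
#' tab-separated. On read, duplicate members within a term are deduplicated
#' and member accessions canonicalized; terms left without members are
#' dropped with a warning; a line with fewer than three fields is an error.
#'
#' @param path File path.
#' @param collection Tibble with columns `term_id`, `description` and
#'   list-column `members`.
#' @return `read_gmt()` returns a collection tibble; `write_gmt()` returns
#'   `path` invisibly.
#' @name gmt_io
NULL

#' @rdname gmt_io
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(term_id = character(), description = character(),
                  members = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  out <- tibble(
    term_id = vapply(fields, `[[`, "", 1L),
    description = vapply(fields, `[[`, "", 2L),
    members = lapply(fields, function(f) {
      unique(canonicalize_accession(f[-(1:2)][nzchar(f[-(1:2)])]))
    })
  )
  empty <- lengths(out$members) == 0L
  if (any(empty)) {
    warn(sprintf("dropping %d empty term(s): %s", sum(empty),
                 paste(out$term_id[empty], collapse = ", ")))
    out <- out[!empty, ]
  }
  out
}

#' @rdname gmt_io
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    collection[c("term_id", "description", "members")],
    function(term_id, description, members) {
      paste(c(term_id, description, members), collapse = "\t")
    }
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a chaperome member list
#'
#' Plain text, one member per line: an accession, optionally followed by a
#' tab and a display name. Comment lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Tibble with columns `accession` and `display_name`.
#' @export
read_chaperome_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- tibble(
    accession = canonicalize_accession(vapply(parts, `[[`, "", 1L)),
    display_name = vapply(parts, function(p) {
      if (length(p) >= 2L) p[[2L]] else p[[1L]]
    }, "")
  )
  if (nrow(out) == 0) abort("chaperome list is empty")
  if (anyDuplicated(out$accession)) {
    abort("duplicate accessions in chaperome list")
  }
  out
}

#' Export an annotated network for Cytoscape import
#'
#' Writes a SIF edge file (`A pp B`) plus TSV node- and edge-attribute
#' tables. Node attributes carry the differential-connectivity annotation
#' (`dc_class`, `raw_p`, `raw_fc`); edge attributes carry the interaction
#' provenance. Values are written at full precision and the output is
#' byte-stable for identical inputs.
#'
#' @param network An annotated igraph network (see [annotate_nodes()]).
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
export_network_tables <- function(network, out_dir, prefix = "network") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    sif = file.path(out_dir, paste0(prefix, ".sif")),
    nodes = file.path(out_dir, paste0(prefix, "_node_attributes.tsv")),
    edges = file.path(out_dir, paste0(prefix, "_edge_attributes.tsv"))
  )
  el <- igraph::as_edgelist(network)
  readr::write_lines(
    if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(),
    paths["sif"]
  )
  va <- igraph::vertex_attr(network)
  nodes <- tibble(
    protein_id = igraph::V(network)$name,
    dc_class = va$dc_class %||% rep(NA_character_, length(va$name)),
    raw_p = va$raw_p %||% rep(NA_real_, length(va$name)),
    raw_fc = va$raw_fc %||% rep(NA_real_, length(va$name))
  )
  readr::write_tsv(nodes, paths["nodes"])
  sources <- igraph::edge_attr(network, "sources")
  edges <- tibble(
    interactor_a = if (nrow(el)) el[, 1] else character(),
    interactor_b = if (nrow(el)) el[, 2] else character(),
    sources = sources %||% rep(NA_character_, nrow(el))
  )
  readr::write_tsv(edges, paths["edges"])
  invisible(paths)
}
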