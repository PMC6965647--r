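#' Load ortholog mapping tables
#'
#' Validates and normalizes the two tables used by the stepwise
#' mouse-to-human conversion: a human reference (UniProt entry name ->
#' accession) backing the direct suffix step, and an HCOP-style pair table
#' (mouse id -> human accession) backing the second step. In the HCOP
#' table, rows with a missing accession are dropped and duplicate mouse
#' ids resolved deterministically by keeping the first occurrence after
#' sorting; the number removed is reported.
#'
#' @param human_reference Tibble/data frame with columns `entry_name` and
#'   `accession`, or a TSV path.
#' @param hcop_pairs Tibble/data frame with columns `mouse_id` and
#'   `human_accession`, or a TSV path.
#' @return An `ortholog_tables` list with the validated tibbles.
#' @export
ortholog_tables <- function(human_reference, hcop_pairs) {
  read_maybe <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      readr::read_tsv(x, show_col_types = FALSE)
    } else {
      as_tibble(x)
    }
  }
  ref <- read_maybe(human_reference)
  if (!all(c("entry_name", "accession") %in% names(ref))) {
    abort("`human_reference` needs columns entry_name, accession")
  }
  ref$entry_name <- toupper(trimws(ref$entry_name))
  ref$accession <- canonicalize_accession(ref$accession)
  ref <- ref[!is.na(ref$accession) & nzchar(ref$accession), ]
  ref <- dplyr::distinct(dplyr::arrange(ref, .data$entry_name,
                                        .data$accession),
                         .data$entry_name, .keep_all = TRUE)

  hcop <- read_maybe(hcop_pairs)
  if (!all(c("mouse_id", "human_accession") %in% names(hcop))) {
    abort("`hcop_pairs` needs columns mouse_id, human_accession")
  }
  n0 <- nrow(hcop)
  hcop$mouse_id <- toupper(trimws(hcop$mouse_id))
  hcop$human_accession <- canonicalize_accession(hcop$human_accession)
  hcop <- hcop[!is.na(hcop$human_accession) & nzchar(hcop$human_accession), ]
  hcop <- dplyr::distinct(
    dplyr::arrange(hcop, .data$mouse_id, .data$human_accession),
    .data$mouse_id, .keep_all = TRUE
  )
  if (nrow(hcop) < n0) {
    inform(sprintf("HCOP table: %d duplicate/missing row(s) removed",
                   n0 - nrow(hcop)))
  }
  structure(list(human_reference = ref, hcop_pairs = hcop),
            class = "ortholog_tables")
}

uniprot_ac_pattern <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9][A-Z][A-Z0-9]{2}[0-9])$"

#' Step 1: direct entry-name suffix conversion
#'
#' Converts the `_MOUSE` suffix of each UniProt entry name into `_HUMAN`
#' and keeps the mapping when the converted entry name exists in the human
#' reference with an accession; successful mappings are labelled
#' `"Direct"`. Entries not ending in `_MOUSE` go straight to the unmapped
#' output with a warning.
#'
#' @param entries Character vector of UniProt entry names.
#' @param reference The `human_reference` tibble of [ortholog_tables()].
#' @return A list with `mapped` (tibble `source_entry`, `mapped_accession`,
#'   `method`) and `unmapped` (character vector).
#' @export
direct_suffix_map <- function(entries, reference) {
  entries <- toupper(trimws(entries))
  if (!length(entries)) {
    return(list(
      mapped = tibble(source_entry = character(),
                      mapped_accession = character(), method = character()),
      unmapped = character()
    ))
  }
  is_mouse <- endsWith(entries, "_MOUSE")
  if (any(!is_mouse)) {
    warn(sprintf("%d entr(ies) without a _MOUSE suffix passed to step 1",
                 sum(!is_mouse)))
  }
  candidate <- sub("_MOUSE$", "_HUMAN", entries)
  acc <- reference$accession[match(candidate, reference$entry_name)]
  hit <- is_mouse & !is.na(acc)
  list(
    mapped = tibble(
      source_entry = entries[hit],
      mapped_accession = acc[hit],
      method = "Direct"
    ),
    unmapped = entries[!hit]
  )
}

#' Step 2: ortholog-table lookup
#'
#' Looks up entries that failed the direct suffix step in the HCOP-style
#' pair table; hits are labelled `"HCOP"`.
#'
#' @param entries Character vector (the step-1 failures).
#' @param hcop_pairs The `hcop_pairs` tibble of [ortholog_tables()].
#' @return A list with `mapped` (tibble) and `still_unmapped` (character).
#' @export
hcop_map <- function(entries, hcop_pairs) {
  entries <- toupper(trimws(entries))
  acc <- hcop_pairs$human_accession[match(entries, hcop_pairs$mouse_id)]
  hit <- !is.na(acc)
  list(
    mapped = tibble(
      source_entry = entries[hit],
      mapped_accession = acc[hit],
      method = "HCOP"
    ),
    still_unmapped = entries[!hit]
  )
}

#' Stepwise mouse-to-human ortholog mapping
#'
#' Runs the direct suffix conversion first and the HCOP lookup on its
#' failures; a step-1 success is never overridden. Entries that already
#' look like human UniProt accessions pass through unchanged with method
#' `"Direct"`. Entries unmapped by either step are emitted with method
#' `"Unmapped"` and a missing accession. The output preserves the input
#' order, one row per input; downstream consumers use accessions as the
#' sole protein identifier.
#'
#' @param entries Character vector of mouse UniProt entry names (or
#'   already-human accessions).
#' @param tables An [ortholog_tables()] object (or a list with
#'   `human_reference` and `hcop_pairs` elements).
#' @return An `ortholog_tbl` tibble: `source_entry`, `mapped_accession`,
#'   `method` (`Direct`, `HCOP` or `Unmapped`).
#' @export
map_orthologs <- function(entries, tables) {
  if (!inherits(tables, "ortholog_tables")) {
    tables <- ortholog_tables(tables$human_reference, tables$hcop_pairs)
  }
  entries <- toupper(trimws(entries))
  out <- tibble(source_entry = entries,
                mapped_accession = NA_character_,
                method = "Unmapped")
  passthrough <- grepl(uniprot_ac_pattern, entries)
  out$mapped_accession[passthrough] <-
    canonicalize_accession(entries[passthrough])
  out$method[passthrough] <- "Direct"

  # vectorized equivalent of direct_suffix_map() then hcop_map(); a step-1
  # success is never overridden and duplicate inputs map independently
  is_mouse <- !passthrough & endsWith(entries, "_MOUSE")
  candidate <- sub("_MOUSE$", "_HUMAN", entries)
  acc1 <- tables$human_reference$accession[
    match(candidate, tables$human_reference$entry_name)]
  step1 <- is_mouse & !is.na(acc1)
  out$mapped_accession[step1] <- acc1[step1]
  out$method[step1] <- "Direct"

  todo <- !passthrough & !step1
  acc2 <- tables$hcop_pairs$human_accession[
    match(entries, tables$hcop_pairs$mouse_id)]
  step2 <- todo & !is.na(acc2)
  out$mapped_accession[step2] <- acc2[step2]
  out$method[step2] <- "HCOP"
  class(out) <- c("ortholog_tbl", class(out))
  out
}

#' @method glance ortholog_tbl
#' @export
glance.ortholog_tbl <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_direct = sum(x$method == "Direct"),
    n_hcop = sum(x$method == "HCOP"),
    n_unmapped = sum(x$method == "Unmapped")
  )
}
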