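#' Canonicalize UniProt accessions
#'
#' Protein identifiers arriving from MS tables, interaction databases and
#' gene-set files are matched by UniProt accession (UniProtAC). This helper
#' applies one canonical form at every ingestion point: uppercase, isoform
#' suffix (`"-2"`) stripped, sequence version (`".3"`) stripped, surrounding
#' whitespace removed.
#'
#' @param x Character vector of accessions or entry names.
#' @return Character vector of the same length.
#' @examples
#' canonicalize_accession(c(" p08238-2 ", "Q9Y4L1.3"))
#' @export
canonicalize_accession <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("-\\d+$", "", x)
  x <- sub("\\.\\d+$", "", x)
  x
}

# shared argument checks -------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_fraction <- function(x, name, upper_open = FALSE) {
  ok <- length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (upper_open) x < 1 else x <= 1)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in [0, 1%s", name,
      if (upper_open) ")" else "]"
    ))
  }
  as.numeric(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

# seed handling: every stochastic entry point takes an integer seed and
# evaluates its draws inside withr::with_seed so the caller's RNG state is
# untouched and identical seeds give bit-identical output.
with_seed_ <- function(seed, code) {
  seed <- check_count(seed, "seed", min = 0L)
  withr::with_seed(seed, code)
}
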