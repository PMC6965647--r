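#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`: sort ascending,
#' multiply the i-th smallest by m/i, enforce monotonicity from the
#' smallest upward, cap at 1, and return in the input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis (ORA)
#'
#' Per term, the upper-tail hypergeometric probability of observing at
#' least the seen overlap: population `N = |universe|`, successes
#' `K = |term members in universe|`, draws `n = |query|`, observed
#' `k = |term members in query|`; `p = P(X >= k)`. P-values are adjusted by
#' Benjamini-Hochberg across all tested terms; `qvalue` is reported equal
#' to the BH-adjusted value. `GeneRatio` is `k` over the number of query
#' proteins annotated anywhere in the tested collection; `BgRatio` is
#' `K / N`, following the conventions of standard enrichment tooling.
#'
#' @param query Character vector of protein accessions (the DC pool under
#'   test); must be contained in `universe` — outside ids are dropped with
#'   a warning.
#' @param universe Character vector, the enrichment background.
#' @param collection Gene-set tibble (`term_id`, `description`, list-column
#'   `members`), e.g. from [read_gmt()] or [simulate_gene_sets()].
#' @param min_size,max_size Terms whose universe-restricted size falls
#'   outside this range are skipped.
#' @return An `ora_tbl` tibble: `term_id`, `description`, `overlap_k`,
#'   `n_query_annotated`, `term_size`, `universe_size`, `gene_ratio`,
#'   `bg_ratio`, `pvalue`, `p_adjust`, `qvalue`, list-column
#'   `overlap_members`; ordered by `pvalue`.
#' @examples
#' coll <- tibble::tibble(term_id = "T1", description = "toy",
#'                        members = list(c("A", "B", "C", "D")))
#' hypergeometric_ora(c("A", "B", "C", "E", "F"), LETTERS[1:10], coll,
#'                    min_size = 3)
#' @export
hypergeometric_ora <- function(query, universe, collection,
                               min_size = 3, max_size = 500) {
  query <- unique(canonicalize_accession(query))
  universe <- unique(canonicalize_accession(universe))
  if (!length(query)) abort("empty query")
  if (!length(universe)) abort("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query id(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
    if (!length(query)) abort("empty query after universe restriction")
  }
  members_u <- lapply(collection$members, intersect, y = universe)
  sizes <- lengths(members_u)
  keep <- sizes >= min_size & sizes <= max_size
  empty <- tibble(
    term_id = character(), description = character(),
    overlap_k = integer(), n_query_annotated = integer(),
    term_size = integer(), universe_size = integer(),
    gene_ratio = character(), bg_ratio = character(),
    pvalue = numeric(), p_adjust = numeric(), qvalue = numeric(),
    overlap_members = list()
  )
  class(empty) <- c("ora_tbl", class(empty))
  if (!any(keep)) return(empty)
  members_u <- members_u[keep]
  N <- length(universe)
  n <- length(query)
  n_annot <- length(intersect(query, unique(unlist(members_u))))
  overlaps <- lapply(members_u, intersect, y = query)
  k <- lengths(overlaps)
  K <- lengths(members_u)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- tibble(
    term_id = collection$term_id[keep],
    description = collection$description[keep],
    overlap_k = k,
    n_query_annotated = n_annot,
    term_size = K,
    universe_size = N,
    gene_ratio = sprintf("%d/%d", k, n_annot),
    bg_ratio = sprintf("%d/%d", K, N),
    pvalue = p,
    p_adjust = bh_adjust(p),
    overlap_members = lapply(overlaps, sort)
  )
  out$qvalue <- out$p_adjust
  out <- out[order(out$pvalue, out$term_id),
             c("term_id", "description", "overlap_k", "n_query_annotated",
               "term_size", "universe_size", "gene_ratio", "bg_ratio",
               "pvalue", "p_adjust", "qvalue", "overlap_members")]
  class(out) <- c("ora_tbl", class(out))
  out
}
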