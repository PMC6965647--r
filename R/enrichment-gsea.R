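#' GSEA running-sum enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing the running sum
#' at set members (hits) by `|score|^weight_exponent` normalized by the sum
#' over hits, and decrementing at non-members by `1/(N - N_hits)`. The
#' enrichment score (ES) is the extremum of largest magnitude (positive on
#' a tie), so a positive ES indicates enrichment at the top of the ranked
#' list. The leading edge is the set of hits at or before the maximum (at
#' or after the minimum, for a negative ES).
#'
#' @param ranked_ids Character vector of unique ids, sorted by decreasing
#'   score.
#' @param scores Numeric vector of the ranking scores, same order.
#' @param member_set Character vector; must intersect `ranked_ids` and not
#'   cover the whole list.
#' @param weight_exponent Hit-weight exponent (0 = unweighted
#'   Kolmogorov-Smirnov form; 1 = magnitude-weighted, the default).
#' @return A list with `es`, the full `running_sum` vector and the
#'   `leading_edge` member ids, of class `es_result`.
#' @examples
#' res <- enrichment_score(letters[1:5], 5:1, c("a", "c"),
#'                         weight_exponent = 0)
#' res$es
#' @export
enrichment_score <- function(ranked_ids, scores, member_set,
                             weight_exponent = 1) {
  if (anyDuplicated(ranked_ids)) abort("`ranked_ids` must be unique")
  if (length(ranked_ids) != length(scores)) {
    abort("`scores` must align with `ranked_ids`")
  }
  hit <- ranked_ids %in% member_set
  n_hits <- sum(hit)
  if (n_hits == 0) abort("`member_set` is disjoint from the ranked list")
  if (n_hits == length(ranked_ids)) {
    abort("`member_set` covers the whole ranked list")
  }
  w <- abs(scores[hit])^weight_exponent
  if (sum(w) == 0) w <- rep(1, n_hits)   # all-zero scores: unweighted hits
  steps <- numeric(length(ranked_ids))
  steps[hit] <- w / sum(w)
  steps[!hit] <- -1 / (length(ranked_ids) - n_hits)
  running <- cumsum(steps)
  mx <- max(running); mn <- min(running)
  # exact magnitude ties resolve to the positive extremum; the small
  # tolerance keeps the choice stable under floating-point accumulation
  if (mx >= -mn - 1e-12) {
    es <- mx
    peak <- which.max(running)
    leading <- ranked_ids[hit & seq_along(running) <= peak]
  } else {
    es <- mn
    trough <- which.min(running)
    leading <- ranked_ids[hit & seq_along(running) >= trough]
  }
  structure(list(es = es, running_sum = running, leading_edge = leading),
            class = "es_result")
}

# closed-form running-sum extrema from hit positions only; used on the
# permutation path. idx must be sorted ascending. Exactly equals the
# extrema of the cumulative walk in enrichment_score().
es_from_hits_ <- function(idx, w, n_total) {
  n_hits <- length(idx)
  sw <- sum(w)
  if (sw == 0) w <- rep(1, n_hits) else w <- w
  miss <- 1 / (n_total - n_hits)
  tops <- cumsum(w) / sum(w) - (idx - seq_len(n_hits)) * miss
  bottoms <- tops - w / sum(w)
  mx <- max(tops); mn <- min(bottoms)
  if (mx >= -mn - 1e-12) mx else mn
}

#' Permutation gene-set enrichment analysis (preranked GSEA)
#'
#' Proteins are ranked by decreasing score (ties broken by ascending
#' accession for determinism). For each term, the observed running-sum
#' enrichment score is compared with a null distribution obtained by
#' drawing `n_perm` random member sets of equal size from the ranked list
#' (gene-label permutation). The normalized enrichment score is
#' `NES = ES / mean(|null ES of the same sign|)` and the permutation
#' p-value is `(1 + #{same-sign null at least as extreme}) / (1 +
#' #{same-sign null})`; p-values are reported unadjusted. A term with no
#' same-sign null draw gets `p = 1/(1 + n_perm)`, `NES = NA`, and is
#' flagged.
#'
#' @param ranked_ids,scores Ids and ranking scores (any order; sorted
#'   internally by decreasing score).
#' @param collection Gene-set tibble (`term_id`, `description`,
#'   list-column `members`).
#' @param n_perm Number of permutations (>= 1; the reference configuration
#'   is 10000).
#' @param weight_exponent Hit-weight exponent (see [enrichment_score()]).
#' @param min_size,max_size Terms whose overlap with the ranked list falls
#'   outside this range are skipped.
#' @param seed Integer seed; identical seeds give identical results.
#' @return A `gsea_tbl` tibble: `term_id`, `description`, `es`, `nes`,
#'   `pvalue`, `set_size`, list-column `leading_edge`,
#'   `null_sign_degenerate`; ordered by `pvalue`.
#' @export
gsea <- function(ranked_ids, scores, collection, n_perm = 1000,
                 weight_exponent = 1, min_size = 3, max_size = 500,
                 seed = 1) {
  n_perm <- check_count(n_perm, "n_perm")
  if (anyDuplicated(ranked_ids)) abort("`ranked_ids` must be unique")
  ord <- order(-scores, ranked_ids)
  ids <- ranked_ids[ord]
  sc <- scores[ord]
  N <- length(ids)
  wts <- abs(sc)^weight_exponent

  res <- with_seed_(seed, {
    purrr::pmap(
      collection[c("term_id", "description", "members")],
      function(term_id, description, members) {
        m <- intersect(members, ids)
        size <- length(m)
        if (size < min_size || size > max_size || size >= N) return(NULL)
        obs <- enrichment_score(ids, sc, m, weight_exponent)
        null_es <- vapply(seq_len(n_perm), function(b) {
          idx <- sort(sample.int(N, size))
          es_from_hits_(idx, wts[idx], N)
        }, numeric(1))
        same <- if (obs$es >= 0) null_es >= 0 else null_es < 0
        n_same <- sum(same)
        degenerate <- n_same == 0
        if (degenerate) {
          p <- 1 / (1 + n_perm)
          nes <- NA_real_
        } else {
          p <- (1 + sum(same & abs(null_es) >= abs(obs$es))) / (1 + n_same)
          nes <- obs$es / mean(abs(null_es[same]))
        }
        tibble(
          term_id = term_id, description = description,
          es = obs$es, nes = nes, pvalue = p, set_size = size,
          leading_edge = list(obs$leading_edge),
          null_sign_degenerate = degenerate
        )
      }
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(
      term_id = character(), description = character(), es = numeric(),
      nes = numeric(), pvalue = numeric(), set_size = integer(),
      leading_edge = list(), null_sign_degenerate = logical()
    )
  }
  out <- out[order(out$pvalue, out$term_id), ]
  class(out) <- c("gsea_tbl", class(out))
  out
}

#' Rank a classified DC table for GSEA
#'
#' DC proteins are ranked by fold change in decreasing order, as required
#' by the preranked GSEA algorithm; ties are broken by ascending accession.
#'
#' @param dc_table A `dc_tbl`, usually restricted to DC proteins upstream.
#' @return A tibble with `protein_id` and `score` (`raw_fc`), sorted.
#' @export
rank_by_fold_change <- function(dc_table) {
  keep <- !is.na(dc_table$raw_fc)
  out <- tibble(protein_id = dc_table$protein_id[keep],
                score = dc_table$raw_fc[keep])
  out[order(-out$score, out$protein_id), ]
}

#' @method glance gsea_tbl
#' @export
glance.gsea_tbl <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    n_significant_p10 = sum(x$pvalue < 0.1),
    n_positive_es = sum(x$es > 0),
    min_pvalue = if (nrow(x)) min(x$pvalue) else NA_real_
  )
}
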