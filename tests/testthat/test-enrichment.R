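test_that("enrichment score reproduces worked examples and edge cases", {
  # single member at rank 1 / rank N
  expect_equal(enrichment_score(letters[1:6], 6:1, "a")$es, 1)
  expect_equal(enrichment_score(letters[1:6], 6:1, "f")$es, -1)

  # hits at ranks 1 and 3 of a 5-long list, unweighted
  res <- enrichment_score(letters[1:5], 5:1, c("a", "c"),
                          weight_exponent = 0)
  expect_equal(res$running_sum, c(1/2, 1/6, 2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(res$es, 2/3, tolerance = 1e-12)
  expect_setequal(res$leading_edge, c("a", "c"))

  expect_error(enrichment_score(letters[1:4], 4:1, "z"), "disjoint")
  expect_error(enrichment_score(letters[1:4], 4:1, letters[1:4]),
               "whole ranked list")
})

test_that("enrichment score equals brute-force enumeration on all small lists", {
  for (n in 2:8) {
    ids <- sprintf("g%d", seq_len(n))
    scores <- rev(seq_len(n)) + 0.5
    subsets <- unlist(lapply(seq_len(n - 1), function(k) {
      utils::combn(ids, k, simplify = FALSE)
    }), recursive = FALSE)
    for (p in c(0, 1)) {
      for (s in subsets) {
        expect_equal(enrichment_score(ids, scores, s, p)$es,
                     es_oracle(ids, scores, s, p), tolerance = 1e-12)
      }
    }
  }
})

test_that("closed-form permutation path equals the full running sum", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(10:60, 1)
    ids <- sprintf("g%d", seq_len(n))
    scores <- sort(rnorm(n), decreasing = TRUE)
    k <- sample(2:(n - 1), 1)
    members <- sample(ids, k)
    full <- enrichment_score(ids, scores, members, weight_exponent = 1)$es
    idx <- sort(which(ids %in% members))
    fast <- chaperomics:::es_from_hits_(idx, abs(scores[idx]), n)
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(13)
  n <- 50
  ids <- sprintf("g%02d", 1:n)
  scores <- sort(rexp(n) + 0.1, decreasing = TRUE)
  for (rep in 1:10) {
    members <- sample(ids, sample(3:15, 1))
    ours <- enrichment_score(ids, scores, members, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(setNames(scores, ids),
                               selectedStats = which(ids %in% members),
                               gseaParam = 1)
    if (ref != 0) {
      expect_equal(ours, ref, tolerance = 1e-9)
    } else {
      # fgsea reports 0 on an exact magnitude tie; our convention takes
      # the positive extremum of the same walk
      ext <- fgsea::calcGseaStat(setNames(scores, ids),
                                 selectedStats = which(ids %in% members),
                                 gseaParam = 1, returnAllExtremes = TRUE)
      expect_equal(ours, max(ext$tops), tolerance = 1e-9)
    }
  }
})

test_that("hypergeometric ORA p-values are exact tail sums", {
  # worked instance: N=10, K=4, n=5, k=3 -> 66/252
  universe <- sprintf("U%02d", 1:10)
  term <- universe[1:4]
  query <- c(universe[1:3], universe[9:10])
  coll <- tibble::tibble(term_id = "T1", description = "toy",
                         members = list(term))
  res <- hypergeometric_ora(query, universe, coll, min_size = 1)
  expect_equal(res$pvalue, 66 / 252, tolerance = 1e-12)
  expect_identical(res$overlap_k, 3L)
  expect_identical(res$bg_ratio, "4/10")

  # term covering the whole universe -> p = 1; zero overlap -> p = 1
  coll2 <- tibble::tibble(term_id = c("ALL", "NONE"),
                          description = "toy",
                          members = list(universe, universe[6:8]))
  res2 <- hypergeometric_ora(universe[1:5], universe, coll2, min_size = 1,
                             max_size = 100)
  expect_equal(res2$pvalue[res2$term_id == "ALL"], 1)
  expect_equal(res2$pvalue[res2$term_id == "NONE"], 1)

  # random instances with N <= 30 against the exact tail-sum oracle
  set.seed(5)
  for (rep in 1:200) {
    N <- sample(5:30, 1)
    universe <- sprintf("U%02d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    term <- sample(universe, K)
    query <- sample(universe, N)[seq_len(n)]
    coll <- tibble::tibble(term_id = "T", description = "t",
                           members = list(term))
    res <- suppressWarnings(
      hypergeometric_ora(query, universe, coll, min_size = 1,
                         max_size = 30))
    k <- length(intersect(term, query))
    expect_equal(res$pvalue, hyper_tail_oracle(N, K, n, k),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up closed form", {
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(21)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("permutation GSEA flags planted top-loaded sets and is seeded", {
  ids <- sprintf("G%03d", 1:100)
  scores <- seq(100, 1, length.out = 100)
  coll <- tibble::tibble(
    term_id = c("TOP", "BG"), description = c("top 5", "spread"),
    members = list(ids[1:5], ids[c(10, 30, 50, 70, 90)])
  )
  res <- gsea(ids, scores, coll, n_perm = 1000, seed = 7)
  top <- res[res$term_id == "TOP", ]
  expect_gt(top$nes, 0)
  expect_lte(top$pvalue, 0.01)
  expect_identical(top$set_size, 5L)
  expect_setequal(top$leading_edge[[1]], ids[1:5])

  res2 <- gsea(ids, scores, coll, n_perm = 1000, seed = 7)
  expect_identical(res, res2)
  res3 <- gsea(ids, scores, coll, n_perm = 1000, seed = 8)
  expect_false(identical(res$pvalue, res3$pvalue))
})

test_that("GSEA p-values are roughly uniform when scores carry no signal", {
  ids <- sprintf("G%03d", 1:60)
  scores <- rep(1, 60)
  set.seed(31)
  coll <- tibble::tibble(
    term_id = sprintf("S%02d", 1:50), description = "random",
    members = lapply(1:50, function(i) sample(ids, 8))
  )
  res <- gsea(ids, scores, coll, n_perm = 200, weight_exponent = 0,
              seed = 9)
  expect_identical(nrow(res), 50L)
  expect_gte(median(res$pvalue), 0.2)
  expect_lte(median(res$pvalue), 0.8)
})
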