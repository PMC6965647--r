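# Independent oracles coded directly from the definitions; they never call
# the package functions they are used to check.

# GSEA running-sum enrichment score by explicit enumeration of the walk.
es_oracle <- function(ranked_ids, scores, member_set, exponent) {
  hit <- ranked_ids %in% member_set
  w <- abs(scores[hit])^exponent
  if (sum(w) == 0) w <- rep(1, sum(hit))
  running <- numeric(length(ranked_ids))
  cur <- 0
  hi <- 0L
  for (i in seq_along(ranked_ids)) {
    if (hit[i]) {
      hi <- hi + 1L
      cur <- cur + w[hi] / sum(w)
    } else {
      cur <- cur - 1 / (length(ranked_ids) - sum(hit))
    }
    running[i] <- cur
  }
  mx <- max(running); mn <- min(running)
  if (mx >= -mn - 1e-12) mx else mn   # positive on a magnitude tie
}

# upper-tail hypergeometric P(X >= k) as an explicit binomial-coefficient
# tail sum; exact in double arithmetic for N <= 30.
hyper_tail_oracle <- function(N, K, n, k) {
  i <- seq(from = k, to = min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up closed form with a cumulative minimum.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# tiny complete dataset built by hand for deterministic preprocessing and
# DC tests: values are chosen tie-free
toy_dataset <- function(intensity, counts = NULL,
                        conditions = NULL, groups = NULL) {
  if (is.null(counts)) {
    counts <- matrix(1L, nrow(intensity), ncol(intensity),
                     dimnames = dimnames(intensity))
  }
  if (is.null(conditions)) {
    conditions <- rep(c("disease", "control"),
                      each = ncol(intensity) / 2)
  }
  if (is.null(groups)) groups <- conditions
  quant_dataset(intensity, counts, tibble::tibble(
    replicate = colnames(intensity),
    condition = conditions,
    sample_group = groups
  ))
}

named_matrix <- function(values, nrow, byrow = TRUE) {
  m <- matrix(values, nrow = nrow, byrow = byrow)
  dimnames(m) <- list(sprintf("P%05d", seq_len(nrow(m))),
                      sprintf("R%02d", seq_len(ncol(m))))
  m
}

# one full synthetic pipeline run: quant data -> DC classes -> hub network
# -> gene sets -> annotated graph; shared by iGSEA and acceptance tests
igsea_fixture <- function(seed, n_proteins = 2000, n_hubs = 2) {
  sim <- simulate_quant_dataset(sim_config(n_proteins = n_proteins,
                                           seed = seed))
  proc <- suppressWarnings(preprocess(sim$dataset))
  dc <- classify_dc(run_dc(proc), "network_human")
  hubs <- sprintf("H%05d", seq_len(n_hubs))
  net <- simulate_ppi_network(n_proteins, hub_ids = hubs,
                              node_ids = dc$protein_id, truth = sim$truth,
                              seed = seed + 1000L)
  gs <- simulate_gene_sets(net$graph, sim$truth, seed = seed + 2000L)
  list(
    sim = sim, dc = dc, hubs = hubs, net = net, gs = gs,
    annotated = annotate_nodes(net$graph, dc)
  )
}
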