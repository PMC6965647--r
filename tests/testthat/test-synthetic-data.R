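test_that("generators are bit-identical under the same seed", {
  cfg <- sim_config(n_proteins = 100, seed = 11)
  a <- simulate_quant_dataset(cfg)
  b <- simulate_quant_dataset(cfg)
  expect_identical(a$dataset$intensity, b$dataset$intensity)
  expect_identical(a$dataset$spectral_counts, b$dataset$spectral_counts)
  expect_identical(a$truth, b$truth)

  n1 <- simulate_ppi_network(50, hub_ids = "H00001", seed = 3)
  n2 <- simulate_ppi_network(50, hub_ids = "H00001", seed = 3)
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  expect_identical(n1$records, n2$records)

  g1 <- simulate_gene_sets(n1$graph, a$truth, n_terms = 8, n_planted = 0,
                           size_range = c(3, 10), seed = 5)
  g2 <- simulate_gene_sets(n2$graph, a$truth, n_terms = 8, n_planted = 0,
                           size_range = c(3, 10), seed = 5)
  expect_identical(g1$collection, g2$collection)

  o1 <- simulate_ortholog_fixture(40, seed = 7)
  o2 <- simulate_ortholog_fixture(40, seed = 7)
  expect_identical(o1, o2)
})

test_that("planted DC labels follow frac_dc exactly", {
  sim0 <- simulate_quant_dataset(sim_config(n_proteins = 100, frac_dc = 0,
                                            seed = 1))
  expect_length(sim0$truth$planted_disease_specific, 0)
  expect_length(sim0$truth$planted_control_specific, 0)

  sim <- simulate_quant_dataset(sim_config(n_proteins = 2000, frac_dc = 0.1,
                                           effect_fold = 2,
                                           n_replicates_per_condition = 6,
                                           seed = 1))
  tr <- sim$truth
  expect_identical(
    length(tr$planted_disease_specific) + length(tr$planted_control_specific),
    200L
  )
  expect_length(
    intersect(tr$planted_disease_specific, tr$planted_control_specific), 0
  )
  expect_true(all(c(tr$planted_disease_specific, tr$planted_control_specific)
                  %in% rownames(sim$dataset$intensity)))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_proteins = 1), "n_proteins")
  expect_error(sim_config(n_replicates_per_condition = 1),
               "n_replicates_per_condition")
  expect_error(sim_config(frac_dc = 1), "frac_dc")
  expect_error(sim_config(effect_fold = 0), "effect_fold")
  expect_error(sim_config(count_dispersion = -1), "count_dispersion")
})

test_that("dropout preferentially removes low-intensity observations", {
  cfg <- sim_config(n_proteins = 1000, frac_dc = 0, seed = 21)
  sim <- simulate_quant_dataset(cfg)
  miss <- is.na(sim$dataset$intensity)
  expect_gt(mean(miss), 0)
  # underlying per-protein baseline: dropped cells come from dimmer proteins
  base <- rowMeans(sim$dataset$intensity, na.rm = TRUE)
  part_missing <- is.finite(base) & rowSums(miss) > 0
  expect_lt(mean(base[part_missing]), mean(base[rowSums(miss) == 0]))
})

test_that("attachment process with m = 1 yields a connected simple tree", {
  net <- simulate_ppi_network(10, attachment_param = 1, seed = 2)
  g <- net$graph
  expect_identical(igraph::ecount(g), 9)
  expect_true(igraph::is_connected(g))
  expect_true(igraph::is_simple(g))
})

test_that("hubs seeded early acquire at least median degree", {
  hubs <- sprintf("H%05d", 1:4)
  net <- simulate_ppi_network(200, hub_ids = hubs, seed = 4)
  deg <- igraph::degree(net$graph)
  expect_gte(min(deg[hubs]), median(deg))
})

test_that("duplicate hub ids are rejected", {
  expect_error(simulate_ppi_network(20, hub_ids = c("A1", "A1"), seed = 1),
               "duplicate hub")
})

test_that("generated interaction tables round-trip through both parsers", {
  net <- simulate_ppi_network(40, hub_ids = "H00001", seed = 6)
  edge_key <- function(a, b) sort(paste(pmin(a, b), pmax(a, b)))
  want <- edge_key(net$records$interactor_a, net$records$interactor_b)
  for (dialect in c("tab_delimited", "psi_mitab")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_interaction_table(net$records, f, dialect)
    back <- suppressMessages(parse_interaction_tables(f, dialect))
    expect_identical(edge_key(back$interactor_a, back$interactor_b), want)
    expect_identical(back$experimental_system,
                     net$records$experimental_system)
  }
})

test_that("gene-set generator respects sizes and records planted truth", {
  sim <- simulate_quant_dataset(sim_config(n_proteins = 500, seed = 8))
  net <- simulate_ppi_network(500, hub_ids = "H00001",
                              node_ids = rownames(sim$dataset$intensity),
                              truth = sim$truth, seed = 8)
  gs0 <- simulate_gene_sets(net$graph, sim$truth, n_terms = 10,
                            n_planted = 0, size_range = c(5, 15), seed = 9)
  expect_identical(nrow(gs0$truth$planted_enriched_terms), 0L)
  expect_true(all(lengths(gs0$collection$members) >= 5 &
                    lengths(gs0$collection$members) <= 15))
  expect_error(
    simulate_gene_sets(net$graph, sim$truth, n_terms = 3, n_planted = 4,
                       seed = 1),
    "n_planted"
  )
})

test_that("planted terms overlap hub interactomes beyond uniform draws", {
  fx <- igsea_fixture(seed = 31, n_proteins = 800)
  tr <- fx$gs$truth$planted_enriched_terms
  expect_gt(nrow(tr), 0)
  for (i in seq_len(nrow(tr))) {
    term <- fx$gs$collection$members[[
      match(tr$term_id[i], fx$gs$collection$term_id)]]
    li <- local_interactome(fx$annotated, tr$hub[i],
                            pool = tr$pool[i])
    k <- length(intersect(term, li))
    # expected overlap of a uniform draw of the same size:
    # |term| * |interactome| / n_nodes (hypergeometric mean)
    expected <- length(term) * length(li) / igraph::vcount(fx$annotated)
    expect_gt(k, expected)
  }
})

test_that("ortholog fixture partitions entries as configured", {
  fx <- simulate_ortholog_fixture(100, frac_direct = 0.5, frac_hcop = 0.3,
                                  seed = 12)
  expect_identical(as.integer(table(fx$expected$method)[c("Direct", "HCOP",
                                                         "Unmapped")]),
                   c(50L, 30L, 20L))
  all_direct <- simulate_ortholog_fixture(20, frac_direct = 1,
                                          frac_hcop = 0, seed = 1)
  expect_true(all(all_direct$expected$method == "Direct"))
  none <- simulate_ortholog_fixture(20, frac_direct = 0, frac_hcop = 0,
                                    seed = 1)
  expect_true(all(none$expected$method == "Unmapped"))
  expect_error(simulate_ortholog_fixture(10, 0.7, 0.5, seed = 1),
               "frac_direct")
})
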