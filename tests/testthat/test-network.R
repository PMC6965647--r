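test_that("parsers handle empty and small fixtures in both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f)
  expect_identical(nrow(suppressMessages(
    parse_interaction_tables(f, "psi_mitab"))), 0L)

  writeLines(c("interactor_a\tinteractor_b\texperimental_system\texperimental_system_type\tsource_db\ttaxid_a\ttaxid_b",
               "P1\tP2\tTwo-hybrid\tphysical\tBioGRID\t9606\t9606",
               "P2\tP3\tAffinity Capture-MS\tphysical\tBioGRID\t9606\t9606",
               "P3\tP4\tReconstituted Complex\tphysical\tBioGRID\t9606\t9606"),
             f)
  recs <- suppressMessages(parse_interaction_tables(f, "tab_delimited"))
  expect_identical(nrow(recs), 3L)
  expect_identical(recs$interactor_a, c("P1", "P2", "P3"))

  # non-human interactors dropped when taxon columns carry other taxa
  writeLines(c("interactor_a\tinteractor_b\texperimental_system\texperimental_system_type\tsource_db\ttaxid_a\ttaxid_b",
               "P1\tP2\tTwo-hybrid\tphysical\tBioGRID\t9606\t9606",
               "P2\tP3\tTwo-hybrid\tphysical\tBioGRID\t10090\t9606"),
             f)
  recs <- suppressMessages(parse_interaction_tables(f, "tab_delimited"))
  expect_identical(nrow(recs), 1L)

  # malformed MITAB line skipped with a warning
  writeLines(c("uniprotkb:P1\tuniprotkb:P2\t-\t-\t-\t-\tpsi-mi:\"MI:0004\"(affinity chromatography technology)\t-\t-\ttaxid:9606(human)\ttaxid:9606(human)\tpsi-mi:\"MI:0915\"(physical association)\tpsi-mi:\"MI:0000\"(IntAct)\t-\t-",
               "too\tshort"), f)
  expect_warning(recs <- suppressMessages(
    parse_interaction_tables(f, "psi_mitab")), "malformed")
  expect_identical(nrow(recs), 1L)
})

test_that("the QC blacklist removes exactly the listed records", {
  systems <- c("Co-localization", "Genetic interference",
               "Synthetic Rescue", "Synthetic Growth Defect",
               "Synthetic Lethality")
  recs <- tibble::tibble(
    interactor_a = sprintf("A%d", 1:9),
    interactor_b = sprintf("B%d", 1:9),
    experimental_system = c(systems, tolower(systems[1]), "Two-hybrid",
                            "Affinity Capture-MS", "affinity chromatography technology"),
    interaction_type = c(rep("physical", 6), "genetic",
                         "psi-mi:MI:0208", "psi-mi:MI:0915"),
    source_db = "x", taxid_a = 9606L, taxid_b = 9606L
  )
  kept <- suppressMessages(filter_interactions(recs))
  # removed: five listed systems + lowercase variant + "genetic" type +
  # MI:0208; retained: the benign Two-hybrid-like record only
  expect_identical(kept$interactor_a, "A9")
  # a fully benign table passes untouched
  benign <- recs[9, ]
  expect_identical(suppressMessages(filter_interactions(benign)), benign)
})

test_that("network construction merges duplicates and drops self-loops", {
  recs <- tibble::tibble(
    interactor_a = c("A1", "B1", "A1"),
    interactor_b = c("B1", "A1", "A1"),
    interaction_type = "physical", experimental_system = "Two-hybrid",
    source_db = c("BioGRID", "IntAct", "BioGRID"),
    taxid_a = 9606L, taxid_b = 9606L
  )
  g <- build_network(recs)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
  expect_identical(igraph::E(g)$sources, "BioGRID;IntAct")

  # n unique filtered pairs -> n edges; adjacency symmetric
  net <- simulate_ppi_network(60, hub_ids = "H00001", seed = 14)
  g <- build_network(net$records)
  key <- unique(paste(pmin(net$records$interactor_a,
                           net$records$interactor_b),
                      pmax(net$records$interactor_a,
                           net$records$interactor_b)))
  expect_equal(igraph::ecount(g), length(key))
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_identical(adj, t(adj))
})

test_that("node annotation covers the union of network and DC proteins", {
  recs <- tibble::tibble(
    interactor_a = c("A1", "B1"), interactor_b = c("B1", "C1"),
    interaction_type = "physical", experimental_system = "Two-hybrid",
    source_db = "BioGRID", taxid_a = 9606L, taxid_b = 9606L
  )
  g <- build_network(recs)
  dc <- tibble::tibble(
    protein_id = c("A1", "D1"),
    raw_p = c(0.3, 0.01), raw_fc = c(1.5, 2),
    sc_p = NA_real_, sc_fc = NA_real_, sc_fc_undefined = TRUE
  )
  dc <- classify_dc(dc, "network_human")
  ann <- annotate_nodes(g, dc)
  expect_setequal(igraph::V(ann)$name, c("A1", "B1", "C1", "D1"))
  cls <- setNames(igraph::V(ann)$dc_class, igraph::V(ann)$name)
  # Raw.p 0.3 fails the 0.25 network threshold -> grey-equivalent
  expect_identical(cls[["A1"]], "unclassified")
  expect_identical(cls[["B1"]], "unclassified")   # absent from DC table
  expect_identical(cls[["D1"]], "disease_specific")
})

test_that("local interactomes intersect neighborhoods with DC pools", {
  # star: center H with leaves X (disease), Y (control), Z (unclassified)
  recs <- tibble::tibble(
    interactor_a = "H0", interactor_b = c("X0", "Y0", "Z0"),
    interaction_type = "physical", experimental_system = "Two-hybrid",
    source_db = "BioGRID", taxid_a = 9606L, taxid_b = 9606L
  )
  dc <- tibble::tibble(
    protein_id = c("X0", "Y0", "Z0"),
    raw_p = c(0.01, 0.01, 0.9), raw_fc = c(2, 0.5, 1.4),
    sc_p = NA_real_, sc_fc = NA_real_, sc_fc_undefined = TRUE
  )
  ann <- annotate_nodes(build_network(recs), classify_dc(dc, "network_human"))
  expect_identical(local_interactome(ann, "H0", "disease_specific"), "X0")
  expect_identical(local_interactome(ann, "H0", "control_specific"), "Y0")
  expect_setequal(local_interactome(ann, "H0", "all"),
                  c(local_interactome(ann, "H0", "disease_specific"),
                    local_interactome(ann, "H0", "control_specific"),
                    "Z0"))
  # leaves see only the center
  expect_identical(local_interactome(ann, "X0", "all"), "H0")
  expect_warning(out <- local_interactome(ann, "NOPE", "all"),
                 "not a network node")
  expect_length(out, 0)
})

test_that("alteration summary follows the documented edge rule", {
  tri <- function(classes) {
    recs <- tibble::tibble(
      interactor_a = c("A0", "B0", "C0"), interactor_b = c("B0", "C0", "A0"),
      interaction_type = "physical", experimental_system = "Two-hybrid",
      source_db = "BioGRID", taxid_a = 9606L, taxid_b = 9606L
    )
    g <- build_network(recs)
    igraph::set_vertex_attr(g, "dc_class",
                            value = classes[igraph::V(g)$name])
  }
  # all unclassified: every percentage zero
  s <- network_alteration_summary(tri(c(A0 = "unclassified",
                                        B0 = "unclassified",
                                        C0 = "unclassified")))
  expect_true(all(unlist(s) == 0))

  # two disease nodes: every edge touches a disease node and none a
  # control node -> all three edges gained
  s <- network_alteration_summary(tri(c(A0 = "disease_specific",
                                        B0 = "disease_specific",
                                        C0 = "unclassified")))
  expect_equal(s$pct_edges_gained, 100)
  expect_equal(s$pct_edges_lost, 0)
  expect_equal(s$pct_nodes_altered, 100 * 2 / 3)

  # mixed edge follows the tie rule
  cls <- c(A0 = "disease_specific", B0 = "control_specific",
           C0 = "unclassified")
  expect_equal(network_alteration_summary(tri(cls))$pct_edges_gained,
               100 * 2 / 3)
  expect_equal(network_alteration_summary(tri(cls),
                                          mixed_edge = "lost")$pct_edges_lost,
               100 * 2 / 3)
})

test_that("gained plus lost equals altered on random annotated graphs", {
  for (seed in 1:3) {
    fx <- igsea_fixture(seed = seed, n_proteins = 150)
    s <- network_alteration_summary(fx$annotated)
    expect_equal(s$pct_nodes_gained + s$pct_nodes_lost, s$pct_nodes_altered)
    expect_equal(s$pct_edges_gained + s$pct_edges_lost, s$pct_edges_altered)
    expect_true(all(unlist(s) >= 0 & unlist(s) <= 100))
  }
})
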