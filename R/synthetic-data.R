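#' Configuration for the synthetic AP-MS generator
#'
#' Bundles the generative model parameters for [simulate_quant_dataset()]:
#' a two-condition AP-MS experiment with log10-normal protein baselines,
#' i.i.d. normal replicate noise on the log10 scale, a planted fraction of
#' differentially connected (DC) proteins with a multiplicative intensity
#' shift, negative-binomial spectral counts, and missing-not-at-random
#' dropout that follows a logistic curve in log10 intensity.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param n_replicates_per_condition Replicates per condition (>= 2).
#' @param baseline_log10_mean,baseline_log10_sd Mean and SD of the
#'   per-protein baseline drawn once on the log10 intensity scale. Defaults
#'   (7, 1) put typical MS1 intensities near 1e7.
#' @param noise_log10_sd Replicate-to-replicate noise SD on the log10 scale.
#' @param frac_dc Fraction of proteins planted as differentially connected,
#'   in `[0, 1)`; split half disease-specific, half control-specific.
#' @param effect_fold Multiplicative intensity shift (> 0) applied to the
#'   disease replicates of planted disease-specific proteins; planted
#'   control-specific proteins receive `1 / effect_fold`.
#' @param count_dispersion Negative-binomial dispersion of spectral counts
#'   (> 0); variance = mu + dispersion * mu^2.
#' @param dropout_logistic_midpoint log10 intensity at which the dropout
#'   probability is 50%.
#' @param dropout_logistic_slope Steepness (> 0) of the dropout logistic;
#'   lower intensity always means a higher dropout probability.
#' @param seed Integer seed; identical configurations give bit-identical
#'   output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_replicates_per_condition = 6,
                       baseline_log10_mean = 7,
                       baseline_log10_sd = 1,
                       noise_log10_sd = 0.1,
                       frac_dc = 0.1,
                       effect_fold = 2,
                       count_dispersion = 0.5,
                       dropout_logistic_midpoint = 5.5,
                       dropout_logistic_slope = 2,
                       seed = 1) {
  cfg <- list(
    n_proteins = check_count(n_proteins, "n_proteins", min = 2L),
    n_replicates_per_condition = check_count(
      n_replicates_per_condition, "n_replicates_per_condition", min = 2L
    ),
    baseline_log10_mean = as.numeric(baseline_log10_mean),
    baseline_log10_sd = check_positive(baseline_log10_sd, "baseline_log10_sd"),
    noise_log10_sd = check_positive(noise_log10_sd, "noise_log10_sd"),
    frac_dc = check_fraction(frac_dc, "frac_dc", upper_open = TRUE),
    effect_fold = check_positive(effect_fold, "effect_fold"),
    count_dispersion = check_positive(count_dispersion, "count_dispersion"),
    dropout_logistic_midpoint = as.numeric(dropout_logistic_midpoint),
    dropout_logistic_slope = check_positive(
      dropout_logistic_slope, "dropout_logistic_slope"
    ),
    seed = check_count(seed, "seed", min = 0L)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a two-condition AP-MS quantification dataset
#'
#' Draws a [quant_dataset] under the model described in [sim_config()] and
#' returns it together with the planted ground truth. Per protein, a baseline
#' log10 intensity is drawn once and shared across conditions; replicate
#' values add i.i.d. normal noise; planted disease-specific proteins have
#' their disease replicates multiplied by `effect_fold` (control-specific by
#' `1/effect_fold`). Spectral counts are negative binomial with mean
#' proportional to the linear intensity. Each cell is then dropped
#' (set `NA` in both matrices) with probability
#' `plogis(slope * (midpoint - log10_intensity))`, so low-abundance
#' observations are missing more often — the missing-not-at-random pattern
#' typical of label-free MS.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [quant_dataset]) and `truth`
#'   (a `sim_truth` list with character vectors `planted_disease_specific`
#'   and `planted_control_specific`, and a `planted_enriched_terms` tibble
#'   filled in by [simulate_gene_sets()]).
#' @examples
#' sim <- simulate_quant_dataset(sim_config(n_proteins = 50, seed = 7))
#' sim$dataset
#' length(sim$truth$planted_disease_specific)
#' @export
simulate_quant_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_proteins
  k <- config$n_replicates_per_condition
  ids <- sprintf("P%05d", seq_len(n))
  reps <- c(sprintf("D%02d", seq_len(k)), sprintf("C%02d", seq_len(k)))
  condition <- rep(c("disease", "control"), each = k)

  with_seed_(config$seed, {
    n_dc <- round(config$frac_dc * n)
    planted <- sample(ids, n_dc)
    n_dis <- ceiling(n_dc / 2)
    planted_dis <- sort(planted[seq_len(n_dis)])
    planted_con <- sort(setdiff(planted, planted_dis))

    base <- rnorm(n, config$baseline_log10_mean, config$baseline_log10_sd)
    log10_mat <- matrix(
      base + rnorm(n * 2L * k, 0, config$noise_log10_sd),
      nrow = n, ncol = 2L * k, dimnames = list(ids, reps)
    )
    shift <- log10(config$effect_fold)
    disease_cols <- which(condition == "disease")
    log10_mat[ids %in% planted_dis, disease_cols] <-
      log10_mat[ids %in% planted_dis, disease_cols] + shift
    log10_mat[ids %in% planted_con, disease_cols] <-
      log10_mat[ids %in% planted_con, disease_cols] - shift

    intensity <- 10^log10_mat
    mu <- 20 * intensity / 10^config$baseline_log10_mean
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / config$count_dispersion),
      nrow = n, dimnames = dimnames(intensity)
    )

    p_drop <- plogis(config$dropout_logistic_slope *
                       (config$dropout_logistic_midpoint - log10_mat))
    dropped <- matrix(runif(length(p_drop)) < p_drop, nrow = n)
    intensity[dropped] <- NA_real_
    counts[dropped] <- NA_integer_

    samples <- tibble(
      replicate = reps,
      condition = condition,
      sample_group = condition
    )
    truth <- structure(
      list(
        planted_disease_specific = planted_dis,
        planted_control_specific = planted_con,
        planted_enriched_terms = tibble(
          term_id = character(), hub = character(),
          pool = character(), overlap_fraction = numeric()
        )
      ),
      class = "sim_truth"
    )
    list(
      dataset = quant_dataset(intensity, counts, samples),
      truth = truth
    )
  })
}

#' Simulate a scale-free PPI reference network with designated hubs
#'
#' Grows an undirected simple preferential-attachment (Barabasi-Albert)
#' graph and labels its earliest-attached vertices — those with the highest
#' expected degree — with the supplied chaperome hub accessions, so the hubs
#' are guaranteed to sit in dense neighborhoods. Also emits a flat
#' interaction-record table (random benign experimental annotations drawn
#' from both supported database dialects) that round-trips through
#' [parse_interaction_tables()].
#'
#' @param n_nodes Number of proteins in the network.
#' @param hub_ids Character vector of accessions to seed as early
#'   high-degree nodes; duplicates are rejected.
#' @param attachment_param Edges added per incoming vertex (Barabasi-Albert
#'   `m`); must be `< n_nodes`.
#' @param node_ids Optional pool of accessions for the non-hub vertices
#'   (e.g. the proteins of a simulated quant dataset); autogenerated when
#'   `NULL`.
#' @param truth Optional `sim_truth` from [simulate_quant_dataset()]. When
#'   given, each hub is additionally wired to a random fraction
#'   `hub_pool_frac` of each planted DC pool present among the network's
#'   nodes — chaperome hubs physically interact with the differentially
#'   connected proteins, which is what places a recoverable signal in their
#'   first-degree interactomes.
#' @param hub_pool_frac Fraction of each planted pool wired to each hub.
#' @param seed Integer seed.
#' @return A list with `graph` (an igraph object with vertex names and a
#'   `hub_ids` graph attribute) and `records` (an interaction-record tibble
#'   with columns `interactor_a`, `interactor_b`, `interaction_type`,
#'   `experimental_system`, `source_db`, `taxid_a`, `taxid_b`).
#' @export
simulate_ppi_network <- function(n_nodes, hub_ids = character(),
                                 attachment_param = 2, node_ids = NULL,
                                 truth = NULL, hub_pool_frac = 0.5,
                                 seed = 1) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  attachment_param <- check_count(attachment_param, "attachment_param")
  if (attachment_param >= n_nodes) {
    abort("`n_nodes` must exceed `attachment_param`")
  }
  hub_ids <- canonicalize_accession(hub_ids)
  if (anyDuplicated(hub_ids)) abort("duplicate hub ids")
  if (length(hub_ids) > n_nodes) abort("more hubs than nodes")

  with_seed_(seed, {
    g <- igraph::sample_pa(n_nodes, power = 1, m = attachment_param,
                           directed = FALSE)
    if (is.null(node_ids)) {
      node_ids <- sprintf("Q%05d", seq_len(n_nodes))
    } else {
      node_ids <- canonicalize_accession(node_ids)
    }
    others <- setdiff(node_ids, hub_ids)
    if (length(others) < n_nodes - length(hub_ids)) {
      abort("`node_ids` does not supply enough non-hub accessions")
    }
    others <- sample(others)[seq_len(n_nodes - length(hub_ids))]
    igraph::V(g)$name <- c(hub_ids, others)
    g <- igraph::set_graph_attr(g, "hub_ids", hub_ids)

    if (!is.null(truth) && length(hub_ids)) {
      pools <- list(truth$planted_disease_specific,
                    truth$planted_control_specific)
      new_edges <- character()
      for (hub in hub_ids) {
        for (pool_ids in pools) {
          present <- intersect(pool_ids, igraph::V(g)$name)
          n_wire <- round(hub_pool_frac * length(present))
          if (n_wire > 0) {
            new_edges <- c(new_edges,
                           rbind(hub, sample(present, n_wire)))
          }
        }
      }
      if (length(new_edges)) {
        g <- igraph::simplify(igraph::add_edges(g, new_edges))
      }
    }

    el <- igraph::as_edgelist(g)
    m <- nrow(el)
    from_biogrid <- runif(m) < 0.5
    systems_bg <- c("Affinity Capture-MS", "Two-hybrid",
                    "Reconstituted Complex", "Co-fractionation")
    types_ia <- c("psi-mi:MI:0915", "psi-mi:MI:0407")
    records <- tibble(
      interactor_a = el[, 1],
      interactor_b = el[, 2],
      interaction_type = ifelse(from_biogrid, "physical",
                                sample(types_ia, m, replace = TRUE)),
      experimental_system = ifelse(
        from_biogrid, sample(systems_bg, m, replace = TRUE),
        "affinity chromatography technology"
      ),
      source_db = ifelse(from_biogrid, "BioGRID", "IntAct"),
      taxid_a = 9606L,
      taxid_b = 9606L
    )
    list(graph = g, records = records)
  })
}

#' Simulate a gene-set collection with enrichment planted in hub
#' neighborhoods
#'
#' Background terms are uniform random member draws from the network's
#' proteins. Planted terms are built preferentially from the first-degree
#' neighbors of a designated hub intersected with a planted DC pool, so the
#' local-interactome enrichment procedure ([run_igsea()]) has a recoverable
#' signal. The updated truth object records each planted (hub, pool, term)
#' triple.
#'
#' @param network The `graph` element returned by [simulate_ppi_network()]
#'   (its `hub_ids` attribute names the candidate hubs).
#' @param truth A `sim_truth` from [simulate_quant_dataset()].
#' @param n_terms Total number of terms to emit.
#' @param size_range Length-2 integer vector; every emitted set size falls
#'   in this range (min >= 3).
#' @param n_planted Number of planted terms (`<= n_terms`).
#' @param planted_overlap Fraction of a planted term drawn from the target
#'   hub neighborhood (the rest is random padding).
#' @param seed Integer seed.
#' @return A list with `collection` (tibble: `term_id`, `description`,
#'   list-column `members`) and `truth` (updated `sim_truth`).
#' @export
simulate_gene_sets <- function(network, truth, n_terms = 30,
                               size_range = c(5, 25), n_planted = 2,
                               planted_overlap = 0.8, seed = 1) {
  n_terms <- check_count(n_terms, "n_terms")
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  if (n_planted > n_terms) abort("`n_planted` exceeds `n_terms`")
  nodes <- igraph::V(network)$name
  if (size_range[1] < 3 || size_range[2] > length(nodes) ||
      size_range[1] > size_range[2]) {
    abort("`size_range` must lie within [3, n_nodes]")
  }
  hubs <- igraph::graph_attr(network, "hub_ids")
  if (n_planted > 0 && length(hubs) == 0) {
    abort("network has no designated hubs to plant enrichment on")
  }

  with_seed_(seed, {
    planted_rows <- list()
    terms <- vector("list", n_terms)
    sizes <- sample(seq(size_range[1], size_range[2]), n_terms,
                    replace = TRUE)
    pools <- c("disease_specific", "control_specific")
    for (i in seq_len(n_terms)) {
      if (i <= n_planted) {
        hub <- hubs[((i - 1L) %% length(hubs)) + 1L]
        pool <- pools[((i - 1L) %% 2L) + 1L]
        pool_ids <- if (pool == "disease_specific") {
          truth$planted_disease_specific
        } else {
          truth$planted_control_specific
        }
        target <- intersect(
          igraph::V(network)$name[igraph::neighbors(network, hub)],
          pool_ids
        )
        if (length(target) < 3) {
          abort(sprintf(
            "hub %s has only %d planted %s neighbors; grow the network or the planted pools",
            hub, length(target), pool
          ))
        }
        size <- max(sizes[i], 5L)
        k <- min(length(target), max(3L, round(planted_overlap * size)))
        core <- sample(target, k)
        pad <- sample(setdiff(nodes, c(core, hub)), size - k)
        terms[[i]] <- sort(c(core, pad))
        planted_rows[[i]] <- tibble(
          term_id = sprintf("T%03d", i), hub = hub, pool = pool,
          overlap_fraction = k / size
        )
      } else {
        terms[[i]] <- sort(sample(nodes, sizes[i]))
      }
    }
    collection <- tibble(
      term_id = sprintf("T%03d", seq_len(n_terms)),
      description = ifelse(seq_len(n_terms) <= n_planted,
                           "synthetic planted term",
                           "synthetic background term"),
      members = terms
    )
    truth$planted_enriched_terms <- dplyr::bind_rows(
      truth$planted_enriched_terms, planted_rows
    )
    list(collection = collection, truth = truth)
  })
}

#' Simulate a mouse-to-human ortholog-mapping fixture
#'
#' Emits a mouse protein list, a human reference table (entry name ->
#' accession) supporting the direct `_MOUSE` -> `_HUMAN` suffix conversion,
#' an HCOP-style pair table supporting the second mapping step, and the
#' exact expected mapping, including entries mappable only through HCOP and
#' entries unmappable by either step. A few direct-mappable entries also
#' appear in the HCOP table so the step-1 precedence rule is exercised, and
#' the HCOP table carries duplicated rows to exercise load-time
#' deduplication.
#'
#' @param n Number of mouse proteins.
#' @param frac_direct Fraction mappable by the suffix step.
#' @param frac_hcop Fraction mappable only by the HCOP step
#'   (`frac_direct + frac_hcop <= 1`).
#' @param seed Integer seed.
#' @return A list with `mouse_entries`, `human_reference` (tibble
#'   `entry_name`, `accession`), `hcop_pairs` (tibble `mouse_id`,
#'   `human_accession`), and `expected` (tibble `source_entry`,
#'   `mapped_accession`, `method`).
#' @export
simulate_ortholog_fixture <- function(n, frac_direct = 0.5, frac_hcop = 0.3,
                                      seed = 1) {
  n <- check_count(n, "n")
  frac_direct <- check_fraction(frac_direct, "frac_direct")
  frac_hcop <- check_fraction(frac_hcop, "frac_hcop")
  if (frac_direct + frac_hcop > 1) {
    abort("`frac_direct` + `frac_hcop` must not exceed 1")
  }
  with_seed_(seed, {
    genes <- sprintf("G%03d", seq_len(n))
    mouse <- paste0(genes, "_MOUSE")
    n_direct <- round(frac_direct * n)
    n_hcop <- min(round(frac_hcop * n), n - n_direct)
    method <- rep("Unmapped", n)
    lab <- sample(n)
    direct_idx <- lab[seq_len(n_direct)]
    hcop_idx <- lab[seq_len(n_hcop) + n_direct]
    method[direct_idx] <- "Direct"
    method[hcop_idx] <- "HCOP"

    acc <- sprintf("P%05d", sample(10000:99999, n))
    human_reference <- tibble(
      entry_name = paste0(genes[direct_idx], "_HUMAN"),
      accession = acc[direct_idx]
    )
    overlap <- head(direct_idx, 3L)   # mappable by both steps -> Direct wins
    hcop_pairs <- tibble(
      mouse_id = mouse[c(hcop_idx, overlap)],
      human_accession = c(acc[hcop_idx],
                          sprintf("P%05d", 1000 + seq_along(overlap)))
    )
    hcop_pairs <- dplyr::bind_rows(hcop_pairs, head(hcop_pairs, 2L))

    expected <- tibble(
      source_entry = mouse,
      mapped_accession = ifelse(method == "Unmapped", NA_character_, acc),
      method = method
    )
    list(
      mouse_entries = mouse,
      human_reference = human_reference,
      hcop_pairs = hcop_pairs,
      expected = expected
    )
  })
}
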