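#' Drop vague annotation terms from a gene-set collection
#'
#' Removes terms whose name matches the exclusion list by case-insensitive
#' exact match on either the term id or the description. The default list
#' excludes the uninformative ontology terms "protein binding", "plasma
#' membrane" and "integral component of plasma membrane".
#'
#' @param collection Gene-set tibble (`term_id`, `description`,
#'   list-column `members`).
#' @param excluded_names Character vector of names to remove.
#' @return The filtered collection.
#' @export
filter_vague_terms <- function(collection,
                               excluded_names = c(
                                 "protein binding", "plasma membrane",
                                 "integral component of plasma membrane")) {
  if (!length(excluded_names)) return(collection)
  ex <- tolower(trimws(excluded_names))
  drop <- tolower(trimws(collection$term_id)) %in% ex |
    tolower(trimws(collection$description)) %in% ex
  collection[!drop, ]
}

#' Interactome gene-set enrichment analysis (iGSEA)
#'
#' For each chaperome member and each differential-connectivity pool, the
#' member's first-degree interactome restricted to that pool
#' ([local_interactome()]) is tested for term enrichment, attributing
#' annotations to the chaperome member from the terms of its direct
#' interactors. The default engine is hypergeometric over-representation
#' with Benjamini-Hochberg adjustment within each member x pool analysis
#' (matching the reported GeneRatio/BgRatio/qvalue/adjusted-p fields); a
#' preranked permutation-GSEA engine over the member's full local
#' interactome is available via `engine = "gsea"`. Associations with
#' adjusted p below `alpha` are retained.
#'
#' @param network Annotated igraph network ([annotate_nodes()]).
#' @param chaperome Chaperome member tibble ([read_chaperome_list()]) or
#'   character vector of accessions. Members absent from the network are
#'   skipped with a notice.
#' @param collection Gene-set tibble; vague terms are removed first via
#'   [filter_vague_terms()] with `excluded_names`.
#' @param alpha Retention threshold on the adjusted p-value (default 0.1).
#' @param universe_policy Enrichment background: `"dc_annotated"` (all
#'   DC-tested proteins that appear in the collection; default),
#'   `"network"` (all network nodes) or `"collection"` (all annotated
#'   proteins).
#' @param excluded_names Vague-term names to drop (see
#'   [filter_vague_terms()]).
#' @param engine `"ora"` (default) or `"gsea"`.
#' @param bh_family `"per_analysis"` (BH within each member x pool run,
#'   default) or `"global"` (one BH family across all members and pools).
#' @param min_size,max_size Term-size limits passed to the engine.
#' @param n_perm,weight_exponent,seed Parameters for the `"gsea"` engine.
#' @return An `igsea_tbl` tibble: `chaperome_member`, `pool`, `term_id`,
#'   `description`, `pvalue`, `p_adjust`, `qvalue`, plus engine-specific
#'   columns (`gene_ratio`, `bg_ratio`, `overlap_k`, list-column
#'   `overlap_members` for ORA; `es`, `nes`, `set_size` for GSEA).
#' @examples
#' sim <- simulate_quant_dataset(sim_config(n_proteins = 300, seed = 5))
#' dc <- classify_dc(run_dc(preprocess(sim$dataset)), "network_human")
#' net <- simulate_ppi_network(300, hub_ids = "P99999",
#'                             node_ids = dc$protein_id[-1], seed = 5)
#' gs <- simulate_gene_sets(net$graph, sim$truth, n_terms = 10,
#'                          n_planted = 0, seed = 5)
#' ann <- annotate_nodes(net$graph, dc)
#' run_igsea(ann, "P99999", gs$collection)
#' @export
run_igsea <- function(network, chaperome, collection, alpha = 0.1,
                      universe_policy = c("dc_annotated", "network",
                                          "collection"),
                      excluded_names = c(
                        "protein binding", "plasma membrane",
                        "integral component of plasma membrane"),
                      engine = c("ora", "gsea"),
                      bh_family = c("per_analysis", "global"),
                      min_size = 3, max_size = 500,
                      n_perm = 1000, weight_exponent = 1, seed = 1) {
  universe_policy <- match.arg(universe_policy)
  engine <- match.arg(engine)
  bh_family <- match.arg(bh_family)
  if (is.data.frame(chaperome)) chaperome <- chaperome$accession
  chaperome <- unique(canonicalize_accession(chaperome))
  if (!length(chaperome)) abort("empty chaperome list")
  collection <- filter_vague_terms(collection, excluded_names)

  nodes <- igraph::V(network)$name
  if (is.null(igraph::vertex_attr(network, "dc_class"))) {
    abort("network is not annotated; run annotate_nodes() first")
  }
  annotated <- unique(unlist(collection$members))
  universe <- switch(
    universe_policy,
    dc_annotated = intersect(
      nodes[!is.na(igraph::vertex_attr(network, "raw_p"))], annotated),
    network = nodes,
    collection = annotated
  )
  if (!length(universe)) abort("empty enrichment universe under this policy")

  missing_members <- setdiff(chaperome, nodes)
  if (length(missing_members)) {
    inform(sprintf("%d chaperome member(s) absent from the network skipped",
                   length(missing_members)))
    chaperome <- setdiff(chaperome, missing_members)
  }

  pools <- c("disease_specific", "control_specific")
  rows <- list()
  for (member in chaperome) {
    for (pool in pools) {
      query <- intersect(local_interactome(network, member, pool), universe)
      if (!length(query)) next
      if (engine == "ora") {
        res <- hypergeometric_ora(query, universe, collection,
                                  min_size = min_size, max_size = max_size)
      } else {
        nb <- local_interactome(network, member, "all")
        fc <- igraph::vertex_attr(network, "raw_fc",
                                  index = match(nb, nodes))
        keep <- !is.na(fc)
        if (sum(keep) < min_size + 1) next
        res <- gsea(nb[keep], fc[keep], collection, n_perm = n_perm,
                    weight_exponent = weight_exponent, min_size = min_size,
                    max_size = max_size, seed = seed)
        res$p_adjust <- res$pvalue   # reported unadjusted by convention
        res$qvalue <- res$pvalue
      }
      if (!nrow(res)) next
      res$chaperome_member <- member
      res$pool <- pool
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(chaperome_member = character(), pool = character(),
                  term_id = character(), description = character(),
                  pvalue = numeric(), p_adjust = numeric(),
                  qvalue = numeric())
  } else {
    if (bh_family == "global" && engine == "ora") {
      out$p_adjust <- bh_adjust(out$pvalue)
      out$qvalue <- out$p_adjust
    }
    out <- out[!is.na(out$p_adjust) & out$p_adjust < alpha, ]
    front <- c("chaperome_member", "pool", "term_id", "description",
               "pvalue", "p_adjust", "qvalue")
    out <- out[, c(front, setdiff(names(out), front))]
    out <- out[order(out$chaperome_member, out$pool, out$p_adjust,
                     out$term_id), ]
  }
  class(out) <- c("igsea_tbl", setdiff(class(out), "ora_tbl"))
  out
}

#' @method glance igsea_tbl
#' @export
glance.igsea_tbl <- function(x, ...) {
  tibble(
    n_associations = nrow(x),
    n_members = length(unique(x$chaperome_member)),
    n_terms = length(unique(x$term_id)),
    n_disease = sum(x$pool == "disease_specific"),
    n_control = sum(x$pool == "control_specific")
  )
}

#' Export iGSEA associations as Cytoscape-importable tables
#'
#' Writes a bipartite edge table with columns `Chaperome_ID` and
#' `Description` (interactors A and B), edge attributes (`pvalue`,
#' `GeneRatio`, `BgRatio`, `qvalue`, `p.adjust`) and an edge `class` column
#' derived from the DC pool (`red` = disease-specific, `blue` =
#' control-specific), plus a node table restricted to nodes with at least
#' one edge (unconnected terms removed).
#'
#' @param associations An `igsea_tbl` from [run_igsea()].
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
export_igsea_cytoscape <- function(associations, out_dir, prefix = "igsea") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edges = file.path(out_dir, paste0(prefix, "_edges.tsv")),
    nodes = file.path(out_dir, paste0(prefix, "_nodes.tsv"))
  )
  n <- nrow(associations)
  edges <- tibble(
    Chaperome_ID = associations$chaperome_member %||% character(),
    Description = associations$description %||% character(),
    pvalue = associations$pvalue %||% numeric(),
    GeneRatio = if (n && !is.null(associations$gene_ratio))
      associations$gene_ratio else rep(NA_character_, n),
    BgRatio = if (n && !is.null(associations$bg_ratio))
      associations$bg_ratio else rep(NA_character_, n),
    qvalue = associations$qvalue %||% numeric(),
    p.adjust = associations$p_adjust %||% numeric(),
    class = if (n) ifelse(associations$pool == "disease_specific",
                          "red", "blue") else character()
  )
  readr::write_tsv(edges, paths["edges"])
  nodes <- dplyr::bind_rows(
    tibble(node_id = unique(edges$Chaperome_ID), node_type = "chaperome"),
    tibble(node_id = unique(edges$Description), node_type = "term")
  )
  readr::write_tsv(nodes, paths["nodes"])
  invisible(paths)
}
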