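#' Parse interaction-database dumps
#'
#' Reads one or more interaction tables in either supported dialect and
#' returns a unified record tibble with canonicalized accessions.
#' Non-human interactors are dropped when taxon fields are present in the
#' file; otherwise all records pass with a notice. Malformed lines are
#' skipped with a counted warning.
#'
#' * `tab_delimited` — BioGRID-style TSV with a header. Columns are located
#'   case-insensitively through `col_map` (defaults match
#'   [write_interaction_table()]).
#' * `psi_mitab` — headerless PSI-MITAB 2.5; identifiers are taken from
#'   columns 1-2 (`uniprotkb:` prefix stripped), the detection method from
#'   column 7, taxa from columns 10-11, the interaction type's MI code from
#'   column 12 and the source database from column 13.
#'
#' @param paths Character vector of file paths.
#' @param dialect `"tab_delimited"` or `"psi_mitab"`.
#' @param col_map Named character vector for the tab-delimited dialect.
#' @return Tibble with columns `interactor_a`, `interactor_b`,
#'   `interaction_type`, `experimental_system`, `source_db`, `taxid_a`,
#'   `taxid_b`.
#' @export
parse_interaction_tables <- function(paths,
                                     dialect = c("tab_delimited", "psi_mitab"),
                                     col_map = c(
                                       interactor_a = "interactor_a",
                                       interactor_b = "interactor_b",
                                       experimental_system = "experimental_system",
                                       interaction_type = "experimental_system_type",
                                       source_db = "source_db",
                                       taxid_a = "taxid_a",
                                       taxid_b = "taxid_b")) {
  dialect <- match.arg(dialect)
  parser <- if (dialect == "tab_delimited") {
    function(p) parse_tab_delimited_(p, col_map)
  } else {
    parse_psi_mitab_
  }
  recs <- dplyr::bind_rows(lapply(paths, parser))
  if (nrow(recs) == 0) return(empty_records_())
  recs$interactor_a <- canonicalize_accession(recs$interactor_a)
  recs$interactor_b <- canonicalize_accession(recs$interactor_b)
  if (all(is.na(recs$taxid_a)) && all(is.na(recs$taxid_b))) {
    inform("no taxon fields present; all records retained")
  } else {
    human <- (is.na(recs$taxid_a) | recs$taxid_a == 9606L) &
      (is.na(recs$taxid_b) | recs$taxid_b == 9606L)
    if (any(!human)) {
      inform(sprintf("dropped %d non-human record(s)", sum(!human)))
    }
    recs <- recs[human, ]
  }
  recs
}

empty_records_ <- function() {
  tibble(interactor_a = character(), interactor_b = character(),
         interaction_type = character(), experimental_system = character(),
         source_db = character(), taxid_a = integer(), taxid_b = integer())
}

parse_tab_delimited_ <- function(path, col_map) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA", "-"))
  if (nrow(tbl) == 0) return(empty_records_())
  lookup <- setNames(names(tbl), tolower(names(tbl)))
  pick <- function(field, default = NA) {
    nm <- lookup[tolower(col_map[[field]])]
    if (!is.na(nm)) tbl[[nm]] else rep(default, nrow(tbl))
  }
  a <- pick("interactor_a"); b <- pick("interactor_b")
  bad <- is.na(a) | is.na(b)
  if (any(bad)) {
    warn(sprintf("skipped %d malformed line(s) in %s", sum(bad), path))
  }
  out <- tibble(
    interactor_a = as.character(a),
    interactor_b = as.character(b),
    interaction_type = as.character(pick("interaction_type", NA_character_)),
    experimental_system = as.character(pick("experimental_system", NA_character_)),
    source_db = as.character(pick("source_db", "BioGRID")),
    taxid_a = suppressWarnings(as.integer(pick("taxid_a", NA_integer_))),
    taxid_b = suppressWarnings(as.integer(pick("taxid_b", NA_integer_)))
  )
  out[!bad, ]
}

# text inside the first (...) of a psi-mi field, else the raw field
mi_label_ <- function(x) {
  lab <- stringr::str_match(x, "\\(([^)]*)\\)")[, 2]
  ifelse(is.na(lab), x, lab)
}

mi_code_ <- function(x) stringr::str_extract(x, "MI:\\d{4}")

parse_psi_mitab_ <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_records_())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 13L
  if (any(!ok)) {
    warn(sprintf("skipped %d malformed line(s) in %s", sum(!ok), path))
  }
  fields <- fields[ok]
  if (length(fields) == 0) return(empty_records_())
  col <- function(i) vapply(fields, `[[`, "", i)
  strip_id <- function(x) sub("^[a-zA-Z ]+:", "", sub("\\|.*$", "", x))
  taxid <- function(x) {
    suppressWarnings(as.integer(stringr::str_match(x, "taxid:(-?\\d+)")[, 2]))
  }
  type_raw <- col(12L)
  code <- mi_code_(type_raw)
  tibble(
    interactor_a = strip_id(col(1L)),
    interactor_b = strip_id(col(2L)),
    interaction_type = ifelse(is.na(code), mi_label_(type_raw),
                              paste0("psi-mi:", code)),
    experimental_system = mi_label_(col(7L)),
    source_db = mi_label_(col(13L)),
    taxid_a = taxid(col(10L)),
    taxid_b = taxid(col(11L))
  )
}

#' Write an interaction-record table
#'
#' Serializes records in either dialect accepted by
#' [parse_interaction_tables()]; writing and re-parsing reproduces the same
#' edge set.
#'
#' @param records Interaction-record tibble.
#' @param path Output path.
#' @param dialect `"tab_delimited"` or `"psi_mitab"`.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path,
                                    dialect = c("tab_delimited", "psi_mitab")) {
  dialect <- match.arg(dialect)
  if (dialect == "tab_delimited") {
    out <- tibble(
      interactor_a = records$interactor_a,
      interactor_b = records$interactor_b,
      experimental_system = records$experimental_system,
      experimental_system_type = records$interaction_type,
      source_db = records$source_db,
      taxid_a = records$taxid_a,
      taxid_b = records$taxid_b
    )
    readr::write_tsv(out, path)
  } else {
    code <- mi_code_(records$interaction_type)
    code[is.na(code) & tolower(records$interaction_type) == "genetic"] <- "MI:0208"
    code[is.na(code)] <- "MI:0915"
    label <- c("MI:0208" = "genetic interaction",
               "MI:0915" = "physical association",
               "MI:0407" = "direct interaction")[code]
    label[is.na(label)] <- "association"
    lines <- sprintf(
      paste0("uniprotkb:%s\tuniprotkb:%s\t-\t-\t-\t-\t",
             "psi-mi:\"MI:0004\"(%s)\t-\t-\ttaxid:%d(human)\ttaxid:%d(human)\t",
             "psi-mi:\"%s\"(%s)\tpsi-mi:\"MI:0000\"(%s)\t-\t-"),
      records$interactor_a, records$interactor_b,
      records$experimental_system,
      records$taxid_a %||% 9606L, records$taxid_b %||% 9606L,
      code, label, records$source_db
    )
    readr::write_lines(lines, path)
  }
  invisible(path)
}

#' Quality-control filter for interaction records
#'
#' Removes interactions annotated as genetic — records whose type is
#' `"genetic"` or carries the MI code `MI:0208` — and records from the
#' blacklisted experimental systems `Co-localization`,
#' `Genetic interference`, `Synthetic Rescue`, `Synthetic Growth Defect`
#' and `Synthetic Lethality`. System names match case-insensitively; MI
#' codes match exactly. All other records are retained.
#'
#' @param records Interaction-record tibble.
#' @return The retained records; the number removed is reported.
#' @export
filter_interactions <- function(records) {
  blacklist <- c("co-localization", "genetic interference",
                 "synthetic rescue", "synthetic growth defect",
                 "synthetic lethality")
  sys <- tolower(trimws(records$experimental_system %||% ""))
  type <- records$interaction_type %||% ""
  code <- mi_code_(type)
  drop <- (!is.na(sys) & sys %in% blacklist) |
    (!is.na(type) & tolower(trimws(type)) == "genetic") |
    (!is.na(code) & code == "MI:0208")
  drop[is.na(drop)] <- FALSE
  if (any(drop)) inform(sprintf("removed %d blacklisted record(s)", sum(drop)))
  records[!drop, ]
}

#' Build a combined PPI reference network
#'
#' Collapses filtered interaction records into an undirected simple igraph
#' network: self-loops dropped, duplicate pairs (in either orientation)
#' merged with the union of their source databases kept as the edge
#' attribute `sources`.
#'
#' @param records Interaction-record tibble (ideally after
#'   [filter_interactions()]).
#' @return An undirected simple igraph object.
#' @export
build_network <- function(records) {
  a <- canonicalize_accession(records$interactor_a)
  b <- canonicalize_accession(records$interactor_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  src <- (records$source_db %||% rep(NA_character_, nrow(records)))[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  edges <- tibble(from = lo, to = hi, src = src) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      sources = paste(sort(unique(stats::na.omit(.data$src))), collapse = ";"),
      .groups = "drop"
    )
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Annotate network nodes with DC results
#'
#' Every node receives `dc_class` (defaulting to `"unclassified"` for
#' proteins absent from the table), `raw_p` and `raw_fc` vertex attributes.
#' Proteins present in the DC table but absent from the reference network
#' are added as isolated nodes, so the annotated map covers all identified
#' proteins.
#'
#' @param network An igraph network from [build_network()].
#' @param dc_table A classified `dc_tbl` ([classify_dc()]).
#' @return The annotated igraph network.
#' @export
annotate_nodes <- function(network, dc_table) {
  if (!"dc_class" %in% names(dc_table)) {
    abort("`dc_table` must be classified first (see classify_dc())")
  }
  ids <- canonicalize_accession(dc_table$protein_id)
  extra <- setdiff(ids, igraph::V(network)$name)
  if (length(extra)) network <- igraph::add_vertices(network, length(extra),
                                                     name = extra)
  idx <- match(igraph::V(network)$name, ids)
  cls <- dc_table$dc_class[idx]
  cls[is.na(cls)] <- "unclassified"
  network <- igraph::set_vertex_attr(network, "dc_class", value = cls)
  network <- igraph::set_vertex_attr(network, "raw_p",
                                     value = dc_table$raw_p[idx])
  igraph::set_vertex_attr(network, "raw_fc", value = dc_table$raw_fc[idx])
}

#' First-degree interactome of a protein, restricted to a DC pool
#'
#' The set of direct (first-degree) interactors of `member` in the
#' annotated network, intersected with the requested
#' differential-connectivity pool.
#'
#' @param network Annotated igraph network ([annotate_nodes()]).
#' @param member Protein accession; if absent from the network an empty set
#'   is returned with a warning.
#' @param pool `"all"`, `"disease_specific"` or `"control_specific"`.
#' @return Character vector of accessions.
#' @export
local_interactome <- function(network, member,
                              pool = c("all", "disease_specific",
                                       "control_specific")) {
  pool <- match.arg(pool)
  member <- canonicalize_accession(member)
  if (!member %in% igraph::V(network)$name) {
    warn(sprintf("'%s' is not a network node; empty interactome", member))
    return(character())
  }
  nb <- igraph::neighbors(network, member)
  ids <- igraph::V(network)$name[nb]
  if (pool == "all") return(sort(unique(ids)))
  cls <- igraph::vertex_attr(network, "dc_class", index = nb)
  if (is.null(cls)) abort("network is not annotated; run annotate_nodes() first")
  sort(unique(ids[cls == pool]))
}

#' Summarize proteome-connectivity alteration of an annotated network
#'
#' Node percentages count nodes whose `dc_class` is a DC pool (gained =
#' disease-specific, lost = control-specific) over all nodes. An edge is
#' altered when it touches a DC node: gained if at least one endpoint is
#' disease-specific and none control-specific, lost in the mirrored case;
#' an edge with one disease- and one control-specific endpoint is altered
#' and assigned by `mixed_edge` (default `"gained"`). By construction
#' gained + lost = altered for both nodes and edges.
#'
#' @param network Annotated igraph network.
#' @param mixed_edge Tie rule for mixed edges: `"gained"` or `"lost"`.
#' @return A one-row tibble with `pct_nodes_altered`, `pct_nodes_gained`,
#'   `pct_nodes_lost`, `pct_edges_altered`, `pct_edges_gained`,
#'   `pct_edges_lost` (percent).
#' @export
network_alteration_summary <- function(network,
                                       mixed_edge = c("gained", "lost")) {
  mixed_edge <- match.arg(mixed_edge)
  n_nodes <- igraph::vcount(network)
  if (n_nodes == 0) abort("empty network")
  cls <- igraph::vertex_attr(network, "dc_class")
  if (is.null(cls)) abort("network is not annotated; run annotate_nodes() first")
  node_gained <- cls == "disease_specific"
  node_lost <- cls == "control_specific"

  el <- igraph::as_edgelist(network, names = FALSE)
  n_edges <- nrow(el)
  if (n_edges > 0) {
    a_dis <- node_gained[el[, 1]]; b_dis <- node_gained[el[, 2]]
    a_con <- node_lost[el[, 1]]; b_con <- node_lost[el[, 2]]
    has_dis <- a_dis | b_dis
    has_con <- a_con | b_con
    edge_gained <- (has_dis & !has_con) |
      (has_dis & has_con & mixed_edge == "gained")
    edge_lost <- (has_con & !has_dis) |
      (has_dis & has_con & mixed_edge == "lost")
  } else {
    edge_gained <- edge_lost <- logical()
  }
  pct <- function(x, n) if (n == 0) 0 else 100 * sum(x) / n
  tibble(
    pct_nodes_altered = pct(node_gained | node_lost, n_nodes),
    pct_nodes_gained = pct(node_gained, n_nodes),
    pct_nodes_lost = pct(node_lost, n_nodes),
    pct_edges_altered = pct(edge_gained | edge_lost, n_edges),
    pct_edges_gained = pct(edge_gained, n_edges),
    pct_edges_lost = pct(edge_lost, n_edges)
  )
}
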