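#' Materialize records as a multigraph network view
#'
#' Builds (or extends) an undirected igraph multigraph. Every binary record
#' contributes one evidence edge between its two protein nodes; parallel
#' edges between the same pair are kept (one per record) and all share one
#' RIGID. Every n-ary record contributes a pseudonode (vertex attribute
#' `i.pseudonode = TRUE`, named `complex:<rigid>`) with one edge to each
#' member protein, so binary and n-ary evidence stay visually and
#' structurally distinct.
#'
#' Provenance: protein nodes introduced by the query get
#' `i.order = 2 * search_index`; nodes introduced as neighbours get
#' `2 * search_index + 1`. Query terms that matched a node are appended to
#' its `i.query` attribute (pipe-joined, accumulating across searches in a
#' session). Repeated builds merge into the existing view without touching
#' attributes of nodes already present.
#'
#' @param store an `iref_store` (supplies overall degree, canonical ROGIDs,
#'   taxids and scores).
#' @param records list of [source_record()] to draw.
#' @param query_rogids ROGIDs that matched the user's query.
#' @param search_index 1-based index of this search within the session.
#' @param query_terms optional named list ROGID -> character vector of query
#'   terms responsible for returning that node.
#' @param view optional existing view to merge into.
#' @return igraph object of class `c("iref_view", "igraph")`.
#' @export
build_view <- function(store, records, query_rogids = character(),
                       search_index = 1L, query_terms = list(), view = NULL) {
  scores <- score_table(store)
  it <- store$interactors

  nt <- if (is.null(view)) empty_node_table() else
    igraph::as_data_frame(view, what = "vertices")
  et <- if (is.null(view)) empty_edge_table() else
    igraph::as_data_frame(view, what = "edges")

  have_node <- function(n) n %in% nt$name
  add_node <- function(name, pseudo, ord) {
    if (have_node(name)) return(invisible())
    i <- match(name, it$rogid)
    nt[nrow(nt) + 1L, ] <<- list(
      name = name, i.pseudonode = pseudo, i.order = ord,
      i.query = "", i.alive = FALSE, i.alive_degree = 0L,
      i.overall_degree = if (!pseudo && name %in% names(store$overall_degree))
        unname(store$overall_degree[name]) else NA_integer_,
      i.canonical_rogid = if (!is.na(i)) it$canonical_rogid[i] else NA_character_,
      taxid = if (!is.na(i)) it$taxid[i] else NA_integer_,
      spoke = FALSE)
    invisible()
  }
  add_edge <- function(from, to, rec, spoke = FALSE) {
    s <- scores[[rec$rigid]]
    et[nrow(et) + 1L, ] <<- list(
      from = from, to = to, record_id = rec$record_id, rigid = rec$rigid,
      i.src_intxn_db = rec$source_db, i.method_cv = rec$method_cv,
      i.method_name = rec$method_name,
      i.PMID = paste(rec$pmids, collapse = "|"),
      i.flag = FALSE, predicted = rec$predicted,
      i.score_np = if (is.null(s)) NA_integer_ else s$np,
      i.score_lpr = if (is.null(s)) NA_integer_ else s$lpr,
      visible = TRUE, spoke = spoke)
    invisible()
  }

  q_order <- 2L * as.integer(search_index)
  existing_ids <- et$record_id
  for (rec in records) {
    if (rec$record_id %in% existing_ids) next
    for (p in unique(rec$participants))
      add_node(p, FALSE, if (p %in% query_rogids) q_order else q_order + 1L)
    if (rec$edgetype == "X") {
      add_edge(rec$participants[1], rec$participants[2], rec)
    } else {
      pn <- paste0("complex:", rec$rigid)
      add_node(pn, TRUE, q_order + 1L)
      for (p in rec$participants) add_edge(pn, p, rec)
    }
  }
  for (q in intersect(query_rogids, nt$name)) {
    terms <- query_terms[[q]]
    if (is.null(terms)) next
    i <- match(q, nt$name)
    old <- strsplit(nt$i.query[i], "|", fixed = TRUE)[[1]]
    nt$i.query[i] <- paste(unique(c(old[nzchar(old)], terms)), collapse = "|")
  }

  g <- igraph::graph_from_data_frame(et, directed = FALSE, vertices = nt)
  class(g) <- unique(c("iref_view", class(g)))
  check_view_invariants(g)
  g
}

empty_node_table <- function() {
  data.frame(name = character(), i.pseudonode = logical(), i.order = integer(),
             i.query = character(), i.alive = logical(),
             i.alive_degree = integer(), i.overall_degree = integer(),
             i.canonical_rogid = character(), taxid = integer(),
             spoke = logical(), stringsAsFactors = FALSE)
}

empty_edge_table <- function() {
  data.frame(from = character(), to = character(), record_id = integer(),
             rigid = character(), i.src_intxn_db = character(),
             i.method_cv = character(), i.method_name = character(),
             i.PMID = character(), i.flag = logical(), predicted = logical(),
             i.score_np = integer(), i.score_lpr = integer(),
             visible = logical(), spoke = logical(), stringsAsFactors = FALSE)
}

# Parallel edges between one protein pair must share one RIGID; pseudonodes
# must have degree >= 2 and only protein neighbours.
check_view_invariants <- function(g) {
  et <- igraph::as_data_frame(g, what = "edges")
  ev <- et[!et$spoke, , drop = FALSE]
  if (nrow(ev) > 0L) {
    pair <- paste(pmin(ev$from, ev$to), pmax(ev$from, ev$to), sep = "\r")
    pseudo <- igraph::V(g)$name[igraph::V(g)$i.pseudonode]
    pp <- !(ev$from %in% pseudo) & !(ev$to %in% pseudo)
    if (any(tapply(ev$rigid[pp], pair[pp],
                   function(x) length(unique(x))) > 1L))
      stop("view invariant violated: parallel edges with differing RIGIDs",
           call. = FALSE)
  }
  nt <- igraph::as_data_frame(g, what = "vertices")
  for (pn in nt$name[nt$i.pseudonode]) {
    nb <- unique(igraph::neighbors(g, pn)$name)
    if (length(nb) < 2L || any(nt$i.pseudonode[match(nb, nt$name)]))
      stop("view invariant violated: malformed pseudonode ", pn, call. = FALSE)
  }
  invisible(g)
}

view_nodes <- function(view) igraph::as_data_frame(view, what = "vertices")
view_edges <- function(view) igraph::as_data_frame(view, what = "edges")

#' Collapse or re-expand parallel evidence edges
#'
#' For each selected protein-node pair with multiple evidence edges, hides
#' all but one edge. The retained edge is a user-flagged one (`i.flag`)
#' when present; otherwise the edge with the smallest record id (a
#' deterministic stand-in for a random pick), or a seeded random edge when
#' `random = TRUE`. The retained edge gets `i.flag = TRUE`. Toggling a
#' collapsed pair again restores all its edges, so visible + hidden edge
#' counts are conserved.
#'
#' @param view an `iref_view`.
#' @param pairs list of length-2 character vectors of node names; `NULL`
#'   toggles every pair that currently has parallel edges.
#' @param random logical; pick the retained edge at random.
#' @param seed integer seed used when `random = TRUE`.
#' @return the modified view.
#' @export
toggle_multi_edges <- function(view, pairs = NULL, random = FALSE, seed = NULL) {
  et <- view_edges(view)
  key <- paste(pmin(et$from, et$to), pmax(et$from, et$to), sep = "\r")
  if (is.null(pairs)) {
    multi <- names(which(table(key) > 1L))
  } else {
    multi <- vapply(pairs, function(p)
      paste(min(p), max(p), sep = "\r"), character(1))
  }
  if (random && !is.null(seed)) set.seed(as.integer(seed))
  for (k in multi) {
    idx <- which(key == k & !et$spoke)
    if (length(idx) <= 1L) next
    if (any(!et$visible[idx])) {
      et$visible[idx] <- TRUE            # re-expand
    } else {
      flagged <- idx[et$i.flag[idx]]
      keep <- if (length(flagged) > 0L) {
        flagged[which.min(et$record_id[flagged])]
      } else if (random) {
        idx[sample.int(length(idx), 1L)]
      } else {
        idx[which.min(et$record_id[idx])]
      }
      et$visible[idx] <- FALSE
      et$visible[keep] <- TRUE
      et$i.flag[keep] <- TRUE
    }
  }
  rebuild_view(view, et = et)
}

rebuild_view <- function(view, nt = view_nodes(view), et = view_edges(view)) {
  g <- igraph::graph_from_data_frame(et, directed = FALSE, vertices = nt)
  class(g) <- unique(c("iref_view", class(g)))
  g
}

#' Mark nodes alive and refresh alive degrees
#'
#' `set_alive()` sets the `i.alive` node attribute from a character vector of
#' node names or a predicate function over the node-attribute table, then
#' refreshes `i.alive_degree`. `update_alive_degree()` recounts, for every
#' node, its distinct neighbouring protein nodes with `i.alive = TRUE`:
#' parallel edges count once, and (by default) proteins co-membered through a
#' pseudonode count as neighbours, since complex co-membership is a
#' relationship.
#'
#' @param view an `iref_view`.
#' @param alive character vector of node names, or a function taking the
#'   node attribute data.frame and returning a logical vector.
#' @param count_pseudonodes logical; count pseudonode-mediated co-members.
#' @return the modified view.
#' @export
set_alive <- function(view, alive, count_pseudonodes = TRUE) {
  nt <- view_nodes(view)
  nt$i.alive <- if (is.function(alive)) alive(nt) else nt$name %in% alive
  update_alive_degree(rebuild_view(view, nt = nt),
                      count_pseudonodes = count_pseudonodes)
}

#' @rdname set_alive
#' @export
update_alive_degree <- function(view, count_pseudonodes = TRUE) {
  nt <- view_nodes(view)
  et <- view_edges(view)
  pseudo <- nt$name[nt$i.pseudonode]
  alive <- nt$name[nt$i.alive & !nt$i.pseudonode]
  members <- lapply(setNames(nm = pseudo), function(pn)
    unique(c(et$to[et$from == pn], et$from[et$to == pn])))
  nbrs <- function(n) {
    direct <- unique(c(et$to[et$from == n], et$from[et$to == n]))
    prot <- setdiff(direct, pseudo)
    if (count_pseudonodes && length(intersect(direct, pseudo)) > 0L)
      prot <- unique(c(prot,
                       unlist(members[intersect(direct, pseudo)],
                              use.names = FALSE)))
    setdiff(prot, n)
  }
  nt$i.alive_degree <- vapply(nt$name, function(n)
    length(intersect(nbrs(n), alive)), 1L)
  rebuild_view(view, nt = nt)
}

#' Select the evidence between a set of nodes
#'
#' Equivalent to marking the selection alive and refreshing alive degrees,
#' then returning the induced evidence among the selection: every record all
#' of whose participants lie inside the selected protein set (binary records
#' with both endpoints selected; n-ary records with every member selected).
#'
#' @param view an `iref_view`.
#' @param selected_nodes character vector of protein node names (>= 2).
#' @return list with `view` (alive attributes updated), `record_ids` and
#'   `edge_idx` (row indices into the view's edge table).
#' @export
select_between <- function(view, selected_nodes) {
  if (length(selected_nodes) < 2L) {
    warning("select_between needs at least 2 nodes; no-op", call. = FALSE)
    return(list(view = view, record_ids = integer(), edge_idx = integer()))
  }
  view <- set_alive(view, selected_nodes)
  et <- view_edges(view)
  nt <- view_nodes(view)
  pseudo <- nt$name[nt$i.pseudonode]
  ok_rec <- vapply(split(seq_len(nrow(et)), et$record_id), function(idx) {
    ends <- unique(c(et$from[idx], et$to[idx]))
    all(setdiff(ends, pseudo) %in% selected_nodes)
  }, TRUE)
  rec_ids <- as.integer(names(ok_rec)[ok_rec])
  list(view = view,
       record_ids = sort(rec_ids),
       edge_idx = which(et$record_id %in% rec_ids & !et$spoke))
}

#' Export a view, collapsing nodes onto a target identifier
#'
#' Maps every protein node to its value of `target_id_type` (via the store's
#' accession table; `"rogid"` is the identity). Nodes lacking the identifier
#' are dropped together with their exclusive edges; nodes sharing one value
#' are merged into a single node with cumulative attributes (constituent
#' ROGIDs, queries and canonical keys pipe-joined). Pseudonodes carry no
#' protein accessions and are therefore always dropped. Edges are re-homed to
#' the merged nodes; edges internal to one merged node become self-loops.
#'
#' @param view an `iref_view`.
#' @param store the `iref_store` providing the accession table.
#' @param target_id_type one of [accession_types()] or `"rogid"`.
#' @return list with `graph` (igraph keyed by the target identifier),
#'   `node_table` and `edge_table` data.frames.
#' @export
export_view <- function(view, store, target_id_type) {
  target_id_type <- match.arg(target_id_type, c(accession_types(), "rogid"))
  nt <- view_nodes(view)
  et <- view_edges(view)
  prot <- nt[!nt$i.pseudonode, , drop = FALSE]
  idof <- function(rogid) {
    if (target_id_type == "rogid") return(rogid)
    v <- store$accessions$value[store$accessions$rogid == rogid &
                                  store$accessions$type == target_id_type]
    if (length(v) == 0L) NA_character_ else sort(v)[1]
  }
  prot$target <- vapply(prot$name, idof, character(1))
  prot <- prot[!is.na(prot$target), , drop = FALSE]
  if (nrow(prot) == 0L)
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                node_table = data.frame(), edge_table = data.frame()))
  cum <- function(x) paste(unique(x[nzchar(as.character(x)) & !is.na(x)]),
                           collapse = "|")
  merged <- do.call(rbind, lapply(split(prot, prot$target), function(d)
    data.frame(name = d$target[1], constituents = cum(d$name),
               i.query = cum(d$i.query), i.order = min(d$i.order),
               i.canonical_rogid = cum(d$i.canonical_rogid),
               i.overall_degree = cum(d$i.overall_degree),
               taxid = cum(d$taxid), n_constituents = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(merged) <- NULL
  key <- setNames(prot$target, prot$name)
  keep <- et$from %in% names(key) & et$to %in% names(key) & !et$spoke
  eo <- et[keep, , drop = FALSE]
  if (nrow(eo) > 0L) {
    eo$from <- unname(key[eo$from]); eo$to <- unname(key[eo$to])
  }
  g <- igraph::graph_from_data_frame(eo, directed = FALSE, vertices = merged)
  list(graph = g, node_table = merged, edge_table = eo)
}

#' Write an exported view to disk
#'
#' Writes `edges.tsv` and `nodes.tsv` attribute tables plus a GraphML file.
#'
#' @param export result of [export_view()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_view_export <- function(export, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(export$node_table, file.path(dir, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(export$edge_table, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (igraph::vcount(export$graph) > 0L)
    igraph::write_graph(export$graph, file.path(dir, "network.graphml"),
                        format = "graphml")
  invisible(dir)
}

#' Overlay spoke-complex pseudonodes on a view
#'
#' Draws each [detect_spoke_complexes()] candidate as an extra grey
#' pseudonode (`spoke = TRUE`) with dashed-style edges (`spoke = TRUE` edge
#' attribute) to every member, visually distinct from real n-ary pseudonodes.
#'
#' @param view an `iref_view`.
#' @param candidates list of spoke candidates.
#' @return the modified view.
#' @export
add_spoke_pseudonodes <- function(view, candidates) {
  nt <- view_nodes(view)
  et <- view_edges(view)
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    name <- paste0("spoke:", cd$hub_rogid, ":", cd$source_db, ":", cd$pmid)
    if (name %in% nt$name) next
    nt[nrow(nt) + 1L, ] <- list(name = name, i.pseudonode = TRUE,
                                i.order = NA_integer_, i.query = "",
                                i.alive = FALSE, i.alive_degree = 0L,
                                i.overall_degree = NA_integer_,
                                i.canonical_rogid = NA_character_,
                                taxid = NA_integer_, spoke = TRUE)
    for (m in intersect(cd$member_rogids, nt$name[!nt$i.pseudonode]))
      et[nrow(et) + 1L, ] <- list(from = name, to = m,
                                  record_id = NA_integer_, rigid = NA_character_,
                                  i.src_intxn_db = cd$source_db,
                                  i.method_cv = cd$method_cv,
                                  i.method_name = NA_character_,
                                  i.PMID = as.character(cd$pmid),
                                  i.flag = FALSE, predicted = FALSE,
                                  i.score_np = NA_integer_,
                                  i.score_lpr = NA_integer_,
                                  visible = TRUE, spoke = TRUE)
  }
  rebuild_view(view, nt = nt, et = et)
}
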