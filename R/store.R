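#' Consolidate source records into a searchable store
#'
#' Groups records by their computed RIGID: records from different source
#' databases that describe the same participant multiset collapse into one
#' RIGID group. The store also carries the interactor and accession tables,
#' a per-ROGID record index, and each interactor's overall degree (number of
#' distinct partner ROGIDs over binary records plus co-members of n-ary
#' records; distinct partners, not edges, so degree is stable under record
#' duplication).
#'
#' @param records list of [source_record()] objects.
#' @param interactors interactor table ([interactor_table()]); records whose
#'   participants are absent from it are excluded with a warning.
#' @param accessions optional accession table ([accession_table()]).
#' @return object of class `iref_store` with elements `records`,
#'   `interactors`, `accessions`, `rigid_groups` (named list: record_ids,
#'   pmids, score_np, score_lpr), `rogid_records` (named list ROGID -> record
#'   indices), `overall_degree` (named integer), and `counts`
#'   (n_records / n_rigids / n_rogids).
#' @export
consolidate <- function(records, interactors, accessions = NULL) {
  if (is.null(accessions)) accessions <- accession_table()
  known <- interactors$rogid
  ok <- vapply(records, function(r) all(r$participants %in% known), TRUE)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) reference unknown interactors; excluded",
            call. = FALSE)
    records <- records[ok]
  }
  rigids <- vapply(records, function(r) r$rigid, character(1))
  groups <- list()
  for (i in seq_along(records)) {
    g <- groups[[rigids[i]]]
    if (is.null(g))
      g <- list(rigid = rigids[i], record_ids = integer(), pmids = integer(),
                score_np = NA_integer_, score_lpr = NA_integer_)
    g$record_ids <- c(g$record_ids, records[[i]]$record_id)
    g$pmids <- sort(unique(c(g$pmids, records[[i]]$pmids)))
    groups[[rigids[i]]] <- g
  }
  used <- sort(unique(unlist(lapply(records, function(r) r$participants))))
  rogid_records <- lapply(setNames(nm = used), function(rog)
    which(vapply(records, function(r) rog %in% r$participants, TRUE)))
  partners <- lapply(setNames(nm = used), function(rog) {
    p <- unlist(lapply(records[rogid_records[[rog]]], function(r) r$participants))
    setdiff(unique(p), rog)
  })
  store <- structure(
    list(records = records,
         interactors = interactors,
         accessions = accessions,
         rigid_groups = groups,
         rogid_records = rogid_records,
         overall_degree = vapply(partners, length, 1L),
         counts = c(n_records = length(records),
                    n_rigids = length(groups),
                    n_rogids = length(used))),
    class = "iref_store")
  store
}

#' @export
print.iref_store <- function(x, ...) {
  cat(sprintf("<iref_store> %d source records -> %d distinct RIGIDs, %d distinct ROGIDs\n",
              x$counts["n_records"], x$counts["n_rigids"], x$counts["n_rogids"]))
  invisible(x)
}

#' Compute bibliometric scores per RIGID group
#'
#' `score_np` is the number of distinct PubMed ids supporting the RIGID.
#' `score_lpr` (lowest PMID re-use) is the minimum, over those PMIDs, of the
#' number of distinct RIGIDs that PMID supports: a low lpr means at least one
#' supporting study was low-throughput, a high lpr means the edge is known
#' only from high-yield screens. Groups with no PMIDs keep NA scores.
#'
#' @param store an `iref_store`.
#' @return the store with `score_np` / `score_lpr` filled in each RIGID group.
#' @export
compute_scores <- function(store) {
  pmid_rigids <- list()
  for (g in store$rigid_groups)
    for (p in g$pmids) {
      key <- as.character(p)
      pmid_rigids[[key]] <- c(pmid_rigids[[key]], g$rigid)
    }
  yield <- vapply(pmid_rigids, function(v) length(unique(v)), 1L)
  for (rg in names(store$rigid_groups)) {
    g <- store$rigid_groups[[rg]]
    if (length(g$pmids) == 0L) {
      message("RIGID group ", rg, " has no supporting PMIDs; scores left NA")
      next
    }
    g$score_np <- length(g$pmids)
    g$score_lpr <- min(yield[as.character(g$pmids)])
    store$rigid_groups[[rg]] <- g
  }
  store
}

#' Scores as a per-RIGID list (np, lpr)
#' @param store an `iref_store` after [compute_scores()].
#' @return named list keyed by RIGID with elements `np` and `lpr`.
#' @export
score_table <- function(store) {
  lapply(store$rigid_groups, function(g) list(np = g$score_np, lpr = g$score_lpr))
}

#' Look up ROGIDs by identifier
#'
#' Exact-match lookup through the accession table. Gene-type queries
#' (`entrez_gene`, `gene_symbol`) return the ROGIDs of all protein products
#' carrying that annotation; `rogid` queries match the interactor table
#' directly. ROGIDs are case-sensitive (base64); gene symbols are
#' case-insensitive. Unknown identifiers return an empty set, not an error.
#'
#' @param store an `iref_store`.
#' @param query identifier text (vector allowed; results are unioned).
#' @param search_type one of [accession_types()] or `"rogid"`.
#' @return character vector of ROGIDs (possibly empty).
#' @export
lookup <- function(store, query, search_type) {
  search_type <- match.arg(search_type, c(accession_types(), "rogid"))
  query <- as.character(query)
  if (search_type == "rogid") {
    hit <- intersect(query, store$interactors$rogid)
    if (length(hit) == 0L) message("no interactor for rogid query")
    return(hit)
  }
  acc <- store$accessions[store$accessions$type == search_type, , drop = FALSE]
  m <- if (search_type == "gene_symbol")
    tolower(acc$value) %in% tolower(query)
  else acc$value %in% query
  hit <- sort(unique(acc$rogid[m]))
  if (length(hit) == 0L)
    message("no match for ", search_type, " query: ",
            paste(head(query, 3), collapse = ", "))
  hit
}

#' Expand a ROGID set to full canonical groups
#'
#' Returns the union of all ROGIDs sharing a canonical ROGID with any input
#' ROGID — i.e. all splice isoforms / products of the same related gene
#' group. Always a superset of the input.
#'
#' @param store an `iref_store` whose interactor table carries
#'   `canonical_rogid` assignments.
#' @param rogids character vector of ROGIDs.
#' @return character vector of ROGIDs.
#' @export
canonical_expand <- function(store, rogids) {
  it <- store$interactors
  crogs <- it$canonical_rogid[it$rogid %in% rogids]
  sort(unique(c(rogids, it$rogid[it$canonical_rogid %in% crogs])))
}

#' Retrieve records around a set of proteins
#'
#' With `iterations = 0` only records entirely inside the query set are
#' returned (equivalent to [complete_neighbourhood()]). With
#' `iterations = 1` every record containing a query protein is returned; each
#' further iteration expands the frontier breadth-first by the participants
#' of the records found so far.
#'
#' @param store an `iref_store`.
#' @param rogids character vector of query ROGIDs.
#' @param iterations non-negative integer.
#' @return list of [source_record()] objects (ordered by record_id).
#' @export
neighbourhood <- function(store, rogids, iterations = 1L) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 0L)
  if (iterations == 0L) return(complete_neighbourhood(store, rogids))
  frontier <- intersect(rogids, names(store$rogid_records))
  found <- integer()
  seen_nodes <- frontier
  for (k in seq_len(iterations)) {
    idx <- sort(unique(unlist(store$rogid_records[frontier], use.names = FALSE)))
    idx <- setdiff(idx, found)
    found <- sort(unique(c(found, idx)))
    members <- unique(unlist(lapply(store$records[idx],
                                    function(r) r$participants)))
    frontier <- setdiff(members, seen_nodes)
    seen_nodes <- c(seen_nodes, frontier)
    if (length(frontier) == 0L) break
  }
  store$records[found]
}

#' Complete the neighbourhood of a node set
#'
#' Returns every record all of whose participants lie within
#' `current_rogids` — the interactions known to occur between the proteins
#' already in a view. Idempotent: completing a completed view adds nothing.
#'
#' @param store an `iref_store`.
#' @param current_rogids character vector of ROGIDs in the current view.
#' @return list of [source_record()] objects.
#' @export
complete_neighbourhood <- function(store, current_rogids) {
  keep <- vapply(store$records,
                 function(r) all(r$participants %in% current_rogids), TRUE)
  store$records[keep]
}

#' Accession-type reachability of the interactor space
#'
#' For an ordered vector of accession types, computes the fraction of
#' distinct ROGIDs first reachable by each type (a ROGID counts for the
#' first listed type that annotates it) plus a catch-all class for ROGIDs
#' carrying none of them (still reachable by direct ROGID search). The
#' fractions sum to 1.
#'
#' @param store an `iref_store`.
#' @param types ordered character vector of accession types.
#' @return named numeric vector of fractions, ending with `"other"`.
#' @export
reachability <- function(store, types = c("uniprot", "refseq", "pdb")) {
  rogs <- store$interactors$rogid
  remaining <- rogs
  out <- numeric()
  for (ty in types) {
    has <- unique(store$accessions$rogid[store$accessions$type == ty])
    hit <- intersect(remaining, has)
    out[ty] <- length(hit) / length(rogs)
    remaining <- setdiff(remaining, hit)
  }
  out["other"] <- length(remaining) / length(rogs)
  out
}

#' Find records by id
#' @param store an `iref_store`.
#' @param record_ids integer vector.
#' @return list of records.
#' @export
records_by_id <- function(store, record_ids) {
  ids <- vapply(store$records, function(r) r$record_id, 1L)
  store$records[match(record_ids, ids)]
}
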