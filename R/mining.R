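#' Default n-ary-capable detection methods
#'
#' PSI-MI accessions for co-purification-style methods known to produce
#' n-ary results and therefore eligible for spoke-pattern detection:
#' affinity chromatography (MI:0004), coimmunoprecipitation (MI:0019),
#' pull down (MI:0096), tandem affinity purification (MI:0676), anti-tag
#' coimmunoprecipitation (MI:0007) and cosedimentation (MI:0027). The list
#' is configurable: pass your own to [detect_spoke_complexes()] or load one
#' from a file with [read_methods_file()].
#'
#' @return character vector of PSI-MI accessions.
#' @export
default_nary_methods <- function() {
  c("MI:0004", "MI:0007", "MI:0019", "MI:0027", "MI:0096", "MI:0676")
}

#' Read a method-filter file
#' @param path text file, one PSI-MI accession per line, `#` comments allowed.
#' @return character vector of accessions.
#' @export
read_methods_file <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  x
}

#' Detect spoke-represented complexes
#'
#' An n-ary experimental result is sometimes stored as a set of binary
#' records radiating from one hub (conventionally the bait of an
#' affinity-purification experiment). Candidates are sets of two or more
#' binary records from the same source database that share the same
#' publication, the same experimental method (one known to produce n-ary
#' data) and a common interactor. When any participant carries the bait
#' role within a record set, only bait participants qualify as hubs;
#' otherwise any shared interactor does.
#'
#' @param records list of [source_record()] objects.
#' @param nary_methods character vector of PSI-MI method accessions eligible
#'   for detection.
#' @return list of candidates, each a list with `hub_rogid`, `member_rogids`
#'   (hub plus partners), `source_db`, `pmid`, `method_cv`,
#'   `record_ids`, and `nary_methods_used` attached as an attribute on the
#'   returned list.
#' @export
detect_spoke_complexes <- function(records, nary_methods = default_nary_methods()) {
  bin <- Filter(function(r) r$edgetype == "X" && !is.na(r$method_cv) &&
                  r$method_cv %in% nary_methods && length(r$pmids) > 0L,
                records)
  out <- list()
  if (length(bin) > 0L) {
    keys <- unlist(lapply(bin, function(r)
      paste(r$source_db, r$pmids, r$method_cv, sep = "\r")))
    idx <- rep(seq_along(bin), vapply(bin, function(r) length(r$pmids), 1L))
    for (k in unique(keys)) {
      recs <- bin[unique(idx[keys == k])]
      if (length(recs) < 2L) next
      parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
      baits <- unique(unlist(lapply(recs, function(r)
        r$participants[r$roles == "bait"])))
      hubs <- table(unlist(lapply(recs, function(r) unique(r$participants))))
      hubs <- names(hubs)[hubs >= 2L]
      if (length(baits) > 0L) hubs <- intersect(hubs, baits)
      for (h in hubs) {
        sup <- Filter(function(r) h %in% r$participants, recs)
        if (length(sup) < 2L) next
        out[[length(out) + 1L]] <- list(
          hub_rogid = h,
          member_rogids = unique(c(h, unlist(lapply(sup, function(r)
            r$participants)))),
          source_db = parts[1], pmid = as.integer(parts[2]),
          method_cv = parts[3],
          record_ids = sort(vapply(sup, function(r) r$record_id, 1L)))
      }
    }
  }
  attr(out, "nary_methods_used") <- nary_methods
  out
}

#' Read a disease-group table
#'
#' Four tab-separated columns: `digid` (integer disease-group id), `title`
#' (disease-group title), `omim_id`, `gene_id`. One row per (group, OMIM,
#' gene) association; group title repeated on each row.
#'
#' @param path TSV file with a header.
#' @return list of disease groups, each with `digid`, `title`, `omim_ids`,
#'   `gene_ids`.
#' @export
read_disease_groups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("integer", "character", "character",
                                  "character"))
  lapply(split(df, df$digid), function(d)
    list(digid = d$digid[1], title = d$title[1],
         omim_ids = sort(unique(d$omim_id)),
         gene_ids = sort(unique(d$gene_id))))
}

#' Search disease groups
#'
#' A `digid` query returns that group's genes; an OMIM id returns the genes
#' of the group containing it; a title fragment returns the union of genes
#' over all groups whose title contains the fragment (case-insensitive).
#' No match returns an empty set.
#'
#' @param groups list from [read_disease_groups()].
#' @param query identifier or title fragment (single string).
#' @param search_type `"digid"`, `"omim"` or `"omim_title"`.
#' @return character vector of gene ids.
#' @export
disease_search <- function(groups, query, search_type = c("digid", "omim", "omim_title")) {
  search_type <- match.arg(search_type)
  query <- as.character(query)
  hit <- switch(search_type,
    digid = Filter(function(g) as.character(g$digid) == query, groups),
    omim = Filter(function(g) query %in% g$omim_ids, groups),
    omim_title = Filter(function(g)
      grepl(tolower(query), tolower(g$title), fixed = TRUE), groups))
  sort(unique(c(character(), unlist(lapply(hit, function(g) g$gene_ids)))))
}

#' Classify connectivity between two node groups
#'
#' Builds the synchronized adjacency matrix between group A (columns) and
#' group B (rows) of protein nodes in a view. Each cell is classified:
#' `DIRECT` (an evidence edge joins the pair; `"¤"` symbol, red),
#' `INDIRECT` (no direct edge, but an intermediate protein connects them
#' with two edges, or both are members of one n-ary pseudonode; blue, with
#' intermediates listed), `BOTH` (green, symbol plus intermediates), `NONE`
#' (black) or `SELF` (row equals column; its direct interactors listed).
#' Rows and columns consisting entirely of `NONE` cells are flagged hidden.
#' Intermediates may themselves belong to either group.
#'
#' @param view an `iref_view`.
#' @param groupA,groupB non-empty character vectors of protein node names.
#' @return object of class `iref_adjacency`: list with `cells` (data.frame
#'   row_rogid, col_rogid, cell_class, colour, symbol, intermediates
#'   (list-column)), `groupA`, `groupB`, `hidden_rows`, `hidden_cols`.
#' @export
adjacency_matrix <- function(view, groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both node groups must be non-empty", call. = FALSE)
  nt <- view_nodes(view)
  et <- view_edges(view)
  et <- et[!et$spoke, , drop = FALSE]
  pseudo <- nt$name[nt$i.pseudonode]
  prot_et <- et[!(et$from %in% pseudo) & !(et$to %in% pseudo), , drop = FALSE]
  nbr <- function(n) unique(c(prot_et$to[prot_et$from == n],
                              prot_et$from[prot_et$to == n]))
  members <- lapply(setNames(nm = pseudo), function(pn)
    unique(c(et$to[et$from == pn], et$from[et$to == pn])))
  cells <- list()
  for (b in groupB) for (a in groupA) {
    if (identical(a, b)) {
      cells[[length(cells) + 1L]] <- list(
        row_rogid = b, col_rogid = a, cell_class = "SELF", colour = "self",
        symbol = FALSE, intermediates = list(sort(setdiff(nbr(a), a))))
      next
    }
    direct <- a %in% nbr(b)
    inter_prot <- sort(setdiff(intersect(nbr(a), nbr(b)), c(a, b)))
    inter_pn <- sort(names(Filter(function(m) a %in% m && b %in% m, members)))
    inter <- c(inter_prot, inter_pn)
    cls <- if (direct && length(inter) > 0L) "BOTH"
      else if (direct) "DIRECT"
      else if (length(inter) > 0L) "INDIRECT"
      else "NONE"
    cells[[length(cells) + 1L]] <- list(
      row_rogid = b, col_rogid = a, cell_class = cls,
      colour = c(DIRECT = "red", INDIRECT = "blue", BOTH = "green",
                 NONE = "black")[[cls]],
      symbol = cls %in% c("DIRECT", "BOTH"),
      intermediates = list(if (cls == "NONE") character() else inter))
  }
  cells <- do.call(rbind, lapply(cells, function(x)
    data.frame(row_rogid = x$row_rogid, col_rogid = x$col_rogid,
               cell_class = x$cell_class, colour = x$colour,
               symbol = x$symbol,
               intermediates = I(x$intermediates),
               stringsAsFactors = FALSE)))
  all_none <- function(key, vals) vapply(setNames(nm = vals), function(v)
    all(cells$cell_class[cells[[key]] == v] == "NONE"), TRUE)
  structure(list(cells = cells, groupA = groupA, groupB = groupB,
                 hidden_rows = names(which(all_none("row_rogid", groupB))),
                 hidden_cols = names(which(all_none("col_rogid", groupA)))),
            class = "iref_adjacency")
}

#' @export
print.iref_adjacency <- function(x, ...) {
  cat(sprintf("<iref_adjacency> %d x %d cells (%d hidden rows, %d hidden cols)\n",
              length(x$groupB), length(x$groupA),
              length(x$hidden_rows), length(x$hidden_cols)))
  print(table(x$cells$cell_class))
  invisible(x)
}

#' Resolve a matrix cell or heading to nodes and edges
#'
#' A heading selects that protein node. A cell selects the row and column
#' nodes, any intermediates or pseudonodes realizing the relationship, and
#' the evidence edges involved (direct edges between the pair, plus the
#' edge bundles through each intermediate / pseudonode). Hidden (`NONE`)
#' cells yield an empty selection.
#'
#' @param matrix an `iref_adjacency`.
#' @param view the view the matrix was computed against.
#' @param row,col node names; give only one of them for a heading.
#' @return list with `nodes` (character) and `edge_idx` (row indices into
#'   the view's edge table).
#' @export
matrix_select <- function(matrix, view, row = NULL, col = NULL) {
  if (is.null(row) != is.null(col)) {
    n <- c(row, col)
    return(list(nodes = n, edge_idx = integer()))
  }
  cell <- matrix$cells[matrix$cells$row_rogid == row &
                         matrix$cells$col_rogid == col, , drop = FALSE]
  if (nrow(cell) == 0L || cell$cell_class == "NONE")
    return(list(nodes = character(), edge_idx = integer()))
  et <- view_edges(view)
  inter <- cell$intermediates[[1]]
  if (cell$cell_class == "SELF")
    return(list(nodes = c(row, inter),
                edge_idx = which((et$from == row & et$to %in% inter) |
                                   (et$to == row & et$from %in% inter))))
  nodes <- unique(c(row, col, inter))
  touch <- function(u, v) which((et$from == u & et$to == v) |
                                  (et$from == v & et$to == u))
  idx <- integer()
  if (cell$cell_class %in% c("DIRECT", "BOTH")) idx <- c(idx, touch(row, col))
  for (x in inter) idx <- c(idx, touch(row, x), touch(col, x))
  list(nodes = nodes, edge_idx = sort(unique(idx)))
}

#' Write an adjacency matrix as TSV
#'
#' One row per cell with class, colour, symbol and pipe-joined
#' intermediates; hidden rows/columns are marked.
#'
#' @param matrix an `iref_adjacency`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(matrix, path) {
  d <- matrix$cells
  out <- data.frame(row = d$row_rogid, col = d$col_rogid,
                    class = d$cell_class, colour = d$colour,
                    symbol = ifelse(d$symbol, "¤", ""),
                    intermediates = vapply(d$intermediates, paste,
                                           character(1), collapse = "|"),
                    row_hidden = d$row_rogid %in% matrix$hidden_rows,
                    col_hidden = d$col_rogid %in% matrix$hidden_cols,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
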