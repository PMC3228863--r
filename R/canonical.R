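#' Group genes into related gene groups (RGGs)
#'
#' Genes are grouped together when they share at least one identical protein
#' product (same ROGID), taking the transitive closure: a chain g1~g2~g3 of
#' pairwise-sharing genes forms one group. Genes with no products form
#' singleton groups. Implemented with a union-find over the gene-product
#' bipartite relation.
#'
#' @param gene_to_proteins named list: Entrez Gene id (as character name) ->
#'   character vector of product ROGIDs (possibly empty).
#' @return list of RGGs, each a list with `rgg_id`, `gene_ids` (character),
#'   `protein_rogids` (character, the initial product list) and
#'   `canonical_rogid` (NA until [select_canonical()]).
#' @export
build_rggs <- function(gene_to_proteins) {
  if (length(gene_to_proteins) == 0L)
    stop("gene-to-protein map must be non-empty", call. = FALSE)
  genes <- names(gene_to_proteins)
  parent <- seq_along(genes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  prot_owner <- list()  # rogid -> first gene index seen with it
  for (i in seq_along(genes)) {
    for (p in gene_to_proteins[[i]]) {
      o <- prot_owner[[p]]
      if (is.null(o)) prot_owner[[p]] <- i else unite(i, o)
    }
  }
  roots <- vapply(seq_along(genes), find, 1L)
  out <- list()
  for (r in sort(unique(roots))) {
    idx <- which(roots == r)
    out[[length(out) + 1L]] <- list(
      rgg_id = length(out) + 1L,
      gene_ids = sort(genes[idx]),
      protein_rogids = sort(unique(unlist(gene_to_proteins[idx]))),
      canonical_rogid = NA_character_)
  }
  out
}

#' Expand an RGG's protein list with isoform and cross-reference links
#'
#' The initial product list (RefSeq-style products of the member genes) is
#' unioned with (1) proteins linked as isoforms of a protein already in the
#' list and (2) proteins cross-referencing one of the member genes. A single
#' pass: isoforms of newly added isoforms are not chased (the link tables are
#' expected to be reflexively complete). Monotone — never removes a protein.
#'
#' @param group one RGG from [build_rggs()].
#' @param isoform_links named list: ROGID -> character vector of isoform
#'   ROGIDs.
#' @param xref_links named list: gene id -> character vector of ROGIDs that
#'   cross-reference the gene.
#' @return the group with `protein_rogids` expanded.
#' @export
expand_rgg <- function(group, isoform_links = list(), xref_links = list()) {
  iso <- unlist(isoform_links[intersect(group$protein_rogids,
                                        names(isoform_links))],
                use.names = FALSE)
  xr <- unlist(xref_links[intersect(group$gene_ids, names(xref_links))],
               use.names = FALSE)
  group$protein_rogids <- sort(unique(c(group$protein_rogids, iso, xr)))
  group
}

#' Choose the canonical protein of an RGG
#'
#' Priority: (1) the sole UniProt-canonical member, if one; (2) the longest
#' among UniProt-canonical members; (3) otherwise the longest protein in the
#' group. Length ties are broken by the ASCII-smallest ROGID, which makes the
#' choice deterministic and implementation-independent.
#'
#' @param group an expanded RGG.
#' @param uniprot_canonical_flags named logical vector: ROGID -> is the
#'   sequence UniProt-canonical. Missing names are treated as FALSE.
#' @param lengths named integer vector: ROGID -> sequence length; required
#'   for every member.
#' @return the chosen canonical ROGID (character).
#' @export
select_canonical <- function(group, uniprot_canonical_flags = logical(),
                             lengths = integer()) {
  members <- group$protein_rogids
  if (length(members) == 0L)
    stop("cannot select a canonical protein for an empty group", call. = FALSE)
  if (!all(members %in% names(lengths)))
    stop("sequence lengths missing for some group members", call. = FALSE)
  flagged <- members[vapply(members, function(m)
    isTRUE(unname(uniprot_canonical_flags[m])), TRUE)]
  pool <- if (length(flagged) > 0L) flagged else members
  len <- lengths[pool]
  best <- pool[len == max(len)]
  sort(best, method = "radix")[1]
}

#' Assign every interactor a canonical ROGID
#'
#' Runs the full canonicalization pipeline: build RGGs from the gene-product
#' map, expand each with isoform and cross-reference links, select each
#' group's canonical protein, and emit one row per protein. Interactors not
#' attached to any gene become their own canonical representative (every
#' node must carry a canonical group key).
#'
#' @param rogids all interactor ROGIDs to cover.
#' @inheritParams build_rggs
#' @inheritParams expand_rgg
#' @inheritParams select_canonical
#' @return data.frame with columns `rogid`, `canonical_rogid`, `rgg_id`
#'   (NA rgg_id for gene-less singletons).
#' @export
assign_canonical <- function(rogids, gene_to_proteins = list(),
                             isoform_links = list(), xref_links = list(),
                             uniprot_canonical_flags = logical(),
                             lengths = integer()) {
  out <- data.frame(rogid = character(), canonical_rogid = character(),
                    rgg_id = integer(), stringsAsFactors = FALSE)
  if (length(gene_to_proteins) > 0L) {
    rggs <- build_rggs(gene_to_proteins)
    for (g in rggs) {
      g <- expand_rgg(g, isoform_links, xref_links)
      if (length(g$protein_rogids) == 0L) next
      cr <- select_canonical(g, uniprot_canonical_flags, lengths)
      out <- rbind(out, data.frame(rogid = g$protein_rogids,
                                   canonical_rogid = cr, rgg_id = g$rgg_id,
                                   stringsAsFactors = FALSE))
    }
  }
  # a protein in several RGGs keeps its first (smallest rgg_id) assignment
  out <- out[!duplicated(out$rogid), , drop = FALSE]
  loose <- setdiff(rogids, out$rogid)
  if (length(loose) > 0L)
    out <- rbind(out, data.frame(rogid = loose, canonical_rogid = loose,
                                 rgg_id = NA_integer_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
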