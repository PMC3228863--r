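#' Construct a source interaction record
#'
#' A `source_record` is one interaction record as curated by one source
#' database: either binary (edgetype `"X"`, exactly two participants) or
#' n-ary (edgetype `"C"`, normally three or more participants, e.g. a
#' co-purified complex). Participants are ROGIDs with roles; at most one
#' participant may carry the `bait` role.
#'
#' @param record_id integer surrogate id, unique within a record set.
#' @param source_db source database name (e.g. `"intact"`); stored on view
#'   edges as `i.src_intxn_db`.
#' @param source_acc the record's accession in its source database.
#' @param participants character vector of participant ROGIDs.
#' @param roles participant roles, one of `"bait"`, `"prey"`, `"neutral"`;
#'   recycled `"neutral"` when omitted.
#' @param pmids integer vector of supporting PubMed identifiers.
#' @param method_cv,method_name PSI-MI accession and name of the interaction
#'   detection method.
#' @param type_cv,type_name PSI-MI accession and name of the interaction type.
#' @param edgetype `"X"` (binary) or `"C"` (n-ary). Defaults to `"X"` for two
#'   participants, `"C"` otherwise. n-ary records with exactly two listed
#'   members are tolerated (real data contains them) but warned about.
#' @param predicted logical; `TRUE` for predicted (OPHID-style) edges.
#' @return a list of class `"source_record"`.
#' @export
source_record <- function(record_id, source_db, source_acc, participants,
                          roles = NULL, pmids = integer(),
                          method_cv = NA_character_, method_name = NA_character_,
                          type_cv = NA_character_, type_name = NA_character_,
                          edgetype = NULL, predicted = FALSE) {
  participants <- as.character(participants)
  n <- length(participants)
  if (n < 1L) stop("record must have at least one participant", call. = FALSE)
  if (is.null(roles)) roles <- rep("neutral", n)
  roles <- as.character(roles)
  if (length(roles) != n)
    stop("`roles` must match `participants` in length", call. = FALSE)
  if (!all(roles %in% c("bait", "prey", "neutral")))
    stop("roles must be bait, prey or neutral", call. = FALSE)
  if (sum(roles == "bait") > 1L)
    stop("at most one bait participant per record", call. = FALSE)
  if (is.null(edgetype)) edgetype <- if (n == 2L) "X" else "C"
  if (!edgetype %in% c("X", "C")) stop("edgetype must be 'X' or 'C'", call. = FALSE)
  if (edgetype == "X" && n != 2L)
    stop("binary (edgetype X) records require exactly 2 participants", call. = FALSE)
  if (edgetype == "C" && n == 2L)
    warning("n-ary record with exactly 2 listed members (record_id ",
            record_id, "); edgetype column kept authoritative", call. = FALSE)
  if (edgetype == "C" && n < 2L)
    stop("n-ary (edgetype C) records require >= 2 participants", call. = FALSE)
  structure(
    list(record_id = as.integer(record_id),
         source_db = as.character(source_db),
         source_acc = as.character(source_acc),
         participants = participants,
         roles = roles,
         pmids = sort(unique(as.integer(pmids))),
         method_cv = method_cv, method_name = method_name,
         type_cv = type_cv, type_name = type_name,
         edgetype = edgetype,
         predicted = isTRUE(predicted),
         rigid = compute_rigid(participants)),
    class = "source_record")
}

#' @export
print.source_record <- function(x, ...) {
  cat(sprintf("<source_record %d> %s:%s [%s] %d participant(s) rigid=%s\n",
              x$record_id, x$source_db, x$source_acc, x$edgetype,
              length(x$participants), x$rigid))
  invisible(x)
}

#' Build an interactor table
#'
#' One row per distinct (sequence, taxon) protein. ROGIDs are recomputed from
#' sequence and taxid so the table is correct by construction; `irogid` is an
#' integer surrogate unique within the table; `canonical_rogid` defaults to
#' the ROGID itself until canonical assignment is run.
#'
#' @param sequence character vector of amino-acid sequences.
#' @param taxid integer vector of NCBI taxonomy ids (recycled if length 1).
#' @param canonical_rogid optional character vector of canonical group keys.
#' @return data.frame with columns rogid, sequence, taxid, irogid,
#'   canonical_rogid.
#' @export
interactor_table <- function(sequence, taxid, canonical_rogid = NULL) {
  if (length(taxid) == 1L) taxid <- rep(taxid, length(sequence))
  rogid <- mapply(compute_rogid, sequence, taxid, USE.NAMES = FALSE)
  keep <- !duplicated(rogid)
  df <- data.frame(rogid = rogid[keep],
                   sequence = toupper(gsub("[[:space:]]+", "", sequence[keep])),
                   taxid = as.integer(taxid[keep]),
                   irogid = seq_len(sum(keep)),
                   canonical_rogid = if (is.null(canonical_rogid))
                     rogid[keep] else as.character(canonical_rogid[keep]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Build an accession table
#'
#' Long-format lookup table mapping accessions to ROGIDs; one row per
#' (rogid, type, value) triple. Recognised types are `uniprot`, `refseq`,
#' `entrez_gene`, `gene_symbol`, `pdb`, `xref` and `original_reference`
#' (retired accessions kept searchable).
#'
#' @param rogid,type,value character vectors of equal length.
#' @return data.frame with columns rogid, type, value.
#' @export
accession_table <- function(rogid = character(), type = character(),
                            value = character()) {
  df <- data.frame(rogid = as.character(rogid), type = as.character(type),
                   value = as.character(value), stringsAsFactors = FALSE)
  unique(df)
}

#' Accession types supported by search
#' @return character vector of search types.
#' @export
accession_types <- function() {
  c("uniprot", "refseq", "entrez_gene", "gene_symbol", "pdb", "xref",
    "original_reference")
}
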