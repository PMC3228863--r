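#' @name mitab
#' @title iRefIndex-style PSI-MITAB 2.5 dialect
#'
#' @description
#' The dialect has the 15 standard MITAB 2.5 columns
#' (uidA, uidB, altA, altB, aliasA, aliasB, method, author, pmids, taxa,
#' taxb, interactionType, sourcedb, interactionIdentifier, confidence)
#' followed by 8 extension columns
#' (rogida, rogidb, rigid, crogida, crogidb, edgetype, numParticipants,
#' roles). Missing values are `"-"`.
#'
#' Binary records occupy one row. An n-ary record with n members occupies n
#' rows whose `uidA` is the placeholder `complex:<rigid>`; each row's B-side
#' columns describe one member, and the member's position within the record
#' is encoded in the roles cell (`"<position>:<role>"`), so assembly does not
#' depend on row order. The extension columns are recomputable: on read the
#' `rigid` column is checked against the RIGID recomputed from the
#' participant ROGIDs (and, when sequences are supplied, ROGIDs are checked
#' against [compute_rogid()]); on mismatch a warning is raised and the
#' recomputed value wins.
NULL

mitab_columns <- c(
  "uidA", "uidB", "altA", "altB", "aliasA", "aliasB", "method", "author",
  "pmids", "taxa", "taxb", "interactionType", "sourcedb",
  "interactionIdentifier", "confidence",
  "rogida", "rogidb", "rigid", "crogida", "crogidb", "edgetype",
  "numParticipants", "roles")

mitab_na <- "-"

fmt_cv <- function(cv, name) {
  if (is.na(cv)) return(mitab_na)
  sprintf('psi-mi:"%s"(%s)', cv, if (is.na(name)) "unknown" else name)
}

parse_cv <- function(cell) {
  if (cell == mitab_na) return(c(NA_character_, NA_character_))
  m <- regmatches(cell, regexec('^psi-mi:"([^"]*)"\\((.*)\\)$', cell))[[1]]
  if (length(m) == 3L) c(m[2], m[3]) else c(cell, NA_character_)
}

fmt_pmids <- function(pmids) {
  if (length(pmids) == 0L) return(mitab_na)
  paste0("pubmed:", pmids, collapse = "|")
}

parse_pmids <- function(cell) {
  if (cell == mitab_na || !nzchar(cell)) return(integer())
  sort(unique(as.integer(sub("^pubmed:", "", strsplit(cell, "|", fixed = TRUE)[[1]]))))
}

# Presentation policy for the uid columns: rotate through the interactor's
# available accession types keyed on record id, so a corpus exercises every
# accession system; falls back to rogid:<rogid>. Not part of the record
# object, hence round-trip neutral.
pick_uid <- function(rogid, accessions, salt) {
  if (!is.null(accessions)) {
    acc <- accessions[accessions$rogid == rogid &
                        accessions$type %in% accession_types(), , drop = FALSE]
    if (nrow(acc) > 0L) {
      acc <- acc[order(acc$type, acc$value), , drop = FALSE]
      i <- (salt %% nrow(acc)) + 1L
      return(paste0(acc$type[i], ":", acc$value[i]))
    }
  }
  paste0("rogid:", rogid)
}

alt_aliases <- function(rogid, accessions) {
  if (is.null(accessions)) return(c(mitab_na, mitab_na))
  acc <- accessions[accessions$rogid == rogid, , drop = FALSE]
  alt <- acc[acc$type %in% c("uniprot", "refseq", "entrez_gene", "pdb", "xref"), ]
  ali <- acc[acc$type %in% c("gene_symbol", "original_reference"), ]
  fmt <- function(d) if (nrow(d) == 0L) mitab_na else
    paste0(d$type, ":", d$value, collapse = "|")
  c(fmt(alt[order(alt$type, alt$value), ]), fmt(ali[order(ali$type, ali$value), ]))
}

#' Write interaction records to a MITAB file
#'
#' @param records list of [source_record()] objects.
#' @param path output file path.
#' @param interactors optional interactor table ([interactor_table()]); used
#'   for taxid and canonical ROGID columns.
#' @param accessions optional accession table ([accession_table()]); used to
#'   fill the uid/alt/alias presentation columns.
#' @param scores optional named list per RIGID with elements `np` and `lpr`
#'   (as produced by [compute_scores()]), written into the confidence column.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(records, path, interactors = NULL, accessions = NULL,
                        scores = NULL) {
  taxof <- function(r) {
    if (is.null(interactors)) return(mitab_na)
    i <- match(r, interactors$rogid)
    if (is.na(i)) mitab_na else paste0("taxid:", interactors$taxid[i])
  }
  crogof <- function(r) {
    if (is.null(interactors)) return(mitab_na)
    i <- match(r, interactors$rogid)
    if (is.na(i)) mitab_na else interactors$canonical_rogid[i]
  }
  conf_cell <- function(rec) {
    tok <- character()
    if (!is.null(scores) && !is.null(scores[[rec$rigid]])) {
      s <- scores[[rec$rigid]]
      if (!is.null(s$np) && !is.na(s$np)) tok <- c(tok, paste0("np:", s$np))
      if (!is.null(s$lpr) && !is.na(s$lpr)) tok <- c(tok, paste0("lpr:", s$lpr))
    }
    if (rec$predicted) tok <- c(tok, "predicted:true")
    if (length(tok) == 0L) mitab_na else paste(tok, collapse = "|")
  }
  rows <- list()
  for (rec in records) {
    shared <- c(method = fmt_cv(rec$method_cv, rec$method_name),
                author = mitab_na,
                pmids = fmt_pmids(rec$pmids),
                interactionType = fmt_cv(rec$type_cv, rec$type_name),
                sourcedb = rec$source_db,
                interactionIdentifier = sprintf("%s:%s|rid:%d", rec$source_db,
                                                rec$source_acc, rec$record_id),
                confidence = conf_cell(rec),
                rigid = rec$rigid,
                edgetype = rec$edgetype,
                numParticipants = as.character(length(rec$participants)))
    if (rec$edgetype == "X") {
      a <- rec$participants[1]; b <- rec$participants[2]
      aa <- alt_aliases(a, accessions); bb <- alt_aliases(b, accessions)
      rows[[length(rows) + 1L]] <- c(
        uidA = pick_uid(a, accessions, rec$record_id),
        uidB = pick_uid(b, accessions, rec$record_id + 1L),
        altA = aa[1], altB = bb[1], aliasA = aa[2], aliasB = bb[2],
        shared["method"], author = mitab_na, shared["pmids"],
        taxa = taxof(a), taxb = taxof(b),
        shared[c("interactionType", "sourcedb", "interactionIdentifier",
                 "confidence")],
        rogida = a, rogidb = b, shared["rigid"],
        crogida = crogof(a), crogidb = crogof(b),
        shared[c("edgetype", "numParticipants")],
        roles = paste(rec$roles, collapse = "|"))
    } else {
      for (k in seq_along(rec$participants)) {
        b <- rec$participants[k]
        bb <- alt_aliases(b, accessions)
        rows[[length(rows) + 1L]] <- c(
          uidA = paste0("complex:", rec$rigid),
          uidB = pick_uid(b, accessions, rec$record_id + k),
          altA = mitab_na, altB = bb[1], aliasA = mitab_na, aliasB = bb[2],
          shared["method"], author = mitab_na, shared["pmids"],
          taxa = mitab_na, taxb = taxof(b),
          shared[c("interactionType", "sourcedb", "interactionIdentifier",
                   "confidence")],
          rogida = mitab_na, rogidb = b, shared["rigid"],
          crogida = mitab_na, crogidb = crogof(b),
          shared[c("edgetype", "numParticipants")],
          roles = paste0(k, ":", rec$roles[k]))
      }
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(mitab_columns, collapse = "\t")), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}

#' Read interaction records from a MITAB file
#'
#' Binary rows become one record each; rows sharing one complex group key
#' (`uidA = "complex:<rigid>"` plus the record identifier) are assembled into
#' a single n-ary record whose participants are the B-side members, ordered
#' by the position encoded in the roles cell. Interactors are deduplicated by
#' ROGID.
#'
#' @param path MITAB file path.
#' @param interactors optional interactor table with sequences; when given,
#'   the rogid extension columns are verified against [compute_rogid()]
#'   (mismatch warns, recomputed value wins).
#' @return list with elements `records` (list of [source_record()]),
#'   `interactors` (data.frame rogid/taxid/canonical_rogid seen in the file)
#'   and `scores` (named per-RIGID list of np/lpr read from the confidence
#'   column, possibly empty).
#' @export
read_mitab <- function(path, interactors = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty MITAB file: ", path, call. = FALSE)
  if (startsWith(lines[1], "#")) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(list(records = list(),
                interactors = data.frame(rogid = character(),
                                         taxid = integer(),
                                         canonical_rogid = character(),
                                         stringsAsFactors = FALSE),
                scores = list()))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(cells, length, 1L) != length(mitab_columns))
  if (length(bad) > 0L)
    stop(sprintf("MITAB parse error at line %d: expected %d columns, found %d",
                 bad[1] + 1L, length(mitab_columns), length(cells[[bad[1]]])),
         call. = FALSE)
  tab <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
  names(tab) <- mitab_columns

  verify_rogid <- function(rog, tax_cell) {
    if (is.null(interactors)) return(rog)
    i <- match(rog, interactors$rogid)
    if (is.na(i)) return(rog)
    rec <- compute_rogid(interactors$sequence[i], interactors$taxid[i])
    if (!identical(rec, rog)) {
      warning("rogid column disagrees with recomputed value; recomputed wins",
              call. = FALSE)
      return(rec)
    }
    rog
  }

  parse_rid <- function(cell) {
    tok <- strsplit(cell, "|", fixed = TRUE)[[1]]
    rid <- grep("^rid:", tok, value = TRUE)
    src <- tok[!startsWith(tok, "rid:")][1]
    sp <- regmatches(src, regexpr(":", src, fixed = TRUE), invert = TRUE)[[1]]
    list(record_id = if (length(rid)) as.integer(sub("^rid:", "", rid[1])) else NA_integer_,
         source_acc = if (length(sp) == 2L) sp[2] else src)
  }
  parse_conf <- function(cell) {
    out <- list(np = NA_integer_, lpr = NA_integer_, predicted = FALSE)
    if (cell == mitab_na) return(out)
    for (tok in strsplit(cell, "|", fixed = TRUE)[[1]]) {
      kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
      if (kv[1] == "np") out$np <- as.integer(kv[2])
      if (kv[1] == "lpr") out$lpr <- as.integer(kv[2])
      if (kv[1] == "predicted") out$predicted <- identical(kv[2], "true")
    }
    out
  }
  tax_int <- function(cell) {
    if (cell == mitab_na) return(NA_integer_)
    as.integer(sub("^taxid:", "", cell))
  }

  records <- list()
  seen <- data.frame(rogid = character(), taxid = integer(),
                     canonical_rogid = character(), stringsAsFactors = FALSE)
  note <- function(rog, tax, crog) {
    if (is.na(rog) || rog == mitab_na) return(invisible())
    if (!rog %in% seen$rogid)
      seen[nrow(seen) + 1L, ] <<- list(rog, tax,
                                       if (is.na(crog) || crog == mitab_na) rog else crog)
    invisible()
  }
  scores <- list()

  is_cx <- startsWith(tab$uidA, "complex:")
  next_id <- 0L
  mk_id <- function(rid) {
    if (!is.na(rid)) return(rid)
    next_id <<- next_id + 1L
    next_id + 10^7L
  }

  for (i in which(!is_cx)) {
    row <- tab[i, ]
    meta <- parse_rid(row$interactionIdentifier)
    conf <- parse_conf(row$confidence)
    a <- verify_rogid(row$rogida, row$taxa)
    b <- verify_rogid(row$rogidb, row$taxb)
    meth <- parse_cv(row$method); ityp <- parse_cv(row$interactionType)
    roles <- strsplit(row$roles, "|", fixed = TRUE)[[1]]
    if (length(roles) != 2L) roles <- c("neutral", "neutral")
    rec <- source_record(mk_id(meta$record_id), row$sourcedb, meta$source_acc,
                         c(a, b), roles, parse_pmids(row$pmids),
                         meth[1], meth[2], ityp[1], ityp[2],
                         edgetype = "X", predicted = conf$predicted)
    if (!identical(rec$rigid, row$rigid))
      warning("rigid column disagrees with recomputed RIGID; recomputed wins",
              call. = FALSE)
    if (!is.na(conf$np) || !is.na(conf$lpr))
      scores[[rec$rigid]] <- list(np = conf$np, lpr = conf$lpr)
    note(a, tax_int(row$taxa), row$crogida)
    note(b, tax_int(row$taxb), row$crogidb)
    records[[length(records) + 1L]] <- rec
  }

  if (any(is_cx)) {
    cx <- tab[is_cx, , drop = FALSE]
    key <- paste(cx$uidA, cx$interactionIdentifier, sep = "\r")
    for (k in unique(key)) {
      grp <- cx[key == k, , drop = FALSE]
      pos <- suppressWarnings(as.integer(sub(":.*$", "", grp$roles)))
      role <- sub("^[0-9]+:", "", grp$roles)
      if (anyNA(pos)) { pos <- seq_len(nrow(grp)); }
      ord <- order(pos)
      grp <- grp[ord, , drop = FALSE]; role <- role[ord]
      members <- vapply(seq_len(nrow(grp)), function(j)
        verify_rogid(grp$rogidb[j], grp$taxb[j]), character(1))
      meta <- parse_rid(grp$interactionIdentifier[1])
      conf <- parse_conf(grp$confidence[1])
      meth <- parse_cv(grp$method[1]); ityp <- parse_cv(grp$interactionType[1])
      np_listed <- suppressWarnings(as.integer(grp$numParticipants[1]))
      if (!is.na(np_listed) && np_listed == 2L)
        warning("n-ary record with exactly 2 listed members kept as edgetype C",
                call. = FALSE)
      rec <- suppressWarnings(
        source_record(mk_id(meta$record_id), grp$sourcedb[1], meta$source_acc,
                      members, role, parse_pmids(grp$pmids[1]),
                      meth[1], meth[2], ityp[1], ityp[2],
                      edgetype = "C", predicted = conf$predicted))
      if (!identical(paste0("complex:", rec$rigid), grp$uidA[1]) ||
          !identical(rec$rigid, grp$rigid[1]))
        warning("rigid column disagrees with recomputed RIGID; recomputed wins",
                call. = FALSE)
      if (!is.na(conf$np) || !is.na(conf$lpr))
        scores[[rec$rigid]] <- list(np = conf$np, lpr = conf$lpr)
      for (j in seq_along(members))
        note(members[j], tax_int(grp$taxb[j]), grp$crogidb[j])
      records[[length(records) + 1L]] <- rec
    }
  }
  records <- records[order(vapply(records, function(r) r$record_id, 1L))]
  list(records = records, interactors = seen, scores = scores)
}
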