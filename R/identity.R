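#' Sequence-hash identifiers for interactors and interactions
#'
#' `compute_rogid()` assigns a ROGID (redundant object group identifier) to a
#' protein: the base64 encoding of the SHA-1 digest of the uppercased,
#' whitespace-stripped amino-acid sequence, with trailing `=` padding removed
#' and the NCBI taxonomy identifier appended as decimal text. Two records
#' that describe the same (sequence, taxon) protein therefore share a ROGID
#' no matter which accession system their source database used.
#'
#' The digest part is always 27 base64 characters (SHA-1 is 20 bytes, one
#' padding character stripped); the taxid is appended after, not inside, the
#' digest, so proteins with identical sequence in different organisms share
#' the digest part but not the full key.
#'
#' Non-standard residue characters are accepted (legacy records contain
#' them) and hashed as-is after uppercasing, with a warning.
#'
#' @param sequence amino-acid sequence; internal whitespace and newlines are
#'   stripped, case is ignored.
#' @param taxid positive integer NCBI taxonomy identifier.
#' @return character ROGID, e.g. `"3y7cCei/p+sWTfo7/JO/A5/Fu5E9606"`.
#' @seealso [compute_rigid()], [filename_safe()]
#' @examples
#' compute_rogid("mkv", 9606) == compute_rogid("MKV", 9606)
#' @export
compute_rogid <- function(sequence, taxid) {
  if (length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single string", call. = FALSE)
  seq <- toupper(gsub("[[:space:]]+", "", sequence))
  if (!nzchar(seq))
    stop("empty sequence: a ROGID requires at least one residue", call. = FALSE)
  taxid <- as.integer(taxid)
  if (length(taxid) != 1L || is.na(taxid) || taxid <= 0L)
    stop("`taxid` must be a single positive integer", call. = FALSE)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBXZJUO*]", seq))
    warning("sequence contains non-IUPAC residue characters; hashed as-is",
            call. = FALSE)
  paste0(sha1_base64(seq), taxid)
}

#' Compute the RIGID of an interaction record
#'
#' The RIGID (redundant interaction group identifier) keys the participant
#' multiset of an interaction record: participant ROGIDs are sorted in ASCII
#' byte order, concatenated without separator, SHA-1 digested and base64
#' encoded with padding stripped. It is invariant under permutation of the
#' participant list, so the same interaction curated by different databases
#' (or with participants listed in a different order) maps to one key.
#'
#' Duplicate participants are preserved: a homodimer record listing one
#' protein twice hashes that ROGID twice and gets a different RIGID from a
#' unary record. This multiset behaviour is isolated in
#' [rigid_participant_key()] so the policy can be changed in one place.
#'
#' @param participant_rogids character vector of ROGID full strings.
#' @return character RIGID (27 base64 characters).
#' @examples
#' a <- compute_rogid("MKV", 9606)
#' b <- compute_rogid("MSEQKV", 9606)
#' identical(compute_rigid(c(a, b)), compute_rigid(c(b, a)))
#' @export
compute_rigid <- function(participant_rogids) {
  if (length(participant_rogids) == 0L || any(is.na(participant_rogids)))
    stop("participant ROGID list must be non-empty and complete", call. = FALSE)
  sha1_base64(rigid_participant_key(participant_rogids))
}

#' Participant key underlying a RIGID
#'
#' Returns the exact byte string that is SHA-1 digested by [compute_rigid()]:
#' the ASCII-sorted concatenation of the participant ROGIDs, duplicates
#' retained. Kept as a separate function so the duplicate-participant policy
#' for self-interactions is a one-line change.
#'
#' @inheritParams compute_rigid
#' @return single character string.
#' @export
rigid_participant_key <- function(participant_rogids) {
  paste(sort(as.character(participant_rogids), method = "radix"),
        collapse = "")
}

#' Filename-safe form of a ROGID or RIGID
#'
#' Base64 keys may contain `/` and `+`, which are unsafe in file names. The
#' filename-safe form replaces `/` with `_` and `+` with `-` (the base64url
#' convention); all other characters are unchanged, so the mapping is
#' injective and [filename_unsafe()] restores the original key.
#'
#' @param key character vector of ROGIDs or RIGIDs.
#' @return character vector of the same length.
#' @export
filename_safe <- function(key) {
  chartr("/+", "_-", as.character(key))
}

#' @rdname filename_safe
#' @export
filename_unsafe <- function(key) {
  chartr("_-", "/+", as.character(key))
}

# base64(SHA-1(text)) with trailing '=' padding stripped; text hashed as
# its ASCII/UTF-8 bytes.
sha1_base64 <- function(text) {
  sub("=+$", "", openssl::base64_encode(openssl::sha1(charToRaw(text))))
}
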