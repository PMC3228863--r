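# Independent oracles. The digest oracle goes through the coreutils sha1sum
# binary and jsonlite's base64 encoder, sharing no code with the package's
# openssl-based implementation.

oracle_sha1_base64 <- function(text) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(text), f)
  hex <- strsplit(system2("sha1sum", f, stdout = TRUE), " ")[[1]][1]
  raw <- as.raw(strtoi(substring(hex, seq(1, 39, 2), seq(2, 40, 2)), 16L))
  sub("=+$", "", jsonlite::base64_enc(raw))
}

oracle_rogid <- function(sequence, taxid) {
  paste0(oracle_sha1_base64(toupper(gsub("[[:space:]]", "", sequence))), taxid)
}

oracle_rigid <- function(rogids) {
  oracle_sha1_base64(paste(sort(rogids, method = "radix"), collapse = ""))
}

random_aa <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

# participant multiset key, used by brute-force consolidation oracles
multiset_key <- function(participants) {
  paste(sort(participants, method = "radix"), collapse = "\r")
}

# brute-force np/lpr tally: two passes over plain (rigid-key, pmid) pairs
oracle_scores <- function(records) {
  keys <- vapply(records, function(r) multiset_key(r$participants), "")
  pairs <- unique(do.call(rbind, lapply(seq_along(records), function(i) {
    if (length(records[[i]]$pmids) == 0L) return(NULL)
    data.frame(key = keys[i], pmid = records[[i]]$pmids,
               stringsAsFactors = FALSE)
  })))
  yield <- tapply(pairs$key, pairs$pmid, function(k) length(unique(k)))
  lapply(split(pairs$pmid, pairs$key), function(p) {
    p <- unique(p)
    list(np = length(p), lpr = as.integer(min(yield[as.character(p)])))
  })
}

# brute-force BFS over records (neighbourhood oracle)
oracle_neighbourhood <- function(records, query, iterations) {
  if (iterations == 0L) {
    keep <- vapply(records, function(r) all(r$participants %in% query), TRUE)
    return(sort(vapply(records[keep], function(r) r$record_id, 1L)))
  }
  nodes <- query
  found <- integer()
  for (i in seq_len(iterations)) {
    hit <- vapply(records, function(r) any(r$participants %in% nodes), TRUE)
    found <- union(found, vapply(records[hit], function(r) r$record_id, 1L))
    nodes <- union(nodes, unlist(lapply(records[hit],
                                        function(r) r$participants)))
  }
  sort(found)
}

record_ids <- function(records) sort(vapply(records, function(r) r$record_id, 1L))
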