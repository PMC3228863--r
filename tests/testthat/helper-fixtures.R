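# Fixtures built in code. A tiny deterministic protein universe plus record
# builders used across test files.

toy_proteins <- function(n = 12, taxid = 9606L, seed = 42L) {
  withr::local_seed(seed)
  seqs <- vapply(50 + seq_len(n) * 7, random_aa, character(1))
  interactor_table(seqs, taxid)
}

# convenience: n-th toy rogid
rog <- function(it, i) it$rogid[i]

toy_record <- function(id, a, b, db = "intact", pmid = 100L + id,
                       method = c("MI:0018", "two hybrid"), roles = NULL,
                       predicted = FALSE) {
  source_record(id, db, paste0("ACC-", id), c(a, b), roles, pmid,
                method[1], method[2], "MI:0915", "physical association",
                predicted = predicted)
}

toy_complex <- function(id, members, db = "corum", pmid = 900L + id,
                        method = c("MI:0004", "affinity chromatography")) {
  source_record(id, db, paste0("CPX-", id), members,
                c("bait", rep("prey", length(members) - 1L)), pmid,
                method[1], method[2], "MI:0915", "physical association",
                edgetype = "C")
}

# spoke-instance generator: one planted pattern plus decoys that each
# mismatch exactly one grouping key (database, publication or method), so
# detection must recover precisely the planted candidate.
spoke_instance <- function(it, seed) {
  withr::local_seed(seed)
  n <- nrow(it)
  memb <- sample(it$rogid, sample(4:6, 1L))
  hub <- memb[1]
  db <- sample(c("intact", "biogrid"), 1L)
  pmid <- 7000L + seed
  method <- c("MI:0019", "coimmunoprecipitation")
  id <- 0L
  recs <- list()
  add <- function(a, b, db., pmid., method., roles = c("bait", "prey")) {
    id <<- id + 1L
    recs[[id]] <<- source_record(id, db., paste0("S", id), c(a, b), roles,
                                 pmid., method.[1], method.[2],
                                 edgetype = "X")
  }
  for (p in memb[-1]) add(hub, p, db, pmid, method)
  other_db <- setdiff(c("intact", "biogrid"), db)
  # decoys each mismatch one grouping key; the two other_db decoys use
  # disjoint pairs so no unplanted shared-interactor pattern can arise
  dis <- sample(it$rogid, 6L)
  add(dis[1], dis[2], other_db, pmid, method)
  add(hub, dis[5], db, pmid + 1L, method)                 # different pmid
  add(hub, dis[6], db, pmid, c("MI:0018", "two hybrid"))  # non-n-ary method
  add(dis[3], dis[4], other_db, pmid, method)
  list(records = recs, hub = hub, members = memb, db = db, pmid = pmid,
       method_cv = method[1])
}

toy_store <- function(records, it = toy_proteins(), acc = NULL) {
  compute_scores(suppressMessages(consolidate(records, it, acc)))
}

make_view_for_mining <- function(recs, it) {
  st <- toy_store(recs, it)
  build_view(st, st$records)
}
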