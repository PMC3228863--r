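test_that("the five-binary-record spoke pattern yields one six-member candidate", {
  it <- toy_proteins()
  hub <- rog(it, 1)
  recs <- lapply(1:5, function(i)
    source_record(i, "biogrid", paste0("B", i), c(hub, rog(it, i + 1)),
                  c("bait", "prey"), 555L, "MI:0004",
                  "affinity chromatography", edgetype = "X"))
  cand <- detect_spoke_complexes(recs)
  expect_length(cand, 1L)
  expect_identical(cand[[1]]$hub_rogid, hub)
  expect_length(cand[[1]]$member_rogids, 6L)
  expect_identical(cand[[1]]$record_ids, 1:5)
  # a single binary record is never a candidate
  expect_length(detect_spoke_complexes(recs[1]), 0L)
})

test_that("spoke grouping respects database, method filter and bait role", {
  it <- toy_proteins()
  hub <- rog(it, 1)
  mk <- function(id, db, partner, method = "MI:0004", pmid = 555L)
    source_record(id, db, paste0("A", id), c(hub, rog(it, partner)),
                  c("bait", "prey"), pmid, method, "m", edgetype = "X")
  # same hub/pmid/method split across two databases: partitions of size 1
  expect_length(detect_spoke_complexes(list(mk(1, "intact", 2),
                                            mk(2, "biogrid", 3))), 0L)
  # a record with a non-eligible method never contributes
  expect_length(detect_spoke_complexes(list(mk(1, "intact", 2, "MI:0018"),
                                            mk(2, "intact", 3, "MI:0018"))), 0L)
  cand <- detect_spoke_complexes(list(mk(1, "intact", 2),
                                      mk(2, "intact", 3, "MI:0018")))
  expect_length(cand, 0L)
  # custom method set is honoured and reported
  cand2 <- detect_spoke_complexes(list(mk(1, "intact", 2, "MI:0018"),
                                       mk(2, "intact", 3, "MI:0018")),
                                  nary_methods = "MI:0018")
  expect_length(cand2, 1L)
  expect_identical(attr(cand2, "nary_methods_used"), "MI:0018")
  # bait is preferred as hub: shared prey does not form a candidate when
  # baits are present but unshared
  r1 <- source_record(1, "intact", "A1", c(rog(it, 2), rog(it, 5)),
                      c("bait", "prey"), 555L, "MI:0004", "m", edgetype = "X")
  r2 <- source_record(2, "intact", "A2", c(rog(it, 3), rog(it, 5)),
                      c("bait", "prey"), 555L, "MI:0004", "m", edgetype = "X")
  expect_length(detect_spoke_complexes(list(r1, r2)), 0L)
})

test_that("planted spokes among decoys: precision = recall = 1", {
  it <- toy_proteins(n = 20)
  for (seed in 1:25) {
    inst <- spoke_instance(it, seed)
    cand <- detect_spoke_complexes(inst$records)
    expect_length(cand, 1L)
    expect_identical(cand[[1]]$hub_rogid, inst$hub)
    expect_setequal(cand[[1]]$member_rogids, inst$members)
    expect_identical(cand[[1]]$source_db, inst$db)
    expect_identical(cand[[1]]$pmid, inst$pmid)
    # candidate invariants hold by construction
    expect_gte(length(cand[[1]]$record_ids), 2L)
    expect_identical(length(cand[[1]]$member_rogids),
                     length(cand[[1]]$record_ids) + 1L)
  }
})

test_that("disease search covers digid, omim id and title fragments", {
  f <- withr::local_tempfile()
  writeLines(c("digid\ttitle\tomim_id\tgene_id",
               "197\tBreast cancer\t114480\t672",
               "197\tBreast cancer\t113705\t675",
               "301\tCancer of colon\t114500\t4292",
               "302\tDeafness\t220290\t2706"), f)
  groups <- read_disease_groups(f)
  expect_identical(disease_search(groups, "197", "digid"), c("672", "675"))
  expect_identical(disease_search(groups, "999", "digid"), character())
  expect_identical(disease_search(groups, "114500", "omim"), "4292")
  # fragment matching two group titles unions both gene sets
  expect_identical(disease_search(groups, "cancer", "omim_title"),
                   c("4292", "672", "675"))
  expect_identical(disease_search(groups, "nothing", "omim_title"), character())
})

test_that("adjacency cells classify the five relationship cases", {
  it <- toy_proteins()
  a <- rog(it, 1); b <- rog(it, 2); x <- rog(it, 3)
  c2 <- rog(it, 4); d2 <- rog(it, 5)
  recs <- list(toy_record(1, a, b),                    # direct a-b
               toy_record(2, a, x), toy_record(3, x, b),  # and via x
               toy_complex(4, c(c2, d2, rog(it, 6))))  # co-complex only
  v <- make_view_for_mining(recs, it)
  m <- adjacency_matrix(v, groupA = c(a, c2), groupB = c(b, d2, a))
  cell <- function(r, c) m$cells[m$cells$row_rogid == r &
                                   m$cells$col_rogid == c, ]
  both <- cell(b, a)                                   # direct + via x
  expect_identical(both$cell_class, "BOTH")
  expect_identical(both$colour, "green")
  expect_true(both$symbol)
  expect_identical(both$intermediates[[1]], x)
  cocx <- cell(d2, c2)                                 # shared pseudonode
  expect_identical(cocx$cell_class, "INDIRECT")
  expect_identical(cocx$colour, "blue")
  expect_false(cocx$symbol)
  expect_match(cocx$intermediates[[1]], "^complex:")
  none <- cell(d2, a)
  expect_identical(none$cell_class, "NONE")
  expect_identical(none$colour, "black")
  self <- cell(a, a)
  expect_identical(self$cell_class, "SELF")
  expect_setequal(self$intermediates[[1]], c(b, x))
  # pure DIRECT: remove the x path
  m2 <- adjacency_matrix(make_view_for_mining(recs[1], it), a, b)
  expect_identical(m2$cells$cell_class, "DIRECT")
  expect_identical(m2$cells$colour, "red")
  expect_error(adjacency_matrix(v, character(), b), "non-empty")
})

test_that("all-NONE rows/columns are hidden; swap transposes the matrix", {
  it <- toy_proteins()
  recs <- list(toy_record(1, rog(it, 1), rog(it, 2)))
  v <- make_view_for_mining(recs, it)
  m <- adjacency_matrix(v, c(rog(it, 1), rog(it, 7)), c(rog(it, 2), rog(it, 8)))
  expect_identical(m$hidden_rows, rog(it, 8))
  expect_identical(m$hidden_cols, rog(it, 7))
  mt <- adjacency_matrix(v, c(rog(it, 2), rog(it, 8)), c(rog(it, 1), rog(it, 7)))
  key <- function(m) {
    d <- m$cells[order(m$cells$row_rogid, m$cells$col_rogid),
                 c("cell_class", "colour", "symbol")]
    rownames(d) <- NULL
    d
  }
  swapped <- m$cells
  names(swapped)[1:2] <- c("col_rogid", "row_rogid")
  expect_identical(key(mt), key(list(cells = swapped)))
})

test_that("adjacency classes match a brute-force path/pseudonode oracle", {
  corpus <- generate_corpus(sim_config(n_records = 150, n_proteins = 60,
                                       n_genes = 15, nary_fraction = 0.2,
                                       seed = 51))
  st <- toy_store(corpus$records, corpus$interactors)
  v <- build_view(st, st$records)
  nt <- igraph::as_data_frame(v, what = "vertices")
  prot <- nt$name[!nt$i.pseudonode]
  withr::local_seed(52)
  ga <- sample(prot, 12); gb <- sample(prot, 12)
  m <- adjacency_matrix(v, ga, gb)
  # oracle straight from the records
  direct_pairs <- unique(unlist(lapply(corpus$records, function(r)
    if (r$edgetype == "X") paste(sort(r$participants), collapse = "\r"))))
  cx_members <- lapply(Filter(function(r) r$edgetype == "C", corpus$records),
                       function(r) unique(r$participants))
  nbr_of <- function(p) unique(unlist(lapply(corpus$records, function(r)
    if (r$edgetype == "X" && p %in% r$participants)
      setdiff(r$participants, p))))
  for (i in seq_len(nrow(m$cells))) {
    a <- m$cells$col_rogid[i]; b <- m$cells$row_rogid[i]
    if (a == b) next
    dir <- paste(sort(c(a, b)), collapse = "\r") %in% direct_pairs ||
      (a %in% nbr_of(b) && length(nbr_of(b)) == 0)  # guard, unreachable
    inter <- length(setdiff(intersect(nbr_of(a), nbr_of(b)), c(a, b))) > 0 ||
      any(vapply(cx_members, function(mm) a %in% mm && b %in% mm, TRUE))
    want <- if (dir && inter) "BOTH" else if (dir) "DIRECT"
      else if (inter) "INDIRECT" else "NONE"
    expect_identical(m$cells$cell_class[i], want)
  }
})

test_that("matrix_select resolves headings and cells to nodes and edges", {
  it <- toy_proteins()
  a <- rog(it, 1); b <- rog(it, 2); x <- rog(it, 3)
  recs <- list(toy_record(1, a, b), toy_record(2, a, b, db = "mint"),
               toy_record(3, a, x), toy_record(4, x, b),
               toy_record(5, rog(it, 5), rog(it, 6)))
  v <- make_view_for_mining(recs, it)
  m <- adjacency_matrix(v, c(a, rog(it, 5)), c(b, rog(it, 6)))
  # heading
  expect_identical(matrix_select(m, v, row = b)$nodes, b)
  # BOTH cell: row+col nodes, intermediate, direct parallel edges + bundles
  sel <- matrix_select(m, v, row = b, col = a)
  expect_setequal(sel$nodes, c(a, b, x))
  et <- igraph::as_data_frame(v, what = "edges")
  expect_setequal(et$record_id[sel$edge_idx], 1:4)
  # NONE cell is an empty selection
  none <- matrix_select(m, v, row = rog(it, 6), col = a)
  expect_length(none$nodes, 0L)
  expect_length(none$edge_idx, 0L)
})

test_that("spoke overlay adds grey pseudonodes distinct from n-ary ones", {
  it <- toy_proteins()
  hub <- rog(it, 1)
  recs <- lapply(1:3, function(i)
    source_record(i, "biogrid", paste0("B", i), c(hub, rog(it, i + 1)),
                  c("bait", "prey"), 555L, "MI:0004", "ac", edgetype = "X"))
  v <- make_view_for_mining(recs, it)
  cand <- detect_spoke_complexes(recs)
  v2 <- add_spoke_pseudonodes(v, cand)
  nt <- igraph::as_data_frame(v2, what = "vertices")
  sp <- nt[nt$spoke, ]
  expect_identical(nrow(sp), 1L)
  expect_true(sp$i.pseudonode)
  et <- igraph::as_data_frame(v2, what = "edges")
  expect_identical(sum(et$spoke), 4L)        # dashed edge per member
})
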