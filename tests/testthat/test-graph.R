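make_view <- function(recs, it, query = character(), ...) {
  st <- toy_store(recs, it)
  build_view(st, st$records, query_rogids = query, ...)
}

test_that("binary and n-ary records materialize per the bipartite rule", {
  it <- toy_proteins()
  v <- make_view(list(toy_record(1, rog(it, 1), rog(it, 2))), it)
  expect_equal(igraph::vcount(v), 2)
  expect_equal(igraph::ecount(v), 1)
  expect_false(any(igraph::V(v)$i.pseudonode))

  v2 <- make_view(list(toy_complex(1, it$rogid[1:4])), it)
  nt <- igraph::as_data_frame(v2, what = "vertices")
  expect_identical(sum(nt$i.pseudonode), 1L)
  expect_equal(igraph::vcount(v2), 5)
  expect_equal(igraph::ecount(v2), 4)
  pn <- nt$name[nt$i.pseudonode]
  expect_true(all(igraph::ends(v2, igraph::E(v2))[, 1] == pn |
                    igraph::ends(v2, igraph::E(v2))[, 2] == pn))
})

test_that("redundant records yield parallel edges sharing one RIGID", {
  it <- toy_proteins()
  recs <- list(toy_record(1, rog(it, 1), rog(it, 2), db = "intact"),
               toy_record(2, rog(it, 2), rog(it, 1), db = "biogrid"),
               toy_record(3, rog(it, 1), rog(it, 2), db = "mint", pmid = 9L))
  v <- make_view(recs, it)
  expect_equal(igraph::vcount(v), 2)
  expect_equal(igraph::ecount(v), 3)
  expect_length(unique(igraph::E(v)$rigid), 1L)
  expect_identical(sort(igraph::E(v)$i.src_intxn_db),
                   c("biogrid", "intact", "mint"))
})

test_that("provenance attributes follow the order/query encoding", {
  it <- toy_proteins()
  recs <- list(toy_record(1, rog(it, 1), rog(it, 2)))
  st <- toy_store(recs, it)
  v <- build_view(st, st$records, query_rogids = rog(it, 1), search_index = 1,
                  query_terms = setNames(list("P12345"), rog(it, 1)))
  nt <- igraph::as_data_frame(v, what = "vertices")
  expect_identical(nt$i.order[nt$name == rog(it, 1)], 2L)
  expect_identical(nt$i.order[nt$name == rog(it, 2)], 3L)
  expect_identical(nt$i.query[nt$name == rog(it, 1)], "P12345")
  # second search merges without moving existing attributes, appends terms
  recs2 <- list(toy_record(2, rog(it, 2), rog(it, 3)))
  st2 <- toy_store(c(recs, recs2), it)
  v2 <- build_view(st2, records_by_id(st2, 2L), query_rogids = rog(it, 2),
                   search_index = 2,
                   query_terms = setNames(list("Q2"), rog(it, 2)), view = v)
  nt2 <- igraph::as_data_frame(v2, what = "vertices")
  expect_identical(nt2$i.order[nt2$name == rog(it, 1)], 2L)   # untouched
  expect_identical(nt2$i.order[nt2$name == rog(it, 2)], 3L)   # untouched
  expect_identical(nt2$i.order[nt2$name == rog(it, 3)], 5L)   # 2*2 + 1
  expect_identical(nt2$i.query[nt2$name == rog(it, 2)], "Q2")
  expect_equal(igraph::ecount(v2), 2)
})

test_that("multi-edge toggle collapses, honours i.flag, and re-expands", {
  it <- toy_proteins()
  recs <- lapply(1:3, function(i)
    toy_record(i, rog(it, 1), rog(it, 2), db = c("intact", "mint", "dip")[i]))
  v <- make_view(recs, it)
  t1 <- toggle_multi_edges(v)
  et1 <- igraph::as_data_frame(t1, what = "edges")
  expect_identical(sum(et1$visible), 1L)
  expect_identical(et1$record_id[et1$visible], 1L)   # smallest record id
  expect_identical(nrow(et1), 3L)                     # conservation
  t2 <- toggle_multi_edges(t1)
  expect_true(all(igraph::as_data_frame(t2, what = "edges")$visible))
  # user-set flag wins
  et <- igraph::as_data_frame(v, what = "edges")
  et$i.flag[et$record_id == 3L] <- TRUE
  vf <- irefkit:::rebuild_view(v, et = et)
  tf <- toggle_multi_edges(vf)
  etf <- igraph::as_data_frame(tf, what = "edges")
  expect_identical(etf$record_id[etf$visible], 3L)
})

test_that("alive degree counts distinct alive neighbours, incl. co-complex", {
  it <- toy_proteins()
  recs <- list(toy_record(1, rog(it, 1), rog(it, 2)),
               toy_record(2, rog(it, 1), rog(it, 2), db = "mint"),
               toy_record(3, rog(it, 1), rog(it, 3)),
               toy_complex(4, it$rogid[c(4, 1, 5)]))
  v <- make_view(recs, it)
  v0 <- set_alive(v, character())
  expect_true(all(igraph::V(v0)$i.alive_degree == 0L))
  # parallel edges to one alive neighbour count once
  v1 <- set_alive(v, rog(it, 2))
  nt <- igraph::as_data_frame(v1, what = "vertices")
  expect_identical(nt$i.alive_degree[nt$name == rog(it, 1)], 1L)
  # pseudonode co-membership counts (and can be switched off)
  v2 <- set_alive(v, rog(it, 4))
  nt2 <- igraph::as_data_frame(v2, what = "vertices")
  expect_identical(nt2$i.alive_degree[nt2$name == rog(it, 1)], 1L)
  v3 <- set_alive(v, rog(it, 4), count_pseudonodes = FALSE)
  nt3 <- igraph::as_data_frame(v3, what = "vertices")
  expect_identical(nt3$i.alive_degree[nt3$name == rog(it, 1)], 0L)
})

test_that("alive degree equals a brute-force adjacency scan on random views", {
  corpus <- generate_corpus(sim_config(n_records = 120, n_proteins = 60,
                                       n_genes = 15, seed = 41))
  st <- toy_store(corpus$records, corpus$interactors)
  v <- build_view(st, st$records)
  withr::local_seed(42)
  nt <- igraph::as_data_frame(v, what = "vertices")
  prot <- nt$name[!nt$i.pseudonode]
  for (rep in 1:5) {
    alive <- sample(prot, length(prot) %/% 3)
    va <- set_alive(v, alive)
    nta <- igraph::as_data_frame(va, what = "vertices")
    # oracle: distinct alive co-participants over all records
    for (n in sample(prot, 10)) {
      co <- unlist(lapply(corpus$records, function(r)
        if (n %in% r$participants) r$participants))
      want <- length(intersect(setdiff(unique(co), n), alive))
      expect_identical(nta$i.alive_degree[nta$name == n], want)
    }
  }
})

test_that("select_between equals completion restricted to the selection", {
  corpus <- generate_corpus(sim_config(n_records = 150, n_proteins = 50,
                                       n_genes = 10, seed = 43))
  st <- toy_store(corpus$records, corpus$interactors)
  v <- build_view(st, st$records)
  withr::local_seed(44)
  sel <- sample(corpus$interactors$rogid, 25)
  got <- select_between(v, sel)
  want <- complete_neighbourhood(st, sel)
  expect_identical(got$record_ids, record_ids(want))
  nt <- igraph::as_data_frame(got$view, what = "vertices")
  expect_setequal(nt$name[nt$i.alive], intersect(sel, nt$name))
  expect_warning(res <- select_between(v, sel[1]), "at least 2")
  expect_length(res$record_ids, 0L)
})

test_that("export drops unmapped nodes, merges shared ids cumulatively", {
  it <- toy_proteins()
  acc <- accession_table(
    rogid = c(rog(it, 1), rog(it, 2), rog(it, 3)),
    type = rep("entrez_gene", 3),
    value = c("g1", "g2", "g2"))              # 2 and 3 are isoforms of g2
  recs <- list(toy_record(1, rog(it, 1), rog(it, 2)),
               toy_record(2, rog(it, 1), rog(it, 3)),
               toy_record(3, rog(it, 3), rog(it, 4)))  # 4 has no gene id
  st <- toy_store(recs, it, acc)
  v <- build_view(st, st$records)
  ex <- export_view(v, st, "entrez_gene")
  expect_setequal(ex$node_table$name, c("g1", "g2"))
  merged <- ex$node_table[ex$node_table$name == "g2", ]
  expect_identical(merged$n_constituents, 2L)
  expect_setequal(strsplit(merged$constituents, "|", fixed = TRUE)[[1]],
                  c(rog(it, 2), rog(it, 3)))
  # node 4 and its exclusive record dropped; both g1-g2 edges re-homed
  expect_identical(nrow(ex$edge_table), 2L)
  expect_true(all(ex$edge_table$from == "g1" | ex$edge_table$to == "g1"))
  expect_error(export_view(v, st, "nonsense"), "arg")
})

test_that("export under a bijective id preserves topology; flags persist", {
  corpus <- generate_corpus(sim_config(n_records = 120, n_proteins = 60,
                                       n_genes = 15, predicted_fraction = 0.2,
                                       seed = 45))
  st <- toy_store(corpus$records, corpus$interactors)
  v <- build_view(st, st$records)
  ex <- export_view(v, st, "rogid")
  nt <- igraph::as_data_frame(v, what = "vertices")
  et <- igraph::as_data_frame(v, what = "edges")
  prot <- nt$name[!nt$i.pseudonode]
  pp <- et[!(et$from %in% nt$name[nt$i.pseudonode]) &
             !(et$to %in% nt$name[nt$i.pseudonode]), ]
  expect_setequal(ex$node_table$name, prot)
  expect_identical(nrow(ex$edge_table), nrow(pp))
  expect_identical(sort(ex$edge_table$record_id), sort(pp$record_id))
  # predicted flag survives build, toggle and export
  expect_identical(sort(ex$edge_table$record_id[ex$edge_table$predicted]),
                   sort(pp$record_id[pp$predicted]))
  tv <- toggle_multi_edges(v)
  ett <- igraph::as_data_frame(tv, what = "edges")
  expect_identical(sort(ett$record_id[ett$predicted]),
                   sort(et$record_id[et$predicted]))
  d <- withr::local_tempdir()
  write_view_export(ex, d)
  expect_true(all(file.exists(file.path(d, c("nodes.tsv", "edges.tsv",
                                             "network.graphml")))))
})
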