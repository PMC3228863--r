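# irefkit

Protein–protein interaction databases curate overlapping slices of the same
literature. The same physical interaction typically exists as many records
across (and within) sources, described with different accession systems
(UniProt, RefSeq, PDB, gene identifiers), sometimes with different splice
isoforms of the same gene product, and sometimes as an n-ary
(complex/co-purification) record rather than binary edges. irefkit is a
headless R toolkit for working with such consolidated interaction data:
who-interacts-with-whom bookkeeping for people who mine interactomes rather
than browse them.

## The identity scheme

Consolidation rests on two sequence-hash keys that anyone can recompute:

* **ROGID** (redundant object group identifier), one per distinct
  (sequence, taxon) protein:

  `ROGID = base64(SHA-1(uppercase(sequence)))` with trailing `=` padding
  stripped, followed by the NCBI taxonomy id as decimal text.

* **RIGID** (redundant interaction group identifier), one per distinct
  participant multiset:

  `RIGID = base64(SHA-1(concat(sort_ascii(participant ROGIDs))))`.

Records from any source that describe the same participants collapse onto
one RIGID regardless of the accession system they were curated with. On top
of this the package provides:

* an iRefIndex-style **PSI-MITAB 2.5 dialect** (15 standard + 8 extension
  columns) with a bipartite serialization of n-ary records,
* a **consolidated store**: RIGID grouping, multi-accession lookup,
  canonical (isoform-group) query expansion, neighbourhood retrieval and
  completion, per-edge bibliometric scores `np` (distinct supporting
  publications) and `lpr` (lowest interaction yield among supporting
  publications — low values mean at least one low-throughput citation),
* **canonicalization**: related gene groups (genes sharing an identical
  protein product, transitively) with a deterministic canonical
  representative per group,
* a **multigraph network view** (igraph) with parallel evidence edges,
  hexagon-style pseudonodes for n-ary records and the `i.*` attribute
  vocabulary (`i.order`, `i.query`, `i.alive`, `i.alive_degree`,
  `i.overall_degree`, `i.flag`, `i.score_np`, `i.score_lpr`, ...),
* **mining tools**: spoke-represented-complex detection, disease-group
  (OMIM-style) search, and a group-vs-group adjacency matrix classifying
  each protein pair as DIRECT / INDIRECT / BOTH / NONE / SELF,
* a **seeded synthetic corpus generator** with ground-truth tables, and an
  `irefkit` command-line interface.

## Worked example

```r
library(irefkit)

corpus <- generate_corpus(sim_config(seed = 1))
store  <- compute_scores(consolidate(corpus$records, corpus$interactors,
                                     corpus$accessions))
store
#> <iref_store> 1506 source records -> 1012 distinct RIGIDs, 300 distinct ROGIDs
```

1,506 source records (1,000 base records, their re-curations by second
databases, and planted spoke patterns) collapse to 1,012 distinct
interactions between 300 distinct proteins — the two-fold redundancy the
hash scheme exists to manage.

```r
hits <- lookup(store, "U00010", "uniprot")
hits
#> [1] "zCypKCT7K9W6E07AL/5tiEcK1O89606"
recs <- neighbourhood(store, hits, iterations = 1)
length(recs)
#> [1] 11
view <- build_view(store, recs, query_rogids = hits,
                   query_terms = setNames(list("U00010"), hits))
igraph::vcount(view); igraph::ecount(view)
#> [1] 11
#> [1] 17
```

A UniProt accession resolves to its ROGID; one search iteration returns the
11 records touching it, drawn as a multigraph of 11 nodes and 17 evidence
edges (parallel edges are separate records sharing one RIGID; n-ary records
appear as pseudonodes with one edge per member).

```r
cand <- detect_spoke_complexes(store$records)
length(cand)
#> [1] 5
cand[[1]][c("hub_rogid", "source_db", "pmid", "method_cv")]
#> $hub_rogid
#> [1] "JNUaP1WQTevtHiPnmXNFScxF4789606"
#> $source_db
#> [1] "intact"
#> $pmid
#> [1] 4000001
#> $method_cv
#> [1] "MI:0096"

round(reachability(store), 3)
#> uniprot  refseq     pdb   other
#>   0.807   0.137   0.003   0.053
```

All five planted spoke-represented complexes (sets of binary records from
one database, one publication and one co-purification-style method sharing
a hub) are recovered; the reachability table shows what fraction of
proteins each accession type can retrieve, with the catch-all class always
reachable by direct ROGID search.

## Command line

```sh
irefkit simulate    --config sim.cfg --out corpus/
irefkit build-index --mitab corpus/records.mitab --fasta corpus/sequences.fasta \
                    --annotations corpus/annotations.tsv --out index/
irefkit search      --index index/ --type uniprot --query-file q.txt \
                    --iterations 1 --complete --out hits/
irefkit search      --index index/ --type uniprot \
                    --query 'COMPARE{P08254,P08588|O00253,O75056}' --out cmp/
irefkit spokes      --index index/ --out spokes.tsv
irefkit export      --index index/ --type uniprot --query P08254 \
                    --id-type entrez_gene --out exported/
```

The launcher lives at `inst/exec/irefkit` (call `irefkit::irefkit_run(args)`
from R for the same behaviour). Exit codes: 0 success, 1 validation error,
2 I/O error. `COMPARE{...|...}` queries are routed to the adjacency-matrix
classifier.

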