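---
title: "irefkit: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{irefkit: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irefkit)
```

# The problem

Public protein–protein interaction databases overlap heavily: the same
experimental result is curated independently by several sources, under
different protein accession systems, occasionally attached to different
splice isoforms of the same gene, and sometimes represented as an n-ary
(complex) record where another database stores binary edges. irefkit
implements the computational machinery for working with such data in a
consolidated way: hash-based identity, redundancy grouping, search with
isoform-group expansion, an evidence-preserving multigraph model, and
mining operations over it.

# The identity scheme

**ROGID.** For a protein with amino-acid sequence $s$ and NCBI taxon $t$:

$$\mathrm{ROGID}(s, t) = \mathrm{b64}(\mathrm{SHA1}(\mathrm{upper}(s)))\,\Vert\,t$$

where `b64` is standard base64 with the single trailing `=` stripped
(SHA-1 is 20 bytes, so the digest part is always 27 characters) and the
taxon is appended as decimal text, *outside* the digest. Consequences that
the tests rely on: hashing is case-insensitive in the sequence,
whitespace-insensitive, and two taxa sharing a sequence share the digest
part but not the key.

**RIGID.** For an interaction record with participant ROGIDs
$r_1,\dots,r_n$: sort the full ROGID strings in ASCII byte order,
concatenate without separator, SHA-1, base64, strip padding. This is
invariant under participant permutation, which is exactly what makes
records redundantly curated by different databases collapse.

Byte-level decisions:

* The recipe above (uppercase before hashing; taxon appended, not hashed;
  padding stripped; ASCII sort for RIGID) is fixed so keys are bit-stable
  and externally reproducible; the test suite checks agreement with an
  independent oracle built from the coreutils `sha1sum` binary and a
  different base64 implementation.
* **Self-interactions.** A record listing a protein once hashes one ROGID;
  listing it twice hashes it twice, giving a different RIGID. We preserve
  the source record's multiset faithfully. The policy is isolated in
  `rigid_participant_key()`, one line to change if the alternative
  (deduplicate before hashing) is ever preferred.
* **Non-IUPAC residues.** Legacy records contain nonstandard residue
  letters; they are uppercased and hashed as-is, with a warning, rather
  than silently dropped or rejected.
* `filename_safe()` maps `/`→`_` and `+`→`-` (the base64url convention),
  an injective substitution so keys remain collision-free as file names.

# The MITAB dialect

Files carry the 15 MITAB 2.5 columns plus 8 extension columns
(`rogida, rogidb, rigid, crogida, crogidb, edgetype, numParticipants,
roles`); missing values are `-`. Choices a maintainer should know:

* **Extension columns are derived data.** On read, the `rigid` column is
  compared with the RIGID recomputed from the participant ROGIDs, and —
  when sequences are available — ROGIDs are recomputed from sequence and
  taxon. Mismatches warn and the recomputed value wins; a file can never
  poison the identity scheme.
* **n-ary serialization.** An n-ary record with $n$ members occupies $n$
  rows sharing the placeholder `uidA = complex:<rigid>`. The member's
  position is encoded in the roles cell (`"<position>:<role>"`), so
  assembly is independent of row order while the record's original
  participant order still round-trips exactly. Two redundant n-ary records
  share a RIGID but not a group key (the record identifier participates),
  so they do not merge at parse time.
* **uid columns are presentation.** The accession shown in `uidA`/`uidB`
  rotates deterministically through the interactor's available accession
  types (keyed on record id). This exercises the promise that search works
  regardless of the accession system used in the original record, without
  making the uid choice part of the record object — which is what makes
  `write` → `read` field-for-field exact.
* n-ary records with exactly two listed members are accepted on read (real
  data contains them) but warned about; the `edgetype` column stays
  authoritative.

# Store semantics

* **Grouping.** `consolidate()` indexes records by computed RIGID. The
  conservation invariant (group sizes sum to the record count) and
  agreement with a brute-force participant-multiset oracle are tested on
  generated corpora.
* **Scores.** `np` is the number of distinct PubMed ids supporting a
  RIGID. `lpr` is the minimum, over those publications, of the number of
  distinct RIGIDs each supports: a small value means at least one
  supporting study was low-throughput. These definitions follow the
  consolidated-index ecosystem this dialect models; groups with no
  publication keep `NA` scores and are logged.
* **Degree.** `overall_degree` counts *distinct partner proteins* (over
  binary records plus n-ary co-membership), not edges, so it is stable
  under record duplication — the property that makes it meaningful in a
  deliberately redundant dataset.
* **Lookup.** Exact-match through the accession table. ROGIDs are
  case-sensitive (base64 is case-significant); gene symbols are
  case-folded (conventional usage); retired accessions stay searchable
  under the `original_reference` type. Gene-type queries return all
  protein products of the gene. Unknown identifiers return an empty set —
  an unanswerable query is not an error.
* **Neighbourhood.** `iterations = 0` returns only records entirely inside
  the query set (the "interactions between what I already see" search,
  also exposed as `complete_neighbourhood()`, which is idempotent);
  `iterations = k` is breadth-first record retrieval, checked against an
  oracle BFS.

# Canonicalization

Genes are grouped into related gene groups (RGGs) when they share an
identical protein product, transitively (union-find; tests compare against
igraph connected components). Each group's product list is expanded once
with isoform links and gene cross-reference links; expansion is *not*
chased transitively (isoforms of isoforms), on the reading that the link
tables are already complete per protein — a single pass keeps the
operation idempotent and order-independent. The canonical member is then:

1. the sole UniProt-canonical member, if exactly one;
2. the longest UniProt-canonical member, if several;
3. otherwise the longest member overall;

with length ties broken by the ASCII-smallest ROGID. The tie-break is our
choice (the selection rules alone do not determine a unique answer);
ASCII order is deterministic and implementation-independent. Proteins not
attached to any gene become their own canonical representative, so every
node carries `i.canonical_rogid` and canonical query expansion
(`canonical_expand()`) is total and reflexive.

# The network view

The view is an igraph multigraph. Every binary record is one evidence
edge; parallel edges between a pair always share one RIGID (checked on
every build). Every n-ary record contributes a pseudonode
(`i.pseudonode = TRUE`) adjacent only to its member proteins — the
bipartite representation that keeps "co-purified together" visually and
structurally distinct from "binary evidence".

* **Provenance.** Nodes matched by the $k$-th search of a session get
  `i.order = 2k`; their neighbours get `2k + 1`. The even/odd encoding is
  our packing of "query vs neighbour, incrementally per search" into one
  integer; a renderer can map colours from it. `i.query` accumulates the
  matching query terms within a session; repeated builds merge into the
  view without touching attributes of existing nodes.
* **Toggle.** Collapsing parallel edges retains a user-flagged edge
  (`i.flag`) when present, otherwise the smallest record id — a
  deterministic stand-in for a random pick, so runs reproduce; a seeded
  random mode exists behind `random = TRUE`. Toggling again restores
  everything; visible + hidden counts are conserved.
* **Alive degree.** `i.alive_degree` counts *distinct* alive protein
  neighbours (parallel edges once). Whether pseudonode co-membership
  counts as neighbourhood is not forced by the model; we count it
  (complex co-membership is a relationship) and expose
  `count_pseudonodes = FALSE` to switch it off.
* **Export.** Collapsing onto a target identifier drops nodes lacking it
  (pseudonodes always lack protein accessions, so they never survive
  export) and merges nodes sharing a value, concatenating their attribute
  lists. When a node carries several values of the target type the
  ASCII-smallest is used as its key. With a bijective identifier the
  protein subgraph is preserved edge-for-edge (tested).

# Mining

* **Spoke detection.** Binary records are partitioned by (source database,
  publication, method ∈ n-ary-capable set); within a partition, any
  interactor shared by ≥ 2 records is a candidate hub — restricted to bait
  participants whenever baits are annotated, since the bait is
  conventionally the hub of a spoke-expanded complex. The method set
  defaults to six co-purification-style PSI-MI terms
  (`default_nary_methods()`), is file-configurable, and is reported with
  every result. Identity of interaction type is deliberately *not*
  required for grouping.
* **Disease groups.** A versioned 4-column table (digid, title, OMIM id,
  gene id) is consumed, never derived; search by group id, by OMIM id, or
  by case-insensitive title fragment (unioning groups on fragment hits).
* **Adjacency matrix.** For groups A (columns) and B (rows), each cell is
  DIRECT (evidence edge; `¤`, red), INDIRECT (length-2 protein path or
  shared pseudonode; blue, intermediates listed — intermediates may
  themselves belong to either group), BOTH (green), NONE (black; all-NONE
  rows/columns flagged hidden) or SELF (diagonal; direct interactors
  listed). Classes are tested against a brute-force path/pseudonode
  enumeration, and swapping the groups transposes the matrix.

# The synthetic world

`sim_config()` defaults describe the corpus the acceptance properties run
on: 1,000 base records over 3 source databases with duplication rate 0.5
(each base record re-curated by a second database with probability 0.5 —
mirroring the roughly two-fold redundancy consolidated indexes exhibit),
10% n-ary records of size 3–6, 5 planted spoke patterns with 3–6 partners,
2 high-throughput publications of yield 100 (driving `lpr`), 5% predicted
edges from an OPHID-like source, 300 proteins over 80 genes with isoform
rate 0.3, all human (taxon 9606). Sequences are uniform over the 20
standard residues, length 50–500: only hashing and identity matter here,
not biological plausibility.

Deliberate generator choices:

* High-throughput publications use the two-hybrid method (MI:0018), which
  is not in the n-ary-capable set — realistic (large Y2H screens) and
  structurally necessary, since an HTP publication with a co-purification
  method would legitimately *be* a spoke pattern and blur the planted
  ground truth.
* Ground truth is computed by bookkeeping during generation — distinct
  participant multisets, per-publication yields, planted canonical
  designations (constructed so the selection rules identify them
  uniquely), planted spoke record sets — never by running the pipeline
  under test.
* Duplicate records permute participant order and present a different
  accession type in the uid columns, exercising order- and
  accession-independence of consolidation.

What the generator does **not** emulate: realistic (scale-free) degree
distributions, organism mixtures, curation errors in sequences, or
ontology-term noise. A green test therefore establishes algorithmic
correctness on the structures above, not robustness to dirty real-world
annotation — the identity scheme itself is exact, so this limitation
concerns primarily the annotation-dependent operations (lookup, export).

# Numerical and degenerate-input choices

* Sorting of identifier strings always uses byte (`radix`) order, never
  locale collation.
* Empty sequences, empty participant lists, empty RGGs and empty
  adjacency groups are hard errors; unknown identifiers and unmatched
  searches are empty results with a log message.
* Records referencing unknown interactors are excluded from consolidation
  with a warning, not an error — one bad record must not poison a corpus.
* `sample()`-style scalar pitfalls in the generator are guarded
  (`sample1()`), so a one-member group can never silently sample from
  `1:n`.

# Known limitations

* The store is in-memory and rebuilt from flat files on load; there is no
  incremental index (the compressed per-key storage of the original
  system is explicitly out of scope).
* PSI-MI terms are carried as id + name pairs; no ontology traversal or
  term normalization is performed (upstream concerns).
* Whether isoform expansion should chase transitively, and whether
  duplicate participants should collapse before RIGID hashing, are both
  open questions in the modelled system; each is isolated behind a single
  function with the current choice documented above.
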