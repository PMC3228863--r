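#' Simulation configuration
#'
#' Describes a synthetic interaction corpus. Defaults give a desk-scale
#' corpus exhibiting every structure the toolkit must handle: redundant
#' re-curation across source databases, splice-isoform gene groups, n-ary
#' (complex) records, planted spoke-represented complexes, high-throughput
#' publications of configurable yield (for lpr scoring) and predicted
#' (OPHID-style) edges.
#'
#' @param n_proteins number of distinct proteins (at least the gene-model
#'   proteins; gene-less extras are added up to this count).
#' @param n_genes number of Entrez-style genes in the gene model.
#' @param isoform_rate probability drivers for extra isoform products,
#'   UniProt isoform links and cross-reference links per gene.
#' @param n_records number of base interaction records before duplication.
#' @param n_source_dbs number of experimental source databases (2-6).
#' @param duplication_rate probability that a base record is re-curated by a
#'   second database (same publication, permuted participants).
#' @param nary_fraction fraction of base records that are n-ary.
#' @param nary_size_range integer length-2 vector, participant count range
#'   for n-ary records (min >= 3 when `nary_fraction > 0`).
#' @param spoke_pattern_count number of planted spoke-represented complexes.
#' @param spoke_partner_range partners per planted spoke hub.
#' @param htp_paper_count,htp_yield number of high-throughput publications
#'   and binary records drawn per publication (drives lpr).
#' @param predicted_fraction fraction of base binary records that are
#'   predicted (source `ophid`).
#' @param taxid NCBI taxon for all proteins.
#' @param seed integer RNG seed; the whole corpus is a pure function of it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300L, n_genes = 80L, isoform_rate = 0.3,
                       n_records = 1000L, n_source_dbs = 3L,
                       duplication_rate = 0.5, nary_fraction = 0.1,
                       nary_size_range = c(3L, 6L),
                       spoke_pattern_count = 5L,
                       spoke_partner_range = c(3L, 6L),
                       htp_paper_count = 2L, htp_yield = 100L,
                       predicted_fraction = 0.05, taxid = 9606L, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_genes = as.integer(n_genes),
              isoform_rate = isoform_rate, n_records = as.integer(n_records),
              n_source_dbs = as.integer(n_source_dbs),
              duplication_rate = duplication_rate,
              nary_fraction = nary_fraction,
              nary_size_range = as.integer(nary_size_range),
              spoke_pattern_count = as.integer(spoke_pattern_count),
              spoke_partner_range = as.integer(spoke_partner_range),
              htp_paper_count = as.integer(htp_paper_count),
              htp_yield = as.integer(htp_yield),
              predicted_fraction = predicted_fraction,
              taxid = as.integer(taxid), seed = as.integer(seed))
  rates <- c(cfg$isoform_rate, cfg$duplication_rate, cfg$nary_fraction,
             cfg$predicted_fraction)
  if (any(rates < 0) || any(rates > 1))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (cfg$n_proteins < 1L || cfg$n_records < 0L || cfg$n_genes < 0L)
    stop("sizes must be positive", call. = FALSE)
  if (cfg$n_source_dbs < 2L || cfg$n_source_dbs > 6L)
    stop("n_source_dbs must be between 2 and 6", call. = FALSE)
  if (cfg$nary_fraction > 0 && max(cfg$nary_size_range) < 3L)
    stop("nary_fraction > 0 requires nary_size_range max >= 3", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

aa_alphabet <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# sample() expands a length-1 numeric x to 1:x; this never does
sample1 <- function(x) x[sample.int(length(x), 1L)]

random_sequence <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

source_db_names <- function(n) {
  head(c("intact", "biogrid", "mint", "dip", "hprd", "corum"), n)
}

#' Simulate a gene/isoform model with known canonical assignments
#'
#' Generates genes with one or more protein products, occasional product
#' sharing between consecutive genes (planting multi-gene related gene
#' groups), UniProt isoform links and gene cross-reference links. For every
#' related gene group a designated canonical protein is planted by
#' construction: either it is flagged UniProt-canonical and made the longest
#' flagged member, or no member is flagged and it is made the strictly
#' longest member. Lengths within a group are distinct, so the selection
#' rules identify the designated protein uniquely.
#'
#' Assumes an active RNG state (callers seed it); see [generate_corpus()].
#'
#' @param n_genes number of genes.
#' @param isoform_rate isoform / cross-reference intensity in `[0, 1]`.
#' @param share_rate probability a gene shares one product with the
#'   previous gene.
#' @param taxid NCBI taxon id.
#' @return list with `proteins` (data.frame protein_id, length, sequence,
#'   rogid), `gene_to_proteins`, `isoform_links`, `xref_links` (named
#'   lists), `uniprot_canonical_flags`, `lengths` (named by ROGID), and
#'   `truth` (data.frame rogid, canonical_rogid, rgg_genes).
#' @export
simulate_gene_model <- function(n_genes, isoform_rate = 0.3, share_rate = 0.1,
                                taxid = 9606L) {
  proteins <- data.frame(protein_id = integer(), length = integer(),
                         sequence = character(), rogid = character(),
                         stringsAsFactors = FALSE)
  new_protein <- function(len) {
    id <- nrow(proteins) + 1L
    seq <- random_sequence(len)
    proteins[id, ] <<- list(id, len, seq, compute_rogid(seq, taxid))
    id
  }
  gene_ids <- as.character(1000L + seq_len(n_genes))
  gene_to_proteins <- setNames(vector("list", n_genes), gene_ids)
  isoform_links <- list(); xref_links <- list()
  group_of <- integer(n_genes)  # planted RGG index per gene
  extra <- setNames(vector("list", n_genes), gene_ids)  # iso/xref proteins
  n_group <- 0L
  prev_last <- NA_integer_
  for (j in seq_len(n_genes)) {
    prods <- integer()
    if (j > 1L && !is.na(prev_last) && runif(1) < share_rate) {
      prods <- prev_last                       # shared product: same RGG
      group_of[j] <- group_of[j - 1L]
    } else {
      n_group <- n_group + 1L
      group_of[j] <- n_group
    }
    n_own <- 1L + rbinom(1L, 2L, isoform_rate)
    for (k in seq_len(n_own)) prods <- c(prods, new_protein(sample(50:500, 1L)))
    gene_to_proteins[[j]] <- prods
    if (runif(1) < isoform_rate) {
      iso <- new_protein(sample(50:500, 1L))
      anchor <- prods[length(prods)]
      isoform_links[[as.character(anchor)]] <-
        c(isoform_links[[as.character(anchor)]], iso)
      extra[[j]] <- c(extra[[j]], iso)
    }
    if (runif(1) < 0.3 * isoform_rate) {
      xr <- new_protein(sample(50:500, 1L))
      xref_links[[gene_ids[j]]] <- c(xref_links[[gene_ids[j]]], xr)
      extra[[j]] <- c(extra[[j]], xr)
    }
    prev_last <- prods[length(prods)]
  }

  flags <- logical(); truth <- NULL
  for (grp in seq_len(n_group)) {
    gidx <- which(group_of == grp)
    members <- unique(c(unlist(gene_to_proteins[gidx]), unlist(extra[gidx])))
    # distinct lengths within the group make the canonical choice unique
    lens <- sample(50:500, length(members))
    designated <- sample1(members)
    if (runif(1) < 0.5) {
      grp_flags <- setNames(runif(length(members)) < 0.3, members)
      grp_flags[as.character(designated)] <- TRUE
      flagged <- members[grp_flags[as.character(members)]]
      lens[match(designated, members)] <- max(lens) + 1L
    } else {
      grp_flags <- setNames(rep(FALSE, length(members)), members)
      lens[match(designated, members)] <- max(lens) + 1L
    }
    for (m in seq_along(members)) {
      id <- members[m]
      if (proteins$length[id] != lens[m]) {
        proteins$length[id] <- lens[m]
        proteins$sequence[id] <- random_sequence(lens[m])
        proteins$rogid[id] <- compute_rogid(proteins$sequence[id], taxid)
      }
    }
    flags <- c(flags, grp_flags)
    truth <- rbind(truth, data.frame(
      protein_id = members,
      canonical_protein = designated,
      rgg = grp,
      rgg_genes = paste(sort(gene_ids[gidx]), collapse = "|"),
      stringsAsFactors = FALSE))
  }

  rog <- proteins$rogid
  to_rog <- function(ids) unique(rog[ids])
  list(proteins = proteins,
       gene_to_proteins = lapply(gene_to_proteins, to_rog),
       isoform_links = setNames(lapply(isoform_links, to_rog),
                                rog[as.integer(names(isoform_links))]),
       xref_links = lapply(xref_links, to_rog),
       uniprot_canonical_flags = setNames(as.logical(flags),
                                          rog[as.integer(names(flags))]),
       lengths = setNames(proteins$length, rog),
       truth = data.frame(rogid = rog[truth$protein_id],
                          canonical_rogid = rog[truth$canonical_protein],
                          rgg = truth$rgg, rgg_genes = truth$rgg_genes,
                          stringsAsFactors = FALSE))
}

#' Generate a seeded synthetic corpus
#'
#' Produces interactors, accession annotations, interaction records and the
#' gene/isoform model, together with ground-truth tables computed by
#' bookkeeping during generation (never by running the pipeline under
#' test): distinct participant-multiset groups, per-publication yields,
#' np/lpr per group, planted canonical assignments and planted spoke
#' candidates. The corpus is a pure function of `config$seed`.
#'
#' Structural choices: sequences are uniform over the 20 standard residues,
#' length 50-500 (only hashing and identity matter, not biology);
#' high-throughput publications use the two-hybrid method (MI:0018), which
#' is not in the n-ary-capable method set, so they can never collide with
#' planted spoke patterns; duplicate records permute participant order and
#' (via the writer's uid rotation) vary the accession type presented in the
#' uid columns.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, all corpus files are
#'   written there via [write_corpus()].
#' @return list of class `iref_corpus` with `config`, `interactors`,
#'   `accessions`, `records`, `gene_model`, `disease_groups`, `truth`
#'   (list: n_rigids, n_rogids, groups, np, lpr, pmid_yield, canonical,
#'   spokes) and `files` (paths or NULL).
#' @export
generate_corpus <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  taxid <- config$taxid
  gm <- simulate_gene_model(config$n_genes, config$isoform_rate,
                            share_rate = 0.1, taxid = taxid)
  proteins <- gm$proteins
  while (nrow(proteins) < config$n_proteins) {
    len <- sample(50:500, 1L)
    seq <- random_sequence(len)
    proteins[nrow(proteins) + 1L, ] <- list(nrow(proteins) + 1L, len, seq,
                                            compute_rogid(seq, taxid))
  }
  rogids <- proteins$rogid
  n <- nrow(proteins)

  # --- accession annotations -------------------------------------------
  acc <- list()
  push <- function(rog, type, value)
    acc[[length(acc) + 1L]] <<- c(rog, type, value)
  has_uniprot <- runif(n) < 0.82
  has_refseq <- runif(n) < 0.60
  has_pdb <- runif(n) < 0.10
  has_old <- runif(n) < 0.20
  for (i in seq_len(n)) {
    if (has_uniprot[i]) push(rogids[i], "uniprot", sprintf("U%05d", i))
    if (has_refseq[i]) push(rogids[i], "refseq", sprintf("NP_%06d", i))
    if (has_pdb[i]) push(rogids[i], "pdb", sprintf("%dABC", (i %% 9) + 1L))
    if (has_old[i]) push(rogids[i], "original_reference", sprintf("OLD%05d", i))
    push(rogids[i], "xref", sprintf("XR%05d", i))
  }
  for (g in names(gm$gene_to_proteins)) {
    prods <- unique(c(gm$gene_to_proteins[[g]],
                      unlist(gm$isoform_links[gm$gene_to_proteins[[g]]]),
                      gm$xref_links[[g]]))
    for (r in prods) {
      push(r, "entrez_gene", g)
      push(r, "gene_symbol", sprintf("GENE%s", g))
    }
  }
  accessions <- accession_table(
    rogid = vapply(acc, `[`, "", 1L), type = vapply(acc, `[`, "", 2L),
    value = vapply(acc, `[`, "", 3L))

  canonical <- assign_canonical(rogids, gm$gene_to_proteins,
                                gm$isoform_links, gm$xref_links,
                                gm$uniprot_canonical_flags, gm$lengths)
  interactors <- interactor_table(proteins$sequence, taxid)
  interactors$canonical_rogid <-
    canonical$canonical_rogid[match(interactors$rogid, canonical$rogid)]

  # --- interaction records ---------------------------------------------
  dbs <- source_db_names(config$n_source_dbs)
  safe_methods <- rbind(c("MI:0018", "two hybrid"),
                        c("MI:0114", "x-ray crystallography"),
                        c("MI:0077", "nuclear magnetic resonance"),
                        c("MI:0065", "isothermal titration calorimetry"))
  nary_methods <- rbind(c("MI:0004", "affinity chromatography technology"),
                        c("MI:0019", "coimmunoprecipitation"),
                        c("MI:0096", "pull down"),
                        c("MI:0676", "tandem affinity purification"))
  records <- list()
  rid <- 0L
  add_record <- function(db, participants, roles, pmid, method, edgetype,
                         predicted = FALSE) {
    rid <<- rid + 1L
    records[[rid]] <<- source_record(
      rid, db, sprintf("%s-%d", toupper(db), rid), participants, roles,
      pmid, method[1], method[2],
      type_cv = "MI:0915", type_name = "physical association",
      edgetype = edgetype, predicted = predicted)
    rid
  }

  n_base <- config$n_records
  n_nary <- round(config$nary_fraction * n_base)
  n_pred <- round(config$predicted_fraction * (n_base - n_nary))
  n_bin <- n_base - n_nary - n_pred

  htp_pmids <- if (config$htp_paper_count > 0L)
    5000000L + seq_len(config$htp_paper_count) else integer()
  pool <- rep(htp_pmids, each = config$htp_yield)
  if (length(pool) < n_bin)
    pool <- c(pool, 1000000L + seq_len(n_bin - length(pool)))
  pool <- sample(pool, n_bin)

  base_ids <- integer()
  for (i in seq_len(n_bin)) {
    pair <- rogids[sample.int(n, 2L)]
    m <- if (pool[i] %in% htp_pmids) safe_methods[1, ] else
      safe_methods[sample.int(nrow(safe_methods) - 1L, 1L) + 1L, ]
    roles <- if (runif(1) < 0.5) c("bait", "prey") else c("neutral", "neutral")
    base_ids <- c(base_ids, add_record(sample(dbs, 1L), pair, roles,
                                       pool[i], m, "X"))
  }
  for (i in seq_len(n_nary)) {
    size <- sample1(seq(max(3L, config$nary_size_range[1]),
                        config$nary_size_range[2]))
    memb <- rogids[sample.int(n, size)]
    roles <- c("bait", rep("prey", size - 1L))
    base_ids <- c(base_ids, add_record(sample(dbs, 1L), memb, roles,
                                       2000000L + i,
                                       nary_methods[sample.int(4L, 1L), ], "C"))
  }
  for (i in seq_len(n_pred)) {
    pair <- rogids[sample.int(n, 2L)]
    add_record("ophid", pair, c("neutral", "neutral"), 3000000L + i,
               c(NA_character_, NA_character_), "X", predicted = TRUE)
  }

  # planted spoke patterns: dedicated publications, n-ary-capable methods
  spokes <- list()
  for (s in seq_len(config$spoke_pattern_count)) {
    k <- sample1(seq(config$spoke_partner_range[1],
                     config$spoke_partner_range[2]))
    memb <- rogids[sample.int(n, k + 1L)]
    hub <- memb[1]
    db <- sample(dbs, 1L)
    pmid <- 4000000L + s
    m <- nary_methods[sample.int(4L, 1L), ]
    ids <- vapply(memb[-1], function(p)
      add_record(db, c(hub, p), c("bait", "prey"), pmid, m, "X"), 1L)
    spokes[[s]] <- list(hub_rogid = hub, member_rogids = memb,
                        source_db = db, pmid = pmid, method_cv = m[1],
                        record_ids = sort(unname(ids)))
  }

  # duplication: base records re-curated by a second database
  dup_of <- integer()
  for (i in base_ids) {
    if (runif(1) >= config$duplication_rate) next
    r <- records[[i]]
    db2 <- sample(setdiff(dbs, r$source_db), 1L)
    perm <- sample(seq_along(r$participants))
    add_record(db2, r$participants[perm], r$roles[perm], r$pmids,
               c(r$method_cv, r$method_name), r$edgetype, r$predicted)
    dup_of <- c(dup_of, i)
  }

  # --- ground truth by bookkeeping (participant multisets, no hashing) --
  mkey <- vapply(records, function(r)
    paste(sort(r$participants, method = "radix"), collapse = "\r"), "")
  groups <- split(vapply(records, function(r) r$record_id, 1L), mkey)
  key_pmids <- lapply(split(lapply(records, function(r) r$pmids), mkey),
                      function(x) sort(unique(unlist(x))))
  pk <- unique(data.frame(
    key = rep(mkey, vapply(records, function(r) length(r$pmids), 1L)),
    pmid = unlist(lapply(records, function(r) r$pmids)),
    stringsAsFactors = FALSE))
  pmid_yield <- tapply(pk$key, pk$pmid, function(x) length(unique(x)))
  np <- vapply(key_pmids, length, 1L)
  lpr <- vapply(key_pmids, function(p)
    if (length(p) == 0L) NA_integer_ else
      as.integer(min(pmid_yield[as.character(p)])), 1L)

  # --- disease groups ----------------------------------------------------
  titles <- c("Breast cancer", "Leukoencephalopathy", "Cardiomyopathy",
              "Obesity", "Deafness")
  genes <- names(gm$gene_to_proteins)
  dg <- NULL
  for (d in seq_len(min(5L, max(1L, length(genes) %/% 4L)))) {
    gset <- sample(genes, min(length(genes), sample(2:6, 1L)))
    dg <- rbind(dg, data.frame(
      digid = 100L + d, title = titles[(d - 1L) %% length(titles) + 1L],
      omim_id = sprintf("6%05d", 100L * d + seq_along(gset)),
      gene_id = gset, stringsAsFactors = FALSE))
  }

  corpus <- structure(list(
    config = config, interactors = interactors, accessions = accessions,
    records = records, gene_model = gm, disease_groups = dg,
    truth = list(
      n_records = length(records), n_base = n_base,
      n_duplicates = length(dup_of),
      n_rigids = length(groups), n_rogids = length(unique(unlist(
        lapply(records, function(r) r$participants)))),
      groups = groups, np = np, lpr = lpr, pmid_yield = pmid_yield,
      canonical = canonical, gene_truth = gm$truth, spokes = spokes),
    files = NULL), class = "iref_corpus")
  if (!is.null(out_dir)) corpus <- write_corpus(corpus, out_dir)
  corpus
}

#' @export
print.iref_corpus <- function(x, ...) {
  cat(sprintf("<iref_corpus> %d records (%d base + %d duplicates), %d proteins, %d genes, seed %d\n",
              x$truth$n_records, x$truth$n_base, x$truth$n_duplicates,
              nrow(x$interactors), x$config$n_genes, x$config$seed))
  invisible(x)
}

#' Write a corpus to a directory of plain-text files
#'
#' Emits `records.mitab` (via [write_mitab()]), `sequences.fasta`,
#' `annotations.tsv` (rogid, taxid, accession_type, accession_value),
#' `gene2product.tsv`, `isoform_links.tsv`, `xref_links.tsv`,
#' `canonical_input.tsv` (rogid, uniprot_canonical, length),
#' `disease_groups.tsv` and ground-truth tables under `truth/`.
#'
#' @param corpus an `iref_corpus`.
#' @param dir output directory.
#' @return the corpus with `files` filled in.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_mitab(corpus$records, p("records.mitab"), corpus$interactors,
              corpus$accessions)
  write_fasta(corpus$interactors, p("sequences.fasta"))
  ann <- data.frame(rogid = corpus$accessions$rogid,
                    taxid = corpus$interactors$taxid[
                      match(corpus$accessions$rogid, corpus$interactors$rogid)],
                    accession_type = corpus$accessions$type,
                    accession_value = corpus$accessions$value)
  tsv <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  tsv(ann, "annotations.tsv")
  gm <- corpus$gene_model
  flat <- function(lst, a, b) do.call(rbind, c(list(
    setNames(data.frame(character(), character(),
                        stringsAsFactors = FALSE), c(a, b))),
    lapply(names(lst), function(k)
      setNames(data.frame(k, lst[[k]], stringsAsFactors = FALSE), c(a, b)))))
  tsv(flat(gm$gene_to_proteins, "gene_id", "rogid"), "gene2product.tsv")
  tsv(flat(gm$isoform_links, "rogid", "isoform_rogid"), "isoform_links.tsv")
  tsv(flat(gm$xref_links, "gene_id", "rogid"), "xref_links.tsv")
  tsv(data.frame(rogid = names(gm$lengths),
                 uniprot_canonical = names(gm$lengths) %in%
                   names(which(gm$uniprot_canonical_flags)),
                 length = as.integer(gm$lengths)), "canonical_input.tsv")
  tsv(corpus$disease_groups, "disease_groups.tsv")
  dir.create(p("truth"), showWarnings = FALSE)
  tsv(corpus$truth$canonical, file.path("truth", "canonical.tsv"))
  tsv(data.frame(stat = c("n_records", "n_base", "n_duplicates", "n_rigids",
                          "n_rogids"),
                 value = c(corpus$truth$n_records, corpus$truth$n_base,
                           corpus$truth$n_duplicates, corpus$truth$n_rigids,
                           corpus$truth$n_rogids)),
      file.path("truth", "counts.tsv"))
  spk <- do.call(rbind, lapply(corpus$truth$spokes, function(s)
    data.frame(hub_rogid = s$hub_rogid,
               members = paste(sort(s$member_rogids), collapse = "|"),
               source_db = s$source_db, pmid = s$pmid,
               method_cv = s$method_cv,
               record_ids = paste(s$record_ids, collapse = "|"))))
  if (!is.null(spk)) tsv(spk, file.path("truth", "spokes.tsv"))
  corpus$files <- list(
    mitab = p("records.mitab"), fasta = p("sequences.fasta"),
    annotations = p("annotations.tsv"), gene2product = p("gene2product.tsv"),
    isoform_links = p("isoform_links.tsv"), xref_links = p("xref_links.tsv"),
    canonical_input = p("canonical_input.tsv"),
    disease_groups = p("disease_groups.tsv"))
  corpus
}

#' Write interactor sequences as FASTA
#'
#' Headers are `>rogid taxid=<taxid>`; 60-column wrapped sequence lines.
#'
#' @param interactors interactor table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(interactors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(interactors))) {
    writeLines(sprintf(">%s taxid=%d", interactors$rogid[i],
                       interactors$taxid[i]), con)
    seq <- interactors$sequence[i]
    starts <- seq(1L, nchar(seq), by = 60L)
    writeLines(substring(seq, starts, pmin(starts + 59L, nchar(seq))), con)
  }
  invisible(path)
}
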