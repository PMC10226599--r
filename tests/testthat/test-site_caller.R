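# Toy single-transcript world reused by several filter tests: one 300-nt
# single-exon coding transcript on a random genome.
toy_world <- function(seed = 2) {
  set.seed(seed)
  genome <- toy_genome(c(c1 = random_seq(400)))
  tx <- make_tx("tx1", "c1", "+", rbind(c(50L, 350L)), cds = c(110L, 290L))
  list(genome = genome, models = list(tx1 = tx))
}

test_that("low-abundance prefilter keeps CPM >= 1 and drops < 1", {
  tr <- make_cpm(data.table(chrom = "c", strand = "+", pos = 1:3,
                            value = c(1.0, 0.99, 5)), genotype = "xrn4")
  kept <- prefilter_low_abundance(tr)
  expect_setequal(kept$pos, c(1L, 3L))
  empty <- make_cpm(data.table(chrom = character(), strand = character(),
                               pos = integer(), value = numeric()))
  expect_equal(nrow(prefilter_low_abundance(empty)), 0L)
  # random track against the one-line oracle
  set.seed(8)
  rnd <- make_cpm(data.table(chrom = "c", strand = "+", pos = 1:200,
                             value = runif(200, 0, 3)))
  expect_setequal(prefilter_low_abundance(rnd)$pos,
                  rnd$values[value >= 1]$pos)
})

test_that("decap catalog: CPM threshold boundary and TSS inclusion", {
  w <- toy_world()
  cap <- make_cpm(data.table(chrom = "c1", strand = "+", pos = c(60L, 70L),
                             value = c(5.0, 4.9)), genotype = "cap_pare")
  cat <- build_decap_catalog(cap, w$models)
  expect_true(dnecall:::catalog_has(cat, "c1", "+", 60L))   # >= 5 CPM
  expect_false(dnecall:::catalog_has(cat, "c1", "+", 70L))  # below threshold
  expect_true(dnecall:::catalog_has(cat, "c1", "+", 50L))   # TSS always in
})

test_that("simulator-planted decap spikes are recovered in the catalog", {
  sim <- small_sim()
  cap <- cpm_normalize(sim$profiles[["cap_pare_rep1"]])
  cat <- build_decap_catalog(cap, sim$models)
  planted <- sim$truth[, .(chrom, strand, pos = decap_pos)]
  found <- vapply(seq_len(nrow(planted)), function(i)
    dnecall:::catalog_has(cat, planted$chrom[i], planted$strand[i],
                          planted$pos[i]), logical(1))
  expect_true(all(found))
  for (m in sim$models[1:5]) {
    expect_true(dnecall:::catalog_has(cat, m$chromosome, m$strand, m$tss))
  }
})

test_that("XRN4-sensitivity thresholds are inclusive at the boundary", {
  pre <- data.table(chrom = "c", strand = "+", pos = 1:3,
                    xrn4_cpm = c(5.0, 100, 4.99))
  setkey(pre, chrom, strand, pos)
  fc <- structure(list(values = data.table(chrom = "c", strand = "+",
                                           pos = 1:3,
                                           value = c(2.0, 1.99, 8),
                                           key = c("chrom", "strand", "pos"))),
                  class = "comparison_track")
  got <- call_xrn4_sensitive(pre, fc)
  expect_equal(got$pos, 1L)     # (5.0, 2.0) in; (100, 1.99) and (4.99, 8) out
  expect_equal(sort(attr(got, "dropped")$pos), c(2L, 3L))
})

test_that("DNE1-dependence: boundary and missing-contrast semantics", {
  cands <- data.table(chrom = "c", strand = "+", pos = 1:3,
                      xrn4_cpm = c(10, 10, 10), fc_xrn4_wt = c(3, 3, 3))
  fc <- structure(list(values = data.table(chrom = "c", strand = "+",
                                           pos = 1:2, value = c(2.0, 1.5),
                                           key = c("chrom", "strand", "pos"))),
                  class = "comparison_track")
  got <- call_dne1_dependent(cands, fc)
  expect_equal(got$pos, 1L)
  drops <- attr(got, "dropped")
  expect_equal(drops[pos == 3L]$reason, "no-signal-in-contrast")
  expect_equal(drops[pos == 2L]$reason, "not-dne1-dependent")
})

test_that("decap proximity: +/-5 nt inclusive, spliced distance", {
  w <- toy_world()
  cap <- make_cpm(data.table(chrom = "c1", strand = "+", pos = 200L,
                             value = 50), genotype = "cap_pare")
  cat <- build_decap_catalog(cap, w$models)
  cands <- annotate_candidates(
    data.table(chrom = "c1", strand = "+", pos = c(205L, 206L),
               xrn4_cpm = c(10, 10), fc_xrn4_wt = c(3, 3),
               fc_xrn4_double = c(3, 3)),
    w$models)
  got <- filter_decap_proximity(cands, cat)
  expect_equal(got$pos, 206L)                       # +6 survives
  expect_equal(attr(got, "dropped")$pos, 205L)      # +5 removed
  # empty catalog is the identity
  empty_cap <- make_cpm(data.table(chrom = character(), strand = character(),
                                   pos = integer(), value = numeric()),
                        genotype = "cap_pare")
  no_tss <- build_decap_catalog(empty_cap, list())
  expect_equal(nrow(filter_decap_proximity(cands, no_tss)), 2L)
  # random candidates against a brute-force distance scan
  set.seed(3)
  rnd <- annotate_candidates(
    data.table(chrom = "c1", strand = "+",
               pos = sample(60:340, 60), xrn4_cpm = 10,
               fc_xrn4_wt = 3, fc_xrn4_double = 3),
    w$models)
  got2 <- filter_decap_proximity(rnd, cat)
  cat_t <- c(genomic_to_transcript(200L, w$models$tx1),
             genomic_to_transcript(50L, w$models$tx1))
  brute_keep <- rnd$pos[vapply(seq_len(nrow(rnd)), function(i) {
    min(abs(cat_t - rnd$tpos[i])) > 5
  }, logical(1))]
  expect_setequal(got2$pos, brute_keep)
})

test_that("uniqueness filter: duplicated and edge k-mers removed", {
  set.seed(6)
  left <- random_seq(120)
  dup <- random_seq(20)
  # genome with the same 20-mer embedded twice
  genome <- toy_genome(c(c1 = paste0(left, dup, random_seq(60), dup,
                                     random_seq(100))))
  tx <- make_tx("tx1", "c1", "+", rbind(c(0L, 320L)), cds = c(30L, 300L))
  models <- list(tx1 = tx)
  cands <- annotate_candidates(
    data.table(chrom = "c1", strand = "+",
               pos = c(120L, 60L, 310L),   # dup k-mer, unique, off-the-end
               xrn4_cpm = 10, fc_xrn4_wt = 3, fc_xrn4_double = 3),
    models)
  got <- filter_uniqueness(cands, genome, models)
  expect_equal(got$pos, 60L)
  drops <- attr(got, "dropped")
  expect_equal(drops[pos == 120L]$reason, "multi-mapping")
  expect_equal(drops[pos == 310L]$reason, "edge")
})

test_that("uniqueness agrees with exhaustive substring counting", {
  sim <- small_sim()
  models <- sim$models[1:10]
  genome_chr <- as.character(sim$genome)
  txome <- spliced_sequences(sim$genome, models)
  set.seed(14)
  cands_raw <- rbindlist(lapply(models, function(m) {
    p <- transcript_to_genomic(sample(0:(m$length - 30L), 3L), m)
    data.table(chrom = m$chromosome, strand = m$strand, pos = p,
               xrn4_cpm = 10, fc_xrn4_wt = 3, fc_xrn4_double = 3)
  }))
  cands <- annotate_candidates(cands_raw, models)
  got <- filter_uniqueness(cands, sim$genome, models)
  txc <- as.character(txome)
  count_all <- function(kmer) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(kmer)))
    g <- 0L
    for (ch in genome_chr) {
      st <- seq_len(nchar(ch) - nchar(kmer) + 1L)
      subs <- substring(ch, st, st + nchar(kmer) - 1L)
      g <- g + sum(subs == kmer) + if (rc != kmer) sum(subs == rc) else 0L
    }
    t <- 0L
    for (s in txc) {
      st <- seq_len(nchar(s) - nchar(kmer) + 1L)
      t <- t + sum(substring(s, st, st + nchar(kmer) - 1L) == kmer)
    }
    c(g, t)
  }
  for (i in seq_len(nrow(cands))) {
    s <- cands$tpos[i]
    seqc <- txc[[cands$transcript_id[i]]]
    expected_keep <- if (s + 20L <= nchar(seqc)) {
      occ <- count_all(substr(seqc, s + 1L, s + 20L))
      occ[1] == 1L && occ[2] == 1L
    } else FALSE
    expect_equal(cands$pos[i] %in% got$pos, expected_keep)
  }
})

test_that("expression filter is one-sided and tolerates missing rows", {
  w <- toy_world()
  cands <- annotate_candidates(
    data.table(chrom = "c1", strand = "+", pos = c(150L, 160L),
               xrn4_cpm = 10, fc_xrn4_wt = 3, fc_xrn4_double = 3),
    w$models)
  tab <- data.frame(transcript_id = "tx1",
                    log2fc_double_vs_xrn4 = -1.0, fdr = 0.01)
  expect_equal(nrow(filter_expression(cands, tab)), 0L)
  tab$fdr <- 0.5
  expect_equal(nrow(filter_expression(cands, tab)), 2L)
  # significant *increase* never disqualifies (one-sided)
  tab$log2fc_double_vs_xrn4 <- 1.0; tab$fdr <- 0.001
  expect_equal(nrow(filter_expression(cands, tab)), 2L)
  expect_warning(filter_expression(cands, NULL), "skipped")
  tab2 <- data.frame(transcript_id = "other", log2fc_double_vs_xrn4 = -2,
                     fdr = 0.001)
  expect_warning(got <- filter_expression(cands, tab2), "absent")
  expect_equal(nrow(got), 2L)
  expect_error(filter_expression(cands, data.frame(x = 1)), "columns")
})

test_that("MaxSeq / Major-internal classification rules", {
  w <- toy_world()
  models <- w$models
  cap <- make_cpm(data.table(chrom = "c1", strand = "+", pos = 50L,
                             value = 100), genotype = "cap_pare")
  cat_with <- build_decap_catalog(cap, models)
  mk_cand <- function(pos, cpm) {
    annotate_candidates(
      data.table(chrom = "c1", strand = "+", pos = pos, xrn4_cpm = cpm,
                 fc_xrn4_wt = 3, fc_xrn4_double = 3), models)
  }
  # candidate is the top position -> MaxSeq
  track <- make_cpm(data.table(chrom = "c1", strand = "+",
                               pos = c(150L, 200L, 50L),
                               value = c(40, 12, 30)), genotype = "xrn4")
  got <- classify_maxseq_major(mk_cand(150L, 40), track, cat_with, models)
  expect_equal(got$site_class, "MaxSeq")
  # top is the catalogued decap site, candidate second -> MajorInternal
  track2 <- make_cpm(data.table(chrom = "c1", strand = "+",
                                pos = c(50L, 150L, 200L),
                                value = c(90, 40, 12)), genotype = "xrn4")
  got2 <- classify_maxseq_major(mk_cand(150L, 40), track2, cat_with, models)
  expect_equal(got2$site_class, "MajorInternal")
  # top is NOT a decap site, candidate second -> unclassified
  track3 <- make_cpm(data.table(chrom = "c1", strand = "+",
                                pos = c(250L, 150L),
                                value = c(90, 40)), genotype = "xrn4")
  got3 <- classify_maxseq_major(mk_cand(150L, 40), track3, cat_with, models)
  expect_equal(nrow(got3), 0L)
  expect_equal(attr(got3, "dropped")$reason, "unclassified")
  # two surviving candidates: only the more abundant is reported
  got4 <- classify_maxseq_major(mk_cand(c(150L, 200L), c(40, 12)),
                                track, cat_with, models)
  expect_equal(got4$pos, 150L)
  expect_true("secondary-site" %in% attr(got4, "dropped")$reason)
})

test_that("control sets follow the fold-change windows with priority", {
  # three transcripts: one with an XRN4-sensitive but DNE1-independent site
  # (nontarget), one XRN4-insensitive (other), one target
  set.seed(21)
  genome <- toy_genome(c(c1 = random_seq(1200)))
  models <- list(
    tA = make_tx("tA", "c1", "+", rbind(c(0L, 300L)), cds = c(60L, 240L),
                 gene = "gA"),
    tB = make_tx("tB", "c1", "+", rbind(c(400L, 700L)), cds = c(460L, 640L),
                 gene = "gB"),
    tC = make_tx("tC", "c1", "+", rbind(c(800L, 1100L)), cds = c(860L, 1040L),
                 gene = "gC"))
  xr <- make_cpm(data.table(chrom = "c1", strand = "+",
                            pos = c(150L, 500L, 900L),
                            value = c(50, 40, 30)), genotype = "xrn4")
  fc_wt <- structure(list(values = data.table(
    chrom = "c1", strand = "+", pos = c(150L, 500L, 900L),
    value = c(3, 3, 0.1), key = c("chrom", "strand", "pos"))),
    class = "comparison_track")
  fc_dbl <- structure(list(values = data.table(
    chrom = "c1", strand = "+", pos = c(150L, 500L, 900L),
    value = c(0.1, 0.2, 0.0), key = c("chrom", "strand", "pos"))),
    class = "comparison_track")
  sets <- define_control_sets(models, xr, fc_wt, fc_dbl,
                              target_ids = character(0))
  expect_setequal(sets$nontargets, c("tA", "tB"))
  expect_equal(sets$others, "tC")
  # a transcript qualifying as nontarget that is a target stays a target
  sets2 <- define_control_sets(models, xr, fc_wt, fc_dbl, target_ids = "tA")
  expect_equal(sets2$targets, "tA")
  expect_equal(sets2$nontargets, "tB")
  expect_true(!"tA" %in% sets2$others)
})

test_that("cascade is monotone and the trace reconstructs every elimination", {
  sim <- small_sim()
  res <- call_sites(sim$profiles, sim$models, sim$genome, sim$rnaseq)
  counts <- res$counts[-1]   # survivor counts after each filtering stage
  expect_true(all(diff(unname(counts)) <= 0))
  # survivors at each stage drop by exactly the eliminations traced there
  stages <- c("dne1_dependent", "annotated", "decap_proximity",
              "uniqueness", "expression")
  prev <- unname(res$counts["xrn4_sensitive"])
  for (s in stages) {
    eliminated <- nrow(res$trace[filter == s])
    expect_equal(unname(res$counts[s]), prev - eliminated)
    prev <- unname(res$counts[s])
  }
  expect_equal(unname(res$counts["classified"]),
               prev - nrow(res$trace[filter == "classification"]))
})

test_that("site tables are byte-identical across reruns", {
  sim <- small_sim()
  r1 <- call_sites(sim$profiles, sim$models, sim$genome, sim$rnaseq)
  r2 <- call_sites(sim$profiles, sim$models, sim$genome, sim$rnaseq)
  f1 <- tempfile(); f2 <- tempfile()
  data.table::fwrite(r1$sites, f1, sep = "\t")
  data.table::fwrite(r2$sites, f2, sep = "\t")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("filter order does not change the final site set", {
  sim <- small_sim()
  cfg <- pipeline_config()
  models <- collapse_isoforms(sim$models)
  cpms <- lapply(sim$profiles, cpm_normalize)
  geno <- vapply(cpms, `[[`, character(1), "genotype")
  xr <- merge_replicates(cpms[geno == "xrn4"])
  wt <- merge_replicates(cpms[geno == "wild_type"])
  db <- merge_replicates(cpms[geno == "dne1_xrn4"])
  cap <- merge_replicates(cpms[geno == "cap_pare"])
  fc_wt <- log2_compare(xr, wt); fc_db <- log2_compare(xr, db)
  catalog <- build_decap_catalog(cap, models, cfg)
  pre <- prefilter_low_abundance(xr, cfg)
  c0 <- call_dne1_dependent(call_xrn4_sensitive(pre, fc_wt, cfg), fc_db, cfg)
  c0 <- annotate_candidates(c0, models)
  # order A: decap -> uniqueness -> expression
  a <- filter_expression(
    filter_uniqueness(filter_decap_proximity(c0, catalog, cfg),
                      sim$genome, models, cfg),
    sim$rnaseq, cfg)
  # order B: expression -> uniqueness -> decap
  b <- filter_decap_proximity(
    filter_uniqueness(filter_expression(c0, sim$rnaseq, cfg),
                      sim$genome, models, cfg),
    catalog, cfg)
  setkey(a, chrom, strand, pos); setkey(b, chrom, strand, pos)
  expect_equal(a[, .(chrom, strand, pos)], b[, .(chrom, strand, pos)])
  ca <- classify_maxseq_major(a, xr, catalog, models)
  cb <- classify_maxseq_major(b, xr, catalog, models)
  expect_equal(ca[, .(chrom, strand, pos, site_class)],
               cb[, .(chrom, strand, pos, site_class)])
})
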