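# The cleavage-site filter cascade: XRN4 sensitivity, DNE1 dependence,
# decapping/TSS exclusion, genome/transcriptome uniqueness, full-length
# expression check, then MaxSeq / Major-internal classification (at most one
# classified site per transcript).

#' Pipeline configuration
#'
#' Thresholds of the site-calling cascade. Defaults follow the published
#' criteria: candidate sites must reach CPM >= 5 in *xrn4* with
#' log2 FC >= 2 against both wild type and the *dne1 xrn4* double mutant;
#' positions under 1 CPM in *xrn4* are removed up front; decapping sites are
#' Cap-PARE positions >= 5 CPM; sites within +/-5 nt of a decapping site or
#' annotated TSS are excluded; the site 20-mer must be unique in genome and
#' transcriptome; transcripts whose full-length abundance drops
#' significantly in the double mutant (log2 FC <= -0.58, FDR <= 0.05) are
#' disqualified. Control-set windows are log2 FC in [-0.25, 0.25].
#'
#' @param min_xrn4_cpm Minimum *xrn4* CPM for a candidate (5).
#' @param prefilter_min_cpm Low-abundance prefilter on *xrn4* (1).
#' @param min_log2fc_xrn4_vs_wt Minimum log2 FC *xrn4*/wild-type (2).
#' @param min_log2fc_xrn4_vs_double Minimum log2 FC *xrn4*/double (2).
#' @param decap_min_cpm Cap-PARE CPM defining a decapping site (5).
#' @param exclusion_window Half-width (nt) of the decap/TSS exclusion (5).
#' @param uniqueness_k Site k-mer length for the uniqueness filter
#'   (20 for PARE-length tags; use 50 for GMUCT-length tags).
#' @param nontarget_fc_window,other_fc_window Closed log2 FC windows defining
#'   the control sets.
#' @param expression_drop_log2fc,expression_fdr One-sided expression-check
#'   thresholds (drop if log2FC(double/xrn4) <= -0.58 AND FDR <= 0.05).
#' @param pseudocount CPM pseudocount of the comparison tracks (0.01).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_xrn4_cpm = 5, prefilter_min_cpm = 1,
                            min_log2fc_xrn4_vs_wt = 2,
                            min_log2fc_xrn4_vs_double = 2,
                            decap_min_cpm = 5, exclusion_window = 5L,
                            uniqueness_k = 20L,
                            nontarget_fc_window = c(-0.25, 0.25),
                            other_fc_window = c(-0.25, 0.25),
                            expression_drop_log2fc = -0.58,
                            expression_fdr = 0.05,
                            pseudocount = 0.01) {
  cfg <- list(min_xrn4_cpm = min_xrn4_cpm,
              prefilter_min_cpm = prefilter_min_cpm,
              min_log2fc_xrn4_vs_wt = min_log2fc_xrn4_vs_wt,
              min_log2fc_xrn4_vs_double = min_log2fc_xrn4_vs_double,
              decap_min_cpm = decap_min_cpm,
              exclusion_window = as.integer(exclusion_window),
              uniqueness_k = as.integer(uniqueness_k),
              nontarget_fc_window = nontarget_fc_window,
              other_fc_window = other_fc_window,
              expression_drop_log2fc = expression_drop_log2fc,
              expression_fdr = expression_fdr,
              pseudocount = pseudocount)
  nums <- unlist(cfg[c(1:7, 10:12)])
  if (any(!is.finite(nums))) stop("pipeline_config: non-finite threshold")
  if (diff(cfg$nontarget_fc_window) < 0 || diff(cfg$other_fc_window) < 0) {
    stop("pipeline_config: fold-change window not ordered")
  }
  structure(cfg, class = "pipeline_config")
}

drop_trace <- function(cands, reason) {
  if (nrow(cands) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), reason = character()))
  }
  cands[, .(chrom, strand, pos)][, reason := reason]
}

#' Remove low-abundance positions
#'
#' Keeps positions whose merged *xrn4* CPM is at least
#' `prefilter_min_cpm` (positions with *xrn4* CPM < 1 are removed).
#'
#' @param xrn4_track Merged normalized *xrn4* profile.
#' @param cfg A [pipeline_config()].
#' @return `data.table(chrom, strand, pos, xrn4_cpm)` of retained positions.
#' @export
prefilter_low_abundance <- function(xrn4_track, cfg = pipeline_config()) {
  out <- xrn4_track$values[value >= cfg$prefilter_min_cpm,
                           .(chrom, strand, pos, xrn4_cpm = value)]
  setkey(out, chrom, strand, pos)
  out
}

#' Build the decapping-site catalog
#'
#' Positions with Cap-PARE abundance >= `decap_min_cpm` are recorded as
#' experimentally supported decapping sites; the annotated TSS of every
#' transcript is always included. Positions are also mapped onto transcripts
#' (spliced coordinates) for proximity filtering.
#'
#' @param cap_pare Normalized Cap-PARE profile.
#' @param models Named list of `transcript_model`s (representative isoforms).
#' @param cfg A [pipeline_config()].
#' @return A `decap_catalog`: `positions` (chrom, strand, pos, source) and
#'   `by_transcript` (transcript_id, tpos, chrom, strand, pos).
#' @export
build_decap_catalog <- function(cap_pare, models, cfg = pipeline_config()) {
  decap <- cap_pare$values[value >= cfg$decap_min_cpm,
                           .(chrom, strand, pos)][, source := "cap_pare"]
  empty_pos <- data.table(chrom = character(), strand = character(),
                          pos = integer(), source = character())
  tss <- rbind(empty_pos, rbindlist(lapply(models, function(m) {
    data.table(chrom = m$chromosome, strand = m$strand, pos = m$tss,
               source = "tss")
  })))
  positions <- unique(rbind(decap, tss), by = c("chrom", "strand", "pos"))
  setkey(positions, chrom, strand, pos)
  mapped <- map_positions_to_transcripts(
    positions[, .(chrom, strand, pos)], models)
  empty_tx <- data.table(chrom = character(), strand = character(),
                         pos = integer(), transcript_id = character(),
                         tpos = integer())
  tss_by_tx <- rbind(empty_tx, rbindlist(lapply(models, function(m) {
    data.table(chrom = m$chromosome, strand = m$strand, pos = m$tss,
               transcript_id = m$transcript_id,
               tpos = genomic_to_transcript(m$tss, m))
  })))
  by_tx <- unique(rbind(mapped[, .(transcript_id, tpos, chrom, strand, pos)],
                        tss_by_tx[, .(transcript_id, tpos, chrom, strand, pos)]),
                  by = c("transcript_id", "tpos"))
  structure(list(positions = positions, by_transcript = by_tx,
                 decap_min_cpm = cfg$decap_min_cpm),
            class = "decap_catalog")
}

catalog_has <- function(catalog, .chrom, .strand, .pos) {
  nrow(catalog$positions[.(.chrom, .strand, .pos), nomatch = NULL]) > 0L
}

#' Call XRN4-sensitive positions
#'
#' Positions that overaccumulate in *xrn4* relative to wild type:
#' CPM >= `min_xrn4_cpm` AND log2 FC(*xrn4*/wild-type) >= 2.
#'
#' @param prefiltered Output of [prefilter_low_abundance()].
#' @param fc_xrn4_wt `comparison_track` of *xrn4* over wild type.
#' @param cfg A [pipeline_config()].
#' @return Candidate table with `xrn4_cpm` and `fc_xrn4_wt`; dropped
#'   candidates recorded in `attr(, "dropped")`.
#' @export
call_xrn4_sensitive <- function(prefiltered, fc_xrn4_wt,
                                cfg = pipeline_config()) {
  j <- merge(prefiltered, fc_xrn4_wt$values, by = c("chrom", "strand", "pos"),
             all.x = TRUE)
  setnames(j, "value", "fc_xrn4_wt")
  keep <- !is.na(j$fc_xrn4_wt) & j$xrn4_cpm >= cfg$min_xrn4_cpm &
    j$fc_xrn4_wt >= cfg$min_log2fc_xrn4_vs_wt
  out <- j[keep]
  attr(out, "dropped") <- drop_trace(j[!keep], "not-xrn4-sensitive")
  out
}

#' Call DNE1-dependent positions
#'
#' XRN4-sensitive candidates that additionally show
#' log2 FC(*xrn4* / *dne1 xrn4*) >= 2. Candidates absent from the
#' comparison track (0-vs-0 skipped) are rejected with trace
#' `no-signal-in-contrast`.
#'
#' @param candidates Output of [call_xrn4_sensitive()].
#' @param fc_xrn4_double `comparison_track` of *xrn4* over the double mutant.
#' @param cfg A [pipeline_config()].
#' @return Candidates with `fc_xrn4_double` added.
#' @export
call_dne1_dependent <- function(candidates, fc_xrn4_double,
                                cfg = pipeline_config()) {
  j <- merge(candidates, fc_xrn4_double$values,
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  setnames(j, "value", "fc_xrn4_double")
  missing <- is.na(j$fc_xrn4_double)
  fail <- !missing & j$fc_xrn4_double < cfg$min_log2fc_xrn4_vs_double
  out <- j[!missing & !fail]
  attr(out, "dropped") <- rbind(drop_trace(j[missing], "no-signal-in-contrast"),
                                drop_trace(j[fail], "not-dne1-dependent"))
  out
}

#' Attach transcripts to candidates
#'
#' Maps candidates onto representative transcript models; candidates not
#' exonic on any model are dropped with trace `unannotated`.
#'
#' @param candidates Candidate table.
#' @param models Named list of `transcript_model`s.
#' @return Candidates with `transcript_id` and spliced coordinate `tpos`.
#' @export
annotate_candidates <- function(candidates, models) {
  mapped <- map_positions_to_transcripts(
    candidates[, .(chrom, strand, pos)], models)
  out <- merge(candidates, mapped, by = c("chrom", "strand", "pos"))
  lost <- candidates[!mapped, on = c("chrom", "strand", "pos")]
  attr(out, "dropped") <- drop_trace(lost, "unannotated")
  out
}

#' Exclude candidates near decapping sites or the TSS
#'
#' Candidates within `exclusion_window` nt (inclusive, spliced distance on
#' the same transcript) of any catalogued decapping site or annotated TSS
#' are removed, so decapping is not misread as cleavage.
#'
#' @param candidates Annotated candidates.
#' @param catalog A `decap_catalog`.
#' @param cfg A [pipeline_config()].
#' @return Filtered candidates.
#' @export
filter_decap_proximity <- function(candidates, catalog,
                                   cfg = pipeline_config()) {
  if (nrow(candidates) == 0L || nrow(catalog$by_transcript) == 0L) {
    attr(candidates, "dropped") <- drop_trace(candidates[0L], "none")
    return(candidates)
  }
  near <- vapply(seq_len(nrow(candidates)), function(i) {
    d <- catalog$by_transcript[transcript_id == candidates$transcript_id[i],
                               tpos]
    length(d) > 0L && min(abs(d - candidates$tpos[i])) <= cfg$exclusion_window
  }, logical(1))
  out <- candidates[!near]
  attr(out, "dropped") <- drop_trace(candidates[near], "decap-proximity")
  out
}

#' Genome/transcriptome uniqueness filter
#'
#' The `uniqueness_k`-mer starting at the site (the 5' end of the surviving
#' 3' fragment, read in the mRNA sense direction) must occur exactly once in
#' the genome (both strands) and exactly once in the spliced transcriptome;
#' multi-mapping tags are removed. k-mers running off the transcript end are
#' removed with trace `edge`.
#'
#' @param candidates Annotated candidates.
#' @param genome `DNAStringSet`.
#' @param models Named list of `transcript_model`s.
#' @param cfg A [pipeline_config()].
#' @param txome Optional precomputed [spliced_sequences()] of `models`.
#' @return Filtered candidates.
#' @export
filter_uniqueness <- function(candidates, genome, models,
                              cfg = pipeline_config(), txome = NULL) {
  if (is.null(txome)) txome <- spliced_sequences(genome, models)
  k <- cfg$uniqueness_k
  txome_chr <- as.character(txome)
  status <- vapply(seq_len(nrow(candidates)), function(i) {
    tid <- candidates$transcript_id[i]
    s <- candidates$tpos[i]
    seq <- txome_chr[[tid]]
    if (s + k > nchar(seq)) return("edge")
    kmer <- Biostrings::DNAString(substr(seq, s + 1L, s + k))
    g <- sum(Biostrings::vcountPattern(kmer, genome))
    rc <- Biostrings::reverseComplement(kmer)
    if (as.character(rc) != as.character(kmer)) {
      g <- g + sum(Biostrings::vcountPattern(rc, genome))
    }
    t <- sum(Biostrings::vcountPattern(kmer, txome))
    if (g == 1L && t == 1L) "unique" else "multi-mapping"
  }, character(1))
  out <- candidates[status == "unique"]
  attr(out, "dropped") <- rbind(
    drop_trace(candidates[status == "edge"], "edge"),
    drop_trace(candidates[status == "multi-mapping"], "multi-mapping"))
  out
}

#' Full-length expression check
#'
#' Disqualifies candidates whose transcript shows a significant *drop* in
#' full-length abundance in the double mutant versus *xrn4*
#' (log2FC <= `expression_drop_log2fc` AND FDR <= `expression_fdr`), so a
#' reduced 5'P signal cannot be explained by reduced expression. One-sided
#' by design. A `NULL` table passes everything with a warning.
#'
#' @param candidates Annotated candidates.
#' @param rnaseq `data.frame` with columns `transcript_id`,
#'   `log2fc_double_vs_xrn4`, `fdr` (extra columns ignored), or `NULL`.
#' @param cfg A [pipeline_config()].
#' @return Filtered candidates.
#' @export
filter_expression <- function(candidates, rnaseq, cfg = pipeline_config()) {
  if (is.null(rnaseq)) {
    warning("no RNA-seq table supplied; expression filter skipped")
    attr(candidates, "dropped") <- drop_trace(candidates[0L], "none")
    return(candidates)
  }
  rnaseq <- as.data.table(rnaseq)
  need <- c("transcript_id", "log2fc_double_vs_xrn4", "fdr")
  if (!all(need %in% names(rnaseq))) {
    stop("RNA-seq table must have columns: ", paste(need, collapse = ", "))
  }
  j <- merge(candidates, rnaseq[, ..need], by = "transcript_id", all.x = TRUE)
  n_missing <- sum(is.na(j$log2fc_double_vs_xrn4))
  if (n_missing > 0L) {
    warning(n_missing, " candidate(s) on transcripts absent from the ",
            "RNA-seq table pass unfiltered")
  }
  bad <- !is.na(j$log2fc_double_vs_xrn4) &
    j$log2fc_double_vs_xrn4 <= cfg$expression_drop_log2fc &
    j$fdr <= cfg$expression_fdr
  out <- j[!bad][, c("log2fc_double_vs_xrn4", "fdr") := NULL]
  attr(out, "dropped") <- drop_trace(j[bad], "expression-drop")
  out
}

#' Classify surviving candidates as MaxSeq or Major internal
#'
#' Per transcript, only the most abundant (merged *xrn4* CPM) surviving
#' candidate is considered; it is labelled `MaxSeq` when it is the
#' transcript's most abundant 5'P position overall, `MajorInternal` when it
#' ranks second and the top position is a catalogued decapping site/TSS, and
#' is otherwise dropped as `unclassified`. Abundance ties break toward the
#' 5'-most spliced coordinate, so output is deterministic.
#'
#' @param candidates Surviving annotated candidates.
#' @param xrn4_track Merged normalized *xrn4* profile.
#' @param catalog A `decap_catalog`.
#' @param models Named list of `transcript_model`s.
#' @return Classified site table (adds `site_class`), one row max per
#'   transcript.
#' @export
classify_maxseq_major <- function(candidates, xrn4_track, catalog, models) {
  if (nrow(candidates) == 0L) {
    out <- copy(candidates)[, site_class := character(0)]
    attr(out, "dropped") <- drop_trace(candidates[0L], "none")
    return(out)
  }
  tx_ids <- unique(candidates$transcript_id)
  mapped <- map_positions_to_transcripts(
    xrn4_track$values[, .(chrom, strand, pos)], models[tx_ids])
  ranks <- merge(mapped,
                 xrn4_track$values[, .(chrom, strand, pos, cpm = value)],
                 by = c("chrom", "strand", "pos"))
  setorder(ranks, transcript_id, -cpm, tpos)
  ranks[, rank := seq_len(.N), by = transcript_id]
  # best candidate per transcript (highest xrn4 CPM, tie -> 5'-most)
  cand <- copy(candidates)
  setorder(cand, transcript_id, -xrn4_cpm, tpos)
  secondary <- cand[, .SD[-1L], by = transcript_id]
  best <- cand[, .SD[1L], by = transcript_id]
  cls <- vapply(seq_len(nrow(best)), function(i) {
    r <- ranks[transcript_id == best$transcript_id[i]]
    my <- r[tpos == best$tpos[i], rank]
    if (length(my) == 0L) return("unclassified")
    if (my == 1L) return("MaxSeq")
    if (my == 2L) {
      top <- r[rank == 1L]
      if (catalog_has(catalog, top$chrom, top$strand, top$pos)) {
        return("MajorInternal")
      }
    }
    "unclassified"
  }, character(1))
  best[, site_class := cls]
  out <- best[site_class != "unclassified"]
  attr(out, "dropped") <- rbind(
    drop_trace(secondary, "secondary-site"),
    drop_trace(best[site_class == "unclassified"], "unclassified"))
  setcolorder(out, c("chrom", "strand", "pos"))
  setorder(out, chrom, strand, pos)
  out
}

#' Define target / nontarget / other transcript sets
#'
#' Targets are transcripts with a classified cleavage site. Nontargets
#' contain an XRN4-sensitive 5'P site (CPM >= 5, log2 FC(xrn4/wt) >= 2)
#' whose *xrn4* vs double-mutant log2 FC sits in the no-change window
#' [-0.25, 0.25]. Others are XRN4-insensitive transcripts: they contain a
#' 5'P site with xrn4/wild-type log2 FC inside [-0.25, 0.25], and exclude
#' targets and nontargets. Priority: targets > nontargets > others.
#'
#' @param models Named list of `transcript_model`s.
#' @param xrn4_track Merged *xrn4* CPM profile.
#' @param fc_xrn4_wt,fc_xrn4_double Comparison tracks.
#' @param target_ids Character vector of target transcript ids.
#' @param cfg A [pipeline_config()].
#' @return A `target_sets` list: `targets`, `nontargets`, `others`
#'   (character vectors, pairwise disjoint) plus the windows used.
#' @export
define_control_sets <- function(models, xrn4_track, fc_xrn4_wt,
                                fc_xrn4_double, target_ids,
                                cfg = pipeline_config()) {
  pos <- xrn4_track$values[value >= cfg$prefilter_min_cpm,
                           .(chrom, strand, pos, xrn4_cpm = value)]
  mapped <- map_positions_to_transcripts(pos[, .(chrom, strand, pos)], models)
  j <- merge(mapped, pos, by = c("chrom", "strand", "pos"))
  j <- merge(j, fc_xrn4_wt$values[, .(chrom, strand, pos, fc_wt = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  j <- merge(j, fc_xrn4_double$values[, .(chrom, strand, pos, fc_dbl = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  nt_win <- cfg$nontarget_fc_window
  ot_win <- cfg$other_fc_window
  nontg <- j[xrn4_cpm >= cfg$min_xrn4_cpm &
               !is.na(fc_wt) & fc_wt >= cfg$min_log2fc_xrn4_vs_wt &
               !is.na(fc_dbl) & fc_dbl >= nt_win[1] & fc_dbl <= nt_win[2],
             unique(transcript_id)]
  oth <- j[!is.na(fc_wt) & fc_wt >= ot_win[1] & fc_wt <= ot_win[2],
           unique(transcript_id)]
  targets <- sort(unique(target_ids))
  nontargets <- sort(setdiff(nontg, targets))
  others <- sort(setdiff(oth, c(targets, nontargets)))
  structure(list(targets = targets, nontargets = nontargets, others = others,
                 nontarget_fc_window = nt_win, other_fc_window = ot_win),
            class = "target_sets")
}

#' @export
print.target_sets <- function(x, ...) {
  cat(sprintf("<target_sets> %d targets, %d nontargets, %d others\n",
              length(x$targets), length(x$nontargets), length(x$others)))
  invisible(x)
}

take <- function(filtered, trace_list, name) {
  dropped <- attr(filtered, "dropped")
  if (!is.null(dropped) && nrow(dropped)) {
    dropped[, filter := name]
    trace_list[[name]] <- dropped
  }
  list(cands = filtered, trace = trace_list)
}

#' Run the full cleavage-site calling cascade
#'
#' Orchestrates normalization, genotype comparison tracks, the filter
#' cascade and classification, and derives the control sets. `profiles` is
#' a list of raw or normalized `degradome_profile`s covering genotypes
#' `wild_type`, `xrn4` and `dne1_xrn4` (any number of replicates each) plus
#' optionally one `cap_pare` profile; without Cap-PARE the decapping catalog
#' contains annotated TSS only.
#'
#' @param profiles List of `degradome_profile`s.
#' @param models Named list of `transcript_model`s (collapsed to
#'   representative isoforms internally).
#' @param genome `DNAStringSet`.
#' @param rnaseq Optional RNA-seq differential-abundance table
#'   (see [filter_expression()]).
#' @param cfg A [pipeline_config()].
#' @return A `site_call_result`: `sites` (classified site table with region
#'   labels), `sets` (target/nontarget/other), `trace` (one row per dropped
#'   candidate with its filter), `counts` (survivors per stage), plus the
#'   merged tracks and catalog.
#' @export
call_sites <- function(profiles, models, genome, rnaseq = NULL,
                       cfg = pipeline_config()) {
  models <- collapse_isoforms(models)
  profiles <- lapply(profiles, function(p) {
    if (p$units != "count") return(p)
    if (p$total == 0) {
      # empty library: keep an empty CPM track so the cascade degrades to
      # an empty site table instead of failing
      return(new_profile(p$library_id, p$genotype, p$replicate,
                         p$values, units = "cpm", total = 0))
    }
    cpm_normalize(p)
  })
  geno <- vapply(profiles, `[[`, character(1), "genotype")
  need <- c("wild_type", "xrn4", "dne1_xrn4")
  if (!all(need %in% geno)) {
    stop("missing genotype(s): ", paste(setdiff(need, geno), collapse = ", "))
  }
  merged <- lapply(need, function(g) merge_replicates(profiles[geno == g]))
  names(merged) <- need
  cap <- if ("cap_pare" %in% geno) {
    merge_replicates(profiles[geno == "cap_pare"])
  } else NULL
  fc_wt <- log2_compare(merged$xrn4, merged$wild_type, cfg$pseudocount)
  fc_dbl <- log2_compare(merged$xrn4, merged$dne1_xrn4, cfg$pseudocount)
  catalog <- if (is.null(cap)) {
    build_decap_catalog(new_profile("empty", "cap_pare", 1L,
                                    data.table(chrom = character(),
                                               strand = character(),
                                               pos = integer(),
                                               value = numeric()),
                                    units = "cpm", total = 1),
                        models, cfg)
  } else build_decap_catalog(cap, models, cfg)
  txome <- spliced_sequences(genome, models)

  trace <- list()
  counts <- c(prefilter = NA_integer_)
  pre <- prefilter_low_abundance(merged$xrn4, cfg)
  counts["prefilter"] <- nrow(pre)
  st <- take(call_xrn4_sensitive(pre, fc_wt, cfg), trace, "xrn4_sensitive")
  counts["xrn4_sensitive"] <- nrow(st$cands)
  st <- take(call_dne1_dependent(st$cands, fc_dbl, cfg), st$trace,
             "dne1_dependent")
  counts["dne1_dependent"] <- nrow(st$cands)
  st <- take(annotate_candidates(st$cands, models), st$trace, "annotated")
  counts["annotated"] <- nrow(st$cands)
  st <- take(filter_decap_proximity(st$cands, catalog, cfg), st$trace,
             "decap_proximity")
  counts["decap_proximity"] <- nrow(st$cands)
  st <- take(filter_uniqueness(st$cands, genome, models, cfg, txome),
             st$trace, "uniqueness")
  counts["uniqueness"] <- nrow(st$cands)
  st <- take(filter_expression(st$cands, rnaseq, cfg), st$trace, "expression")
  counts["expression"] <- nrow(st$cands)
  st <- take(classify_maxseq_major(st$cands, merged$xrn4, catalog, models),
             st$trace, "classification")
  counts["classified"] <- nrow(st$cands)
  sites <- st$cands
  if (nrow(sites)) {
    sites[, region := vapply(seq_len(.N), function(i) {
      assign_region(pos[i], models[[transcript_id[i]]])
    }, character(1))]
    sites[, wt_cpm := lookup_cpm(merged$wild_type, sites)]
    sites[, double_cpm := lookup_cpm(merged$dne1_xrn4, sites)]
    setcolorder(sites, c("chrom", "strand", "pos", "transcript_id", "tpos",
                         "site_class", "region", "xrn4_cpm", "wt_cpm",
                         "double_cpm", "fc_xrn4_wt", "fc_xrn4_double"))
  } else {
    sites <- data.table(chrom = character(), strand = character(),
                        pos = integer(), transcript_id = character(),
                        tpos = integer(), site_class = character(),
                        region = character(), xrn4_cpm = numeric(),
                        wt_cpm = numeric(), double_cpm = numeric(),
                        fc_xrn4_wt = numeric(), fc_xrn4_double = numeric())
  }
  sets <- define_control_sets(models, merged$xrn4, fc_wt, fc_dbl,
                              sites$transcript_id, cfg)
  trace_dt <- if (length(st$trace)) rbindlist(st$trace) else {
    data.table(chrom = character(), strand = character(), pos = integer(),
               reason = character(), filter = character())
  }
  structure(list(sites = sites, sets = sets, trace = trace_dt,
                 counts = counts, merged = merged, cap_pare = cap,
                 fc_xrn4_wt = fc_wt, fc_xrn4_double = fc_dbl,
                 catalog = catalog, config = cfg, models = models),
            class = "site_call_result")
}

lookup_cpm <- function(track, sites) {
  m <- merge(sites[, .(chrom, strand, pos)],
             track$values, by = c("chrom", "strand", "pos"), all.x = TRUE,
             sort = FALSE)
  ifelse(is.na(m$value), 0, m$value)
}

#' @export
print.site_call_result <- function(x, ...) {
  cat("<site_call_result>\n  survivors per stage:\n")
  for (n in names(x$counts)) cat(sprintf("    %-16s %d\n", n, x$counts[[n]]))
  cat(sprintf("  classified: %d MaxSeq, %d MajorInternal\n",
              sum(x$sites$site_class == "MaxSeq"),
              sum(x$sites$site_class == "MajorInternal")))
  print(x$sets)
  invisible(x)
}
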