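# Site-feature analytics: region assignment, metagene and exon-junction
# profiles, sequence windows, degenerate-motif scanning, k-mer differential
# enrichment, set-overlap tests, half-life and decapping-abundance shifts.

#' Assign a genomic site to a transcript region
#'
#' Exonic positions of coding transcripts partition into 5'UTR / CDS /
#' 3'UTR (strand-aware, in spliced coordinates); intronic positions are
#' `intron`; exonic positions of non-coding models are `noncoding-exon`.
#'
#' @param pos Genomic position (0-based) on the transcript's chromosome.
#' @param tx A `transcript_model`.
#' @return One of `"5UTR"`, `"CDS"`, `"3UTR"`, `"intron"`,
#'   `"noncoding-exon"`.
#' @export
assign_region <- function(pos, tx) {
  s <- genomic_to_transcript(pos, tx)
  if (is.na(s)) return("intron")
  if (is.null(tx$cds_span)) return("noncoding-exon")
  cds <- cds_transcript_span(tx)
  if (s < cds[1L]) "5UTR" else if (s >= cds[2L]) "3UTR" else "CDS"
}

#' Metagene profile of sites over 5'UTR / CDS / 3'UTR
#'
#' Each region of each transcript is divided into 100 bins spanning 1% of
#' its length; every non-intronic site of a coding transcript increments
#' one bin of its region (bin = floor(100 * relative position), clamped to
#' 99). Intronic/non-coding sites and sites on transcripts lacking the
#' region are skipped with a warning.
#'
#' @param sites `data.table` with `pos` and `transcript_id`.
#' @param models Named list of `transcript_model`s.
#' @return A `metagene_profile`: list of three 100-bin count vectors
#'   (`utr5`, `cds`, `utr3`) and `n_sites_assigned`.
#' @export
metagene_profile <- function(sites, models) {
  bins <- list(utr5 = integer(100L), cds = integer(100L),
               utr3 = integer(100L))
  n <- 0L
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    tx <- models[[sites$transcript_id[i]]]
    if (is.null(tx) || is.null(tx$cds_span)) { skipped <- skipped + 1L; next }
    s <- genomic_to_transcript(sites$pos[i], tx)
    if (is.na(s)) { skipped <- skipped + 1L; next }
    cds <- cds_transcript_span(tx)
    reg_bounds <- if (s < cds[1L]) c(0L, cds[1L])
      else if (s >= cds[2L]) c(cds[2L], tx$length)
      else cds
    reg <- if (s < cds[1L]) "utr5" else if (s >= cds[2L]) "utr3" else "cds"
    len <- reg_bounds[2L] - reg_bounds[1L]
    if (len <= 0L) { skipped <- skipped + 1L; next }
    b <- min(floor(100 * (s - reg_bounds[1L]) / len), 99)
    bins[[reg]][b + 1L] <- bins[[reg]][b + 1L] + 1L
    n <- n + 1L
  }
  if (skipped > 0L) {
    warning(skipped, " site(s) skipped (intronic, non-coding or unknown ",
            "transcript)")
  }
  structure(list(bins = bins, n_sites_assigned = n),
            class = "metagene_profile")
}

#' Distance-to-junction profile (50 nt upstream window)
#'
#' For sites in the CDS of nuclear protein-coding transcripts that do not
#' coincide with a catalogued decapping position, computes the spliced
#' distance to the nearest downstream exon-exon junction; a site on the last
#' base of the upstream exon has distance 1. Distances 1..50 are binned;
#' larger distances or sites with no downstream junction are excluded.
#'
#' @param sites `data.table` with `chrom`, `strand`, `pos`,
#'   `transcript_id`.
#' @param models Named list of `transcript_model`s.
#' @param catalog Optional `decap_catalog` used to exclude decapping
#'   positions.
#' @return A `junction_profile`: `distances` (relative frequencies over
#'   1..50, summing to 1 when any site falls in the window),
#'   `counts`, and `n_sites_in_window`.
#' @export
junction_distance_profile <- function(sites, models, catalog = NULL) {
  counts <- integer(50L)
  for (i in seq_len(nrow(sites))) {
    tx <- models[[sites$transcript_id[i]]]
    if (is.null(tx) || !tx$is_protein_coding || !tx$is_nuclear) next
    if (!is.null(catalog) &&
        catalog_has(catalog, sites$chrom[i], sites$strand[i], sites$pos[i])) next
    s <- genomic_to_transcript(sites$pos[i], tx)
    if (is.na(s)) next
    cds <- cds_transcript_span(tx)
    if (s < cds[1L] || s >= cds[2L]) next
    jn <- exon_junctions(tx)$transcript_coordinate
    jn <- jn[jn >= s]
    if (length(jn) == 0L) next
    d <- min(jn) - s + 1L
    if (d >= 1L && d <= 50L) counts[d] <- counts[d] + 1L
  }
  n <- sum(counts)
  structure(list(distances = if (n > 0L) counts / n else numeric(50L),
                 counts = counts, n_sites_in_window = n),
            class = "junction_profile")
}

#' Motif specification
#'
#' @param iupac_pattern IUPAC pattern (RNA or DNA; U is mapped to T). The
#'   default `YGGWG` is the degenerate G-rich pentamer (Y = C/T, W = A/T)
#'   found adjacent to cleavage sites.
#' @param window_halfwidth Half-width of the extracted sequence window
#'   (default 20 nt, i.e. 40-nt windows).
#' @param coarse_bin Coarse histogram bin (5 nt).
#' @param inset_halfwidth Inset half-width around the site (5 nt).
#' @return A `motif_spec` list.
#' @export
motif_spec <- function(iupac_pattern = "YGGWG", window_halfwidth = 20L,
                       coarse_bin = 5L, inset_halfwidth = 5L) {
  pat <- toupper(gsub("U", "T", iupac_pattern))
  ok <- strsplit(pat, "")[[1]] %in%
    c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  if (nchar(pat) == 0L || !all(ok)) {
    stop("invalid IUPAC pattern: ", iupac_pattern)
  }
  structure(list(iupac_pattern = pat,
                 window_halfwidth = as.integer(window_halfwidth),
                 coarse_bin = as.integer(coarse_bin),
                 inset_halfwidth = as.integer(inset_halfwidth)),
            class = "motif_spec")
}

#' Extract sense-strand sequence windows around sites
#'
#' Windows are taken in spliced-transcript space (mRNA sense strand): each
#' window has length `2 * window_halfwidth`, with the 5'P site base at
#' 0-based index `window_halfwidth`. Windows truncated by transcript ends
#' are dropped and counted.
#'
#' @param sites `data.table` with `pos` and `transcript_id`.
#' @param genome `DNAStringSet`.
#' @param models Named list of `transcript_model`s.
#' @param spec A [motif_spec()].
#' @param txome Optional precomputed [spliced_sequences()].
#' @return Named `DNAStringSet` of windows; dropped-site count in
#'   `attr(, "n_dropped")`.
#' @export
extract_window_sequences <- function(sites, genome, models,
                                     spec = motif_spec(), txome = NULL) {
  if (is.null(txome)) {
    txome <- spliced_sequences(genome, models[unique(sites$transcript_id)])
  }
  txc <- as.character(txome)
  hw <- spec$window_halfwidth
  out <- character(0)
  nm <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    tid <- sites$transcript_id[i]
    tx <- models[[tid]]
    s <- genomic_to_transcript(sites$pos[i], tx)
    if (is.na(s) || s - hw < 0L || s + hw > tx$length) {
      dropped <- dropped + 1L
      next
    }
    out <- c(out, substr(txc[[tid]], s - hw + 1L, s + hw))
    nm <- c(nm, sprintf("%s:%d", tid, sites$pos[i]))
  }
  if (dropped > 0L) {
    warning(dropped, " site(s) too close to a transcript end; window dropped")
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- nm
  attr(res, "n_dropped") <- dropped
  res
}

#' Scan sequences for a degenerate IUPAC motif
#'
#' Returns all (possibly overlapping) 0-based start offsets of the pattern
#' in each sequence.
#'
#' @param seqs `DNAStringSet` or character vector (U mapped to T).
#' @param spec A [motif_spec()].
#' @return List of integer vectors, one per sequence.
#' @export
scan_motif <- function(seqs, spec = motif_spec()) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(gsub("U", "T", seqs)))
  }
  hits <- Biostrings::vmatchPattern(spec$iupac_pattern, seqs, fixed = FALSE)
  lapply(seq_along(hits), function(i) Biostrings::startIndex(hits)[[i]] - 1L)
}

#' Positional distribution of motif hits around the 5'P site
#'
#' Offsets are re-expressed relative to the site base (offset 0 = motif
#' starting at the 5'P site; negative = 5' of it). The coarse histogram
#' uses `coarse_bin`-nt bins over the whole window; the inset histogram
#' uses 1-nt bins over +/- `inset_halfwidth` nt; `inset_fraction` is the
#' fraction of sequences with at least one hit starting in the inset.
#'
#' @param hits Output of [scan_motif()] on windows from
#'   [extract_window_sequences()].
#' @param spec The same [motif_spec()].
#' @return List with `coarse` (named counts), `inset` (named counts),
#'   `inset_fraction`, `n_hits`, `n_sequences`.
#' @export
motif_positional_distribution <- function(hits, spec = motif_spec()) {
  hw <- spec$window_halfwidth
  rel <- lapply(hits, function(h) h - hw)
  all_rel <- unlist(rel)
  edges <- seq(-hw, hw, by = spec$coarse_bin)
  coarse <- integer(length(edges) - 1L)
  names(coarse) <- sprintf("[%d,%d)", edges[-length(edges)], edges[-1L])
  if (length(all_rel)) {
    idx <- findInterval(all_rel, edges, rightmost.closed = FALSE)
    idx <- idx[idx >= 1L & idx <= length(coarse)]
    tab <- tabulate(idx, nbins = length(coarse))
    coarse <- coarse + tab
    names(coarse) <- sprintf("[%d,%d)", edges[-length(edges)], edges[-1L])
  }
  iw <- spec$inset_halfwidth
  inset_range <- (-iw):iw
  inset <- integer(length(inset_range))
  names(inset) <- as.character(inset_range)
  in_inset_seq <- vapply(rel, function(r) any(r >= -iw & r <= iw), logical(1))
  for (r in all_rel) {
    if (r >= -iw && r <= iw) {
      k <- which(inset_range == r)
      inset[k] <- inset[k] + 1L
    }
  }
  list(coarse = coarse, inset = inset,
       inset_fraction = if (length(hits)) mean(in_inset_seq) else 0,
       n_hits = length(all_rel), n_sequences = length(hits))
}

#' Exhaustive k-mer differential enrichment
#'
#' Enumerates all k-mers (k in `k_min..k_max`) present in either sequence
#' set, scores per-sequence presence/absence, and tests target enrichment
#' with an upper-tail hypergeometric: among the N = |targets| + |controls|
#' sequences, K contain the k-mer; the probability of drawing >= x of them
#' in |targets| draws. BH adjustment is applied jointly across all tested
#' k-mers of all lengths. This replaces motif-discovery EM with an exact,
#' exhaustive scan.
#'
#' @param target_seqs,control_seqs `DNAStringSet`s or character vectors.
#' @param k_min,k_max k-mer length range (default 5..7).
#' @return `data.table(kmer, k, target_count, control_count, p, q)` ordered
#'   by increasing p.
#' @export
kmer_differential_enrichment <- function(target_seqs, control_seqs,
                                         k_min = 5L, k_max = 7L) {
  as_chr <- function(x) {
    if (is.character(x)) toupper(gsub("U", "T", x)) else as.character(x)
  }
  tg <- as_chr(target_seqs)
  ct <- as_chr(control_seqs)
  if (length(tg) == 0L || length(ct) == 0L) {
    stop("both sequence sets must be non-empty")
  }
  if (k_max > min(nchar(c(tg, ct)))) {
    stop("k_max exceeds the shortest sequence length")
  }
  present_kmers <- function(s, k) {
    n <- nchar(s)
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  rows <- list()
  for (k in k_min:k_max) {
    tg_sets <- lapply(tg, present_kmers, k = k)
    ct_sets <- lapply(ct, present_kmers, k = k)
    kmers <- unique(c(unlist(tg_sets), unlist(ct_sets)))
    tcount <- vapply(kmers, function(km)
      sum(vapply(tg_sets, function(s) km %in% s, logical(1))), integer(1))
    ccount <- vapply(kmers, function(km)
      sum(vapply(ct_sets, function(s) km %in% s, logical(1))), integer(1))
    rows[[as.character(k)]] <- data.table(kmer = kmers, k = k,
                                          target_count = tcount,
                                          control_count = ccount)
  }
  res <- rbindlist(rows)
  N <- length(tg) + length(ct)
  res[, p := phyper(target_count - 1L, target_count + control_count,
                    N - (target_count + control_count), length(tg),
                    lower.tail = FALSE)]
  res[, q := p.adjust(p, method = "BH")]
  setorder(res, p, -target_count, kmer)
  res[]
}

#' Collapse concrete k-mers into a degenerate IUPAC pattern count
#'
#' Report helper: counts how many rows of an enrichment table match a
#' degenerate pattern (e.g. all four YGGWG expansions).
#'
#' @param enrichment Output of [kmer_differential_enrichment()].
#' @param pattern IUPAC pattern.
#' @return Subset of rows whose k-mer matches the pattern exactly.
#' @export
collapse_degenerate <- function(enrichment, pattern = "YGGWG") {
  spec <- motif_spec(pattern)
  hit <- vapply(enrichment$kmer, function(km) {
    nchar(km) == nchar(spec$iupac_pattern) &&
      length(scan_motif(km, spec)[[1]]) > 0L
  }, logical(1))
  enrichment[hit]
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Gene-set overlap: hypergeometric, Fisher and Monte Carlo permutation
#'
#' The permutation test replaces a Monte Carlo gene-set tool: it draws
#' `n_permutations` random subsets of `universe` of size `|set_a|`, counts
#' overlaps with `set_b` at least as large as observed, and reports
#' p = (1 + hits) / (1 + n_permutations).
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible ids.
#' @param n_permutations Number of Monte Carlo draws (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @return List with `overlap`, `p_hypergeometric`, `odds_ratio`,
#'   `p_fisher`, `p_permutation`, and the set sizes.
#' @export
set_overlap_test <- function(set_a, set_b, universe,
                             n_permutations = 10000L, seed = 1L) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of the universe")
  }
  obs <- length(intersect(set_a, set_b))
  N <- length(universe)
  p_hyper <- phyper(obs - 1L, length(set_b), N - length(set_b),
                    length(set_a), lower.tail = FALSE)
  tab <- matrix(c(obs, length(set_a) - obs, length(set_b) - obs,
                  N - length(set_a) - length(set_b) + obs), nrow = 2L)
  ft <- fisher.test(tab)
  hits <- with_local_seed(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      length(intersect(sample(universe, length(set_a)), set_b)) >= obs
    }, logical(1)))
  })
  list(overlap = obs, n_a = length(set_a), n_b = length(set_b),
       n_universe = N, p_hypergeometric = p_hyper,
       odds_ratio = unname(ft$estimate), p_fisher = ft$p.value,
       p_permutation = (1 + hits) / (1 + n_permutations))
}

# exact two-sided rank-sum p by full enumeration of group assignments
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  if (n > 16L) stop("exact rank-sum enumeration limited to n <= 16")
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  stats <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(stats - ew) >= abs(obs - ew) - 1e-9)
}

#' Compare half-lives between transcript groups
#'
#' Joins both groups against a half-life table, reports group medians, the
#' fraction of short-lived transcripts (t1/2 <= `short_cutoff` minutes) per
#' group, and a two-sided Wilcoxon rank-sum p-value (`method = "exact"`
#' enumerates all group assignments, feasible for n <= 16 total).
#'
#' @param targets,nontargets Character vectors of transcript ids.
#' @param halflife Named numeric vector or `data.frame(transcript_id, t_half)`
#'   of half-lives in minutes (must be positive).
#' @param short_cutoff Minutes defining "short-lived" (default 60).
#' @param method `"asymptotic"` (stats::wilcox.test with ties) or `"exact"`.
#' @return List with per-group `n`, `median`, `short_fraction`, and `p`.
#' @export
halflife_group_compare <- function(targets, nontargets, halflife,
                                   short_cutoff = 60, method = "asymptotic") {
  if (is.data.frame(halflife)) {
    hl <- stats::setNames(halflife$t_half, halflife$transcript_id)
  } else hl <- halflife
  if (any(hl <= 0, na.rm = TRUE)) stop("half-lives must be positive")
  x <- unname(hl[intersect(targets, names(hl))])
  y <- unname(hl[intersect(nontargets, names(hl))])
  if (length(x) < 3L || length(y) < 3L) {
    stop("need at least 3 half-life values per group")
  }
  p <- if (method == "exact") exact_ranksum_p(x, y) else {
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
  }
  list(n = c(targets = length(x), nontargets = length(y)),
       median = c(targets = median(x), nontargets = median(y)),
       short_fraction = c(targets = mean(x <= short_cutoff),
                          nontargets = mean(y <= short_cutoff)),
       p = p)
}

#' Decapping-site abundance shift between mutant genotypes
#'
#' Considers catalogued decapping positions with abundance >= `min_cpm` in
#' both *xrn4* and the double mutant and xrn4/wild-type log2 FC >= `min_fc`.
#' At those positions, the distributions of log2(genotype/wild-type) are
#' returned for both mutant genotypes, split into target vs rest transcript
#' groups, with a two-sided Wilcoxon p comparing the two genotypes within
#' each group and the median shift (double - xrn4).
#'
#' @param catalog A `decap_catalog`.
#' @param fc_xrn4_wt,fc_double_wt Comparison tracks vs wild type.
#' @param xrn4_track,double_track Merged CPM profiles.
#' @param target_ids Character vector of target transcript ids.
#' @param min_cpm Abundance floor at the decapping site (default 5 CPM).
#' @param min_fc Minimum xrn4/wild-type log2 FC (default 1).
#' @return List of per-group results (`targets`, `rest`): the two FC
#'   vectors, `median_shift`, and `p`.
#' @export
decap_abundance_shift <- function(catalog, fc_xrn4_wt, fc_double_wt,
                                  xrn4_track, double_track, target_ids,
                                  min_cpm = 5, min_fc = 1) {
  pos <- copy(catalog$by_transcript)
  j <- merge(pos, xrn4_track$values[, .(chrom, strand, pos, xrn4_cpm = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  j <- merge(j, double_track$values[, .(chrom, strand, pos, dbl_cpm = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  j <- merge(j, fc_xrn4_wt$values[, .(chrom, strand, pos, fc_x = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  j <- merge(j, fc_double_wt$values[, .(chrom, strand, pos, fc_d = value)],
             by = c("chrom", "strand", "pos"), all.x = TRUE)
  j <- j[!is.na(xrn4_cpm) & !is.na(dbl_cpm) &
           xrn4_cpm >= min_cpm & dbl_cpm >= min_cpm &
           !is.na(fc_x) & fc_x >= min_fc]
  one_group <- function(sub) {
    if (nrow(sub) == 0L) {
      return(list(fc_xrn4_wt = numeric(0), fc_double_wt = numeric(0),
                  median_shift = NA_real_, p = NA_real_))
    }
    list(fc_xrn4_wt = sub$fc_x, fc_double_wt = sub$fc_d,
         median_shift = median(sub$fc_d) - median(sub$fc_x),
         p = if (nrow(sub) >= 3L) {
           suppressWarnings(wilcox.test(sub$fc_x, sub$fc_d)$p.value)
         } else NA_real_)
  }
  list(targets = one_group(j[transcript_id %in% target_ids]),
       rest = one_group(j[!transcript_id %in% target_ids]),
       n_eligible = nrow(j))
}
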