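# Seeded synthetic degradome generator with planted ground truth.
#
# The stated world: three genotypes (wild type, xrn4 exonuclease-null,
# dne1 xrn4 double mutant) x replicates of 5'-end count tracks over a
# synthetic multi-exon transcriptome. Decapping intermediates accumulate at
# transcript 5' ends in both exonuclease-null genotypes; internal cleavage
# intermediates accumulate only when the endoribonuclease is present (xrn4
# single mutant); a degenerate YGGWG motif is planted adjacent to cleavage
# sites. Per-transcript 5'P mass is conserved across genotypes, so
# full-length abundances show no systematic genotype difference.

#' Simulation configuration
#'
#' Defaults encode the standard validation scenario: 200 transcripts, 30%
#' endoribonuclease targets, 2 x 10^6 tags per library, 2 replicates per
#' genotype, cleavage effect log2 = 3. Spike sizes are parameterized as
#' fractions of a transcript's 5'P mass (cleavage 0.28; decapping 0.25
#' with +/-40% per-transcript jitter in *xrn4*), which with the default
#' abundance distribution keeps every planted spike far above 20 CPM while
#' the diffuse background stays near 1-3 CPM per position, as in sparse
#' real degradome tracks.
#'
#' @param n_transcripts Number of simulated transcripts (200).
#' @param class_fractions Named fractions (`dne1_target`, `decap_only`,
#'   `xrn4_insensitive`) summing to <= 1; the remainder goes to
#'   `xrn4_insensitive`.
#' @param depth Tags per library (2e6).
#' @param replicates Replicates per genotype (2).
#' @param n_chromosomes Chromosomes to spread transcripts over (4).
#' @param utr5_range,cds_range,utr3_range Region length ranges (nt).
#' @param exon_count_range,intron_range Exon count and intron length ranges.
#' @param bg_dispersion Negative-binomial size of marginal background
#'   counts, realized as the shape of a per-position gamma cleavability
#'   weight shared across genotypes and replicates (1 = strongly
#'   hotspot-structured, as in real degradome tracks).
#' @param cleavage_effect log2 overaccumulation of the cleavage intermediate
#'   in *xrn4* vs wild type and vs the double mutant (3).
#' @param decap_effect log2 overaccumulation of the decapping intermediate
#'   in exonuclease-null genotypes vs wild type (3).
#' @param decap_redistribution Multiplier (>= 1) on the double mutant's
#'   decapping spike, reflecting flux redistribution into decapping when
#'   the endoribonuclease is absent (1.5).
#' @param cleavage_fraction,decap_fraction Fractions of a transcript's 5'P
#'   mass carried by the spikes in *xrn4*.
#' @param abundance_sdlog,abundance_clamp Transcript abundance lognormal
#'   spread and clamp (relative to the mean).
#' @param libsize_cv Lognormal sdlog of per-library size factors (0.05).
#' @param motif_rate Probability a target carries a planted YGGWG (0.9).
#' @param motif_offsets Integer offsets (relative to the cleavage site, 0 =
#'   motif starting on the site base) sampled for planted motifs.
#' @param ejc_protection Optional multiplier (> 1 activates) on background
#'   25-30 nt upstream of junctions, mimicking exon-junction-complex
#'   protection; 1 = off.
#' @param halflife Logical: also draw a half-life table (targets short-lived,
#'   median 45 min; rest median 120 min).
#' @param seed Mandatory RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_transcripts = 200L,
                              class_fractions = c(dne1_target = 0.3,
                                                  decap_only = 0.3,
                                                  xrn4_insensitive = 0.4),
                              depth = 2e6, replicates = 2L,
                              n_chromosomes = 4L,
                              utr5_range = c(50L, 150L),
                              cds_range = c(300L, 900L),
                              utr3_range = c(100L, 250L),
                              exon_count_range = c(2L, 5L),
                              intron_range = c(60L, 200L),
                              bg_dispersion = 1,
                              cleavage_effect = 3,
                              decap_effect = 3,
                              decap_redistribution = 1.5,
                              cleavage_fraction = 0.28,
                              decap_fraction = 0.25,
                              abundance_sdlog = 0.6,
                              abundance_clamp = c(0.25, 4),
                              libsize_cv = 0.05,
                              motif_rate = 0.9,
                              motif_offsets = 0L,
                              ejc_protection = 1,
                              halflife = FALSE,
                              seed = NULL) {
  if (is.null(seed)) stop("simulation_config: 'seed' is mandatory")
  if (sum(class_fractions) > 1 + 1e-9) {
    stop("class fractions must sum to <= 1")
  }
  if (depth <= 0) stop("depth must be positive")
  if (decap_redistribution < 1) stop("decap_redistribution must be >= 1")
  structure(as.list(environment()), class = "simulation_config")
}

iupac_expand <- function(pattern) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  lapply(strsplit(toupper(gsub("U", "T", pattern)), "")[[1]],
         function(ch) codes[[ch]])
}

random_motif_instance <- function(pattern = "YGGWG") {
  vapply(iupac_expand(pattern), function(opts) {
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# write sense-strand bases at spliced coords of a model into the genome
# (character-vector form)
write_sense_bases <- function(chrs, tx, tpos, bases) {
  g <- transcript_to_genomic(tpos, tx)
  if (tx$strand == "-") bases <- unname(COMPLEMENT[bases])
  s <- chrs[[tx$chromosome]]
  for (i in seq_along(g)) substr(s, g[i] + 1L, g[i] + 1L) <- bases[i]
  chrs[[tx$chromosome]] <- s
  chrs
}

#' Simulate genome, annotation and planted site structure
#'
#' Lays random multi-exon coding transcripts on synthetic chromosomes over
#' an i.i.d. nucleotide background, assigns class labels, plants decapping
#' positions at/near each TSS and, for target-class transcripts, a cleavage
#' position in the CDS (its 20-mer made genome-unique by bounded redraws)
#' with a YGGWG motif written at the configured offset.
#'
#' @param cfg A [simulation_config()].
#' @return A `degradome_simulation` (structure part): `genome`
#'   (`DNAStringSet`), `models`, `truth` table, `config`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  n_targets <- round(cfg$class_fractions[["dne1_target"]] * n)
  n_decap <- round(cfg$class_fractions[["decap_only"]] * n)
  classes <- sample(c(rep("dne1_target", n_targets),
                      rep("decap_only", n_decap),
                      rep("xrn4_insensitive", n - n_targets - n_decap)))
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %% cfg$n_chromosomes + 1L)
  offsets <- stats::setNames(rep(0L, cfg$n_chromosomes),
                             paste0("chr", seq_len(cfg$n_chromosomes)))
  models <- list()
  truth_rows <- list()
  min_exon <- 40L
  k <- 20L
  for (i in seq_len(n)) {
    u5 <- sample(cfg$utr5_range[1]:cfg$utr5_range[2], 1L)
    cd <- sample(cfg$cds_range[1]:cfg$cds_range[2], 1L)
    u3 <- sample(cfg$utr3_range[1]:cfg$utr3_range[2], 1L)
    L <- u5 + cd + u3
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1L)
    n_ex <- min(n_ex, L %/% (2L * min_exon))
    n_ex <- max(n_ex, 1L)
    # exon widths: random composition of L with minimum exon size
    if (n_ex > 1L) {
      cuts <- sort(sample(seq(min_exon, L - min_exon),
                          n_ex - 1L, replace = FALSE))
      while (any(diff(c(0L, cuts, L)) < min_exon)) {
        cuts <- sort(sample(seq(min_exon, L - min_exon), n_ex - 1L))
      }
      widths <- diff(c(0L, cuts, L))
    } else widths <- L
    introns <- if (n_ex > 1L) {
      sample(cfg$intron_range[1]:cfg$intron_range[2], n_ex - 1L,
             replace = TRUE)
    } else integer(0)
    strand <- sample(c("+", "-"), 1L)
    chrom <- chrom_of[i]
    gap <- sample(100:300, 1L)
    start <- offsets[[chrom]] + gap
    ex_starts <- start + c(0L, cumsum(widths[-n_ex] + introns))
    ex_ends <- ex_starts + widths
    offsets[[chrom]] <- ex_ends[n_ex]
    tid <- sprintf("SYN%04d", i)
    m <- new_transcript_model(tid, sprintf("G%04d", i), chrom, strand,
                              cbind(ex_starts, ex_ends))
    # CDS occupies spliced [u5, u5 + cd)
    cds_g <- range(transcript_to_genomic(c(u5, u5 + cd - 1L), m))
    m <- new_transcript_model(tid, sprintf("G%04d", i), chrom, strand,
                              cbind(ex_starts, ex_ends),
                              cds_span = c(cds_g[1L], cds_g[2L] + 1L))
    models[[tid]] <- m
    decap_tpos <- sample(0:2, 1L)
    cleav_tpos <- NA_integer_
    motif_off <- NA_integer_
    if (classes[i] == "dne1_target") {
      # candidate spliced positions: in the CDS, with the whole k-mer inside
      # one exon (so the tag maps contiguously) and a full +/-20 nt window
      cum <- cumsum(c(0L, if (strand == "-") rev(widths) else widths))
      cand <- integer(0)
      for (e in seq_len(n_ex)) {
        lo <- max(cum[e], u5, k)
        hi <- min(cum[e + 1L] - k, u5 + cd - 1L)
        if (hi >= lo) cand <- c(cand, lo:hi)
      }
      if (length(cand) == 0L) stop("no eligible cleavage position for ", tid)
      cleav_tpos <- sample(cand, 1L)
      if (runif(1) < cfg$motif_rate) {
        motif_off <- if (length(cfg$motif_offsets) == 1L) {
          as.integer(cfg$motif_offsets)
        } else sample(as.integer(cfg$motif_offsets), 1L)
      }
    }
    truth_rows[[tid]] <- data.table(
      transcript_id = tid, class = classes[i], chrom = chrom,
      strand = strand, length = L,
      decap_tpos = decap_tpos, cleavage_tpos = cleav_tpos,
      motif_offset = motif_off)
  }
  chr_lens <- offsets + 200L
  chrs <- lapply(names(chr_lens), function(cn) {
    paste0(sample(c("A", "C", "G", "T"), chr_lens[[cn]], replace = TRUE),
           collapse = "")
  })
  names(chrs) <- names(chr_lens)
  truth <- rbindlist(truth_rows)
  # plant motifs, then enforce genome-uniqueness of each cleavage 20-mer
  for (r in which(truth$class == "dne1_target")) {
    tx <- models[[truth$transcript_id[r]]]
    s <- truth$cleavage_tpos[r]
    o <- truth$motif_offset[r]
    motif_rng <- if (!is.na(o)) (s + o):(s + o + 4L) else integer(0)
    if (length(motif_rng)) {
      chrs <- write_sense_bases(chrs, tx, motif_rng, random_motif_instance())
    }
    free <- setdiff(s:(s + k - 1L), motif_rng)
    for (try in seq_len(50L)) {
      genome <- Biostrings::DNAStringSet(unlist(chrs))
      kmer_chr <- substr(spliced_sequences(genome, models[truth$transcript_id[r]])[[1L]] |>
                           as.character(), s + 1L, s + k)
      kmer <- Biostrings::DNAString(kmer_chr)
      cnt <- sum(Biostrings::vcountPattern(kmer, genome)) +
        sum(Biostrings::vcountPattern(Biostrings::reverseComplement(kmer),
                                      genome))
      if (cnt == 1L) break
      if (try == 50L) stop("could not make cleavage k-mer unique for ",
                           truth$transcript_id[r])
      chrs <- write_sense_bases(chrs, tx, free,
                                sample(c("A", "C", "G", "T"), length(free),
                                       replace = TRUE))
    }
  }
  genome <- Biostrings::DNAStringSet(unlist(chrs))
  names(genome) <- names(chrs)
  truth[, decap_pos := mapply(function(tid, tp)
    transcript_to_genomic(tp, models[[tid]]), transcript_id, decap_tpos)]
  truth[, cleavage_pos := mapply(function(tid, tp)
    if (is.na(tp)) NA_integer_ else transcript_to_genomic(tp, models[[tid]]),
    transcript_id, cleavage_tpos)]
  structure(list(genome = genome, models = models, truth = truth,
                 config = cfg),
            class = "degradome_simulation")
}

# expected per-position 5'P mass fractions for one transcript and genotype;
# D is the transcript's (jittered) decapping fraction
genotype_masses <- function(cls, cfg, genotype, D = cfg$decap_fraction) {
  C <- cfg$cleavage_fraction
  de <- 2^cfg$decap_effect
  ce <- 2^cfg$cleavage_effect
  r <- cfg$decap_redistribution
  decap <- switch(genotype,
    wild_type = D / de,
    xrn4 = if (cls == "xrn4_insensitive") D / de else D,
    dne1_xrn4 = if (cls == "xrn4_insensitive") D / de else min(D * r, 0.7))
  cleav <- if (cls != "dne1_target") 0 else switch(genotype,
    wild_type = C / ce,
    xrn4 = C,
    dne1_xrn4 = C / ce)
  c(decap = decap, cleavage = cleav, background = 1 - decap - cleav)
}

#' Simulate degradome libraries, Cap-PARE and RNA-seq tables
#'
#' Builds per-position expected-count maps for every genotype. Per
#' transcript, the 5'P mass (proportional to a clamped lognormal abundance)
#' is conserved across genotypes and split between a decapping spike at the
#' planted decapping position, a cleavage spike at the planted cleavage
#' position (targets), and a diffuse background whose per-position rates
#' carry a gamma "cleavability" weight drawn once and shared by all
#' genotypes and replicates (sequence-driven hotspots); counts are then
#' Poisson around the library-scaled rates, so marginally the background is
#' negative binomial with size `bg_dispersion`, while genotype contrasts at
#' background positions stay centred on zero. Spike counts are Poisson.
#' Per-library lognormal size factors give library-size variation. Also
#' emits a Cap-PARE profile concentrated (98% of mass) on the planted
#' decapping positions, an RNA-seq abundance table with no systematic
#' target difference between *xrn4* and the double mutant, and optionally a
#' half-life table.
#'
#' @param sim Output of [simulate_annotation()].
#' @return The `degradome_simulation` extended with `profiles` (list of raw
#'   `degradome_profile`s incl. one `cap_pare`), `rnaseq`, `halflife`
#'   (or `NULL`), and truth columns with expected spike CPMs.
#' @export
simulate_degradome <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  truth <- copy(sim$truth)
  n <- nrow(truth)
  w <- rlnorm(n, 0, cfg$abundance_sdlog)
  w <- pmin(pmax(w, cfg$abundance_clamp[1]), cfg$abundance_clamp[2])
  w <- w / sum(w)
  truth[, abundance := w]
  # per-transcript decapping fraction: +/-40% uniform jitter, so both
  # MaxSeq (cleavage tops decapping) and Major-internal configurations occur
  D_t <- cfg$decap_fraction * runif(n, 0.6, 1.4)
  truth[, decap_fraction := D_t]
  genotypes <- c("wild_type", "xrn4", "dne1_xrn4")
  for (g in genotypes) {
    mass <- t(vapply(seq_len(n), function(i)
      genotype_masses(truth$class[i], cfg, g, D_t[i]), numeric(3)))
    truth[, (paste0("decap_cpm_", g)) := mass[, 1] * w * 1e6]
    truth[, (paste0("cleavage_cpm_", g)) :=
            ifelse(class == "dne1_target", mass[, 2] * w * 1e6, NA_real_)]
  }
  # per-position scaffold in spliced space, mapped to genomic coordinates
  pos_tabs <- lapply(seq_len(n), function(i) {
    tx <- sim$models[[truth$transcript_id[i]]]
    tp <- 0:(tx$length - 1L)
    data.table(transcript_id = tx$transcript_id, chrom = tx$chromosome,
               strand = tx$strand, tpos = tp,
               pos = transcript_to_genomic(tp, tx))
  })
  scaffold <- rbindlist(pos_tabs)
  ejc_w <- rep(1, nrow(scaffold))
  if (cfg$ejc_protection > 1) {
    for (i in seq_len(n)) {
      tx <- sim$models[[truth$transcript_id[i]]]
      jn <- exon_junctions(tx)$transcript_coordinate
      if (!length(jn)) next
      idx <- which(scaffold$transcript_id == tx$transcript_id)
      d <- outer(scaffold$tpos[idx], jn, function(s, j) j - s + 1L)
      prot <- apply(d, 1L, function(x) any(x >= 25L & x <= 30L))
      ejc_w[idx][prot] <- cfg$ejc_protection
    }
  }
  profiles <- list()
  spike_idx <- list(
    decap = match(paste(truth$transcript_id, truth$decap_tpos),
                  paste(scaffold$transcript_id, scaffold$tpos)),
    cleavage = ifelse(is.na(truth$cleavage_tpos), NA_integer_,
                      match(paste(truth$transcript_id, truth$cleavage_tpos),
                            paste(scaffold$transcript_id, scaffold$tpos))))
  tx_len <- truth$length[match(scaffold$transcript_id, truth$transcript_id)]
  tx_w <- w[match(scaffold$transcript_id, truth$transcript_id)]
  # shared per-position cleavability weights (mean 1 within transcript):
  # gamma heterogeneity drawn once -> NB marginal counts, but fold changes
  # between genotypes at background positions remain centred on zero
  u <- stats::rgamma(nrow(scaffold), shape = cfg$bg_dispersion,
                     rate = cfg$bg_dispersion)
  u <- u / stats::ave(u, scaffold$transcript_id, FUN = mean)
  for (g in genotypes) {
    mass <- t(vapply(seq_len(n), function(i)
      genotype_masses(truth$class[i], cfg, g, D_t[i]), numeric(3)))
    bg_frac <- mass[match(scaffold$transcript_id, truth$transcript_id), 3]
    bg_w_pos <- tx_w * bg_frac * u * ejc_w / tx_len
    # renormalize so the transcript's background mass is unchanged by the
    # EJC protection pattern
    if (cfg$ejc_protection > 1) {
      scale <- stats::ave(bg_w_pos, scaffold$transcript_id, FUN = sum) /
        (tx_w * bg_frac)
      bg_w_pos <- bg_w_pos / scale
    }
    for (rep_i in seq_len(cfg$replicates)) {
      f <- rlnorm(1, 0, cfg$libsize_cv)
      counts <- rpois(nrow(scaffold), cfg$depth * f * bg_w_pos)
      dk <- spike_idx$decap
      counts[dk] <- counts[dk] +
        rpois(n, cfg$depth * f * mass[, 1] * w)
      ck <- spike_idx$cleavage
      ok <- !is.na(ck)
      counts[ck[ok]] <- counts[ck[ok]] +
        rpois(sum(ok), cfg$depth * f * (mass[, 2] * w)[ok])
      lid <- sprintf("%s_rep%d", g, rep_i)
      profiles[[lid]] <- new_profile(
        lid, g, rep_i,
        scaffold[, .(chrom, strand, pos)][, value := counts],
        units = "count")
    }
  }
  # Cap-PARE experimentally marks decapping sites: 98% of a transcript's
  # Cap-PARE mass sits on the planted decapping position (the assay is
  # cap-specific; only a thin nonspecific background remains)
  f <- rlnorm(1, 0, cfg$libsize_cv)
  counts <- rpois(nrow(scaffold), cfg$depth * f * 0.02 * tx_w * u / tx_len)
  counts[spike_idx$decap] <- counts[spike_idx$decap] +
    rpois(n, cfg$depth * f * 0.98 * w)
  profiles[["cap_pare_rep1"]] <- new_profile(
    "cap_pare_rep1", "cap_pare", 1L,
    scaffold[, .(chrom, strand, pos)][, value := counts],
    units = "count")
  rnaseq <- data.table(
    transcript_id = truth$transcript_id,
    rpkm_xrn4 = pmax(0.1, 5000 * w * exp(rnorm(n, 0, 0.05))),
    rpkm_double = pmax(0.1, 5000 * w * exp(rnorm(n, 0, 0.05))))
  rnaseq[, log2fc_double_vs_xrn4 := log2(rpkm_double / rpkm_xrn4)]
  rnaseq[, fdr := runif(n, 0.2, 1)]
  halflife <- NULL
  if (isTRUE(cfg$halflife)) {
    halflife <- data.table(
      transcript_id = truth$transcript_id,
      t_half = ifelse(truth$class == "dne1_target",
                      rlnorm(n, log(45), 0.5), rlnorm(n, log(120), 0.5)))
  }
  out <- sim
  out$truth <- truth
  out$profiles <- profiles
  out$rnaseq <- rnaseq
  out$halflife <- halflife
  out
}

#' Score called sites against the planted truth
#'
#' A call is a true positive iff it lies within `tolerance_nt` of a planted
#' cleavage position on the correct transcript; each planted site can be
#' matched at most once (closest call wins).
#'
#' @param sites Called site table (`chrom`, `strand`, `pos`,
#'   `transcript_id`).
#' @param truth Simulation truth table.
#' @param tolerance_nt Matching tolerance in nt (default 0).
#' @return List with `precision`, `recall`, `f1`, `tp`, `n_called`,
#'   `n_planted`, `no_calls` flag, and a per-class `confusion` table of
#'   called transcript classes.
#' @export
evaluate_recovery <- function(sites, truth, tolerance_nt = 0L) {
  planted <- truth[class == "dne1_target" & !is.na(cleavage_pos)]
  n_planted <- nrow(planted)
  n_called <- nrow(sites)
  tp <- 0L
  if (n_called > 0L && n_planted > 0L) {
    pairs <- merge(sites[, .(transcript_id, call_pos = pos)],
                   planted[, .(transcript_id, cleavage_pos)],
                   by = "transcript_id")
    pairs <- pairs[abs(call_pos - cleavage_pos) <= tolerance_nt]
    setorder(pairs, transcript_id)
    pairs[, d := abs(call_pos - cleavage_pos)]
    setorder(pairs, d)
    used_call <- character(0)
    used_truth <- character(0)
    for (i in seq_len(nrow(pairs))) {
      ck <- paste(pairs$transcript_id[i], pairs$call_pos[i])
      tk <- paste(pairs$transcript_id[i], pairs$cleavage_pos[i])
      if (ck %in% used_call || tk %in% used_truth) next
      used_call <- c(used_call, ck)
      used_truth <- c(used_truth, tk)
      tp <- tp + 1L
    }
  }
  precision <- if (n_called > 0L) tp / n_called else 0
  recall <- if (n_planted > 0L) tp / n_planted else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  confusion <- if (n_called > 0L) {
    merge(sites[, .(transcript_id)], truth[, .(transcript_id, class)],
          by = "transcript_id", all.x = TRUE)[, .N, by = class]
  } else data.table(class = character(), N = integer())
  list(precision = precision, recall = recall, f1 = f1, tp = tp,
       n_called = n_called, n_planted = n_planted,
       no_calls = n_called == 0L, confusion = confusion)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, GFF3, per-library per-strand bedGraph files, the RNA-seq
#' and truth tables, the optional half-life table, and a JSON echo of the
#' configuration. All output is deterministic given the config seed.
#'
#' @param sim A completed `degradome_simulation` (after
#'   [simulate_degradome()]).
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.gff3"),
             rnaseq = file.path(dir, "rnaseq.tsv"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"),
             samples = file.path(dir, "samples.tsv"))
  write_genome(sim$genome, paths["genome"])
  write_gff3(sim$models, paths["annotation"])
  fwrite(sim$rnaseq, paths["rnaseq"], sep = "\t")
  fwrite(sim$truth, paths["truth"], sep = "\t")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(sim$halflife)) {
    paths["halflife"] <- file.path(dir, "halflife.tsv")
    fwrite(sim$halflife, paths["halflife"], sep = "\t")
  }
  samples <- list()
  for (lid in names(sim$profiles)) {
    p <- sim$profiles[[lid]]
    for (st in c("+", "-")) {
      tag <- if (st == "+") "plus" else "minus"
      f <- file.path(dir, sprintf("%s_%s.bedGraph", lid, tag))
      write_bedgraph(p, f, st)
      samples[[paste(lid, tag)]] <- data.table(
        library_id = lid, genotype = p$genotype, replicate = p$replicate,
        strand = st, path = basename(f))
      paths[paste0(lid, "_", tag)] <- f
    }
  }
  fwrite(rbindlist(samples), paths["samples"], sep = "\t")
  invisible(paths)
}

#' Write transcript models as GFF3
#'
#' @param models Named list of `transcript_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- c(m$exons[1L, 1L] + 1L, m$exons[nrow(m$exons), 2L])
    lines <- c(lines,
               sprintf("%s\tdnecall\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$chromosome, span[1L], span[2L], m$strand, m$gene_id),
               sprintf("%s\tdnecall\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       m$chromosome, span[1L], span[2L], m$strand,
                       m$transcript_id, m$gene_id))
    for (e in seq_len(nrow(m$exons))) {
      lines <- c(lines,
                 sprintf("%s\tdnecall\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         m$chromosome, m$exons[e, 1L] + 1L, m$exons[e, 2L],
                         m$strand, m$transcript_id))
    }
    if (!is.null(m$cds_span)) {
      cds_ex <- m$exons[m$exons[, 2L] > m$cds_span[1L] &
                          m$exons[, 1L] < m$cds_span[2L], , drop = FALSE]
      for (e in seq_len(nrow(cds_ex))) {
        lines <- c(lines,
                   sprintf("%s\tdnecall\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                           m$chromosome,
                           max(cds_ex[e, 1L], m$cds_span[1L]) + 1L,
                           min(cds_ex[e, 2L], m$cds_span[2L]),
                           m$strand, m$transcript_id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
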