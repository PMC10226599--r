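# Sparse per-position 5'-end count tracks.
#
# A profile holds one data.table keyed by (chrom, strand, pos) with a `value`
# column: integer counts (units = "count") or CPM (units = "cpm").  Zero
# values are never stored.

new_profile <- function(library_id, genotype, replicate, values, units,
                        total = NULL) {
  genotype <- match.arg(genotype,
                        c("wild_type", "xrn4", "dne1_xrn4", "cap_pare", "other"))
  stopifnot(is.data.frame(values))
  values <- as.data.table(values)[, .(chrom, strand, pos, value)]
  values <- values[value != 0]
  if (any(values$value < 0)) stop("negative track values")
  setkey(values, chrom, strand, pos)
  if (anyDuplicated(values, by = c("chrom", "strand", "pos"))) {
    stop("duplicate positions in profile ", library_id)
  }
  if (is.null(total)) total <- sum(values$value)
  structure(list(library_id = library_id, genotype = genotype,
                 replicate = as.integer(replicate), values = values,
                 units = units, total = total),
            class = "degradome_profile")
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("<degradome_profile> %s [%s rep %d] %d positions, total %s (%s)\n",
              x$library_id, x$genotype, x$replicate, nrow(x$values),
              format(x$total, big.mark = ","), x$units))
  invisible(x)
}

#' Load a per-strand bedGraph into a raw count profile
#'
#' bedGraph intervals (0-based, half-open, 4 columns) of width w are expanded
#' to w per-base entries carrying the interval's value, as produced by
#' per-base 5'-end coverage ("bin size 1, offset 1": only the first
#' nucleotide of each read is counted).
#'
#' @param path bedGraph file (chrom, start, end, count).
#' @param strand `"+"` or `"-"`; degradome strands live in separate files.
#' @param library_id,genotype,replicate Library metadata; `genotype` one of
#'   `wild_type`, `xrn4`, `dne1_xrn4`, `cap_pare`, `other`.
#' @return A raw `degradome_profile` (units `"count"`).
#' @export
load_bedgraph <- function(path, strand, library_id = basename(path),
                          genotype = "other", replicate = 1L) {
  stopifnot(strand %in% c("+", "-"))
  bg <- if (file.exists(path) && file.size(path) == 0) {
    data.table(chrom = character(), start = integer(), end = integer(),
               count = numeric())
  } else {
    fread(path, header = FALSE, sep = "\t",
          col.names = c("chrom", "start", "end", "count"))
  }
  if (nrow(bg) && any(bg$count < 0)) stop("negative values in ", path)
  if (nrow(bg) && any(bg$end <= bg$start)) stop("empty interval in ", path)
  if (nrow(bg) == 0L) {
    values <- data.table(chrom = character(), strand = character(),
                         pos = integer(), value = numeric())
  } else {
    w <- bg$end - bg$start
    values <- data.table(
      chrom = rep(bg$chrom, w),
      strand = strand,
      pos = as.integer(unlist(Map(seq.int, bg$start, bg$end - 1L))),
      value = rep(bg$count, w))
    if (anyDuplicated(values, by = c("chrom", "strand", "pos"))) {
      stop("overlapping intervals in ", path)
    }
  }
  new_profile(library_id, genotype, replicate, values, units = "count")
}

#' Write a profile (one strand) as bedGraph
#'
#' Runs of adjacent equal-valued positions are collapsed into intervals.
#'
#' @param profile A `degradome_profile`.
#' @param path Output file.
#' @param strand Which strand to emit.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, strand) {
  st <- strand
  v <- profile$values[strand == st][order(chrom, pos)]
  if (nrow(v)) {
    brk <- c(TRUE, v$chrom[-1L] != v$chrom[-nrow(v)] |
               v$pos[-1L] != v$pos[-nrow(v)] + 1L |
               v$value[-1L] != v$value[-nrow(v)])
    run <- cumsum(brk)
    out <- v[, .(chrom = chrom[1L], start = pos[1L], end = pos[.N] + 1L,
                 value = value[1L]), by = .(run = run)][, run := NULL]
  } else {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, scipen = 50L)
  invisible(path)
}

#' Normalize a raw profile to counts per million (CPM)
#'
#' Per-position CPM = count x 10^6 / total mapped tags; the key set is
#' preserved and CPM values sum to 10^6.
#'
#' @param raw A raw `degradome_profile`.
#' @return A `degradome_profile` with units `"cpm"`.
#' @export
cpm_normalize <- function(raw) {
  stopifnot(inherits(raw, "degradome_profile"))
  if (raw$units != "count") stop("profile already normalized")
  if (raw$total <= 0) stop("empty library: ", raw$library_id)
  v <- copy(raw$values)[, value := value * 1e6 / raw$total]
  new_profile(raw$library_id, raw$genotype, raw$replicate, v,
              units = "cpm", total = raw$total)
}

#' Merge replicate CPM profiles by per-position mean
#'
#' Absent positions count as 0, so the merged value is sum(CPM)/n
#' replicates; positions with mean 0 are dropped. Libraries are weighted
#' equally regardless of sequencing depth.
#'
#' @param profiles List of normalized profiles of one genotype.
#' @return A merged `degradome_profile` (replicate 0).
#' @export
merge_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  if (length(unique(vapply(profiles, `[[`, character(1), "genotype"))) != 1L) {
    stop("cannot merge profiles of mixed genotypes")
  }
  if (any(vapply(profiles, `[[`, character(1), "units") != "cpm")) {
    stop("merge_replicates expects CPM profiles")
  }
  n <- length(profiles)
  all <- rbindlist(lapply(profiles, `[[`, "values"))
  merged <- all[, .(value = sum(value) / n), by = .(chrom, strand, pos)]
  new_profile(paste0(profiles[[1]]$genotype, "_merged"),
              profiles[[1]]$genotype, 0L, merged, units = "cpm",
              total = sum(vapply(profiles, `[[`, numeric(1), "total")) / n)
}

#' Pearson correlation between replicate tracks
#'
#' Computed on raw CPM values over the union of positions where either
#' replicate has CPM >= `min_cpm` (absent positions count as 0), following
#' the usual replicate-reproducibility scatter (CPM >= 1).
#'
#' @param a,b Normalized profiles.
#' @param min_cpm Inclusion threshold (default 1 CPM).
#' @return List with `r`, `r_squared`, `n_positions`.
#' @export
replicate_correlation <- function(a, b, min_cpm = 1) {
  j <- merge(a$values, b$values, by = c("chrom", "strand", "pos"),
             all = TRUE, suffixes = c("_a", "_b"))
  j[is.na(value_a), value_a := 0]
  j[is.na(value_b), value_b := 0]
  j <- j[value_a >= min_cpm | value_b >= min_cpm]
  if (nrow(j) < 3L) stop("fewer than 3 positions with CPM >= ", min_cpm)
  r <- cor(j$value_a, j$value_b)
  list(r = r, r_squared = r^2, n_positions = nrow(j))
}

#' Pseudocount log2 fold-change track between two CPM profiles
#'
#' value = log2((a + pc) / (b + pc)) over the union of stored positions;
#' positions where both inputs are 0 are skipped ("SkipZeroOverZero") and
#' counted. An explicit `positions` universe may be supplied (e.g. candidate
#' positions), in which case both-zero members of it are skipped and counted
#' in `skipped_zero_pairs`.
#'
#' @param numerator,denominator Normalized profiles.
#' @param pseudocount CPM added to both sides (default 0.01).
#' @param positions Optional `data.table(chrom, strand, pos)` universe.
#' @return A `comparison_track`: values table with `value` = log2 FC, plus
#'   `skipped_zero_pairs`.
#' @export
log2_compare <- function(numerator, denominator, pseudocount = 0.01,
                         positions = NULL) {
  stopifnot(numerator$units == "cpm", denominator$units == "cpm")
  j <- merge(numerator$values, denominator$values,
             by = c("chrom", "strand", "pos"), all = TRUE,
             suffixes = c("_a", "_b"))
  j[is.na(value_a), value_a := 0]
  j[is.na(value_b), value_b := 0]
  skipped <- 0L
  if (!is.null(positions)) {
    u <- as.data.table(positions)[, .(chrom, strand, pos)]
    j <- merge(u, j, by = c("chrom", "strand", "pos"), all.x = TRUE)
    j[is.na(value_a), value_a := 0]
    j[is.na(value_b), value_b := 0]
  }
  skipped <- sum(j$value_a == 0 & j$value_b == 0)
  j <- j[value_a != 0 | value_b != 0]
  j[, value := log2((value_a + pseudocount) / (value_b + pseudocount))]
  structure(list(numerator_id = numerator$library_id,
                 denominator_id = denominator$library_id,
                 pseudocount = pseudocount,
                 values = setkey(j[, .(chrom, strand, pos, value)],
                                 chrom, strand, pos),
                 skipped_zero_pairs = as.integer(skipped)),
            class = "comparison_track")
}

#' @export
print.comparison_track <- function(x, ...) {
  cat(sprintf("<comparison_track> log2(%s/%s), pc=%g, %d positions, %d 0/0 skipped\n",
              x$numerator_id, x$denominator_id, x$pseudocount,
              nrow(x$values), x$skipped_zero_pairs))
  invisible(x)
}

#' Export a track or comparison as TSV
#'
#' @param x A `degradome_profile` or `comparison_track`.
#' @param path Output TSV (chrom, strand, pos, value).
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(x, path) {
  fwrite(x$values[, .(chrom, strand, pos, value)], path, sep = "\t")
  invisible(path)
}
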