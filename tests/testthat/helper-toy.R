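# Toy builders shared across test files.

library(data.table)

toy_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

make_tx <- function(id, chrom, strand, exons, cds = NULL, gene = id,
                    coding = !is.null(cds), nuclear = TRUE) {
  dnecall:::new_transcript_model(id, gene, chrom, strand, exons,
                                 cds_span = cds,
                                 is_protein_coding = coding,
                                 is_nuclear = nuclear)
}

# CPM profile straight from a data.frame of (chrom, strand, pos, value)
make_cpm <- function(df, id = "p", genotype = "other", replicate = 1L) {
  dnecall:::new_profile(id, genotype, replicate, as.data.table(df),
                        units = "cpm", total = 1e6)
}

make_counts <- function(df, id = "p", genotype = "other", replicate = 1L) {
  dnecall:::new_profile(id, genotype, replicate, as.data.table(df),
                        units = "count")
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genomic -> spliced map built base by base (independent of the package's
# coordinate arithmetic): returns named integer vector genomic -> spliced
brute_spliced_map <- function(exons, strand) {
  bases <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    exons[i, 1]:(exons[i, 2] - 1L)
  }))
  bases <- sort(bases)
  if (strand == "-") bases <- rev(bases)
  stats::setNames(seq_along(bases) - 1L, bases)
}

# a small simulated dataset reused by several files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_transcripts = 40L, depth = 1e6,
                               n_chromosomes = 2L, replicates = 2L,
                               decap_redistribution = 1.0, seed = 11L)
      cache <<- simulate_degradome(simulate_annotation(cfg))
    }
    cache
  }
})

# brute-force IUPAC matcher: position-by-position comparison
brute_iupac_match <- function(seq, pattern) {
  codes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  k <- length(p)
  hits <- integer(0)
  if (length(s) < k) return(hits)
  for (o in 0:(length(s) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!s[o + j] %in% codes[[p[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, o)
  }
  hits
}
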