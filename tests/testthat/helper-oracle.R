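# Independent straight-line reimplementation of the whole site-calling
# cascade: dense per-chromosome arrays, plain loops, no sparse structures,
# no early exits. Used to verify the package's cascade end to end.

oracle_call_sites <- function(profiles, models, genome, rnaseq = NULL,
                              cfg = pipeline_config()) {
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  genome_chr <- as.character(genome)
  strands <- c("+", "-")

  dense_cpm <- function(p) {
    arr <- lapply(names(chrom_len), function(cn) {
      sapply(strands, function(st) numeric(chrom_len[[cn]]),
             simplify = FALSE)
    })
    names(arr) <- names(chrom_len)
    tot <- sum(p$values$value)
    ch <- p$values$chrom; st_ <- p$values$strand
    po <- p$values$pos; va <- p$values$value
    for (i in seq_along(po)) {
      arr[[ch[i]]][[st_[i]]][po[i] + 1L] <-
        arr[[ch[i]]][[st_[i]]][po[i] + 1L] + va[i]
    }
    if (p$units == "count") {
      for (cn in names(arr)) for (st in strands) {
        arr[[cn]][[st]] <- arr[[cn]][[st]] * 1e6 / tot
      }
    }
    arr
  }
  geno <- vapply(profiles, `[[`, character(1), "genotype")
  merged_dense <- function(g) {
    ps <- profiles[geno == g]
    arrs <- lapply(ps, dense_cpm)
    out <- arrs[[1]]
    if (length(arrs) > 1) {
      for (j in 2:length(arrs)) {
        for (cn in names(out)) for (st in strands) {
          out[[cn]][[st]] <- out[[cn]][[st]] + arrs[[j]][[cn]][[st]]
        }
      }
    }
    for (cn in names(out)) for (st in strands) {
      out[[cn]][[st]] <- out[[cn]][[st]] / length(arrs)
    }
    out
  }
  xr <- merged_dense("xrn4")
  wt <- merged_dense("wild_type")
  db <- merged_dense("dne1_xrn4")
  cp <- if ("cap_pare" %in% geno) merged_dense("cap_pare") else NULL

  models <- collapse_isoforms(models)
  maps <- lapply(models, function(m) brute_spliced_map(m$exons, m$strand))

  spliced_seq <- function(m) {
    map <- maps[[m$transcript_id]]
    gpos <- as.integer(names(map))
    ord <- order(unname(map))
    bases <- substring(genome_chr[[m$chromosome]], gpos[ord] + 1L,
                       gpos[ord] + 1L)
    if (m$strand == "-") {
      comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
      bases <- unname(comp[bases])
    }
    paste0(bases, collapse = "")
  }
  txseqs <- vapply(models, spliced_seq, character(1))

  count_occurrences <- function(kmer) {
    k <- nchar(kmer)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(kmer)))
    g <- 0L
    for (ch in genome_chr) {
      starts <- seq_len(nchar(ch) - k + 1L)
      subs <- substring(ch, starts, starts + k - 1L)
      g <- g + sum(subs == kmer)
      if (rc != kmer) g <- g + sum(subs == rc)
    }
    t <- 0L
    for (s in txseqs) {
      if (nchar(s) >= k) {
        starts <- seq_len(nchar(s) - k + 1L)
        t <- t + sum(substring(s, starts, starts + k - 1L) == kmer)
      }
    }
    c(genome = g, txome = t)
  }

  # decapping catalog: dense Cap-PARE scan + every TSS
  catalog <- list()
  if (!is.null(cp)) {
    for (cn in names(chrom_len)) for (st in strands) {
      hit <- which(cp[[cn]][[st]] >= cfg$decap_min_cpm) - 1L
      for (p in hit) catalog[[length(catalog) + 1L]] <- c(cn, st, p)
    }
  }
  for (m in models) {
    catalog[[length(catalog) + 1L]] <- c(m$chromosome, m$strand, m$tss)
  }
  catalog <- unique(do.call(rbind, catalog))

  pc <- cfg$pseudocount
  results <- list()
  for (cn in names(chrom_len)) for (st in strands) {
    for (p in 0:(chrom_len[[cn]] - 1L)) {
      a <- xr[[cn]][[st]][p + 1L]
      if (a < cfg$prefilter_min_cpm) next
      b <- wt[[cn]][[st]][p + 1L]
      if (a == 0 && b == 0) next
      fc_wt <- log2((a + pc) / (b + pc))
      if (!(a >= cfg$min_xrn4_cpm && fc_wt >= cfg$min_log2fc_xrn4_vs_wt)) next
      d <- db[[cn]][[st]][p + 1L]
      if (a == 0 && d == 0) next
      fc_db <- log2((a + pc) / (d + pc))
      if (fc_db < cfg$min_log2fc_xrn4_vs_double) next
      # transcript assignment: exonic, smallest id
      tid <- NA_character_
      for (id in sort(names(models))) {
        m <- models[[id]]
        if (m$chromosome == cn && m$strand == st &&
            as.character(p) %in% names(maps[[id]])) { tid <- id; break }
      }
      if (is.na(tid)) next
      results[[length(results) + 1L]] <- list(
        chrom = cn, strand = st, pos = p, transcript_id = tid,
        tpos = unname(maps[[tid]][as.character(p)]),
        xrn4_cpm = a, fc_xrn4_wt = fc_wt, fc_xrn4_double = fc_db)
    }
  }
  cands <- data.table::rbindlist(results)
  if (nrow(cands) == 0L) return(cands)

  keep <- logical(nrow(cands))
  for (i in seq_len(nrow(cands))) {
    m <- models[[cands$transcript_id[i]]]
    map <- maps[[m$transcript_id]]
    # catalogued positions on this transcript, in spliced coordinates
    cat_t <- integer(0)
    for (r in seq_len(nrow(catalog))) {
      if (catalog[r, 1] == m$chromosome && catalog[r, 2] == m$strand &&
          catalog[r, 3] %in% names(map)) {
        cat_t <- c(cat_t, unname(map[catalog[r, 3]]))
      }
    }
    near <- length(cat_t) > 0 &&
      min(abs(cat_t - cands$tpos[i])) <= cfg$exclusion_window
    if (near) next
    s <- cands$tpos[i]
    txs <- txseqs[[cands$transcript_id[i]]]
    if (s + cfg$uniqueness_k > nchar(txs)) next
    kmer <- substr(txs, s + 1L, s + cfg$uniqueness_k)
    occ <- count_occurrences(kmer)
    if (occ["genome"] != 1L || occ["txome"] != 1L) next
    if (!is.null(rnaseq)) {
      row <- rnaseq[rnaseq$transcript_id == cands$transcript_id[i], ]
      if (nrow(row) == 1L &&
          row$log2fc_double_vs_xrn4 <= cfg$expression_drop_log2fc &&
          row$fdr <= cfg$expression_fdr) next
    }
    keep[i] <- TRUE
  }
  cands <- cands[keep]
  if (nrow(cands) == 0L) return(cands)

  out <- list()
  for (tid in unique(cands$transcript_id)) {
    m <- models[[tid]]
    map <- maps[[tid]]
    sub <- cands[cands$transcript_id == tid, ]
    sub <- sub[order(-sub$xrn4_cpm, sub$tpos), ]
    best <- sub[1, ]
    # full per-transcript ranking of all nonzero track positions
    gpos <- as.integer(names(map))
    cpm <- xr[[m$chromosome]][[m$strand]][gpos + 1L]
    rk <- data.table::data.table(gpos = gpos, tpos = unname(map),
                                 cpm = cpm)[cpm > 0]
    rk <- rk[order(-rk$cpm, rk$tpos), ]
    my <- which(rk$tpos == best$tpos)
    cls <- NULL
    if (length(my) == 1L && my == 1L) cls <- "MaxSeq"
    if (length(my) == 1L && my == 2L) {
      top <- rk[1, ]
      in_cat <- any(catalog[, 1] == m$chromosome &
                      catalog[, 2] == m$strand &
                      catalog[, 3] == as.character(top$gpos))
      if (in_cat) cls <- "MajorInternal"
    }
    if (!is.null(cls)) {
      best$site_class <- cls
      out[[tid]] <- best
    }
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, strand, pos)
  res
}
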