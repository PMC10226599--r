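#' @importFrom data.table data.table setkey setkeyv rbindlist fread fwrite := .N .SD setorder setorderv setcolorder copy as.data.table foverlaps setnames
#' @importFrom stats cor median p.adjust phyper rnbinom rpois runif rlnorm rnorm wilcox.test fisher.test setNames
#' @importFrom utils head tail
NULL

# Internal convention: all coordinates are 0-based, half-open on the forward
# genomic strand.  GFF3/GTF (1-based, closed) and bedGraph (already 0-based,
# half-open) are converted at the parser boundary only.

#' Load a genome from FASTA
#'
#' Reads all records into a `DNAStringSet`, normalizes to uppercase and
#' validates the alphabet (A/C/G/T/N only).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate chromosome names in ", path)
  names(seqs) <- nm
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  names(seqs) <- nm
  bad <- vapply(seq_along(seqs), function(i) {
    f <- Biostrings::alphabetFrequency(seqs[[i]])
    sum(f) - sum(f[c("A", "C", "G", "T", "N")]) > 0
  }, logical(1))
  if (any(bad)) {
    stop("record '", nm[which(bad)[1]], "' contains letters outside A/C/G/T/N")
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty sequence record in ", path)
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

new_transcript_model <- function(transcript_id, gene_id, chromosome, strand,
                                 exons, cds_span = NULL,
                                 is_protein_coding = !is.null(cds_span),
                                 is_nuclear = TRUE) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("transcript ", transcript_id, ": zero/negative width exon")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  len <- sum(exons[, 2L] - exons[, 1L])
  if (!is.null(cds_span)) {
    cds_span <- as.integer(cds_span)
    inside <- cds_span[1L] >= exons[1L, 1L] &&
      cds_span[2L] <= exons[nrow(exons), 2L]
    in_exon <- function(p) any(p >= exons[, 1L] & p < exons[, 2L])
    if (!inside || !in_exon(cds_span[1L]) || !in_exon(cds_span[2L] - 1L)) {
      stop("transcript ", transcript_id, ": CDS not covered by exons")
    }
  }
  tss <- unname(if (strand == "+") exons[1L, 1L] else
    exons[nrow(exons), 2L] - 1L)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chromosome = chromosome, strand = strand, exons = exons,
                 cds_span = cds_span, tss = tss, length = len,
                 is_protein_coding = is_protein_coding,
                 is_nuclear = is_nuclear),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), length %d%s\n",
              x$transcript_id, x$gene_id, x$chromosome, x$strand,
              nrow(x$exons), x$length,
              if (is.null(x$cds_span)) " [non-coding]" else ""))
  invisible(x)
}

organellar_chromosomes <- c("ChrM", "ChrC", "chrM", "chrC", "Mt", "Pt",
                            "mitochondria", "chloroplast")

#' Load transcript models from GFF3/GTF
#'
#' Parses transcript/mRNA + exon (+ optional CDS) features into
#' `transcript_model` objects validated against the genome. Both GFF3
#' (ID/Parent) and GTF (transcript_id/gene_id) attribute dialects are
#' supported via `rtracklayer`.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param genome A `DNAStringSet` from [load_genome()]; transcripts on
#'   chromosomes absent from it, or with exons outside chromosome bounds,
#'   raise an error.
#' @return Named list of `transcript_model` objects (names = transcript ids).
#' @export
load_annotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  md <- as.data.frame(S4Vectors::mcols(gr))
  df <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,        # to 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type  = as.character(md$type))
  if (fmt == "gtf") {
    df[, tx_id := md$transcript_id]
    df[, gene := md$gene_id]
  } else {
    par <- md$Parent
    par1 <- vapply(as.list(par), function(p) if (length(p)) as.character(p)[1] else NA_character_,
                   character(1))
    df[, id := md$ID]
    df[, parent := par1]
  }
  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "tRNA", "rRNA",
                "snoRNA", "snRNA", "miRNA_primary_transcript")
  models <- list()
  if (fmt == "gff3") {
    txs <- df[type %in% tx_types]
    exons <- df[type == "exon"]
    cds <- df[type == "CDS"]
    if (nrow(txs) == 0L) stop("no transcript/mRNA features in ", path)
    for (i in seq_len(nrow(txs))) {
      tid <- txs$id[i]
      ex <- exons[parent == tid]
      if (nrow(ex) == 0L) next
      cd <- cds[parent == tid]
      cds_span <- if (nrow(cd)) c(min(cd$start), max(cd$end)) else NULL
      models[[tid]] <- build_validated_model(
        tid, ifelse(is.na(txs$parent[i]), tid, txs$parent[i]),
        txs$chrom[i], txs$strand[i],
        cbind(ex$start, ex$end), cds_span, txs$type[i], genome)
    }
  } else {
    for (tid in unique(df[type == "exon"]$tx_id)) {
      ex <- df[type == "exon" & tx_id == tid]
      cd <- df[type == "CDS" & tx_id == tid]
      cds_span <- if (nrow(cd)) c(min(cd$start), max(cd$end)) else NULL
      models[[tid]] <- build_validated_model(
        tid, ex$gene[1], ex$chrom[1], ex$strand[1],
        cbind(ex$start, ex$end), cds_span, "mRNA", genome)
    }
  }
  if (length(models) == 0L) stop("no transcripts with exons parsed from ", path)
  models
}

build_validated_model <- function(tid, gid, chrom, strand, exons, cds_span,
                                  type, genome) {
  if (!chrom %in% names(genome)) {
    stop("transcript ", tid, " on chromosome '", chrom,
         "' absent from genome")
  }
  if (max(exons[, 2L]) > length(genome[[chrom]]) ||
      min(exons[, 1L]) < 0L) {
    stop("transcript ", tid, ": exon outside chromosome bounds")
  }
  m <- new_transcript_model(tid, gid, chrom, strand, exons, cds_span,
                            is_protein_coding = type == "mRNA" && !is.null(cds_span),
                            is_nuclear = !chrom %in% organellar_chromosomes)
  if (!is.null(cds_span)) {
    # CDS must be fully covered by the exon union
    cov <- sum(pmax(0L, pmin(m$exons[, 2L], cds_span[2L]) -
                      pmax(m$exons[, 1L], cds_span[1L])))
    ex_cov <- exonic_span_coverage(m, cds_span)
    if (!ex_cov) stop("transcript ", tid, ": CDS not covered by exons")
  }
  m
}

# every base of [span[1], span[2]) that lies between the CDS endpoints must be
# exonic at the endpoints themselves (introns inside the CDS are allowed)
exonic_span_coverage <- function(tx, span) {
  in_exon <- function(p) any(p >= tx$exons[, 1L] & p < tx$exons[, 2L])
  in_exon(span[1L]) && in_exon(span[2L] - 1L)
}

cumulative_exon_starts <- function(tx) {
  w <- tx$exons[, 2L] - tx$exons[, 1L]
  cumsum(c(0L, w))[seq_len(nrow(tx$exons))]
}

#' Map genomic positions to spliced-transcript coordinates
#'
#' Exonic positions map bijectively to `[0, length)` measured from the
#' transcript 5' end (strand-aware); intronic positions return `NA`.
#'
#' @param pos Integer vector of genomic positions (0-based).
#' @param tx A `transcript_model`.
#' @return Integer vector of spliced coordinates; `NA` where intronic.
#'   Positions outside the transcript span raise an error.
#' @export
genomic_to_transcript <- function(pos, tx) {
  span <- c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])
  if (any(pos < span[1L] | pos >= span[2L])) {
    stop("position outside span of ", tx$transcript_id)
  }
  cum <- cumulative_exon_starts(tx)
  out <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(tx$exons))) {
    hit <- pos >= tx$exons[i, 1L] & pos < tx$exons[i, 2L]
    out[hit] <- cum[i] + (pos[hit] - tx$exons[i, 1L])
  }
  if (tx$strand == "-") {
    ok <- !is.na(out)
    out[ok] <- tx$length - 1L - out[ok]
  }
  out
}

#' Map spliced-transcript coordinates back to genomic positions
#'
#' Inverse of [genomic_to_transcript()] on exonic bases.
#'
#' @param tpos Integer vector of spliced coordinates in `[0, length)`.
#' @param tx A `transcript_model`.
#' @return Integer vector of genomic positions (0-based).
#' @export
transcript_to_genomic <- function(tpos, tx) {
  if (any(tpos < 0L | tpos >= tx$length)) {
    stop("spliced coordinate outside [0, length) for ", tx$transcript_id)
  }
  fwd <- if (tx$strand == "-") tx$length - 1L - tpos else tpos
  cum <- cumulative_exon_starts(tx)
  w <- tx$exons[, 2L] - tx$exons[, 1L]
  idx <- findInterval(fwd, cum)
  as.integer(tx$exons[idx, 1L] + (fwd - cum[idx]))
}

#' Exon-exon junctions of a transcript
#'
#' One junction per adjacent exon pair; `transcript_coordinate` is the
#' 0-based spliced coordinate of the last base of the upstream exon,
#' i.e. cumulative exon length minus one in transcript orientation.
#'
#' @param tx A `transcript_model`.
#' @return `data.table` with `junction_index` and `transcript_coordinate`
#'   (strictly increasing); zero rows for single-exon transcripts.
#' @export
exon_junctions <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) {
    return(data.table(junction_index = integer(), transcript_coordinate = integer()))
  }
  w <- tx$exons[, 2L] - tx$exons[, 1L]
  if (tx$strand == "-") w <- rev(w)
  data.table(junction_index = seq_len(n - 1L),
             transcript_coordinate = as.integer(cumsum(w)[-n] - 1L))
}

#' CDS bounds in spliced coordinates
#'
#' @param tx A `transcript_model` with a CDS.
#' @return Integer `c(start, end)` half-open in spliced coordinates, or
#'   `NULL` for non-coding models.
#' @export
cds_transcript_span <- function(tx) {
  if (is.null(tx$cds_span)) return(NULL)
  a <- genomic_to_transcript(tx$cds_span[1L], tx)
  b <- genomic_to_transcript(tx$cds_span[2L] - 1L, tx)
  c(min(a, b), max(a, b) + 1L)
}

#' Select one representative isoform per gene
#'
#' Longest CDS wins; ties go to the longest transcript, then the
#' lexicographically smallest transcript id.
#'
#' @param models Named list of `transcript_model`s.
#' @return Filtered named list, one model per `gene_id`.
#' @export
collapse_isoforms <- function(models) {
  dt <- data.table(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    cds_len = vapply(models, function(m) {
      if (is.null(m$cds_span)) 0L else {
        sp <- cds_transcript_span(m); sp[2L] - sp[1L]
      }
    }, integer(1)),
    len = vapply(models, `[[`, integer(1), "length"))
  setorder(dt, gene_id, -cds_len, -len, transcript_id)
  keep <- dt[, .SD[1L], by = gene_id]$transcript_id
  models[keep]
}

#' Spliced (mature mRNA) sequences
#'
#' @param genome A `DNAStringSet`.
#' @param models Named list of `transcript_model`s.
#' @return `DNAStringSet` of sense-strand spliced sequences, one per model.
#' @export
spliced_sequences <- function(genome, models) {
  seqs <- vapply(models, function(m) {
    parts <- substring(as.character(genome[[m$chromosome]]),
                       m$exons[, 1L] + 1L, m$exons[, 2L])
    s <- paste0(parts, collapse = "")
    if (m$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(models)
  out
}

# flat exon table used for bulk position->transcript mapping
exon_table <- function(models) {
  rbindlist(lapply(models, function(m) {
    data.table(transcript_id = m$transcript_id, chrom = m$chromosome,
               strand = m$strand, start = m$exons[, 1L], end = m$exons[, 2L],
               cum_before = cumulative_exon_starts(m), tx_len = m$length)
  }))
}

#' Map a table of genomic positions onto transcripts
#'
#' Bulk, vectorized equivalent of [genomic_to_transcript()] over a position
#' table: each (chrom, strand, pos) row landing in an exon of a model (on the
#' matching strand) gains that model's id and the spliced coordinate.
#' Positions hitting several models keep the lexicographically smallest
#' transcript id (isoforms should be collapsed first).
#'
#' @param positions `data.table` with columns `chrom`, `strand`, `pos`.
#' @param models Named list of `transcript_model`s.
#' @return `data.table`: input columns plus `transcript_id`, `tpos`.
#'   Unmapped rows are absent.
#' @export
map_positions_to_transcripts <- function(positions, models) {
  ex <- exon_table(models)
  if (nrow(positions) == 0L || nrow(ex) == 0L) {
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), transcript_id = character(),
                      tpos = integer()))
  }
  p <- copy(positions)[, `:=`(start = pos, end = pos + 1L)]
  setkey(ex, chrom, strand, start, end)
  ov <- foverlaps(p, ex, by.x = c("chrom", "strand", "start", "end"),
                  type = "within", nomatch = NULL)
  fwd <- ov$cum_before + (ov$pos - ov$start)
  ov[, tpos := as.integer(ifelse(strand == "-", tx_len - 1L - fwd, fwd))]
  out <- ov[, .(chrom, strand, pos, transcript_id, tpos)]
  setorder(out, chrom, strand, pos, transcript_id)
  out[, .SD[1L], by = .(chrom, strand, pos)]
}
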