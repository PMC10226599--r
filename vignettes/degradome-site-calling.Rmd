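---
title: "Calling endoribonuclease-dependent cleavage sites from degradome data"
author: "dnecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling endoribonuclease-dependent cleavage sites from degradome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Degradome sequencing (PARE, GMUCT and related protocols) captures RNA decay
intermediates that carry a 5'-monophosphate (5'P) terminus and reports, per
genomic position and strand, how many fragment 5' ends start there. Two
pathways dominate the 5'P landscape of plant mRNA: decapping (which leaves a
5'P at or near the transcription start site) and endonucleolytic cleavage
(which leaves a 5'P at an internal position). Both kinds of intermediate are
normally degraded within seconds by the cytoplasmic 5'->3' exoribonuclease
XRN4, so neither is easy to observe in wild-type tissue.

`dnecall` implements the genotype-contrast logic that makes the cleavage
products of the endoribonuclease DNE1 visible:

* in an *xrn4* mutant, 5'P intermediates are stabilized — both decapping
  products and DNE1 cleavage products overaccumulate;
* in a *dne1 xrn4* double mutant, decapping products still accumulate but
  DNE1 cleavage products vanish, because the nuclease that creates them is
  gone.

A position is therefore called a DNE1 cleavage site when its 5'P signal
(i) overaccumulates in *xrn4* relative to wild type, **and** (ii) drops in
the double mutant relative to *xrn4*, **and** (iii) survives a set of
artifact filters. All abundances are counts per million mapped tags (CPM,
per-base bins, only the first nucleotide of each read counted), and all
contrasts are per-position log2 fold changes with a 0.01-CPM pseudocount and
skip-both-zero semantics:

    log2FC(p) = log2((a_p + 0.01) / (b_p + 0.01)),  omitted when a_p = b_p = 0.

## The filter cascade

Candidates flow through a fixed cascade (`call_sites()`); every elimination
is recorded in a trace table, so the per-filter survivor counts in the run
manifest are an audit trail, not a re-computation.

1. **Prefilter** — positions with merged *xrn4* CPM < 1 are removed.
2. **XRN4 sensitivity** — keep positions with *xrn4* CPM >= 5 and
   log2FC(*xrn4*/wild type) >= 2.
3. **DNE1 dependence** — keep positions with log2FC(*xrn4*/double) >= 2;
   positions absent from that comparison (both zero) are rejected with
   trace `no-signal-in-contrast`.
4. **Annotation** — candidates must be exonic on a representative
   transcript model; everything downstream works in spliced coordinates.
5. **Decapping/TSS exclusion** — candidates within +/-5 nt (spliced,
   inclusive) of a catalogued decapping site (Cap-PARE CPM >= 5) or
   annotated TSS are removed, so decapping is not misread as cleavage.
6. **Uniqueness** — the 20-mer starting at the site (the 5' end of the
   surviving 3' fragment, read in mRNA sense) must occur exactly once in
   the genome (both strands) and once in the spliced transcriptome.
   A k-mer that spans an exon junction does not occur in the genome at all
   and is likewise removed; the simulator never plants sites within one
   k of a junction, so this conservative rule costs nothing in validation.
7. **Expression check** — one-sided: a candidate is disqualified only if
   its transcript's full-length abundance drops significantly in the double
   mutant (log2FC <= -0.58 and FDR <= 0.05), because only a drop could
   mimic DNE1 dependence. A missing RNA-seq table passes everything with a
   warning.
8. **Classification** — per transcript, only the most abundant surviving
   candidate is kept and labelled `MaxSeq` if it is the transcript's most
   abundant 5'P position overall, or `MajorInternal` if it ranks second
   behind a catalogued decapping position. Anything else is dropped as
   unclassified. Ties in abundance break toward the 5'-most spliced
   coordinate, making the output deterministic.

Filter order only affects the trace, never the final set; a test asserts
order-invariance on simulated data.

**Control sets.** Targets are transcripts with a classified site.
*Nontargets* contain an XRN4-sensitive site whose *xrn4*-vs-double log2 FC
lies in [-0.25, 0.25] — i.e. XRN4 substrates that do not depend on DNE1.
*Others* are XRN4-insensitive: they contain a 5'P site with
*xrn4*-vs-wild-type log2 FC in [-0.25, 0.25]. Priority is
targets > nontargets > others, so the sets are disjoint by construction.
The defining windows are published figure-legend values; which site of a
transcript carries the window test ("contain 5'P sites with no change") is
not fully pinned in the source, and we use *any* qualifying site, which on
simulated data recovers the planted classes almost perfectly.

## Downstream analytics

* **Region assignment** partitions exonic bases of coding transcripts into
  5'UTR / CDS / 3'UTR in spliced coordinates; intron and noncoding-exon
  complete the label set.
* **Metagene profile**: each region is divided into 100 bins of 1% of its
  length; a site increments `floor(100 * relative position)`, clamped to
  bin 99. Bin sums equal the number of assigned sites (a tested
  invariant).
* **Junction profile**: for CDS sites of nuclear protein-coding
  transcripts not coinciding with decapping positions, the spliced distance
  to the nearest downstream exon-exon junction is computed with the
  convention that the last base of the upstream exon has distance 1 — so
  the exon-junction-complex footprint appears as a 25-30 nt peak on this
  axis. Distances beyond 50 nt are excluded from the window count.
* **Sequence windows and motif**: 40-nt spliced sense windows centred on
  the site (site base at 0-based offset 20). The degenerate pentamer
  YGGWG (Y = C/T, W = A/T) is scanned with full IUPAC semantics; offsets
  are reported relative to the site base (offset 0 = motif starting on the
  site). The coarse histogram uses 5-nt bins over the window, the inset
  1-nt bins over +/-5 nt, and `inset_fraction` is the fraction of windows
  with a hit starting in the inset. The published motif figure restricts
  its denominator to "true positive" sequences chosen by an external
  enrichment tool; our fraction is over all windows and is therefore not
  numerically comparable to the published 51%/14%.
* **k-mer differential enrichment** replaces motif-discovery
  expectation-maximization with an exhaustive scan: all 5-7-mers present
  in either set, scored per sequence as presence/absence so the upper-tail
  hypergeometric test is exact, with Benjamini-Hochberg correction jointly
  across all k-mer lengths. Degenerate collapsing (e.g. the four YGGWG
  expansions) is a reporting convenience, not part of the test.
* **Set overlap** reports the upper-tail hypergeometric p, Fisher's exact
  odds ratio, and a seeded Monte Carlo permutation p,
  `(1 + #{draws with overlap >= observed}) / (1 + n_draws)`, drawing
  `|set A|`-sized subsets of the universe — a transparent stand-in for
  Monte Carlo gene-set tools.
* **Half-life comparison** reports group medians, the fraction of
  short-lived transcripts (t1/2 <= 60 min), and a two-sided Wilcoxon
  rank-sum p; `method = "exact"` enumerates all group assignments (n <= 16)
  and is the oracle used in tests.
* **Decapping-abundance shift**: at catalogued decapping positions with
  >= 5 CPM in both mutants and *xrn4*/wild-type log2 FC >= 1, the
  distributions of log2(mutant/wild type) are compared between *xrn4* and
  the double mutant, split into target vs rest transcripts (unpaired
  two-sided Wilcoxon; positions are shared between the genotype tracks,
  so a paired test would also be defensible — the unpaired variant matches
  the generic "Wilcoxon test" wording of the source analyses).

## The synthetic world

The generator (`simulate_annotation()` + `simulate_degradome()`) states a
world rather than tuning one; its defaults are the validation scenario
used by the acceptance tests: 200 multi-exon coding transcripts (30%
DNE1 targets, 30% decapping-only, 40% XRN4-insensitive) on 4 synthetic
chromosomes, three genotypes x 2 replicates at 2 x 10^6 tags per library,
cleavage effect log2 = 3, decapping effect log2 = 3.

Key modelling choices, and why:

* **Mass conservation.** A transcript's total 5'P mass (proportional to a
  clamped lognormal abundance) is identical across genotypes; genotypes
  differ only in how that mass is split between the decapping spike, the
  cleavage spike and the diffuse background. This encodes the observation
  that full-length transcript abundance barely changes across these
  genotypes, and it makes the RNA-seq table honest by construction.
* **Spikes as mass fractions.** The cleavage spike carries 28% of the
  transcript's *xrn4* 5'P mass; the decapping spike carries 25% with a
  +/-40% per-transcript jitter. The jitter is what produces a realistic
  mixture of MaxSeq (cleavage tops decapping) and Major-internal
  configurations. With the default abundance distribution, every planted
  spike exceeds 300 CPM — far above the 20-CPM floor the validation
  scenario promises — while the diffuse background sits near 1-3 CPM per
  position.
* **Background = shared gamma x Poisson.** Each position draws a
  "cleavability" weight from a gamma distribution (shape =
  `bg_dispersion`, default 1) once, shared by all genotypes and
  replicates; counts are Poisson around the library-scaled rate.
  Marginally this is exactly a negative binomial, but because the
  heterogeneity is sequence-driven and shared, genotype contrasts at
  background positions stay centred on zero — which is what makes a
  fold-change-threshold pipeline testable. Independent negative-binomial
  draws per genotype would instead manufacture fold-change outliers that
  no real shared-sequence background produces.
* **Cap-PARE specificity.** 98% of a transcript's Cap-PARE mass sits on
  the planted decapping position. At desk-scale depths, a less specific
  assay floods the >= 5 CPM decapping catalog with one-count flukes and
  the +/-5 nt exclusion then erodes recall — an artifact of scaled-down
  worlds, not of the method.
* **No stabilized 5' fragment.** The fragment upstream of a cut
  contributes no signal, mirroring the difficulty of stabilizing 5'
  fragments in vivo.
* **Optional EJC pattern.** `ejc_protection > 1` multiplies background
  rates 25-30 nt upstream of junctions (renormalized within the
  transcript) to exercise the junction profiler; it is off by default.
* **Uniqueness by construction.** Planted cleavage 20-mers are redrawn
  (outside any planted motif bases) until genome-unique, and sites are
  placed so the whole k-mer lies within one exon.

What the generator does **not** emulate: read-level errors and
multi-mapping beyond the k-mer construction, alternative isoforms,
positional biases of ligation chemistry, and intronic background. A green
recovery test therefore establishes that the cascade's logic and
arithmetic are correct under the stated noise model — not that the
thresholds are optimal for any particular real library.

## Numerical and engineering choices

* Internal coordinates are 0-based, half-open, forward-strand; GFF3/GTF
  are converted at the parser boundary. A 5'P site's genomic coordinate is
  the 5'-most base of the surviving 3' fragment (on minus-strand
  transcripts, the numerically larger end).
* One representative isoform per gene: longest CDS, then longest
  transcript, then smallest id. The source reports per-transcript sites
  without stating isoform resolution; this rule is ours.
* CPM values are kept at full double precision; replicate pooling is the
  mean of per-library CPM (not pooled raw counts) so libraries are
  weighted equally regardless of depth.
* The pseudocount (0.01 CPM) and every threshold are `pipeline_config()`
  fields, so sensitivity analyses need no code changes.
* Every command is deterministic given config + inputs + seed; the run
  manifest's only non-reproducible field is its wall-clock timestamp,
  which the determinism test strips before comparing.
* Monte Carlo routines take an explicit seed and restore the caller's RNG
  state.

## Known limitations

* Whether the published pipeline applied its fold-change filters on merged
  tracks or per replicate pair is not stated; we filter on merged tracks.
* The Fig.-legend-derived control-set rule ("contain 5'P sites with no
  change") is interpreted as *any* qualifying site per transcript.
* The uniqueness filter's GMUCT-length variant (k = 50) is exposed via
  `uniqueness_k` but the validation scenario exercises k = 20.
* Multi-site transcripts are reported only through the trace
  (`secondary-site`); the primary output keeps one site per transcript.
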