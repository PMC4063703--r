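---
title: "Detecting transcription-termination read-through and its genomic context"
author: "tilingRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transcription-termination read-through and its genomic context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one page

`tilingRT` implements the transcriptome-level analysis used to characterise
mutants of the 3'-end processing machinery (e.g. fission-yeast CPF-associated
factors): strand-specific tiling signal over a genome is summarised per gene,
differential expression is called between a mutant and a reference genotype,
and a *read-through index* flags genes where transcription continues past the
normal termination site. The genomic context of the flagged gene sets is then
tested against permutation nulls, and AP-MS peptide matrices are mined for
deletion-dependent co-purification modules.

The pipeline stages, in the order `runPipeline()` chains them:

1. **Normalization.** All tracks (one strand of one array) are quantile
   normalized jointly (`quantileNormalize()`, backed by
   `limma::normalizeQuantiles`): every track receives the across-track mean
   of order statistics, ranks preserved, ties assigned the mean of the tied
   quantile values. Background correction (RMA) is assumed to have happened
   upstream; the readers accept any linear-scale intensities.
2. **Gene summarization.** A gene's expression in one genotype is the mean
   over replicates of the median intensity of the probes whose midpoints fall
   in the gene span, on the gene's own strand (`geneExpression()`).
3. **Differential expression.** The signed fold change is `mut/wt` when the
   mutant is higher and `-(wt/mut)` otherwise, so `FC <= -1.9` reads
   "at least 1.9-fold down". A gene is called when the fold-change threshold
   (default 1.9, inclusive) *and* the significance threshold (default
   p < 0.01, from a pooled-variance t-test on log2 per-replicate values) are
   both met (`callDE()`).
4. **Read-through.** For every gene with an annotated 3'UTR, the ratio of the
   mean 3'UTR signal to the mean ORF signal is computed per replicate and
   averaged, in each genotype (`utrOrfRatio()`). A gene is flagged as having
   a termination defect (`is_gterm`) when the mutant ratio is at least 1.5
   times (inclusive) the reference ratio *and* the ORF shows no expression
   difference, operationalised as "not DE-called on the ORF interval with the
   same thresholds" (`callReadthrough()`). That gate is the only quantitative
   reading of "no difference in the coding region" consistent with the
   pipeline's own thresholds; a `|log2 FC|` cap would be an alternative and
   can be emulated by passing a custom `de` table.
5. **Genomic context.** Three per-gene quantities are computed from the
   annotation alone (`contextObservations()`):
   * `igr` — signed gap between a gene's 5' end and the 3' end of its nearest
     upstream same-strand neighbour (negative when the spans overlap);
   * `igr_term` — signed gap between a gene's 3' end and the 3'-facing
     boundary of the first downstream gene in reverse orientation (negative
     exactly for convergent overlapping pairs);
   * `f_as` — fraction of the gene span covered by the union of
     opposite-strand gene spans, in [0, 1].
   The median of a quantity over a flagged gene set is compared with medians
   of random gene sets of the same size (`permutationMedianTest()`, default
   10,000 sets), and antisense-coverage distributions are compared with a
   two-sample Kolmogorov-Smirnov test against the pooled values of the random
   sets (`ksSetVsNull()`).
6. **Co-purification.** Unique-peptide matrices are filtered against a no-tag
   control (any prey seen in the control is discarded as non-specific) and
   deletion dependencies are inferred: prey present in the wild-type
   purification (>= 2 unique peptides by default) and absent in a deletion
   background depends on the deleted gene (`inferDependencies()`). Mutually
   dependent proteins form modules (`dependencyModules()`), the signature of
   a sub-module that detaches from its host complex as a unit.

## Data containers

`GenomeAnnotation` holds one model per gene (ORF, optional UTRs, span =
ORF plus UTRs) as parallel `GRanges`, with chromosome lengths in the
`Seqinfo`; GFF3 in/out goes through `rtracklayer`. `SignalSet` extends
`RangedSummarizedExperiment`: rows are width-1 probe midpoints (stranded),
columns are arrays (genotype x replicate), the assay is the linear intensity.
`PeptideMatrix` is a long-format (bait, background, prey, peptides) store.

Coordinates are 1-based inclusive throughout (the GFF3/GRanges convention);
all reported distances and overlaps are convention-independent base-pair
counts, so nothing downstream depends on this choice. It buys native
interval arithmetic (IRanges) and lossless GFF3 round trips.

## Definitions where the natural-language description is ambiguous

* **"Directly upstream".** The upstream same-strand partner is the nearest
  same-strand gene lying upstream, irrespective of intervening
  opposite-strand genes. `skipOpposite = FALSE` instead requires the nearest
  upstream gene on *any* strand to be the same-strand one. A gene slightly
  overlapping the focal gene's 5' end still counts as upstream (both its
  ends must lie 5' of the focal gene's corresponding ends), which is what
  makes negative IGR values well-defined.
* **"First downstream reverse gene".** Among opposite-strand genes whose span
  reaches to or beyond the focal 3' end, the one with the smallest signed
  gap; this is the gene a read-through transcript runs into, including the
  convergent-overlap case.
* **"Average signal" in the read-through ratio.** Arithmetic mean of probe
  intensities per region and replicate, then the per-replicate ratios are
  averaged (`stat = "median"` is available). Replicate handling is not
  dictated by the ratio's definition; averaging ratios rather than signals
  keeps the statistic scale-free per replicate.
* **Probe-to-region assignment** is by probe midpoint: strand-safe, and
  independent of probe width bookkeeping.
* **No additional gates.** No minimum mutant ratio or minimum UTR intensity
  is required for a gTERM call beyond the ratio-of-ratios and the ORF gate
  (an intensity floor of 1e-6 guards the ratios).
* **Ties** (two pairing candidates at equal distance) resolve by
  lexicographic gene id, making every output deterministic.
* **Self-dependencies** are excluded in `inferDependencies()`: the deleted
  gene's own protein is trivially absent in its deletion background and
  carries no information about complex architecture.

## Statistical choices

* **Empirical p-values.** Sampled permutation tests report the add-one
  estimate `(k + 1) / (n + 1)` (never exactly zero) *and* the reporting-style
  bound `"< 1/n"` when no null median is as extreme as the observation, so
  both conventions are visible. Exhaustive mode (all subsets, guarded to
  10^6) reports exact `k / n_subsets`. Ties between a null median and the
  observed value count as extreme (conservative). Random sets are sampled
  without replacement within a set and independently across sets.
* **Choice of t-test.** The default is the pooled-variance t on log2
  per-replicate values. With three replicates per genotype the Welch test's
  true size at alpha = 0.01 falls well below nominal (its Satterthwaite
  degrees of freedom are noisy at n = 3), which both wastes power and makes
  the null-calibration property fail; the pooled t is exact under the
  equal-variance noise model the generator implements and is a reasonable
  default for arrays processed through a common pipeline. `welch_t_on_log2`
  and `wilcoxon_ranksum` remain available. No multiple-testing correction is
  applied by default (calls gate on raw p plus the fold-change threshold);
  Benjamini-Hochberg is available via `adjust = "BH"`.
* **Rank tests.** The signed-rank departure-from-zero test removes zeros and
  uses the exact null for n <= 25 without ties, a tie-corrected normal
  approximation otherwise; the Mann-Whitney comparison is exact for a
  smallest group of <= 8 without ties. Both delegate to `stats::wilcox.test`
  and are checked in the test suite against full enumeration oracles (all
  2^n sign assignments; all C(n1+n2, n1) rank assignments).
* **KS pairing.** The flagged set's `f_as` values are compared against the
  pooled values of the random sets (the alternative, set vs whole genome, is
  a one-liner with `ksSetVsNull()`). `f_as` is computed from the annotation;
  computing it from observed antisense signal instead would require a
  signal-threshold convention the data do not pin down, but the generator
  does place antisense transcription signal so a signal-based variant can be
  exercised.

## What the generator emulates — and what it does not

`simulateAnnotation()` lays out 5'UTR + ORF + 3'UTR gene models
left-to-right with random strands and plants the three structures the
context statistics detect: a set with deliberately short upstream same-strand
gaps (the short-gap genes and their predecessors are forced to the plus
strand, because for a minus-strand gene the left-hand gap would be its
*downstream* side), convergent overlapping antisense partners for most
read-through genes (focal genes forced to the plus strand so the partner
extends into free space), and antisense genes exactly covering a subset of
the under-expressed set. Chromosome lengths are derived from the layout, so
packing can never fail. `simulateSignal()` draws a per-gene baseline
(log2 ~ N(10, 1)) over a flat intergenic background (log2 = 4), adds
whole-gene +/- log2(fold) effects for DE genes and a 3'UTR-only +log2(fold)
effect for read-through genes (mutant only), then per-probe, per-array
Gaussian log2 noise. Injected folds are therefore exact in expectation and
exactly recovered in the noise-free limit.

Defaults describe the benchmark conditions used by the test suite and the
acceptance script: 500 genes on 3 chromosomes, 20 bp probe spacing,
triplicates, log2 noise sd 0.1, 47 under- and 14 over-expressed genes at
3-fold, 50 read-through genes at 3-fold, short gaps of 1-30 bp versus
normal gaps of 300-1500 bp, 35% of the under-expressed set fully antisense
covered. The DE benchmarks run on 2,000-gene genomes (a ~3% DE fraction):
quantile normalization maps values through ranks, so when a tenth of a small
genome shifts three-fold the displaced rank mass visibly compresses the very
fold changes being tested — an inherent property of the method, mild at
realistic genome sizes, which the 500-gene read-through benchmark does not
suffer because 3'UTR probes are a small fraction of the signal mass.

Not modelled: probe-level affinity or GC effects, cross-hybridization, RMA
background structure, transcript isoforms, correlated replicate effects, and
expression-coupled neighbours (the partner log-ratio test therefore has no
injected effect to find; on simulated data its p-value is only
approximately uniform because conditioning a gene set on DE calls mildly
biases which baselines enter the ratio). Passing the recovery benchmarks
shows the statistics and thresholds behave as designed under this noise
model, not that real tiling arrays are this clean.

## Degenerate inputs and numerical conventions

Regions with no probe summarise to `NA` and flow through as "unmeasured" /
"excluded" rather than errors. Genes without an annotated 3'UTR stay in the
expression analysis but are excluded from the read-through universe. Zero
within-group variance on the log2 scale yields p = 1 when the group means
agree and p = 0 otherwise (the noise-free limit). An all-zero log-ratio
vector yields p = 1 with a warning. Intensities are floored at 1e-6 before
any ratio. The permutation test seeds every draw; an unset seed is generated
and reported so a run can always be reproduced.

## Limitations

The gTERM call inherits the DE gate's behaviour: anything that distorts
ORF-level fold changes (including quantile normalization at high DE
fractions) can veto true read-through genes. IGR statistics require the
relevant partner to exist; genes at chromosome ends or without a reverse
downstream gene drop out of the universe (counts are reported). The
co-purification logic is presence/absence on unique-peptide counts — it
deliberately does not model abundance, so partial dissociation
(`rule = "fold_drop"`) is off by default and a single-peptide wild-type
identification never seeds an edge.
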