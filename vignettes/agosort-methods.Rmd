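---
title: "agosort: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{agosort: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what each stage computes, under which assumptions, which knobs matter, and
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The experimental design being modeled

The target experiment profiles small RNA from adult female mosquito abdomens
at 0, 12, 24, 36, 48 and 72 h after a blood meal. At each time point three
RNA pools are sequenced: total cellular small RNA, and RNA
co-immunoprecipitated with Argonaute 1 or Argonaute 2 — 18 libraries in all.
The Ago-IP pools proxy the RISC-loaded population, so comparing a strand's
representation across pools reads out its sorting, and comparing time points
reads out differential loading during blood-meal digestion and egg
maturation.

## Quantification

Reads are collapsed (`_x<count>` FASTA dialect), adapter-trimmed (leftmost
exact occurrence of the adapter prefix, minimum 6 nt overlap), filtered for
ambiguous bases, and size-selected to 15–30 nt inclusive. Two size windows
circulate for this design (gel selection 15–30 nt; library methods
sometimes state 20–30 nt); the default is 15–30 because observed length
distributions extend to 15 nt, and the bounds are plain arguments.

The aligner is hairpin-first and exact: a read is assigned to a mature
strand when its maximal exact match to the precursor begins within ±3 nt of
the annotated mature 5' end and any unmatched 3' suffix is ≤ 3 nt. Two
deliberate policies:

* **Template precedence.** A 3' suffix is recorded as a non-templated tail
  only if it cannot be extended along the hairpin. This prevents
  over-counting 3' additions at the price of misclassifying the genuinely
  ambiguous case (an added nucleotide identical to the next template base) —
  undecidable from sequence alone; the simulator marks such reads and the
  recovery tests score only unambiguous ones.
* **Multimapping.** A read matching k strands gets weight 1/k to each, so
  total read mass is conserved (an invariant the tests check).
* A 14-nt minimum templated match keeps chance hits from short background
  reads out; with the ±3 window and ≤3 tail this bound is rarely binding.

TPM is `count / mapped_total × 10⁶`. What counts as `mapped_total` is not
uniquely determined by the published description ("mapped reads"): the
package defaults to all categorized reads (miRNA + repeats + ncRNA + mRNA +
unannotated, i.e. everything that would map at genome scale), with
`"annotated"` and `"mirna"` bases available. On the `"mirna"` basis strand
TPMs sum to exactly 10⁶ per library, which is the invariant the tests pin.
The abundance filter drops strands below 20 TPM in *every* library; "< 20
discarded" is read literally, so exactly 20.0 survives.

## Strand curation and Ago sorting

For each precursor the strand with the higher mean total-pool TPM across
time points is miR; the other is miR\*; single-strand loci are miR. Exact
ties go to the 5p arm (an arbitrary but deterministic rule; the upstream
convention is unstated). Curation is invariant to library order and uniform
TPM scaling.

Partitioning uses time-point-mean TPM in the two IP pools:
`ago1_fraction = ago1 / (ago1 + ago2)`, biased toward Ago1 above 0.70 and
toward Ago2 below 0.30. The single pooled fraction (not per-library calls)
defines the biased sets because those sets feed one composition analysis;
per-library fractions are still emitted for heatmap-style display.

miR\* enrichment per strand is a one-sided Fisher exact test on
`[[star, other] in Ago pool; [star, other] in total]`, implemented as the
hypergeometric tail; the test suite checks it against an independent
`choose()`-based enumeration to 1e-10. The headline flag uses raw p ≤ 0.01
to match the published threshold; BH q-values are reported alongside.

Position-1 nucleotide bias of a strand set is tested with a two-sided exact
binomial against the background frequency among all detected miRNAs. The
original analysis reports p-values without naming a test; the binomial is
the minimal choice and is labeled as such — the package does not claim to
reproduce those printed p-values.

Duplex pairing profiles score mature position i as 1 iff that hairpin base
pairs with a base of the partner arm in the dot-bracket structure; bulges
and mismatches are 0; profiles aggregate as per-position medians over
positions 1–22. When a locus arrives without a structure, a Nussinov
maximum-pairing fold (minimum loop 3, Watson–Crick + G:U, ties toward
5'-most pairing) is used and flagged: it is a combinatorial fallback for
synthetic inputs, never claimed equivalent to a thermodynamic MFE fold.

## isomiR taxonomy

The reference per strand is the most abundant assigned sequence pooled over
all libraries (ties: longer, then lexicographic) — deliberately global, one
reference per miRNA. Relative to it, each end classifies independently:
5' template shifts of ±1–3 nt; 3' template shifts, 1–3 nt trims, or
non-templated additions of 1, 2, or ≥3 nt. Per-library class fractions
partition to 1 by construction. 5' non-template additions are only flagged,
since the modeled data show strong 5' homogeneity.

## Differential loading without replicates

The design has no biological replicates, so the package implements an
MA-plot z-test with a random-sampling (binomial) null: for counts k₁, k₂
from totals n₁, n₂,

M = log₂(k₁/n₁) − log₂(k₂/n₂), A = their mean,
Var(M) = [(1−p̂₁)/k₁ + (1−p̂₂)/k₂] / ln²2, z = M/√Var, two-sided normal p.

Numerical choices: a pseudo-count of 0.5 replaces **zero counts only**, so
non-zero data are untouched and equal proportions give exactly M = 0; the
variance is the per-observation binomial approximation rather than an
A-conditional smoothing, so output is labeled "MARS-style" rather than
claimed identical to DEGSeq. Type-I calibration at α = 0.05 (within
[0.035, 0.065] over thousands of null simulations) and monotone power in
fold change are enforced by the acceptance tests. BH correction is applied
across strands within each (pool, time) comparison; the published scope of
correction is unstated. Flags require |M| ≥ 2 (>4-fold) with q ≤ α at ≥1
time point; a raw-fold-only flag is emitted in parallel because the
original flag's significance qualification is also unstated. Every DE
result carries a no-replicates warning attribute.

Fold-change profiles cluster by Euclidean complete-linkage `hclust`, cut at
k = 3 by default (three major temporal classes is the modeled outcome).

## Novel-miRNA retention and conservation

Hairpin prediction itself is upstream (external predictors); the package
implements retention: ≥2 predictors, ≥20 perfectly aligned reads in **more
than one** Ago-IP library (strict reading), free energy strictly below
−20 kcal/mol, and a "vast majority" of reads on the arms — quantified as
arm read fraction ≥ 0.9, a number the source does not give; it is a
configurable, logged default. Energies are inputs, not computed. The
packaged candidate table (13 loci with printed energies) drives the worked
example: the energy rule alone retains all 13.

Reciprocal best hit: top hit = lowest e-value, ties by higher identity then
subject id (BLAST output order is not guaranteed); found iff both
directions pass identity ≥ 80 and e-value ≤ 0.1 and the reverse top hit
returns the query. Untested (miRNA, genome) pairs are reported as
`untested`, never silently dropped.

## What the simulator emulates — and what it does not

`paper_like_config()` encodes the stated world: 18 libraries; 60 hairpin
loci; 200,000 reads per library; duplexes of 22-nt arms with 2-nt 3'
overhangs, loops of 8–15 nt; mono-addition probabilities 0.35 (Ago2) and
0.08 (total, Ago1); trim probability 0.15; a 3-locus cluster upregulated
8-fold from 12 h; background fractions 0.856/0.155/0.795 chosen so the
baseline miRNA share of each pool matches the observed pool compositions
(14.4% total, 84.5% Ago1-IP, 20.5% Ago2-IP).

Calibrations fixed once, analytically, before any test was run:

* `arm_asymmetry_sd = 12.66` (log2): solves E[1/(1+2^|x|)] = 0.062,
  x ~ N(0, sd), so the *expected* total-pool miR\* share matches the
  published 6.2%. The implied arm ratios (often 100–1000:1) match
  steady-state miR:miR\* asymmetry, where passenger strands are largely
  degraded.
* Ago-logit intercept 1.29 and `is_star = −0.78`: solved from the pool-wise
  star shares (5.0% in Ago1-IP, 10.3% in Ago2-IP) given the 6.2% total
  share. Terminal-nucleotide (±0.9 for 5'-U/5'-C) and duplex-structure
  (±0.7 for position-9 / 3'-end mismatches) coefficients are moderate
  values with the reported directions; a per-strand logit random effect
  (sd 1.5) supplies the strand-to-strand diversity needed for non-empty
  >70% biased sets in both directions.

Modeling decisions worth knowing:

* Baseline locus abundance is log-normal (meanlog 0, sdlog 1.5) — a
  stand-in, not a claim; real per-miRNA abundance distributions are not
  published for this design. Because a few loci dominate each realized
  pool, realized star shares scatter widely around the 6.2% expectation
  between seeds; the acceptance criteria therefore test directions and
  per-read rates, not realized pool shares.
* Counts are multinomial at exact library depth, making depth conservation
  a hard invariant.
* Background is a fixed **absolute** pool anchored to make up the
  configured fraction of the 0 h library. Anchoring the fraction per
  library instead would renormalize upregulated loci away and compress
  their fold changes; with absolute anchoring a locus still self-compresses
  only through genuine compositionality (bounded by the miRNA share of the
  library).
* Cluster membership is drawn among loci of at-least-median baseline
  abundance, since the modeled upregulated cluster is a well-expressed one.
* Non-templated additions draw uniformly from the 3 non-template options
  (all 4 at the hairpin 3' terminus, where no template exists), so
  generated classes are unambiguous and recovery can be scored exactly.
* Not simulated: sequencing error, quality scores, 5' heterogeneity,
  piRNA/tiRNA classes, genome multimapping. A green recovery test
  establishes that the pipeline inverts *this* generative model at desk
  scale — not that it reproduces archive-scale results.

## Known limitations

* The aligner is exact-match by design (hairpin-first); it does not replace
  genome-scale alignment and tolerates no internal mismatches (editing-type
  variants are out of scope).
* The MARS-style variance is approximate at very low counts even with the
  pseudo-count; the calibration criterion constrains counts ≥ 50.
* The Nussinov fallback can pair loop-adjacent bases a thermodynamic model
  would not; profiles computed from fallback folds are flagged.
* Fisher tests on weighted (fractional) counts round to integers; with
  heavy multimapping this loses information, but simulated multimapping is
  negligible.
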