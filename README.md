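# agosort

Small RNA loaded into an RNA-induced silencing complex acts through an
Argonaute protein, and which Argonaute a mature miRNA strand ends up in
determines what it can do. In *Anopheles gambiae* — the major African malaria
vector — Ago1 is the main miRNA carrier while Ago2 is dominated by
endogenous siRNAs, yet a reproducible subset of miRNAs and passenger (miR\*)
strands sorts into Ago2, guided by sequence and duplex-structure features.
`agosort` is an R package for analyzing exactly this kind of experiment:
small-RNA sequencing of a total-RNA pool plus Ago1 and Ago2
immunoprecipitates, sampled over a blood-meal time course.

It provides, as composable functions with a thin CLI:

* **Quantification** — collapsed-read FASTA I/O, 3' adapter trimming, 15–30 nt
  size selection, a hairpin-first exact aligner with a ±3 nt 5' window and
  ≤3 nt non-templated 3' tails (template extension takes precedence over
  tail calls), category annotation, TPM normalization
  (`tpm = count / mapped_total × 10⁶`), and the "discard < 20 TPM in all
  libraries" filter.
* **Strand sorting** — miR/miR\* curation by mean total-pool abundance,
  Ago1/Ago2 partition fractions with >70% bias calls, one-sided Fisher exact
  tests for miR\* enrichment in an Ago pool versus total RNA (raw p ≤ 0.01
  headline flag, BH q-values alongside), 5' nucleotide composition of biased
  strand sets, and per-position duplex pairing profiles from Vienna
  dot-bracket structures (with a clearly flagged Nussinov maximum-pairing
  fallback for toy inputs).
* **isomiR classification** — per-read 5'/3' variant classes relative to the
  most abundant isoform: template-directed shifts of 1–3 nt, 3' trimming,
  and non-templated single/dual/longer 3' additions.
* **Differential loading** — a replicate-free MA-plot z-test ("MARS-style":
  `M = log2(k1/n1) − log2(k2/n2)`, binomial variance, two-sided normal p)
  against the 0 h baseline, BH correction per comparison, >4-fold flags, and
  hierarchical clustering of fold-change profiles.
* **Discovery** — the novel-miRNA retention rules (two predictors, ≥20
  perfectly aligned reads in more than one Ago-IP library, hairpin free
  energy < −20 kcal/mol, reads concentrated on the arms) and
  reciprocal-best-hit ortholog calls from BLAST outfmt-6 tables
  (identity ≥ 80%, e-value ≤ 0.1, both directions).
* **A ground-truth simulator** — 18 libraries (3 pools × 6 time points at 0,
  12, 24, 36, 48, 72 h post blood meal) with known strand asymmetry,
  logistic Ago-sorting biases (5'-U toward Ago1, 5'-C toward Ago2, miR\*
  toward Ago2, structural mismatch effects), pool-specific 3' mono-addition
  rates (35% in Ago2, 8% elsewhere), 3' trimming, an upregulated 3-locus
  cluster, and non-miRNA background — so every downstream stage is testable
  at desk scale without downloads.

## Worked example

```r
library(agosort)
res <- run_demo(seed = 1)          # simulate + quantify + sort + isomiR + DE
res$recovery
```

Output on this machine (seed 1, 60 loci, 200,000 reads per library):

```
miR/miR* label accuracy (arm ratio >= 4): 1.000 (n = 71)
miR* read share  total 0.018 | ago1 0.011 | ago2 0.040
3' mono-addition total 0.081 | ago1 0.080 | ago2 0.350
strands retained at 20 TPM: 87
Ago-biased strands (>70%): ago1 50, ago2 14
planted cluster: sim-mir-025,sim-mir-042,sim-mir-059 | up at all post-onset points: TRUE | co-clusters at k=3: TRUE
miR* strands tested for Ago2 enrichment: 26; enriched at p<=0.01: 14
```

Reading this: the pipeline re-derives every planted truth from raw reads
alone — every detectable strand with at least a 4-fold arm asymmetry gets
the correct miR/miR\* label; the miR\* read share is higher in the Ago2-IP
libraries than in total RNA (the direction the Fisher tests flag per
strand); the Ago2 pool shows the configured 35% single-nucleotide 3'
addition rate versus ~8% elsewhere; and the three loci planted as an
8-fold-upregulated cluster are flagged up (|log2FC| ≥ 2, q ≤ 0.01) at every
post-onset time point and fall into one cluster at k = 3. Realized pool
shares (e.g. the 1.8% miR\* share here vs the ~6% expectation) vary between
seeds because a handful of loci dominate each simulated pool, exactly as in
real small-RNA libraries.

The same stages are scriptable:

```sh
inst/scripts/agosort simulate --out sim/ --seed 7
inst/scripts/agosort quantify --reads sim/ --hairpins sim/hairpins.fa \
    --mature sim/mature.gff3 --out quant/
inst/scripts/agosort demo --out demo/ --seed 7
```

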