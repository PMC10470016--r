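---
title: "ceRNAnet: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNAnet: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAnet)
```

ceRNAnet implements a desk-scale lncRNA analysis pipeline for two-group
bulk RNA-seq studies of the kind used to probe innate-immune signaling in
the insect gut: an antibiotic-reared group ("A") against a normally reared
control ("C"), three biological replicates each. This vignette is the
package's own account of the models it uses, the thresholds it applies,
and the choices made where the underlying procedures are conventions
rather than mathematics.

## Coding-potential consensus classification

Transcripts first pass a candidate filter — at least 2 exons and a spliced
length strictly greater than 200 bp — and are then labeled by a 3-of-4
consensus over four lines of evidence supplied as inputs (the classifiers
themselves are not run by this package):

* CNCI score: coding iff > 0,
* CPC score: coding iff > 0,
* txCdsPredict score: coding iff > 500,
* Pfam domain hit: coding iff present.

At least three coding votes gives mRNA, at least three noncoding votes
gives lncRNA, and a 2–2 split is *ambiguous*. Two conventions are fixed
here and covered by boundary tests: a score exactly at its threshold is a
noncoding vote (the coding call is a strict inequality), and a Pfam hit is
exactly one coding vote, with absence one noncoding vote — the only
reading that yields a 4-way vote. Ambiguous transcripts are excluded from
both classes but always reported; the candidate filter is applied to all
transcripts, not only lncRNA candidates (configurable via the
`min_exons`/`min_length` arguments).

## Normalization and differential expression

Both TPM and FPKM are provided. TPM divides the per-transcript read rate
(count/length) by the per-sample rate total, so every column sums to one
million; FPKM is `count * 1e9 / (length * library_size)`. The
low-expression filter and all downstream expression stages run on FPKM:
a transcript is dropped iff its FPKM is below 1 in *every* sample.

Differential expression between the two groups uses:

* fold change on group-mean FPKM with a pseudo-count of 1:
  `log2fc = log2((mean_A + 1) / (mean_C + 1))`;
* a Welch two-sample t-test on `log2(FPKM + 1)`;
* the call rule `up` iff `log2fc > 1` and `p < 0.001`, `down` iff
  `log2fc < -1` and `p < 0.001`, otherwise `ns`. Both inequalities are
  strict; no multiple-testing correction is applied by default
  (Benjamini–Hochberg is available via `adjust = "BH"`).

The Welch test is a deliberate, documented simplification: the moderated
negative-binomial machinery of dedicated DE packages is out of scope here,
and the package is validated by parameter recovery on synthetic data
rather than by equality with any particular tool. Two consequences
matter in practice. First, at the study design of n = 3 per group the
Welch test has between 2 and 4 degrees of freedom, where the critical t
for p < 0.001 ranges from 8.6 up to 31.6; even extreme fold changes then
fail the 0.001 cut whenever the variance estimate is unlucky. Recovery
experiments in the test suite therefore run at n = 5 per group, where the
test has genuine power; the conservative behavior at n = 3 is a property
of the test, not a bug, and is asserted only loosely (null calibration is
checked at n = 10 per group, where the p-values are approximately
uniform). Second, FPKM is a relative measure, so fold changes are only
interpretable when the two groups sequence comparable read mass; the
synthetic generator plants direction-balanced differential expression for
exactly this reason (below).

qPCR validation data are supported through `ddct()`: per sample,
`dCt = Ct_target − Ct_reference`; per gene, `ddCt` subtracts the
control-group mean `dCt`; the reported relative expression is `2^−ddCt`.

## lncRNA target prediction

**Cis targets.** A gene is colocated with a lncRNA when its span
intersects the window from 10 kb upstream to 20 kb downstream of the
lncRNA, with upstream/downstream oriented by the lncRNA's strand. The
window is anchored on the lncRNA (gene-anchored windows can be had by
swapping the arguments); overlapping genes count as cis with distance 0.

**Trans targets.** A gene outside the cis window is a trans target when
the RNA–RNA hybridization energy is strictly below −30 kcal/mol (the
threshold is exposed as an argument; the published rule is unitless and
kcal/mol is the convention of RNA hybridization tools). The built-in
energy model scans all antiparallel Watson–Crick duplex windows formed by
*contiguous* complementary stretches and scores them with embedded
Turner-style nearest-neighbor stack energies, returning the most negative
helix sum. Loops, bulges and G–U wobbles are deliberately not modeled —
this is a screening heuristic, not a secondary-structure predictor — and
`trans_targets()` accepts a table of externally precomputed energies so
results from RNAplex/IntaRNA-class tools can be plugged in unchanged.

**Coexpression targets.** A pair is reported when signed Pearson r ≥ 0.6
*and* signed Spearman rho ≥ 0.6 (average ranks for ties). The signed
reading follows the literal rule; `unsigned = TRUE` thresholds |r|
instead. Correlation thresholds at n = 3 samples are near-degenerate
(|r| ≥ 0.811 is needed for p < 0.05 even at n = 6), so correlation-based
stages are only meaningful with at least 5–6 profiles.

**Overlap classes.** The four published category names are operationalized
as a containment-by-strand grid: same strand with one span containing the
other is `overlap`, opposite strand with containment `anti-overlap`,
partial intersections `incomplete`/`anti-incomplete`. The names are used
in the field without formal definitions; this grid is the package's
documented reading and is frozen by an exhaustive truth-table test.

## ceRNA triads

A (lncRNA, miRNA, mRNA) triple is a ceRNA triad when all of:

1. lncRNA and mRNA have the same DE direction (`up` or `down`),
2. the miRNA has the opposite direction,
3. the miRNA targets the mRNA and the lncRNA (maps are inputs; miRNA
   seed-match prediction is out of scope),
4. both miRNA-facing Pearson correlations satisfy r ≤ −0.6,
5. both correlation p-values (two-sided t approximation on n − 2 df) are
   below 0.05.

The published magnitude rule (|r| ≥ 0.6) does not fix the sign; the
sponge model implies the miRNA anti-correlates with both partners, so the
signed rule is the default and `unsigned = TRUE` restores the magnitude
reading. The lncRNA–mRNA correlation is not additionally thresholded —
only their trend equality is required. Networks export as Cytoscape-ready
edge/node tables and SIF.

## Pathway summaries and enrichment

`pathway_de_table()` counts distinct DE ids per pathway and reports
ratios against the study-wide DEL/DEM totals, rounded to 8 decimals —
the worked-example arithmetic the acceptance suite checks against the
published immune-pathway table. `hypergeometric_enrichment()` is a
generic one-sided over-representation test, `P(X >= k)` under sampling
without replacement, with the universe supplied by the caller (the
expressed transcripts after the FPKM filter is the recommended choice);
terms with raw p < 0.01 are flagged, BH adjustment optional.

## Protein characterization

`translate_orf()` validates a complete ORF (ATG start, stop end, length
divisible by 3, no internal stops) and translates it: a complete ORF of
L bp encodes L/3 − 1 amino acids. Molecular weight is the sum of average
residue masses plus one water; the isoelectric point is the bisection
root of the Henderson–Hasselbalch net-charge function on [0, 14] to 0.01
pH. Both constant sets live in one file (`genechar-constants.R`) so they
can be tuned for parity with other calculators; published MW/pI values
depend on the exact deposited sequences, so numeric parity with any
specific server is a non-goal. Of the 25 published (ORF bp, aa) pairs in
the shipped Toll/Imd gene table, 24 satisfy the complete-ORF rule
exactly; the Imd row (621 bp, 207 aa) is internally inconsistent as
published (621/3 − 1 = 206) and `orf_aa_consistency()` flags it rather
than silently "correcting" either number.

Toll receptor architectures are validated as ≥ 1 LRR, exactly one
transmembrane span, exactly one TIR domain, TIR after the TM. The P/sP/sPP
subfamily nomenclature is descriptive in the literature, not operational;
the package's documented heuristic is: ≥ 15 LRRs and ≥ 1100 aa ⇒ P;
≥ 15 LRRs but shorter ⇒ sPP; fewer LRRs ⇒ sP (thresholds are arguments).
This rule reproduces the published subfamily labels of all six shipped
Toll receptors.

## Microbiota integration

`gene_microbe_matrix()` computes Pearson r with two-sided t-approximation
p-values for every gene × genus pair over shared samples and annotates
them with the conventional stars (`*` p < 0.05, `**` p < 0.01, `***`
p < 0.001; boundaries belong to the weaker category, so the three cuts
partition (0, 1] exactly). Genus abundances are used as supplied — no
CLR or other compositional transform — mirroring direct-correlation
practice; be aware that correlations on relative abundances carry
compositional artifacts. `select_features()` operationalizes "most
changed genera" as the top-k absolute difference in group-mean abundance,
a choice made here because the selection statistic is not standardized in
the field.

## The synthetic-data generator

Every stage above is validated by parameter recovery against planted
truth, so the generator is first-class, tested code. It emulates:

* a two-group design with (by default) 3 replicates per group;
* negative-binomial counts, `NB(mean, size = 1/dispersion)`, with
  log-normal per-sample library size factors (sigma 0.2) to exercise
  normalization;
* a planted DE fraction with ±`lfc_location` log2 group-mean shifts.
  Planted directions are balanced (half up, half down, matched base
  means): FPKM is relative, so unbalanced planted read mass would shift
  the apparent fold change of every unperturbed transcript;
* classifier scores drawn uniformly on the correct side of each threshold
  with independent per-classifier wrong-side probability `noise_rate`;
* genomic placement of lncRNAs in three strata — a cis fraction inside
  the 10/20 kb window of an mRNA, an overlapping fraction (cycling
  contained/partial × same/opposite strand), and isolated loci > 30 kb
  from every mRNA;
* a miRNA layer whose planted triads anti-correlate with the standardized
  mean of their partners' log2-FPKM profiles at a target magnitude
  `triad_r`, plus decoys violating exactly one rule; the noise component
  is orthogonalized in-sample so the planted coefficient is the realized
  sample correlation, making power statements exact rather than
  Fisher-z-noisy at n = 6;
* genus abundance tables with planted gene–genus correlations of chosen
  sign and magnitude (same orthogonalized construction) on a log-normal
  background.

What the generator does *not* emulate: raw reads, alignment or assembly
artifacts, isoform structure shared between transcripts, GC or length
biases, batch effects, or compositional coupling between genera. Passing
the recovery suites therefore demonstrates the pipeline's rules and
arithmetic are implemented correctly under the stated noise model — not
that the thresholds are well-powered on any particular real data set.

### Problem sizes and conditions used by the test suite

All suites run at desk scale, chosen once:

* exact-closure runs (classify → DE → triads recovers planted truth
  exactly): 200 transcripts, 5 replicates per group, planted |lfc| = 6,
  dispersion 5e-4, `triad_r = 1`, classifier noise 0. The strong effect
  and n = 5 give the Welch test enough degrees of freedom that exactness
  is a fair demand (see the DE section);
* binomial vote checks: 1000 transcripts at noise 0.1 and 0.5 against the
  closed-form 3-of-4 error rates;
* triad recovery at planted anti-correlation 0.9: 20 seeds, dispersion
  0.01, 6 samples; miRNA profiles correlate on log2 counts because a
  10-member miRNA panel is too small for within-panel FPKM (the planted
  profiles dominate the panel's read mass, and the resulting composition
  noise attenuates every correlation);
* microbiota power: 50 seeds at planted r = 0.95, n = 6; the null check
  compares against the exact t-distribution tail rather than a rounded
  rule of thumb;
* DE null calibration: 2000 transcripts at n = 10 per group.

## Numerical conventions

Ties in Spearman ranks use average ranks. Zero-variance profiles are
flagged (warning + NA or skip), never imputed. A t-test with zero
variance in both groups returns p = 1 with a warning. TPM columns sum to
1e6 within 1e-6 relative error. The pI bisection tolerance is 0.01 pH.
Every generator consumes a seed from its configuration and restores the
caller's RNG state, so identical configurations give byte-identical
output files.

## Known limitations

* The Welch t-test is underpowered at n = 3 per group relative to
  moderated NB tests; results at the original design scale are
  directional screens, not calibrated inference.
* The duplex-energy scan has no loop/bulge states, so it underestimates
  binding for imperfect duplexes; use precomputed energies for serious
  trans-target screens.
* Correlation thresholds at 6 samples sit close to the p < 0.05
  significance boundary (|r| = 0.811), so ceRNA and microbiota edges near
  r = 0.6 are fragile by construction.
* The P/sP/sPP subfamily rule is a heuristic stand-in for an
  LRR-arrangement classification that has no published operational
  definition.
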