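---
title: "Screening substrate-degradation gene clusters from label-free proteomics"
author: "proteoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening substrate-degradation gene clusters from label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoscreen)
```

## The problem

Bacteria that catabolise an unusual substrate — an aromatic pollutant, a
plant hormone, a xenobiotic — usually carry the responsible genes in one
or a few operon-like clusters, and they usually induce those genes only
when the substrate is present. That makes the cluster discoverable from
comparative proteomics alone: grow the strain on the substrate and on a
reference carbon source, quantify the proteome in both conditions, and
look for a run of neighbouring genes whose proteins are all strongly
induced. `proteoscreen` implements that screen as a reusable pipeline:

1. **DAP calling** — classify every quantified protein as up, down,
   unchanged, unique to one condition, or undetected
   (`call_daps()`);
2. **window detection** — slide fixed-length gene windows along the
   genome and keep regions dense in induced proteins
   (`find_candidate_clusters()`);
3. **AFCL ranking** — score each candidate by its average fold-change
   level and select the top-ranked candidate of sufficient size
   (`screen_clusters()`);
4. supporting computations: term over-representation
   (`hypergeom_enrich()`), qPCR confirmation (`delta_delta_ct()`), and
   run-level QC (`qc_report()`).

A synthetic-data generator (`simulate_dataset()`) produces datasets with
the same statistical structure plus ground truth, so every stage of the
pipeline is testable without any external download.

## Differential abundance model

The input is a protein × run intensity matrix with an explicit missing
state: `NA` means *not observed in that run*, which is distinct from an
observed zero. Runs carry condition, biological-replicate and
technical-replicate labels; the default design is 2 conditions × 2
biological × 2 technical replicates (8 runs, 4 per condition).

For each protein:

* **Detection.** A protein is detected in a group if it is present in at
  least `min_detect_runs` runs of that group (default 2). Detected in
  one group only ⇒ *unique* to that group. The detection floor is a
  parameter because there is no field-wide convention for how many runs
  constitute presence.
* **Testing.** Proteins detected in both groups get a two-sided Welch
  *t*-test on log2 intensities. Testing on the log scale matches
  label-free practice (intensities are approximately log-normal and the
  log stabilises variance); Welch rather than pooled variance is the
  safer default when per-group variances differ. Two degenerate inputs
  are resolved directly: two zero-variance samples with equal means give
  p = 1, with unequal means p = 0 (the statistic diverges). Zero
  intensities cannot be logged and are excluded from the test; a side
  left with fewer than 2 usable values makes the protein untestable
  (status `unchanged`, flagged).
* **Fold change.** The ratio of linear-scale group means (case over
  control), so `fold_change(a, b) = 1/fold_change(b, a)` exactly.
* **Thresholds.** `up` requires fold change ≥ 2.0 (inclusive) *and*
  p < 0.05 (strict); `down` mirrors it at ≤ 0.5. No multiple-testing
  correction is applied by default, matching common screening practice
  for this kind of candidate generation; a Benjamini–Hochberg switch
  (`adjust = "BH"`) is available for conservative use.
* **Unique-protein imputation.** Proteins unique to the case condition
  have no defined ratio; they are assigned a fold change of 2 (the
  screening cut-off), and control-unique proteins its reciprocal. This
  keeps unique proteins inside the DAP set — they are often the most
  interesting proteins, induced from undetectable to detectable — while
  giving them a deliberately conservative score in the cluster ranking.

The *case-up DAP set* is `up` ∪ `unique_case`; the *case-down set* is
`down` ∪ `unique_control`.

### Pseudo-replication

The four runs per condition comprise two technical replicates of each of
two biological replicates. The default treats them as four exchangeable
samples, which is how such designs are commonly analysed; but technical
replicates share their biological sample, so the four values are
positively correlated and raw p-values are anti-conservative with
respect to biological variation. Two handles exist: the
`average_tech_reps` option collapses technical replicates before testing
(n = 2 per group), and the calibration property below is assessed on
independent replicates. Users with more than two biological replicates
should prefer them over technical replication.

Calibration: under a pure-null simulation with independent replicates
(4 biological × 1 technical per condition, no true effects, no dropout),
the fraction of proteins with p < 0.05 sits at the nominal level, and
adding the 2-fold gate suppresses essentially all false DAP calls (the
acceptance suite measures both over 1,000 replicate datasets of 60
proteins each).

## Window detection and AFCL ranking

Genes are put in genome order by sorting on (contig, start, end) and
assigned dense 0-based ordinals; *consecutive* always means consecutive
ordinals on one contig. Windows never span contigs — adjacency across an
assembly gap is undefined in a draft genome — and strand is recorded but
ignored, since catabolic clusters routinely contain genes in both
orientations.

A window of `window_len` consecutive genes qualifies if it contains at
least `min_dap` genes whose protein is in the screened DAP set. The
default rule pair is **3-in-10 or 5-in-15**. All qualifying windows of
all rules that overlap or abut are merged into one maximal candidate,
and each candidate is trimmed so that its span starts and ends on DAP
genes. This makes candidate spans canonical: endpoints are always
flagged genes, no two candidates overlap, and none contains another. The
implementation (cumulative-sum window counts plus run-length coverage
merging) is verified against literal enumeration of every window with
naive interval merging on a thousand random flag vectors.

Each candidate's **AFCL** (average fold-change level) is the arithmetic
mean, on the linear fold-change scale, of its DAP genes' fold changes,
unique-imputed values included. Averaging over DAP genes only — rather
than all genes in the span — prevents unquantified or unchanged
neighbours from diluting the score of a genuinely induced operon; the
`afcl_all_genes` switch (undefined fold changes counted as 1) is kept
for sensitivity analysis. The linear scale is deliberate: a cluster of
20–40-fold-induced genes should score in the tens, an order of magnitude
above any background candidate, and that separation is what the
selection rule exploits.

Candidates are ranked by AFCL descending. Ties — essentially impossible
on real-valued scores but fixed for determinism — break by more DAP
genes, then larger span, then leftmost position. The **selected**
cluster is the highest-ranked candidate with at least `min_genes` genes
(default 5): a catabolic pathway needs several enzymes, so a tiny
high-scoring candidate is more plausibly noise.

Screening direction defaults to up-DAPs only, because degradation genes
are induced by their substrate. `direction = "down"` screens the
repressed set, scoring by reciprocal fold change so that larger still
means more regulated; `direction = "both"` uses `max(fc, 1/fc)`.

## Enrichment, qPCR and QC

* **Over-representation.** For each term with at least `min_daps`
  (default 3) annotated DAP-set members, the upper-tail hypergeometric
  probability P[X ≥ k] is computed against a universe that defaults, by
  proteomic convention, to the *identified* proteins rather than the
  whole genome (detection bias would otherwise inflate every term);
  p-values are BH-adjusted across reported terms.
* **qPCR.** The plain 2^−ΔΔCT chain: average technical CT replicates,
  subtract the reference gene's CT within each sample, subtract the
  calibrator sample's ΔCT, exponentiate. Amplification efficiency is
  fixed at 2 — no Pfaffl-style correction — and any statistics belong on
  the approximately normal ΔCT scale, not on the ratios.
* **QC.** Run-by-run Pearson correlation on log2 intensities,
  pairwise-complete with a 3-observation floor per pair, and detection
  Venn counts (both / case-only / control-only) under the same detection
  rule as the caller.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates, from one seed, a tiled genome annotation
(1 kb genes, 100 bp gaps, 2 contigs), a quantification matrix, a CT
table and ground truth. The generative model for protein *i* in run *r*:

```
log2 A[i, r] = baseline_i + lfc_i * [r in case]
             + bio_{i, sample(r)} + tech_{i, r}
```

with `baseline_i ~ N(20, 2)`, biological effects shared by the technical
replicates of one biological sample (`sd 0.25` log2), technical noise
(`sd 0.1` log2), and logistic abundance-dependent dropout
(`P(missing) = plogis((16 − log2 A)/1.5)`, about 9% of cells at the
defaults — low-abundance values vanish first, as in real label-free
data). Default conditions: 400 genes, 65% of them quantified (echoing an
identified-proteome of roughly 2,600 proteins against some 4,800 coding
sequences), a 2% background rate of true effects at 2–8-fold, and one
planted 9-gene cluster at 20–40-fold of which 20% of proteins are made
case-unique by forcing control-side dropout — so the caller is exercised
on the same missingness mechanism it must interpret. Planted-cluster
genes always carry a quantified protein: the screen's premise is that an
induced operon's proteins are detectable under induction, and a planted
truth that the data cannot express would only test the generator, not
the method. CT values for the first five planted genes follow
`CT = 40 − log2(expression) + N(0, 0.15)` with a constant high-abundance
reference gene.

What it does **not** emulate: peptide-level quantification and roll-up,
between-run normalisation drift, intensity-dependent variance beyond the
dropout mechanism, correlated contamination, or shared-peptide protein
inference. Passing the recovery benchmark therefore shows that the
window/AFCL machinery is correct and well-calibrated under a reasonable
noise model — not that any particular real dataset will yield its
cluster this cleanly.

## Numerical and testing choices

Problem sizes in the test suite were chosen to exercise each property at
meaningful scale: 1,000 random flag vectors (length ≤ 200) for the
window-rule oracle equivalence, 100 independent seeds for end-to-end
planted-cluster recovery (the selected span must intersect the planted
span), 1,000 pure-null datasets of 60 proteins for calibration, 500
4-vs-4 draws for Welch-vs-exact-permutation decision agreement, and full
(N ≤ 60, K, n, k) grids for hypergeometric exactness against
binomial-coefficient enumeration. Recovery is deliberately defined by
span intersection rather than exact span equality: a background DAP
within one window-length of the planted cluster legitimately merges into
the candidate and stretches its trimmed span.

Floating-point conventions: result tables are written with 15
significant digits so TSV round-trips are faithful to 1e-6 relative;
ranking ties break deterministically as described; the fold-change
cut-off is inclusive and the p cut-off strict, so a protein at exactly
2.0-fold with p = 0.049 is `up` and one at p = 0.05 is not.

## Limitations

* The screen finds *co-located, co-induced* genes; a degradation pathway
  scattered across the genome, or regulated post-translationally, is
  invisible to it.
* AFCL is sensitive to the unique-protein imputation constant: unique
  proteins enter at fold change 2, which is conservative, and a cluster
  dominated by unique proteins will rank lower than its biology might
  merit.
* With only two biological replicates, the t-test has little power and
  unstable variance estimates; the defaults reflect a screening posture
  (raw p, 2-fold gate), not confirmatory inference.
* Candidate spans are trimmed to DAP genes, so flanking members of a
  real operon whose proteins were not detected are excluded from the
  reported span (though visible in `member_genes` context).
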