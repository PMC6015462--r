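---
title: "Master regulator discovery from coexpression networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Master regulator discovery from coexpression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masterreg)
```

# Overview

`masterreg` implements a four-stage chain for nominating disease master
regulators (MRs) and repositioning drugs against them:

1. **Network inference.** A transcription-factor (TF)-centered coexpression
   network is reconstructed from a reference (non-diseased) cohort with
   mutual information (MI), a permutation-derived significance threshold,
   bootstrap consensus filtering, and data-processing-inequality (DPI)
   pruning. Each TF's inferred target set (its *regulon*) is split into
   positive- and negative-mode targets by the sign of the TF–target Pearson
   correlation.
2. **Master regulator analysis (MRA).** For each case–control study, genes
   differentially expressed at FDR < 0.05 (empirical-Bayes moderated t) are
   intersected with each regulon; enrichment is scored with an upper-tail
   hypergeometric test, BH-corrected across TFs. TFs enriched in three or
   more studies are MR candidates.
3. **Activation states.** Two-tail gene set enrichment analysis (GSEA)
   scores the positive-mode subset (EsA) and negative-mode subset (EsB)
   independently in each study's logFC ranking. The differential score
   dES = EsA − EsB is positive when the regulon is induced in disease and
   negative when repressed; significance comes from a gene-label permutation
   null with BH correction.
4. **Connectivity map.** The DE targets of strong candidates form an up/down
   tag-list query; each instance of a compound signature database is scored
   with the Kolmogorov–Smirnov (KS) connectivity statistic; per-compound mean
   scores carry instance-resampling permutation p-values; compounds
   significant with a consistent direction in at least two studies are
   consensus calls — signature reversal (negative) suggests therapeutic
   potential, mimicry (positive) a disease-mimetic.

A synthetic-data module generates every input with known ground truth, so
the whole chain is testable end to end without downloads.

# The generative model

The simulator draws a signed bipartite network: each of `n_tf` TFs receives
`targets_per_tf` targets sampled without replacement from the non-TF genes;
an edge's mode is +1 with probability 0.7 (else −1) and its effect size is
β. Expression follows a linear-Gaussian model per sample:

* TF activity: \(a_t \sim N(0, 1)\), i.i.d. across samples and TFs;
* TF expression: \(x_t = a_t + \sigma \varepsilon\);
* target expression: \(y_g = \sum_{t \to g} \beta \,\mathrm{mode}(t,g)\, a_t + \sigma \varepsilon\);
* unregulated genes: \(\sigma \varepsilon\) (pure noise).

TF expression is deliberately a *noisy readout of activity* so that
expression-based MI can recover activity-driven regulation — the assumption
implicit in all coexpression network inference. Case–control studies reuse
the model; cases shift the activity of each perturbed TF by ±δ. Hence a
repressed TF's positive-mode targets have expected logFC \(-\beta\delta\)
and its negative-mode targets \(+\beta\delta\) — exactly the signal the
two-tail GSEA is designed to read. Closed-form moments (target variance
\(\sum\beta^2 + \sigma^2\), logFC expectations) back the simulator's tests.

The drug simulator ranks genes per treatment instance by
\(\mp s_g + \mathrm{noise}\), where \(s_g\) is the standardised planted
disease signature: therapeutic compounds reverse it (disease-up genes near
the bottom of the instance list), mimetics reproduce it, neutral compounds
are uniform random permutations.

**Reference study conditions.** The `simulation_config()` defaults are the
conditions every recovery test runs under: 10 TFs over 500 genes with 30
targets each, β = 1, σ = 0.25, a 200-sample reference cohort, four
case–control studies of 50 + 50 samples with two activated and two
repressed planted MRs at δ = 2, and a signature database of 3 therapeutic,
3 mimetic and 44 neutral compounds with 5 instances each (rank noise 0.5).
These sizes keep a laptop-scale run under a minute while leaving the
planted effects realistically mixed with noise: roughly 40% of edges land
on shared (multi-regulator) targets whose MI is strongly diluted, which is
what makes recovery non-trivial.

What the simulator does **not** emulate: probe-level measurement, batch
effects, heavy-tailed noise, correlated TF activities, autoregulation, and
any matching of a real cohort's moments. Passing recovery tests therefore
demonstrates the statistical machinery is correct and calibrated — not that
a particular biological dataset would yield the same funnel.

# Numerical and design choices

## MI estimation and binning

MI is estimated on equal-frequency (rank) bins — symmetric, invariant to
strictly monotone transforms, and checkable against a brute-force
joint-histogram oracle. Ties are broken by original position, so the
estimate is fully deterministic. The bin count matters more than any other
numeric choice in the package: the plug-in estimator's bias is roughly
\((B-1)^2/2n\) nats under independence. With the common \(B = \lfloor\sqrt
n\rfloor\) rule at \(n = 200\) that bias is ≈ 0.42 nats — larger than the
entire MI of a two-regulator target (≈ 0.30 nats) — and the weak half of
the true network becomes statistically invisible. `default_bins()` instead
uses a Cochran-style criterion, \(B = \max(2, \lfloor\sqrt{n/5}\rfloor)\),
which keeps the expected joint-cell count at or above 5; at \(n = 200\)
this gives 6 bins, bias ≈ 0.06 nats, and clean separation between null and
weak-but-real edges. `n_bins` is exposed everywhere for users who prefer a
different rule.

## Permutation threshold

Rather than per-edge permutation p-values, a pooled null is built from
`n_perm` random TF–target pairs with one member's samples permuted; the MI
threshold is the empirical \(1 - p\) quantile (type-1, inverse-ECDF, so the
degenerate all-equal null returns that value and `p_cutoff = 1` returns the
minimum). Defaults: 1000 permutations, p ≤ 0.001. The pooled design keeps
cost linear in `n_perm` and matches the "minimum MI threshold" framing; its
calibration (fraction of truly null edges retained ≈ p) is asserted by a
test.

## Bootstrap consensus and the duplicate-pair effect

Stability filtering resamples the cohort with replacement 100 times and
keeps edges present in ≥ 95% of bootstrap networks. Implementing this
revealed a subtlety worth documenting: resampling with replacement
duplicates (x, y) sample pairs, and duplicated pairs are *genuine*
dependence in the resampled data — null-pair MI inflates from ≈ 0.50 to ≈
0.79 nats at \(n = 200\) with 14 bins (and proportionally at the default
6), so a threshold calibrated on the full cohort
passes essentially every pair inside a bootstrap and the consensus filter
becomes vacuous. The remedy is to recalibrate the null *within* each
bootstrap with the duplicate structure preserved: permute the target's
samples in the original sample space first, then resample both vectors with
the bootstrap's index vector. The effective per-bootstrap threshold is the
larger of the full-data threshold and this bootstrap-null quantile at the
same tail probability. The spec-literal fixed-threshold behaviour remains
available (`p_cutoff = NULL`). With recalibration, truly null edges have
support near zero while strong edges keep support ≈ 1, which is what the
consensus filter is meant to distinguish.

## DPI, modes, tie rules and degenerate inputs

* DPI removes a TF–target edge when its MI is strictly below
  \((1-\mathrm{tol})\min\) of the other two edges of a closed triplet,
  evaluated against the pre-pruning edge set in a single pass — so the
  output is order-independent and equality (with null tolerance) keeps the
  edge. Only TF–target edges are removable; TF–TF edges participate in
  triplets but persist, and are dropped from regulons at mode assignment.
* Pearson r exactly 0 at mode assignment (a measure-zero event) maps to the
  positive mode with a warning, keeping the pipeline deterministic; a
  zero-variance gene is a hard error.
* A constant vector has no rank structure: MI returns 0 with a warning.
* logFC ties in the GSEA ranking break lexicographically by gene id; an
  empty mode subset scores Es = 0 (logged), needed for one-sided regulons.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` after range
  validation; a brute-force step-up oracle cross-checks it.
* The moderated t follows the standard empirical-Bayes scheme: method-of-
  moments fit of (d0, s0²) on log residual variances via trigamma
  inversion; a non-positive moment falls back to d0 = ∞ (fully pooled);
  zero-variance genes get p = 1 and are excluded from the fit. The
  pre-installed limma implementation is used in the test suite as an
  independent reference, not in the pipeline itself.

## Regulon-size tiers

Genome-scale analyses conventionally report regulons with more than 25
targets and restrict MRA to regulons with at least 100 targets. Both
thresholds are exposed (`filter_regulons()`, with `>` and `≥` rules kept
deliberately distinct). The synthetic universe plants 30 targets per TF, so
`run_pipeline()` defaults the MRA-tier floor to 15 — the threshold scales
with the target count the network can support, and a floor tuned to a
20,000-gene platform would empty a 500-gene simulation.

## Two-tail GSEA

The enrichment score is the signed maximum deviation of the weighted KS
running sum (hit increments \(|m|^q/\sum_{hits}|m|^q\), miss decrements
\(1/(N-|S|)\)); the weighting exponent defaults to 1 with 0 available. The
permutation null resamples *gene labels* — random disjoint subsets of the
two mode-subset sizes — because only summary logFC values enter this stage;
sample-level phenotype permutation would require the expression matrices
downstream of where this statistic lives. Two significance tiers are kept
separate on purpose: FDR ≤ 0.05 (BH across TFs per study) for activation
state calls, and raw p ≤ 0.01 as the stricter filter selecting candidates
for the connectivity query.

## Connectivity scoring

The KS tag statistic follows the classic build02 formulation
(\(a = \max_j[j/t - V_j/n]\), \(b = \max_j[V_j/n - (j-1)/t]\), score
\(a\) if \(a > b\) else \(-b\)); an instance whose up and down tags move the
same way is incoherent and scores 0; raw scores are scaled so the extreme
instances anchor ±1. Per-compound p-values resample same-size instance
subsets from the whole study (10,000 draws, shared across compounds of
equal instance count, deterministic under the seed). Tag lists are capped
at 1000 per direction, truncating by |logFC|. Consensus requires the same
direction in ≥ 2 studies at p ≤ 0.05; direction conflicts are excluded with
a message rather than silently resolved. The query pools the targets of all
qualifying candidates ("grouped"); per-state queries are possible by
filtering the GSEA records passed in.

## Seeding and determinism

Every stochastic stage takes an explicit seed and restores the caller's RNG
state afterwards. `run_pipeline()` derives per-stage seeds from the config's
master seed (`(seed + 10007k) mod 2^31 - 1`), so no stage's stream depends
on another's consumption, and a rerun under the same config reproduces
byte-identical artifacts (the test suite hashes the output manifests of two
runs).

# Known limitations

* The linear-Gaussian simulator cannot tell this implementation apart from
  one that is only correct under Gaussian marginals; the rank-based MI and
  GSEA stages are distribution-free by construction, but that is asserted
  by invariance tests, not by the recovery scenario.
* Targets regulated by three or more TFs sit at or below the MI detection
  limit under the reference conditions; the bootstrap consensus stage
  prunes a fraction of them. Median regulon F1 ≈ 0.92–0.95 across seeds,
  not 1.
* MRA pools both mode subsets in one hypergeometric test; mode-specific
  enrichment is delegated entirely to the two-tail GSEA.
* The two-group moderated t supports no covariates; contrasts are plain
  case vs control per study.
* Drug scoring uses rank lists only; moderated z-score pipelines for
  modern L1000-style databases are out of scope.
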