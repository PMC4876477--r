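---
title: "Assessing reference-gene stability from raw Ct values: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing reference-gene stability from raw Ct values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## Why reference-gene validation

Relative qPCR quantification divides a target gene's signal by one or more
reference genes assumed constant across conditions. When that assumption
fails — and in injury models it often does — every downstream fold change
and p-value inherits the reference's instability. refstab implements the
four standard candidate-screening algorithms on raw cycle-threshold (Ct)
tables, aggregates them into one comprehensive ranking, and provides the
surrounding pieces (standard-curve efficiencies, 2^−ΔΔCt expression,
location comparisons) so the whole workflow is scriptable and seeded.

A Ct value is the PCR cycle at which fluorescence crosses a threshold; it
is inversely and log-linearly related to starting template, so one cycle ≈
one doubling at 100% efficiency. All internal arithmetic treats Ct as a
log₂-scale quantity.

## The four stability algorithms

**Comparative ΔCt.** For genes *j*, *k* the per-sample difference
Ct_sj − Ct_sk removes everything the two genes share (RNA input, reverse
transcription yield). Gene *j*'s statistic is the mean over partners of the
sample SD (n−1 throughout the package) of these differences. Assumption:
most partners are themselves reasonably stable, so a gene that disagrees
with everyone is the unstable one. This fails if candidates are
co-regulated — a caveat shared by geNorm.

**geNorm.** Ct is converted to relative quantities
q_sj = A_j^(min_s Ct_sj − Ct_sj) (A_j = amplification factor, default 2;
per-gene factors from `standard_curve_table()` can be supplied). The
pairwise variation V_jk is the SD over samples of log₂(q_sj/q_sk) and
M_j = mean_k V_jk. The gene with the highest M is excluded and M recomputed
until two genes remain; those two share the final M and rank 1 — by
construction geNorm cannot separate its best pair. Each excluded gene
reports the M at its elimination step, ranked in reverse elimination order.
When all A_j = 2, log₂ q differences reduce to negated Ct differences, so
the first-round M *equals* the ΔCt statistic; the test suite asserts this
identity to 1e−10 on random matrices, which is the strongest internal
cross-check the two implementations give each other. Exact M ties during
elimination are broken by column order (first listed gene removed first);
exact statistic ties in the output share a dense rank.

**NormFinder.** Samples are centred across genes
(d_sj = Ct_sj − mean_g Ct_sg), which removes the shared loading effect but
mixes every gene's noise into every centred value. With g genes, the
observed variance obeys E[v_j] = σ²_j(g−2)/g + Σ_k σ²_k/g², solved by
σ̂²_j = g/(g−2)·[v_j − Σv/(g(g−1))]; the stability value is σ̂_j. The
decomposition can go negative at small n; estimates are truncated at zero
before the square root (genes tied at 0 then share rank 1). Grouped mode
applies the decomposition per group and reports
mean_g(|γ̂_jg| + √(σ̂²_jg/m_g)), with γ̂_jg the group's centred mean minus
the grand mean — combining inter- and intra-group variation. At least
3 genes are required (the decomposition is singular below that), and in
grouped mode ≥ 2 groups of ≥ 3 samples. The default is ungrouped, matching
how web aggregators run NormFinder without annotation input; grouped mode
is the Andersen-style analysis for designed experiments.

**BestKeeper.** Works on raw Ct, not differences: per-sample index =
geometric mean of all candidates' Ct, per-gene descriptives (geometric and
arithmetic means, min/max, dispersion, CV%), and Pearson correlation of
each gene with the index (two-sided p, undefined and reported NA for a
constant gene). The ranking statistic is the dispersion — sample SD by
default, matching how "SD" columns are conventionally reported, with the
original mean-absolute-deviation variant selectable via
`sd_variant = "mean_abs_dev"`. A dispersion ≥ 1 cycle is flagged unstable.
Unlike the other three methods, BestKeeper responds to per-sample loading
shifts; the invariance tests document this asymmetry explicitly.

**Comprehensive ranking.** The geometric mean of the four dense method
ranks, kept at full precision internally and rounded to 2 decimals only for
display. Final ranks are assigned in ascending geomean order; exact ties
break by ΔCt statistic, then gene id — the published tables never exhibit a
comprehensive tie, but a deterministic rule is required for reproducible
output. No method weighting and no Borda/Kemeny alternatives are offered;
the geometric mean of ranks is what the aggregation platforms report.

## Standard curves

`fit_standard_curve()` is OLS of Ct on log₁₀ dilution with ≥ 3 distinct
dilution levels; duplicate wells enter as separate observations (they carry
real replicate information and degrees of freedom for R²). Slope converts
via amplification A = 10^(−1/slope), efficiency E% = (A − 1)·100 — the
universal relation, under which slope −3.32193 ⇔ exactly 100%. A fitted
slope ≥ 0 indicates a failed assay: the curve is returned with a
`positive_slope` flag and NA efficiency rather than an error, so batch
tables don't abort on one bad gene. R² is computed as 1 − SS_res/SS_tot
(defined as 1 for an exactly collinear series). Note that published
slope/efficiency pairs are not always internally consistent under this
relation (rounded slopes, transcribed rows); refstab always derives
efficiency from the slope it fitted.

## 2^−ΔΔCt expression and group statistics

ΔCt = Ct_goi − Ct_ref per sample (multiple references: arithmetic mean of
their Ct, i.e. geometric-mean normalization on the quantity scale);
ΔΔCt subtracts the *arithmetic mean* ΔCt of the control group (the standard
Livak formulation), so the control group's geometric-mean fold is exactly 1.
Group summaries are mean ± SEM of per-sample folds, matching the
conventional bar-plot presentation. `group_anova()` runs one-way ANOVA
across groups plus each-group-vs-control Welch t-tests with Holm
adjustment and 0.05/0.01/0.001 star tiers — the post-hoc procedure behind
published vs-control asterisks is rarely stated, so this choice is
documented here as ours, not inferred. Tests default to the fold scale to
match that presentation; `scale = "log"` tests ΔΔCt instead and is
statistically preferable (folds are log-normal). A gene normalized against
an identical profile yields all folds = 1; this is flagged degenerate, not
an error. Efficiency-corrected folds (per-gene amplification factors
replacing the 2s) are available via `efficiencies`.

`location_compare()` runs per-group two-sided Welch t-tests of one gene's
Ct between the two sampling locations with five-number summaries per arm;
arms with n < 2 are skipped with a warning.

## The synthetic-data generator

Real raw Ct tables for this kind of study are usually unpublished, so the
generator is first-class, tested code, not a fixture. The model is

Ct_sg = baseline_g + u_s + Σ(matching effect shifts) + ε_sg,

with u_s ~ N(0, sample_effect_sd²) shared across genes and
ε_sg ~ N(0, noise_sd_g²). Gaussian noise on the Ct scale is the standard
qPCR error model (Ct is already log-scale). The shared u_s is what makes
genuinely stable genes co-vary; without it the stability methods would have
no signal to separate. Its default SD of 0.5 cycles is our choice of a
plausible loading/RT variation — no published variance decomposition exists
to pin it down.

`default_design()` encodes the study conditions: baselines and per-gene
noise SDs from the published non-dependent-tissue descriptives (18S 12.36 ±
1.139, GAPDH 27.42 ± 1.170, ACTB 26.12 ± 1.858, TOP1 27.86 ± 1.366, RPS29
37.19 ± 1.641 cycles), six groups × two locations × n = 10, and a
+1.78-cycle gravity-dependent shift on RPS29 (38.97 − 37.19). Since the
published SDs already contain whatever loading variation the experiment
had, stacking sample_effect_sd = 0.5 on top slightly overstates total
variance; we accept this rather than back out a split the data cannot
support. Censoring at a maximum cycle (e.g. 45) is available but off by
default — RPS29 sits near cycle 39 and censoring is a realism knob, not
something the validation suite needs. Undetected reactions in real data are
stored as missing and never imputed; all stability methods run on complete
cases only (`complete_cases()`), because max-cycle imputation silently
deflates SDs. How technical replicates were collapsed before analysis is
typically unreported; refstab collapses them by arithmetic mean of Ct, a
documented package choice.

What the generator does *not* emulate: amplification-curve artifacts,
primer-dimer effects, inhibitor kinetics, non-Gaussian outliers, or
co-regulation between candidates. Passing recovery tests on this model
therefore shows the algorithms are implemented correctly and have power
against additive group/location shifts — it does not certify behaviour on
pathological real-world plates.

### Recovery benchmarks and problem sizes

The test suite's recovery benchmarks run at the design's own sizes:

* an injected unstable gene (noise SD 0.5) carrying a 3-cycle
  group-dependent shift — implemented as a ±3-cycle shift of alternating
  sign across the six groups, i.e. a gene whose expression genuinely
  depends on treatment — is ranked last by *all four* methods in ≥ 95% of
  200 seeded replicates. The alternating-sign choice matters: a shift
  confined to half the groups adds only 9/4 cycle² of variance, which is
  *less* than ACTB's designed noise (1.86² ≈ 3.45 cycle²), so such a gene
  is not detectably "worst" against this panel by the pairwise methods —
  an instructive reminder that stability screens judge candidates only
  relative to each other. The alternating shift adds 9 cycle² and
  dominates cleanly. Grouped NormFinder, whose inter-group term reads the
  shift directly, flags a half-group +3 shift without this help, and is
  tested that way.
* the RPS29 location shift is recovered as a mean gravity-dependent −
  non-dependent difference of 1.78 cycles over 200 seeds, and detected by
  a pooled Welch test in ≥ 90% of 100 seeds while GAPDH stays at its
  nominal false-positive rate.
* dilution-series recovery at 98.7% designed efficiency (replicate SD 0.1,
  50 seeds) and exact noiseless recovery to 1e−9.
* expression calibration: a designed −2-cycle shift reads out as ~4-fold
  within 3 SEM over 100 seeds; a null simulation (6 × 10 samples, 1000
  replicates) keeps the fold-scale ANOVA type-I rate within Monte-Carlo
  error of 5%.

## Numerical conventions

* SDs use the n−1 denominator everywhere, including BestKeeper's default.
* Dense ranks: ties (exact float equality) share a rank and rank values are
  consecutive from 1.
* Oracle identities are asserted to 1e−10; definitional arithmetic to
  1e−12; Monte-Carlo checks to 2–3 standard errors of their own replicate
  spread.
* All simulation entry points take a seed and restore the caller's RNG
  state; the pipeline writes byte-identical outputs for a fixed seed.
* Hard minimums: 3 samples and 2 genes for any stability statistic,
  3 genes for NormFinder and geNorm exclusion, 3 distinct dilution levels
  for a curve.

## Limitations

* Stability is always relative to the candidate panel; a panel of
  co-regulated genes can agree on a wrong answer.
* Exact numeric reproduction of published stability tables requires raw Ct
  data; where those are unpublished, only self-consistent derived cells
  (geomean-of-ranks from printed sub-ranks) can be reproduced, and the
  dialects of web-based NormFinder/BestKeeper implementations differ in
  undocumented ways.
* The fold-scale ANOVA default mirrors common practice, not optimal
  inference; use `scale = "log"` for skew-robust testing.
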