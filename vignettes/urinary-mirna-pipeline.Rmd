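---
title: "Methods: urinary miRNA biomarker discovery and validation"
author: "urimir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary miRNA biomarker discovery and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urimir)
```

# The problem

Bladder cancer is diagnosed and monitored by cystoscopy, an invasive and
expensive procedure. Cell-free miRNAs are stable in urine, and their
profiles shift with tumor presence, grade, and invasiveness, which makes
a urine-based miRNA panel an attractive non-invasive triage test. The
workflow implemented here takes a cohort of urine small RNA-seq samples
(cases stratified as low-grade NMIBC, high-grade NMIBC, and MIBC, plus
controls), discovers candidate biomarkers per subtype, selects
endogenous-control miRNAs for qPCR normalization from the sequencing
data itself, and validates candidates with qPCR statistics, ordered
subtype trend tests, and a risk-model comparison.

Because no patient-level data ship with the package, a cohort simulator
with planted truth is a first-class module: every statistical guarantee
claimed for the pipeline is demonstrated by parameter-recovery and
calibration experiments against that simulator.

# Count model and differential expression

Read counts $K_{ij}$ for miRNA $i$ in sample $j$ are modelled as
negative binomial with mean $s_j \mu_{ij}$ and dispersion $\alpha_i$,
$\mathrm{Var} = \mu + \alpha\mu^2$. Size factors $s_j$ use the
median-of-ratios convention: the median over miRNAs of
$K_{ij}/(\prod_j K_{ij})^{1/n}$, restricted to miRNAs with no zero
count, rescaled to geometric mean 1. The median is taken on the ratio
scale; this matches the textbook definition exactly and differs from a
log-scale median only in the fourth decimal when the middle pair is
averaged.

Dispersions come from a method-of-moments estimate within design groups
(with the per-group mean corrected by the mean inverse size factor, so
counting noise is not mistaken for overdispersion), shrunk halfway
towards a least-squares trend $\alpha(\mu) = a_0 + a_1/\mu$. The half
weight is a fixed compromise: pure per-miRNA moments are unusably noisy
below ~50 samples, a pure trend ignores genuine dispersion outliers.
The Wald test fits each miRNA's NB GLM (log link, $\log s_j$ offsets,
fixed dispersion) by IRLS; the subtype coefficient is reported in log2
units with a normal-approximation p-value, and Benjamini–Hochberg
adjustment is applied within each subtype-vs-control comparison
separately, mirroring the three separate discovery comparisons.
Non-converging fits (including all-zero rows) are flagged, excluded
from the multiple-testing burden, and counted.

Candidate DEmiRNAs require FDR $\le 0.05$ *and* raw mean read count
$\ge 300$; both bounds are inclusive, and the abundance filter operates
on raw counts because reported abundance tables are on the raw scale.

# Predictive power

The second discovery track scores each miRNA alone: a one-covariate
logistic model $\mathrm{class} \sim \log_2(1 + K/s)$, scored as
leave-one-out cross-validated classification accuracy. Two details
matter:

* **Cutoff.** The probability cutoff is the training-fold prevalence,
  not a fixed 0.5. Under leave-one-out the held-out sample is always
  the training fold's minority class; a fixed 0.5 cutoff therefore
  votes systematically against it and biases null predictive power far
  below one half (empirically ~0.35 at $n = 100$). With the prevalence
  cutoff, null features score close to 0.5 and a feature whose
  class-conditional distributions have Bayes accuracy 0.85 scores
  within a few points of 0.85.
* **Separation.** When the training fold is completely separated the
  logistic MLE diverges but the induced classifier is well defined; a
  midpoint threshold on the covariate is used. A constant covariate
  predicts the majority class, so its predictive power equals the
  majority-class proportion — on unbalanced comparisons (e.g. 10 MIBC
  vs 48 controls) that proportion can exceed the 0.70 candidate
  threshold, which is a real weakness of accuracy-based scoring that
  the package reproduces rather than hides; `scheme = "apparent"` is
  available for comparison.

PPmiRNAs require predictive power $\ge 0.70$ (inclusive). The
candidate panel is the DE∩PP intersection; manually curated additions
are accepted only as an explicit list and are provenance-tagged
`"manual"`, because plot inspection and literature knowledge cannot be
automated honestly.

# Unwanted variation

Technical structure (batches, extraction runs) is estimated from the
data: log2 depth-normalized counts are residualized on the class
design, the residual matrix is decomposed by SVD, and the number of
real components is decided by a Buja–Eyuboglu-style permutation test —
each miRNA's residuals are permuted independently, permuted matrices
are re-projected onto the residual space (so observed and null
matrices share rank), and a component is kept while its variance share
exceeds the permutation 95th percentile, stopping at the first
failure.

Two further choices were forced by experiments on the simulator:

* **Per-sample residual scaling.** Counting noise makes low-depth
  samples noisier on the log scale; without equalizing per-sample
  residual scale the SVD reports a spurious "depth" factor in ~20% of
  null cohorts. With scaling (and $\log s_j$ in the known design) the
  null rate of spurious components is ~4–5%, matching the nominal 5%
  of the sequential permutation test.
* **Reconstruction from unresidualized data.** Residual right-singular
  vectors are orthogonal to the class design by construction, so they
  can never absorb the class-correlated share of a confounded batch —
  adjusting with them leaves the confounding bias intact. Each kept
  component is therefore rebuilt from the unresidualized, gene-centred
  data via its residual-space gene loadings and sharpened by three
  rounds of iterative reweighting (genes weighted by the strength of
  their association with the current surrogate, given the design),
  the same idea the SVA literature uses. On cohorts with a batch
  70/30-confounded with class, the naive test rejects 30–55% of null
  miRNAs at $p < 0.05$; with the reconstructed surrogate in the design
  the rate returns to ~1%, while planted fold changes under a balanced
  batch are recovered without attenuation.

Surrogate variables enter the DE design whenever any are found.

# Endogenous controls from sequencing

qPCR needs stable normalizers, selected from the sequencing counts by
three criteria: at least 2 raw reads in *every* sample (a detection
requirement, deliberately on unnormalized counts); standard deviation
of log2 normalized expression below 12; and every sample's log2
deviation from the miRNA's mean within $[-4, 7]$. The reference point
for the third criterion is the miRNA's own across-sample mean — the
"no exceptional expression in any sample" reading; a case-vs-control
contrast reading would conflate stability with differential
expression. The printed default thresholds are intentionally
permissive (an SD bound of 12 log2 units excludes almost nothing);
the ranking by ascending SD, ties broken lexicographically, is what
does the work, and stricter bounds are exposed as arguments.

# qPCR statistics

$\Delta Ct_{ij} = Ct_{ij} - \overline{Ct}_{\text{controls},j}$ per
sample; $\Delta\Delta Ct$ is the case-minus-control difference of group
means and the log2 fold change is $-\Delta\Delta Ct$ (the standard
$2^{-\Delta\Delta Ct}$ quantification in log2 units), so positive
values mean up-regulation. Both identities are exact, and $\Delta Ct$
is invariant to any per-sample Ct offset. Association with case status
is tested by logistic regression of the class on expression ($-\Delta
Ct$) adjusted for age and smoking (indicator contrasts against never
smokers), BH-adjusted within each subtype panel. Complete separation
falls back to a Firth-penalized fit (Jeffreys-prior score correction),
flagged in the output. Samples missing a control assay are excluded
and counted; undetected assays simply carry missing values. The
spike-in is a QC flag only (Ct SD threshold of 1 cycle), never a
normalizer.

The subtype trend test regresses expression on the ordinal disease
score (control 0 < low-grade NMIBC 1 < high-grade NMIBC 2 < MIBC 3),
adjusted for age and smoking, reporting the two-sided slope p-value; a
cases-only mode drops controls and rescores consecutively. With two
groups and no covariates this reduces exactly to the equal-variance
two-sample t-test (not to the logistic association p-value, which
answers a different question with a different statistic).

# Model comparison

Model 0 is logistic on age + smoking; Model 1 adds one $-\Delta Ct$
covariate per panel miRNA. Both are scored by in-sample fitted
probabilities — apparent AUC, matching how such panels are typically
first reported — and compared by DeLong's paired test computed from
placement values, with normal-approximation confidence intervals on
the AUC scale truncated to $[0, 1]$. The AUC itself is exact
pair-counting (ties one half) via midranks. A zero-variance difference
(identical scores) returns $p = 1$ with a degeneracy flag. Apparent
AUC is optimistic; the comparison between the two nested models is
still meaningful because both enjoy the same optimism, but the
absolute AUC of Model 1 on new samples would be lower.

# The simulator and what the tests do (and do not) show

`simulation_config()` defaults define the study conditions: 114
discovery samples (48 controls / 39 low-grade NMIBC / 17 high-grade /
10 MIBC), 1822 miRNAs with baseline log2 mean counts uniform on
$[-3, 14]$ (so a few percent fail the 20-read filter, as observed in
real urinary cohorts), dispersion trend $\alpha(\mu) = 0.05 + 2/\mu$,
depth factors in $[0.5, 2]$, a two-level batch with per-miRNA log2
shifts of SD 0.5, planted fold changes from −1.8 to +3.7 matching the
magnitudes of validated urinary biomarkers, two planted housekeeping
miRNAs, and Ct values linked to depth-normalized log2 counts with
slope −1, intercept 35 and 0.5 cycles of Gaussian noise. Age and
smoking are generated independently of class so covariate-adjusted
tests are null by construction. The Ct link uses the *realized*
normalized count as latent expression, so qPCR inherits biological
plus counting noise, not just the 0.5-cycle measurement term.

Test problem sizes are chosen to finish in minutes on one CPU: null
calibration of the Wald test on 2000 miRNAs at 50/50 (with baselines
drawn from the abundance range the candidate filter targets, log2
means 6–14, since the dispersion machinery is designed for the
mean ≥ 300 regime), DeLong calibration over 2000 replicates at
$n = 100$, batch repair at 1000 miRNAs, and 100 end-to-end replicates
at the validation-scale 112 cases / 65 controls with a 3-miRNA panel
planted at a combined Bayes AUC of 0.85 (the per-feature shift is
derived analytically from the NB and Ct noise terms, including the
correlation induced by shared endogenous-control normalization).

What passing these tests shows: the implementation recovers what was
planted, holds its nominal error rates, and is internally consistent.
What it does not show: robustness to features of real urine data the
generator does not emulate — zero inflation from failed extractions,
miRNA-correlated degradation, annotation drift across miRBase
versions, assay-specific qPCR efficiency, or case–control imbalance in
covariates. Conclusions about real cohorts still require real
replication.

# Numerical and degenerate-input conventions

Dispersions are floored at $10^{-8}$ and NB size parameters capped at
$10^8$ (a Poisson fit beyond that precision). Normalized counts are
offset by 0.5 before logs where zeros are possible. IRLS is capped at
50 iterations; non-convergence flags the miRNA rather than aborting
the run. Normalizer ranking ties break lexicographically. The
permutation count for surrogate-variable selection defaults to 100,
which puts the component threshold at the resolution of the 95th
percentile of 100 draws; seeds make every run reproducible, and equal
seeds give bit-identical outputs throughout the package.

# Known limitations

* Apparent AUC overstates out-of-sample discrimination; the optional
  cross-validated scheme in `predictive_power()` has no counterpart in
  `compare_models()`.
* Accuracy-based predictive power saturates at the majority-class
  proportion on unbalanced designs, admitting null features when the
  imbalance exceeds the 0.70 threshold.
* The Wald test's normal approximation is anti-conservative below ~20
  total counts; calibration is only claimed for the abundance range
  the candidate filter keeps.
* One surrogate variable per latent factor: overlapping soft batches
  are not separated, only captured jointly.
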