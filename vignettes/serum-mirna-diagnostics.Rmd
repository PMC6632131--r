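---
title: "Building serum miRNA diagnostic indices: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building serum miRNA diagnostic indices: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecindex)
```

# The problem

Esophageal squamous cell carcinoma (ESCC) is usually detected late, and
no practical population screening test exists: endoscopy is sensitive
but invasive and costly. Circulating microRNAs in serum are stable,
measurable on fluorescence microarrays from a few hundred microliters of
blood, and differ between cancer patients and non-cancer controls, which
makes a small miRNA panel an attractive screening instrument. `ecindex`
implements the full modeling path from raw case-control array data to a
deployable linear index: preprocessing, candidate filtering, discriminant
fitting, combinatorial feature search, a frozen published six-miRNA
scorer (the *EC index*), diagnostic evaluation, and the Bayes arithmetic
that converts test characteristics into screening consequences. A
synthetic cohort generator with known ground truth makes every stage
testable without any external download.

# Preprocessing model

Raw inputs are per-array fluorescence signals with one background value
per array.

1. **Positive calls.** A probe is used only where its signal strictly
   exceeds the array background; the background is then subtracted.
   Everything else is a *negative call*, kept as an explicit missing
   value — deliberately distinct from a zero signal.
2. **Internal-control normalization.** Three stably expressed control
   miRNAs (miR-149-3p, miR-2861, miR-4463) anchor each array: array *i*
   is multiplied by \(f_i = R / c_i\), where \(c_i\) is the arithmetic
   mean of its control signals (linear scale) and \(R\) the reference
   level. Within a study, \(R\) defaults to the grand mean of the
   \(c_i\); for prospective scoring of a single new array, a frozen
   `fixed_reference` must be used instead, which makes the transform
   exactly invariant to any per-array rescaling — the property the
   per-array artifact model requires.
3. **Log transform.** Model inputs are \(\log_2\) signals, floored at
   `pseudo_floor` (default 0.1) before the log. Negative calls among a
   model's miRNAs are imputed at the floor: deterministic, conservative
   low-expression handling. The scale on which the original index
   coefficients were estimated is not recoverable from the published
   formula; log2 is the platform-standard convention and is fixed as
   this package's contract for all scoring.
4. **Robust-miRNA filter.** A miRNA is a model candidate only if its
   linear normalized signal exceeds 64 in more than 50% of the samples
   of *each* group. Both inequalities are strict, matching the
   retention rule's wording; the weaker "any group" reading is exposed
   as `group_rule = "any_group"` because the phrase admits it.

# The discriminant and its search

For a feature subset the classifier is a two-class Fisher linear
discriminant: \(w = S_w^{-1}(m_1 - m_0)\) with \(S_w\) the pooled
within-class scatter (ridge-stabilized, default `1e-8` on the diagonal),
intercept at the class-mean midpoint, equal priors by default (the
design was a 1:1 cohort). A sample is called a case iff its score is
strictly positive; an exact tie is called control, which favors
specificity. The Fisher direction is identified only up to a positive
scalar, so coefficient *magnitudes* of a refit cannot be compared with
published ones — feature identity and sign pattern can.

Subsets are scored by leave-one-out cross-validated accuracy. The
search is a greedy beam: every single miRNA is scored and the best 20
kept; each kept subset is extended by every remaining candidate,
duplicate sets are collapsed, and the best 20 of each size survive, up
to 8 miRNAs. Ties are broken by higher training AUC, then by the
lexicographically smallest sorted feature tuple — the published
procedure is silent here, and a total, deterministic order is required
for reproducibility. Extensions are generated from *all* beam members
(the per-member reading; it strictly contains the union reading the
wording also admits). Per-subset LOOCV is computed from scratch in
compiled code and memoized by feature-set key, so correctness does not
depend on incremental updates across subsets.

The final model is the smallest size whose best LOOCV accuracy is
within `epsilon` (default 0.005) of the maximum over sizes — a
formalization of "high accuracy with few miRNAs". With LOOCV accuracy
quantized at \(1/N\), the default tolerates exactly one extra
misclassification at \(N = 200\).

# The frozen EC index and screening arithmetic

`ec_index_model()` carries the published six-miRNA discriminant as
immutable constants; `ec_score()` routes through the same scorer as
every other model, so there is a single scoring code path. The
screening functions are the exact closed forms
\[
\mathrm{PPV} = \frac{\mathrm{sens}\cdot p}{\mathrm{sens}\cdot p +
  (1-\mathrm{spec})(1-p)}, \qquad
1-\mathrm{NPV} = \frac{(1-\mathrm{sens})\,p}{(1-\mathrm{sens})\,p +
  \mathrm{spec}\,(1-p)},
\]
reported internally at full precision and printed at two significant
figures. Sensitivity and specificity of exactly 1 are admitted (a
perfect test is a legitimate boundary case); prevalence must be
strictly interior.

# Evaluation choices

ROC curves sweep thresholds over the observed unique scores; tied
scores move diagonally in one step. AUC is the Mann-Whitney statistic
with ties counted one half; its confidence interval uses DeLong's
structural-components variance. Proportions get Wilson score intervals
by default (Clopper-Pearson as an option) — the original report does
not name its CI procedures, so interval agreement is explicitly not a
comparison surface. Subgroup sensitivity is computed per tumour stage
among cases, subgroup specificity per control cohort among controls,
and pooling the strata by size reproduces the overall estimates
exactly. Predictions always derive from the model's fixed threshold,
never from a re-optimized cutoff.

# What the synthetic cohorts emulate

`simulate_cohort()` draws, for miRNA \(m\) and sample \(i\),
\[
\log_2 s_{im} = \mu_m + \beta_m\,\kappa_{\mathrm{stage}(i)}\,
\mathbf 1[\text{case}] + \varepsilon_{im}, \qquad
\varepsilon_{im}\sim N(0, \sigma_b^2),
\]
then multiplies linear signals by a per-array factor
\(\exp N(0, \sigma_a)\), adds a per-array background draw, and pushes a
small fraction of *weakly detected* probes (linear signal below 4x the
robust threshold of 64) under the background to create negative calls.
Internal controls sit at fixed log2 levels 10, 11, 12 with SD 0.05.
Defaults: 100 + 100 samples, 500 miRNAs, 6 planted differential miRNAs
with alternating-sign log2 shifts of 4, \(\sigma_b = 1\),
\(\sigma_a = 0.25\), background \(30 \pm 5\). The stage mix of cases
(8% / 49% / 18% / 21% / 4% for 0/I/II/III/IV) follows a surgical ESCC
cohort dominated by stage I disease, and stage multipliers
(0.6, 0.8, 1, 1, 1.2) encode the weaker circulating signal of early
disease, qualitatively reproducing a sensitivity-by-stage gradient.
Planted markers draw their baselines from the upper detectable band
(log2 12–13.5) so that they remain positive calls in both groups — a
deliberate mirror of the fact that real index candidates must first
survive the robust filter. All draws flow through one seeded RNG
stream; the caller's RNG state is restored afterwards.

What the generator does **not** emulate: batch or site confounding
beyond the single array scale factor, correlated miRNA modules,
heavy-tailed signal noise, hemolysis artifacts, or quantitative
agreement with real scanner distributions. Passing recovery tests on
these cohorts therefore demonstrates correctness of the *procedure*,
not clinical performance on real serum data.

Two design notes that surfaced during development. First, sub-detection
dropout is restricted to the low-signal regime: fluorescence probes at
thousands of units do not fall below a background of ~30, and allowing
them to would inject pseudo-floor imputation outliers (17 log2 units
below baseline) that no realistic assay produces and that dominate any
linear score. Second, with the default planted effect of 4 (Cohen's
*d* = 4 per marker), one or two markers already separate the classes
almost perfectly, so the parsimony selection rule stops at two or three
features essentially always: the planted *set* is larger than the
smallest sufficient model, and a full six-of-six recovery by the
selected model should not be expected at that effect size — the
recovery experiment in the test suite measures exactly this tension.
The null-effect counterpart (validation AUC near 0.5 on an independent
cohort despite an optimistically selected training model) is the
selection-bias guard that motivates external validation in the first
place.

# Problem sizes and numerics

The test suite exercises oracle equivalence (independent linear solves,
naive per-fold LOOCV refits, all-pairs AUC, brute-force filtering) on
hundreds of small randomized instances, exhaustive-search equivalence
on 8 candidates, and the study-scale experiments at 100 + 100 samples
by 500 miRNAs across 20 seeds per arm — sizes chosen so the whole suite
completes in minutes on one core while still covering the regime the
procedure targets. Degenerate inputs are defined, not accidental:
constant features yield a zero coefficient vector and all-control calls
(tie rule); a singular scatter with `ridge = 0` raises an error
advising a positive ridge; empty strata are omitted with a message;
single-array grand-mean normalization is the identity.

# Known limitations

- The published coefficient magnitudes cannot be reproduced by
  refitting: the Fisher direction's scale and the original
  normalization reference are not identifiable from the printed
  formula. The frozen constants are therefore shipped verbatim, and
  refit comparisons are restricted to feature identity and signs.
- The GEO series-matrix reader is best-effort plumbing for
  deposited matrices and sidecar metadata; series matrices rarely carry
  raw per-array backgrounds, in which case signals are treated as
  already background-handled.
- How a single prospective sample was normalized against the original
  training reference is unspecified in the source material; the
  frozen-reference mechanism here is this package's design.
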