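---
title: "Assessing small study-effects in diagnostic accuracy meta-analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing small study-effects in diagnostic accuracy meta-analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtabias)
```

## The model and its assumptions

A diagnostic test accuracy (DTA) study yields a 2×2 table of true/false
positives and negatives. The package summarizes each study by the
diagnostic odds ratio `DOR = (tp·tn)/(fp·fn)` on the log scale, with the
Woolf variance `1/tp + 1/fp + 1/fn + 1/tn`. The DOR is the univariate
workhorse for funnel-plot work in DTA reviews: bivariate
sensitivity/specificity models are preferable for accuracy estimation, but
no bivariate small-study-effects test is in common use, so asymmetry
assessment falls back on the lnDOR.

Small study-effects — smaller studies showing systematically larger
effects — are the observable footprint of selective publication, but in
DTA data they have a benign competitor: the *threshold effect*. When
studies use different positivity cut-offs, sensitivity and specificity
move along a ROC curve at roughly constant DOR, and because the standard
error of the lnDOR depends on the proportion of positive tests, a
correlation between effect and SE arises with no publication bias at all.
This is the core reason variance-based asymmetry tests misbehave on DTA
data, and the reason Deeks' test replaces the SE with a pure design
quantity, the effective sample size `ESS = 4·n1·n2/(n1+n2)`.

Three tests are implemented on a common footing (two-sided, alpha 0.05 by
default, minimum k = 3, per-meta failures flagged rather than fatal):

* **Begg** — Kendall tau-b between effect and variance. The default
  variant standardizes the effects first (deviation from the
  inverse-variance pooled mean divided by its exact SD), which is the
  original formulation and removes the correlation the pooled mean induces;
  the literal "lnDOR vs its variance" form is available as
  `variant = "naive"`. The null distribution of the S statistic is
  enumerated exactly (via the inversion-number recursion) for tie-free
  data up to k = 8; beyond that a tie-corrected normal approximation is
  used. A lattice continuity correction on z is available
  (`z_continuity`) but off by default; at k ≥ 8 the corrected
  approximation is within ~0.012 of the exact p everywhere, while the
  uncorrected one can deviate by ~0.08 in the mid-range (where nothing is
  decided) yet stays within 0.02 in the decision-relevant tail.
* **Egger** — WLS of lnDOR on SE(lnDOR) with weights 1/Var. We test the SE
  slope on k − 2 df; dividing the model through by SE shows this is
  exactly the classical "intercept of standardized effect on precision"
  test, an equivalence the suite verifies to 1e-10. Student-t rather than
  normal reference because small k is the norm (corpus median ≈ 13).
* **Deeks** — WLS of lnDOR on 1/√ESS with weights ESS, slope t-test on
  k − 2 df.

Degenerate inputs are flagged, not guessed at: all-tied ranks give p = 1
with a note; an exact linear fit (zero residual variance) or a constant
regressor yields `p = NA` with a degeneracy note, and such results are
excluded downstream with a recorded reason.

## Concordance and moderators

Across a corpus, each test's strict `p < alpha` calls are collated into a
call matrix (p exactly equal to alpha is *not* significant). For each test
pair, agreement is summarized by the raw concordance percentage and
Cohen's kappa with the asymptotic (Fleiss–Cohen–Everitt) standard error
and normal 95% CI. With binary calls, weighted and unweighted kappa
coincide, so no weighting option is exposed. Pairs are formed
complete-case per pair (a meta dropped for one test still contributes to
pairs not involving that test). When both tests return constant calls with
identical margins, chance agreement is 1 and kappa is reported as
undefined with a flag.

Whether concordance relates to meta-analysis characteristics is assessed
by univariable logistic regressions of the pair-specific concordance
indicator on (i) pooled DOR ≥ 38, (ii) the number of studies and (iii) the
number of participants — one odds ratio per factor and pair, matching the
one-OR-per-cell layout conventional for such tables. Choices worth
stating:

* the pooled DOR uses DerSimonian–Laird random effects by default, since
  heterogeneity is the rule in DTA meta-analyses (a fixed-effect option
  exists); the published cut is quoted both as "38 or higher" and
  "DOR > 38", so the indicator is inclusive (≥ 38) by default and
  configurable;
* continuous predictors enter untransformed per unit, which is why
  participants ORs are expected to print as 1.00 with tight CIs;
* separation is detected (non-convergence or |beta| > 15) and flagged with
  no OR reported, rather than silently penalized.

## The synthetic-data generator

Real corpora of extracted 2×2 tables are rarely deposited, so the
generator is the package's ground truth. Its defaults emulate the scale of
a contemporary DTA meta-analysis corpus:

* studies per meta: lognormal, median 13, IQR ≈ 9–19, truncated to
  [4, 118] (the calibration is checked by a property test over 10,000
  draws);
* study size: lognormal, median 100, sdlog 0.6, truncated to [20, 2000] —
  a realistic spread for accuracy studies, chosen once;
* prevalence: Beta(2, 2) truncated to [0.05, 0.95], giving unbalanced
  groups most of the time.

Each study draws a log-DOR `L_i ~ N(Λ, tau²)` and a threshold shift
`θ_i ~ N(0, sigma_theta²)` and sets `logit(sens) = θ_i + L_i/2`,
`logit(1 − spec) = θ_i − L_i/2` — the symmetric-ROC constant-DOR device in
which `logit(sens) − logit(1 − spec) = L_i` holds exactly. Counts are
binomial. Selective publication is an explicit step rule on the one-sided
Wald p for `lnDOR > 0`: significant studies always publish, others publish
with probability `retain_prob`; studies are redrawn until the target k
published studies are collected (capped at 50·k attempts). Selection on
the magnitude of sensitivity/specificity is deliberately not the default
mechanism — it is implausible for most clinical pathways — but the rule
object is pluggable.

All randomness flows from one seed with a documented stream order (per
meta: k; per study attempt: n, prevalence, L, θ, tp, tn, then a
publication uniform *only when the decision is genuinely random*), so
`retain_prob = 1` is stream-identical to no selection and every corpus is
bit-reproducible.

What a green simulation test does and does not establish: the generator
produces unbalanced, heterogeneous, threshold-shifted binomial tables at
realistic corpus scale, but real corpora add features it does not model —
correlated sensitivity/specificity beyond the symmetric ROC, time-lag and
language bias, outcome-dependent extraction error, non-lognormal size
distributions. Calibration and power results here are statements about
this stated world, not about any particular literature.

## Numerical and design choices

* Rounding when reconstructing tables from sensitivity/specificity:
  round-half-to-even, recorded in the result metadata — deterministic and
  unbiased over a corpus; recomputed fractions differ from the inputs by
  at most 0.5/n per group (property-tested).
* Continuity correction: add 0.5 to *all four* cells only when some cell
  is zero (configurable constant, or always-add). The ESS is always
  computed from uncorrected group sizes — it is a design quantity.
* Exact-vs-approximate switch for Begg at k = 8: chosen because 8! is
  cheaply enumerable and the normal approximation is already adequate
  beyond.
* WLS is solved in closed form (two-parameter normal equations); the test
  suite checks it against an independent matrix-algebra oracle to 1e-10.
* Scenario choices in the acceptance suite are part of the stated world:
  the null calibration uses Λ = 0, k = 15, 1000 replicates; the
  type-I-inflation contrast uses DOR = 81 with sigma_theta = 0.75 (high
  accuracy plus threshold variation, no suppression); the power contrast
  uses Λ = ln 2 — a modest DOR chosen so that a sizeable fraction of
  simulated studies are non-significant one-sided and the suppression
  step has something to suppress — with retain_prob 0.2 against a matched
  no-suppression arm at 500 replicates per arm.

## Known limitations

Bivariate/HSROC pooling and bivariate asymmetry tests are out of scope, as
are trim-and-fill adjustment and the Harbord/Peters variants. The kappa CI
defaults to asymptotic, which can be poor for very small corpora
(`ci = "bootstrap"` gives a percentile interval instead). Firth-penalized logistic
regression for separated moderator fits is deliberately replaced by
detect-and-flag. The funnel axis catalogue covers the conventions
expressible from 2×2 tables alone; exotic axes (relative risk, arcsine
differences, AUC) need inputs the corpus format does not carry.
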