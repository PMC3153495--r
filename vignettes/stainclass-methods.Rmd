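---
title: "Scoring EGFR mutation-specific immunohistochemistry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring EGFR mutation-specific immunohistochemistry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainclass)
```

## The problem

Mutation-specific rabbit monoclonal antibodies against the two "classical"
activating EGFR mutations of lung adenocarcinoma — the exon-21 point
mutation L858R and the exon-19 in-frame deletion E746-A750 — make it
possible to screen tumors for EGFR-TKI-sensitising mutations by routine
immunohistochemistry (IHC) instead of DNA sequencing.  The readings are
simple: for each antibody a pathologist records a staining intensity grade
$I \in \{0,1,2,3\}$ and the percentage $P \in [0,100]$ of tumor cells
stained.  The difficulty is *interpretation*: wild-type tumors with high
total-EGFR expression show weak nonspecific staining with the
mutation-specific antibodies, so the conventional positivity rule — more
than 10% of tumor cells at intensity 1+ or more — produces false
positives that track total-EGFR level.

`stainclass` implements a scoring pipeline that addresses this: quickscore
quantification, logistic-regression combination of the mutation-marker
score with total-EGFR expression, ROC-based cutoff selection, diagnostic
accuracy against sequencing truth, and TKI outcome analysis — together
with a seeded synthetic-cohort generator so that every stage is testable
without patient data.

## Scoring

The **quickscore** is $Q = P \times I$, ranging 0–300.  `quickscore()`
validates both readings and returns the product; `intensity_positive()`
implements the conventional rule with a strict inequality on percent
("more than 10%") and an inclusive one on intensity.  A pan-cytokeratin
control gates sample quality: sections whose control shows no staining are
excluded by `read_cohort()`.

Each target mutation is scored under six schemes (`all_schemes()`): the
raw intensity, the raw quickscore, and the four logistic models crossing
the marker feature (intensity or quickscore) with a total-EGFR feature
(intensity or quickscore).  Labels come from the sequencing genotype:
L858R counts any genotype containing an L858R component (complex
mutations such as `L858R+V834L` are carriers), while the deletion target
counts only exact E746-A750 deletions.

## The logistic score combination

`fit_logistic()` is a plain maximum-likelihood binary logistic regression
fitted by iteratively reweighted least squares with step-halving, so the
deviance is non-increasing across iterations; convergence is declared
when the deviance change falls below `1e-8` (at most 100 iterations).
Features enter unstandardized — predicted probabilities are invariant to
affine rescaling.  No regularization is applied.

Two degenerate situations are handled explicitly:

* **Single-class labels** are an error (the model is undefined).
* **Complete separation** — a linear combination of features classifies
  the training data perfectly, so the MLE diverges — is detected when the
  deviance collapses toward zero or a coefficient runs away, and raised
  as an error rather than returned as a silently huge coefficient.
  `fit_logistic(..., firth = TRUE)` provides Firth's bias-reduced
  penalized likelihood (the Jeffreys-prior score correction), which
  remains finite under separation; `evaluate_scheme()` falls back to it
  automatically and flags the result, since small cohorts make
  separation a realistic event.

The combined score of a patient is the fitted probability
$\hat p = \mathrm{logit}^{-1}(\beta_0 + \beta_1 x_\text{marker} +
\beta_2 x_\text{total})$.  In practice $\beta_2 < 0$: at a given marker
score, higher total-EGFR expression makes a false positive more likely,
and the model discounts it.

## ROC construction and the optimal cutoff

`roc_curve()` builds the empirical ROC under the convention *positive
when score ≥ threshold*, with candidate thresholds at every distinct
score plus $\pm\infty$ sentinels; tied scores share one vertex.  The AUC
is the Mann–Whitney statistic (pairwise wins plus half-ties), computed
from midranks in $O(n\log n)$; it equals the trapezoid area under the
curve exactly, and the test suite checks this against an $O(n^2)$
brute-force oracle.  Ordinal intensity scores yield few-vertex curves; no
interpolation or smoothing is applied.

`optimal_cutoff()` selects the vertex minimizing
$d^2 = (1-\text{sens})^2 + (1-\text{spec})^2$, the closest-to-corner
criterion.  Ties on $d^2$ are broken toward the higher-specificity vertex
(fewer false positives), and exact duplicates toward the larger
threshold, so the result is deterministic and equals exhaustive search.

`paired_auc_test()` compares two scores measured on the same patients by
DeLong's nonparametric method: structural components per case and
control, a covariance-aware variance of the AUC difference, and a normal
reference for the two-sided p value.  Confidence intervals for single
AUCs (`auc_ci_delong()`) use the same variance estimate and are labeled
as DeLong intervals.  Zero variance with a zero difference returns
p = 1 by convention; zero variance with a nonzero difference is an error.

## Diagnostic metrics and the printed-rounding convention

`diagnostic_metrics()` computes sensitivity, specificity, PPV, NPV,
accuracy (as percentages) and the likelihood ratios
$LR^+ = \text{sens}/(1-\text{spec})$, $LR^- = (1-\text{sens})/\text{spec}$.
Two conventions are exposed because published clinical tables are typeset
from one-decimal percentages: in `"printed"` mode the percentages are
rounded to one decimal first and the likelihood ratios formed from the
rounded values (to three decimals).  From the 2×2 table 38/23/5/77 the
exact LR+ is $(38/43)/(23/100) = 3.842$ while the printed convention
gives $88.4/23.0 = 3.843$ — reproducing table arithmetic requires the
printed mode.  Zero denominators are flagged (`undefined`), with LR+
reported as `Inf` when specificity is 100%.

Categorical contrasts use Pearson's χ² without continuity correction,
switching to Fisher's exact test when any expected cell count is below 5
(`categorical_test()`).  Wilson score intervals (`wilson_ci()`) are
provided as an extension for uncertainty on proportions.

## Survival analysis

The survival layer wraps the `survival` package behind the pipeline's
interface: `km_estimate()` (product-limit estimator), `logrank_test()`,
and `cox_fit()` (partial likelihood, hazard ratios with Wald intervals).
Choices worth noting:

* **Median survival** is the smallest $t$ with $S(t) \le 0.5$, not the
  midpoint convention some software applies when the curve sits exactly
  at 0.5; an undefined median is flagged, not silently `NA`.
* **Ties** use the Efron approximation by default — month-resolution
  follow-up makes ties common — with Breslow available via `ties=`.
  (Exact duplication-invariance of the estimate holds under Breslow;
  Efron redistributes induced ties slightly.)
* **Median follow-up** uses the reverse-Kaplan–Meier convention
  (`median_followup()`), labeled as such.
* **Responders** are complete or partial responses; stable and
  progressive disease are non-responders (`is_responder()`).
* Non-convergence and monotone partial likelihood (e.g. a group without
  events) are explicit errors.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the pipeline assumes:
157 collected sections of which 14 fall below the 60% tumor-content
enrollment gate; genotypes drawn proportional to 31:10:43:8:50 over
E746-A750 deletion, other Del-19, L858R, other mutation, and wild type
(the source counts sum to 142 against 143 enrolled patients; the
proportions are renormalized rather than resolved); sex and smoking drawn
so that mutation prevalence is 79.2% in females vs 50.7% in males and
77.7% in never-smokers vs 40.8% in ever-smokers (Bayes inversion of the
conditional rates at the cohort's overall mutation rate).

Staining is generated from a latent-Gaussian model:

* **Total EGFR** is genotype-independent, $N(1.3, 1)$ cut at fixed
  thresholds into the 0–3 scale, with percent-positive drawn from
  intensity-dependent Beta distributions.  Independence is a deliberate
  choice: no distribution of total expression by genotype is available,
  and making total EGFR informative about genotype on its own would
  confound the mechanism of interest, in which total EGFR matters only
  through nonspecific staining.
* **Carriers** stain their cognate antibody diffusely (percent from a
  Beta(6, 1.8) scaled to 15–100) with an intensity-grade mix calibrated
  to the observed operating points (L858R: 13.2% / 36.8% / 50% over
  1+/2+/3+ among stained carriers).  A configurable false-negative
  minority (5/43 for L858R, 2/31 for the deletion) does not stain at
  all, so the conventional rule's sensitivity equals
  $1 - \text{false-negative rate}$ in expectation.
* **Non-carriers** receive nonspecific staining through a latent
  $b_m + \kappa\,Q_\text{tot}/300 + (\kappa/10)\,\varepsilon$, with
  $\varepsilon \sim N(0, 1.4)$: cross-reactivity rises with total-EGFR
  quickscore, tumor-level susceptibility noise scales with the mechanism
  strength $\kappa$ (default 10), and $\kappa = 0$ switches nonspecific
  staining off entirely.  The marker baselines and intensity cuts are
  fixed at the exceedance quantiles that reproduce the observed marginal
  operating points simultaneously: ~42% of non-carriers positive for
  L858R under the 1+/>10% rule and ~18% at the 2+ cutoff (9.8% and 5.4%
  for the deletion antibody).
* One "other Del-19" tumor per cohort (the L747-T751 deletion pattern) is
  made cross-reactive with the deletion antibody.

`simulate_outcomes()` adds recurrence (rate 80/143), TKI treatment
(37/80 of recurrent patients), responder flags by IHC status (77.3% vs
33.3%), and exponential progression-free survival with group medians
12.0 and 4.7 months.  Censoring is *independent* uniform
$U(0, m)$ with $m$ solved so the expected censored fraction equals
`censor_rate` (default 0.2) — censoring at a uniform fraction of the
event time would be informative and bias the Kaplan–Meier estimator.
An optional scenario flag adds a hazard multiplier of 5.52 for poor
performance status (ECOG 2–4).

Under these conditions the combined (marker Q + total-EGFR Q) logistic
score discriminates better than intensity alone in the large majority of
cohort-sized replicates, and at matched-or-higher sensitivity it admits
fewer false positives than the conventional rule — the two directional
claims the test suite verifies.  A caveat on the second: the
closest-to-corner cutoff generically trades a little sensitivity for
specificity, so the comparison is made at matched sensitivity on the
ROC, which is also how the false-positive-rate contrast is defined.

**What the generator does not emulate.**  Staining distributions are a
modeling choice (latent Gaussians and Betas); real inter-observer
variability, intratumoral heterogeneity (beyond the all-or-nothing
false-negative mechanism), batch effects in staining, sequencing error,
and any correlation between staining strength and outcome within IHC
strata are absent.  Passing tests therefore demonstrate the correctness
and calibration of the *pipeline*, not clinical performance on real
tissue.

## Problem sizes in the test suite

Stochastic checks run at sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: marginal calibration at 20k–100k
simulated tumors, parameter recovery at n = 2000–5000, the AUC ordering
over 100 cohort replicates of the study's size (n = 143), the DeLong vs
bootstrap comparison with 20,000 resamples of an n = 30 fixture, and the
log-rank type-I error over 500 null simulations of n = 1000.

## Known limitations

* Separation handling detects *complete* separation via deviance
  collapse; quasi-complete separation may instead surface as
  non-convergence after 100 iterations.
* The printed-rounding mode reproduces one-decimal table arithmetic;
  exact mode should be used for any further computation.
* DeLong inference is asymptotic; with very few cases or controls the
  paired bootstrap is the safer reference (the suite quantifies the
  agreement at n = 30).
* The Cox wrapper exposes only right-censored, time-fixed covariates —
  sufficient for the pipeline's multivariate PFS model.
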