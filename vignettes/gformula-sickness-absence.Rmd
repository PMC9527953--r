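---
title: "Counterfactual sickness-absence rates with the parametric g-formula"
author: "gabsence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual sickness-absence rates with the parametric g-formula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Psychosocial working conditions — bullying, low influence at work, poor
leadership quality, high demands — are consistently associated with sickness
absence. The policy question is prospective: *how much lower would a
workforce's sickness absence rate be if the psychosocial environment were
improved?* `gabsence` answers this with the parametric g-formula on a
one-wave occupational cohort: fit an outcome model for individual absence
hours, replace the observed exposure levels with intervened levels, predict
every employee's counterfactual absence, and standardize over the observed
covariate distribution.

Two contrasts are reported per factor (and for all factors jointly), each as
a rate ratio (RR) for the total, short- (1–3 days), intermediate- (4–28
days) and long-term (≥ 29 days) absence rate:

* **etiologic**: everyone at the most desirable level vs. everyone at the
  least desirable level — an all-treated vs. none-treated trial analogue,
  independent of the observed exposure distribution;
* **realistic**: everyone at the most desirable level vs. everyone at their
  observed level — a population-attributable-fraction analogue
  (`1 − RR` is the prevented fraction of the absence rate).

# The model and its assumptions

## Exposures

Seventeen psychosocial factors are handled: fifteen *working conditions*
(eleven Likert scales plus four binary adversities — bullying, sexual
harassment, threats, violence) and two *cognitive and emotional reactions*
(job satisfaction, perceived stress). Likert items are mapped linearly to
0–100 (`100·(response − 1)/(K − 1)`, reversed items flipped so higher is
always more desirable), averaged into scale scores, and categorized
Low/Medium/High at the 25th/75th percentile of the analysis sample "or as
close as possible": cutpoint candidates sit at observed score values, each
side minimizes the distance between its achieved tail share and 25%, and
ties break toward the *smaller* extreme group so the intervention target is
never inflated. Achieved shares are recorded in the `sa_cutpoints` object,
never discarded. Binary adversities are Yes/No; the desirable level is
always High (scales) or No (binaries).

Items with partial missingness follow the instrument convention: a scale
score is computed when at least half its items are present (`na_rule =
"half"`, switchable to `"strict"`). Employee-level missingness is all-or-none
in the generator, matching a person-level complete-case definition.

## Outcomes

Absence spells are classified by their full duration into the three terms
(1–3 / 4–28 / ≥ 29 days); terms are mutually exclusive, so per-employee term
hours sum *exactly* to total hours. Rates divide absence hours by fixed
(contracted) working hours over the one-year follow-up; employees with
non-positive fixed hours are excluded with a logged count because the model
offset is undefined for them.

## Missing exposure data

A logistic model of completeness on the sociodemographic, workplace and
employment covariates is fitted on all eligible responders; complete cases
are weighted by `1/P(complete | X)` (weight 0 for incomplete employees).
The paper-style wording "inverse probability of having *incomplete*
information" is read as the standard complete-case IPW estimand — weighting
by the inverse probability of being *complete* — since the former does not
yield a consistent reweighting. Weights are truncated at their 99th
percentile by default (switchable off); under separation the logistic fit
falls back to a lightly ridge-stabilized version.

## Outcome models

Eight weighted Poisson regressions (two exposure blocks × four terms)
predict individual absence hours with `log(fixed hours)` as offset. The
working-conditions block adjusts for the covariates only; the reactions
block additionally contains the fifteen working conditions (default), so one
model holds all seventeen factors and can serve the joint scenario — the
narrow reading, adjusting reactions for the shared covariates only, is a
switch. Hours are treated as a continuous nonnegative response under the log
link: a quasi-likelihood estimating equation whose dispersion is irrelevant
here because only mean predictions enter the g-formula and uncertainty comes
from resampling, not model-based standard errors.

Estimation is ridge-penalized IRLS maximizing the weighted log-likelihood
minus `λ/2‖β‖²` over the penalized block, intercept never penalized, columns
standardized to weighted mean 0/sd 1 so penalization is scale-equivariant.
Convergence requires a relative penalized-deviance change below `1e-8` and is
then *polished* until the Newton step is numerically zero — Newton steps
converge quadratically, so this costs 1–3 extra iterations and makes
closed-form identities (the intercept-only solution, the weighted score
equation `Σwŷ = Σwy`) hold to near machine precision. Coefficients are boxed
at ±30 on the standardized scale: beyond that a cell is separated and its
fitted mean is numerically 0 anyway.

## Penalization choices (design rationale)

Two decisions here were genuinely open and were settled by measurement:

1. **What is penalized.** `fit_ridge_poisson()` penalizes every slope (the
   textbook objective). The pipeline, however, penalizes *only the
   exposure-factor dummies* (`penalize = "factors"`), leaving confounder
   coefficients free. The ridge exists to stabilize the mutually correlated
   work factors; a single λ shared with the covariates cannot both fit the
   real covariate signal and shrink factor noise — in null-effect
   simulations the joint all-factor contrast drifted to RR ≈ 0.4 purely from
   unshrunk factor noise, while shrinking covariates instead would trade
   confounding bias for nothing. Exempted columns receive a negligible
   stabilizing ridge (10⁻⁴ of the information scale) so quasi-separated
   bootstrap subsets keep a finite optimum.
2. **How λ is chosen.** `select_penalty()` does seeded k-fold CV on held-out
   weighted Poisson deviance and returns the grid argmin (ties to the larger
   λ). Because hours are heavily overdispersed relative to the Poisson
   working model, the CV curve is nearly flat and the argmin is noisy; the
   pipeline therefore defaults to the one-standard-error rule — the largest
   λ within one SE of the minimum — the standard conservative choice.

The consequence, stated plainly: ridge shrinkage biases rate ratios toward 1,
and the conservative default shrinks hard when effects are small relative to
the noise. Parameter-recovery checks therefore pin the penalty near 0, while
pipeline runs record the selected penalty in every output row. Users wanting
maximally anti-conservative point estimates can pass `penalty = 0` (or
`cv_rule = "min"`) and rely on the BLB intervals.

Weights and the penalty share one scale: multiplicity weights from the
bootstrap sum to `n` and carry pseudo-sample-size information, so the penalty
is deliberately *not* normalized away; the fit is invariant to row order,
exactly invariant to weight rescaling at `λ = 0`, and jointly scale
equivariant — `fit(c·w, c·λ) = fit(w, λ)`.

## The g-formula step

Interventions act only on the exposure columns; covariates and offsets are
never modified (static, single-wave point exposure — there is no
treatment-confounder feedback to model). The standardized rate under a
scenario is `Σᵢ wᵢ ŷᵢ(scenario) / Σᵢ wᵢ Tᵢ` over complete cases, with the
design re-encoded through frozen metadata (factor levels, column set,
standardization constants), so counterfactual predictions use exactly the
training encoding. Single working-condition factors are evaluated on the
working-conditions models; single reactions and the joint set on the
all-17-factor models; non-targeted factors stay at observed levels. The full
enumeration — 18 factor sets × 2 contrasts × 4 terms = 144 rows — is emitted
as one tidy table, or the run fails loudly.

## Uncertainty: Bag of Little Bootstraps

Confidence intervals come from the Bag of Little Bootstraps: `s` disjoint
subsets of size `b = ⌈n^γ⌉` (defaults γ = 0.7, s = 10, r = 50 — standard BLB
practice; all configurable), `r` multinomial weight vectors of total mass `n`
per subset, the full estimator re-run on each weighted resample (the
completeness model is refit inside each resample by default so
weight-estimation uncertainty propagates; switchable for speed), within-
subset percentile intervals, bounds averaged across subsets. RR intervals are
formed on the log scale and exponentiated. The estimator returns all 144
contrasts at once, so one BLB pass prices the whole table. Model refits
inside resamples reuse the penalties selected on the full data. A resample on
which the estimator fails is recorded; a subset with > 20% failures is
dropped and any dropped subset aborts the run — the conservative default.
Percentile intervals need not contain the full-data point estimate; the
package asserts only `lower ≤ upper`.

# The synthetic-data generator

Because the motivating cohort is not public, the generator *states* a world
with the published structure and known truth:

* **Covariates**: 79% women, 35% part-time, eight occupational groups
  dominated by nurses (34%), age ≈ N(45, 11) truncated to 18–69, log-normal
  household income, exponential-ish seniority, 20 workplaces with N(0, 0.1)
  log-rate effects.
* **Exposures**: ordinal items from a Gaussian copula — a per-factor latent
  with loading 0.3 on an "adversity composite" of part-time work,
  occupational group and income, inter-item correlation 0.5, thresholded
  into equal-probability bins (reversed items flipped); binary adversities
  as Bernoulli with covariate-dependent logits (prevalences 3–8%).
* **Outcomes**: expected absence hours follow
  `T·baseline·exp(covariate effects)·Π RR_f^{s_f}` with `s_f` = 1/0.5/0 for
  the desirable/middle/least-desirable realized level, calibrated so the
  expected overall rate is exactly 4% of fixed hours. Spell counts are
  Poisson per term with expected hours split 37/32/31 across terms; spell
  durations are uniform{1,2,3} (short), 4 + truncated-geometric with mean ≈ 8
  days (intermediate), and 29 + truncated-geometric with mean ≈ 45 days
  capped at 365 (long) — right-skewed, lower-end-realistic choices for
  hospital employees, fixed once. Spell hours are duration × daily contracted
  hours (7.4 for full time; the instrument never states an hours-per-day
  conversion, so it is a parameter — only ratios matter downstream).
* **Missingness**: logistic-in-covariates (MAR) with the intercept solved by
  root finding to hit the target incomplete share (default 15.3%),
  all-or-none across a person's items.
* **Defaults as stated world**: default true effects mirror the published
  per-factor etiologic RRs (bullying 0.86, perceived stress 0.90, skill
  discretion 0.91, all others 0.97), whose product ≈ 0.46 matches the
  published joint contrast.

The ground-truth object stores every employee's generating rate components,
so `ground_truth_rr()` computes any scenario contrast by *exact enumeration*
over the generated cohort (reported as `method = "exact_enumeration"`) — for
most-vs-least contrasts this reduces to the analytic product of per-factor
RRs. One stated conflict: the spell mixture is sometimes described by
spell-count weights, but the published decomposition (37/32/31) and the
convergence property both concern *hours*; the generator lets `term_split`
govern expected hours shares and derives per-term spell intensities from
them.

What a green test does **not** establish: the generator draws Poisson spell
counts (no extra overdispersion beyond the compound-Poisson hours process),
uses a single exposure wave, one workplace level of clustering, and
item-threshold structure exactly matched to the analysis's categorization.
Real cohorts have negative-binomial-ish spell counts, informative cluster
effects, and measurement drift; recovery results here validate the
estimator's logic, not its robustness to those violations.

# Numerical choices and degenerate inputs

* Cutpoints need ≥ 3 distinct score values; otherwise the factor must be
  declared binary or excluded (error, not silent).
* `score ≤ lower_cut` → Low and `score ≥ upper_cut` → High, so boundary
  scores always land in the extreme groups.
* CV folds with zero total weight are an error; fold assignment is seeded.
* An unseen category at prediction/rebuild time is an error (encoding
  mismatch), never silently re-leveled.
* Seed plumbing: one master seed derives the generation, missingness, CV and
  BLB seeds (`derive_seed`), so a pipeline run is reproducible byte-for-byte
  from its config; all derived seeds stay below 2³¹.

A caution on BLB settings: each subset's percentile interval is centered at
that subset's own estimate, so the averaged bounds are centered at the mean
of `s` independent size-`b` estimates — with dispersion
`σₙ·√(n/(s·b))` against a half-width of about `1.96·σₙ`. When `s·b ≪ n`
(e.g. `s = 5` with `b = n^0.7` at `n = 4000`, covering 42% of the sample)
this caps two-sided coverage near 79% no matter how good the estimator is,
and heavy-tailed influence (rare long spells) narrows the subset widths
further. Choose `s ≈ n/b` — the package default `s = 10` at these sizes —
for near-nominal coverage; the acceptance suite measures this undercoverage
rather than hiding it.

# Known limitations

* Short-, intermediate- and long-term rates are treated as mutually
  exclusive outcomes; shortening a long spell into an intermediate one is a
  transition no single-spell classification can express (multi-state
  modelling is out of scope).
* The two-block model structure guards against adjusting working-condition
  effects for their own downstream reactions, but no formal mediation
  decomposition is attempted.
* Ridge-CV defaults are deliberately conservative (see above); realistic
  contrasts from default pipeline runs on small cohorts will sit close to 1.
* The factor→item map is user configuration; the shipped 40-item map is a
  synthetic stand-in with the field-typical structure, not the original
  instrument's wording or allocation.
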