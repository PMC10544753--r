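---
title: "Non-invasive NASH screening: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive NASH screening: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nashscreen)
```

## The problem

Non-alcoholic steatohepatitis (NASH) — the inflammatory, progressive subset of
non-alcoholic fatty liver disease (NAFLD) — is formally diagnosed by liver
biopsy, which no population survey can perform. Surveys such as NHANES III do,
however, carry hepatic ultrasound (grading steatosis none / mild / moderate /
severe) plus the laboratory panel needed by several biopsy-validated clinical
scores. This package operationalizes that two-stage logic: ultrasound defines
the NAFLD set (moderate-to-severe steatosis with other liver-disease causes
excluded), and within that set each score flags probable NASH. Everyone else is
"normal/mild". Each scheme therefore assigns one of three classes:
normal/mild steatosis, simple NAFLD, or NASH.

## The three scores

All laboratory units follow NHANES conventions: glucose mg/dL, insulin
µU/mL (= mU/L), AST/ALT U/L. Helpers `insulin_pmol_to_uU()` and
`glucose_mmol_to_mgdl()` convert from SI units. The insulin units in the liver
fat score deserve a note: the original formula's publication used mU/L, which
equals µU/mL, and that is what `nash_lfs()` expects; the conversion helper
exists precisely because this is a common source of silent error.

**HAIR** (`hair_score()`): one point each for HOMA-IR > 5, ALT > 40, and
hypertension (BP ≥ 140/90, a prior diagnosis, or antihypertensive
medication); positive at ≥ 2 of 3 points. HOMA-IR itself
(`compute_homa_ir()`) uses the Matthews formula, glucose × insulin / 405 —
the formula is not restated in every clinical publication that uses it, so it is
pinned here explicitly.

**Gholam** (`gholam_score()`): 2.627·ln(AST), plus 2.13 for type-2 diabetes
defined as prior diagnosis or fasting glucose *strictly greater than*
126 mg/dL; positive at ≥ 8.22. The natural logarithm is used.

**NASH liver fat score** (`nash_lfs()`):
1.18·MS + 0.45·DM + 0.15·insulin + 0.04·AST − 0.94·(AST/ALT) − 2.89, with
metabolic syndrome coded 0/1 and diabetes coded 0/2 (diagnosis, fasting
glucose ≥ 126, *or* 2-hour glucose ≥ 200 mg/dL — deliberately not the same
definition as Gholam's; the package keeps the two distinct). Positive at
≥ 2.122. The source describes the cutoff without an inequality direction;
we adopt the inclusive comparison to mirror the other scores' "≥" phrasing
and expose `lfs_cutoff_inclusive` in `nash_thresholds()` for the strict
reading. Since the score is continuous, the choice is measure-zero in
practice but must still be fixed and tested.

**Metabolic syndrome** is the harmonized 3-of-5 criterion set (waist > 94 cm
men / > 80 cm women; triglyceride ≥ 150; HDL < 40 men / < 50 women;
BP ≥ 130/85 or treated; glucose ≥ 100 or treated). The blood-pressure
criterion's "≥ 130/85" is ambiguous between requiring both limbs or either;
we default to both (`ms_bp_rule = "and"`) — the conjunctive reading of a
compound BP threshold — and provide `"or"` by configuration.

Every cutoff and coefficient lives in one table, `nash_thresholds()`, so a
sensitivity analysis changes one argument rather than hunting constants.

## Combined classifications and screening algebra

Beyond the three single methods, two combinations are computed per subject:
`all3` (NASH only if all three scores are positive) and `any1` (NASH if at
least one is). For independent tests these correspond to the classical
serial (AND) and parallel (OR) screening compositions implemented by
`net_serial()` and `net_parallel()`:

* serial: SE = ∏ SEᵢ, SP = 1 − ∏ (1 − SPᵢ)
* parallel: SE = 1 − ∏ (1 − SEᵢ), SP = ∏ SPᵢ

The pairwise textbook formulas extend associatively to *k* methods, which is
how the package generalizes them. Two consequences are asserted as package
invariants: serial sensitivity never exceeds the weakest method's (and its
specificity never falls below the strongest's), with the mirror-image
statement for parallel; and on every dataset the prevalence ordering
all3 ≤ each single method ≤ any1 holds by set containment. Conditional
independence of the methods' errors is assumed by the formulas — the three
scores share inputs (AST appears in two of them), so the composed values are
an approximation, which is the standard caveat of screening algebra.

```{r netperf}
net_performance_table()[, c("combination", "lfs_variant", "sensitivity", "specificity")]
```

`published_performances()` carries the validation-study values (HAIR
0.80/0.89; Gholam 0.76/0.66; liver fat score 0.595/0.797 in its Finnish
validation and 0.929/0.327 in its Italian one), and the table above is what
the serial/parallel algebra does to them.

## Eligibility and exclusions

`apply_exclusions()` reproduces the standard fatty-liver eligibility logic:
age 20–74 inclusive; gradable ultrasound; no chronic hepatitis B (HBsAg and
anti-HBc both positive) or C (antibody and RNA both positive); transferrin
saturation ≤ 50 % (iron-overload predisposition); average alcohol at most
2 drinks/day for men and 1 for women (strict "more than" excludes);
no steatogenic medication; then listwise deletion over a configurable
required-field set. Published cohort flows give these as an unordered pool,
so the package fixes a precedence order (the order of
`exclusion_reasons()`) and counts each subject exactly once under the first
matching reason — making the flow tally reproducible and the partition
invariant (`n_input = n_retained + Σ exclusions`) testable. Missing serology
is treated as negative with a warning: exclusion demands positive evidence
on both tests.

## Design-based estimation

NHANES-type samples are stratified multistage cluster designs; ignoring the
design biases variances badly. Because the statistical layer is part of what
this package provides, the design machinery is implemented here directly:

* **Weighted prevalence** (`weighted_prevalence()`): ratio estimator
  Σwᵢyᵢ/Σwᵢ with Taylor-linearized variance over strata and PSUs
  (with-replacement first-stage approximation, the documented NHANES
  default), degrees of freedom #PSUs − #strata. Confidence intervals are
  formed on the logit scale and back-transformed, keeping them inside
  [0, 1]; a Wald interval on the proportion scale can stray outside it at
  the small prevalences (2–10 %) this problem lives at. Degenerate
  prevalences of exactly 0 or 1 return zero-width intervals.
* **Direct age standardization** (`direct_standardize()`): Σ std(g)·prev(g)
  over the four age groups 20–34, 35–49, 50–64, 65–74. Two bundled standard
  populations (`standard_population()`): the year-2000 projected US standard
  and the 1990 census distribution, each renormalized to ages 20–74 from
  published 5-year census tables — approximations at the ±0.1 % level,
  stated as such in their help page.
* **Association tests** (`rao_scott_chi2()`): Pearson statistic on the
  weighted contingency table with a first-order Rao–Scott correction — the
  statistic is divided by the mean generalized design effect estimated from
  linearized cell and margin design effects. A naive Pearson test on
  weighted data is invalid under clustering, which is why the corrected form
  is the default; `correction = FALSE` gives the uncorrected statistic. The
  binomial reference variance uses the n−1 divisor so that, with equal
  weights and each subject its own PSU, the statistic collapses *exactly*
  onto the classical Pearson value.
* **Risk-factor models** (`fit_weighted_multinomial()`): baseline-category
  multinomial logit maximizing the weighted pseudo-log-likelihood by full
  Newton–Raphson (analytic gradient, expected information, step-halving;
  convergence at gradient max-norm 10⁻⁸ after normalizing weights to mean 1,
  at most 100 iterations, with a clear error carrying the iteration count
  and gradient norm otherwise, and a separation warning when any
  |coefficient| exceeds 15). Covariance is the design sandwich: inverse
  information × linearized covariance of the score totals × inverse
  information. `or_aor_table()` produces the conventional risk-factor table —
  adjusted odds ratios from the joint model, unadjusted from single-covariate
  refits — with t-based intervals on the design degrees of freedom.

Equal-weight reductions are the key correctness anchors, and all are tested:
prevalence → simple proportion; Rao–Scott → classical Pearson; weighted
multinomial → ordinary maximum likelihood (binary case checked against
`glm`, three-class against `nnet::multinom`, both independent optimizers).
No multiplicity adjustment is applied across contrasts (α = 0.05,
two-sided), matching standard practice for descriptive risk-factor tables.

## The synthetic-cohort generator

`generate_cohort()` exists so that every stage — including the survey
machinery — can be exercised end-to-end with known truth. Its model:

* a three-level latent liver state drawn from a multinomial logit whose NASH
  equation carries the configured covariate odds ratios, with intercepts
  recalibrated (iterative proportional adjustment) so the *marginal* latent
  prevalences still match the configured values — by default 80 % / 12 % /
  8 %, an NAFLD burden of ~20 % of which ~40 % NASH, consistent with
  ultrasound-era US population estimates;
* class-conditional Gaussian / log-normal laboratory values, with the
  score-relevant tails (insulin, glucose, AST, ALT, blood pressure, waist)
  shifted by class so each score discriminates the latent state imperfectly
  — sensitivities and specificities strictly inside (0, 1), verified by
  test;
* ultrasound moderate/severe for latent NAFLD/NASH and none/mild for latent
  normals, crossed at a 2 % misgrading rate, plus 1 % ungradable scans;
* exclusion-relevant fields (serology, transferrin saturation, alcohol,
  steatogenic medication) at low population rates so the eligibility stage
  has real work;
* a stratified design (default 15 strata × 2 PSUs) with every cell
  guaranteed non-empty and log-normal weights normalized to mean 1 at a
  configurable coefficient of variation (default 0.5).

The generator is deterministic given its seed (RNG kind pinned, caller's RNG
state restored) and transparent by construction — conditionally independent
labs given class, no measurement-error model, no within-PSU intra-class
correlation beyond what the latent-class mixture induces. Real survey data
differ in all those ways, plus informative weighting and item-nonresponse
structure. Passing tests on this generator therefore demonstrate the
*estimators and plumbing* are correct, not that the scores themselves have
any particular accuracy in the real population: score accuracy against the
latent state here is whatever the chosen lab shifts imply, and the published
real-data prevalences are not reproduction targets.

## Simulation scale and numerical choices

The test suite runs its heavier checks at sizes chosen to give clean
statistical resolution: prevalence-interval coverage at 100 replicates of
n = 10,000; odds-ratio recovery (a configured NASH odds ratio of 3.0 on a
binary covariate) at 100 replicates of n = 50,000, asking the nominal 95 %
interval to cover in at least 93; composition-formula simulation at 10⁶
subjects per arm, matching within 3 Monte-Carlo standard errors. Tie-breaks
worth restating: HOMA-IR exactly 5 and ALT exactly 40 score no HAIR point
(strict), BP exactly 140/90 does (inclusive); Gholam and liver-fat-score
cutoffs are inclusive; waist exactly at the metabolic-syndrome cutoffs does
not qualify (strict ">"), while triglyceride, BP and glucose cutoffs are
inclusive ("≥"). Category boundaries for cholesterol (200), CRP (0.3, 1),
C-peptide (0.26, 1.03) and HEI (50, 80) place the shared endpoint in the
middle band, resolving the overlapping printed ranges one way, once, in
`nash_thresholds()`.

One further documented wrinkle: the published waist-hip-ratio risk cutoffs
appear with the sexes swapped in one place in the source literature's text;
the package follows the methods-section version (at-risk at ≥ 0.90 for men,
≥ 0.85 for women). And of the published combined-screening ranges, the
parallel net-sensitivity "97 %" endpoint cannot be recovered from the
published single-method inputs (the high-sensitivity liver-fat-score variant
gives 99.7 %); the package reports what the algebra gives.

## Limitations

Scores are treated as error-free functions of their inputs (no lab
measurement error model); the serial/parallel algebra assumes conditional
independence; the weighted multinomial uses a pseudo-likelihood, so
likelihood-ratio tests are not provided (use Wald statistics); and the
bundled standard populations are 4-group approximations. The pipeline
performs listwise deletion, never imputation — by design, as the analysis it
reproduces did the same.
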