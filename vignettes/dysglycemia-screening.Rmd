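---
title: "Evaluating diabetes risk scores as dysglycemia screening tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating diabetes risk scores as dysglycemia screening tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubdrisc)
```

## The screening problem

Questionnaire risk scores are used to triage adults for an oral glucose
tolerance test (OGTT). A score is an additive total over eight items; the
screening question is how well `score >= cutoff` predicts *dysglycemia* —
any glucose-regulation disorder on the OGTT, i.e. prediabetes (altered
fasting glucose, altered glucose tolerance, or both) or previously
undiagnosed type 2 diabetes. This package scores three scale variants
(FINDRISC and its Latin-American and Cuban waist-circumference adaptations),
classifies the OGTT gold standard, and evaluates and compares the scales as
diagnostic tests.

## Scoring model and band conventions

Each scale is a banded lookup per item; the total is the sum of per-item
points (0--26 for all three variants, which differ *only* in the waist
bands). Published scoring tables state bands like "25--30" and "higher than
30" without specifying boundary closure, so the package fixes these
conventions once:

* **BMI**: `[25, 30]` scores 1 point, strictly above 30 scores 3. The waist
  middle band of FINDRISC is likewise closed: men `[94, 102]` -> 3, `> 102`
  -> 4; women `[80, 88]` -> 3, `> 88` -> 4. This matches the "lower
  than"/"higher than" wording of the outer bands.
* **Age** bands are integer-year closed bands: `<45`, `45--54`, `55--64`,
  `>=65`.
* **Risk categories**: `<7` low (1% ten-year risk), `7--11` slightly
  elevated (4%), `12--14` moderate (17%), `15--20` high (33%), `>=21` very
  high (50%). Published descriptions disagree between "15--19" and "15--20"
  for the high band; the package follows the tabular form (15--20), treating
  the scoring table rather than narrative prose as the operative artifact.
* **Family history**: a spouse's gestational diabetes is grouped with
  second-degree relatives (3 points); first-degree relatives score 5.
* A directly supplied BMI takes precedence over one derived from height and
  weight (`weight / height^2`, unrounded).

Bands are stored as ordered `(lower, upper, points)` triples with open ends
`null`; a value belongs to the *first* matching band, which is how adjacent
closed bands sharing a boundary (30 kg/m2, 102 cm) resolve deterministically.
The JSON (de)serializer (`scale_to_json()`) preserves this ordering so users
can register further national variants. Missing questionnaire items are a
hard error naming the item — silent imputation would bias a screening
evaluation in ways invisible downstream.

## OGTT classification

The canonical unit is mmol/L; mg/dL inputs convert with divisor 18.0 (the
conventional factor; the difference from the exact molar mass ratio 18.016
is far below threshold resolution). The five states partition the
(fasting, 2-hour) plane with thresholds 5.6 and 7.0 mmol/L fasting, 7.8 and
11.1 mmol/L at 2 hours; diabetes is diagnosed by *either* measure
(`fpg >= 7.0` or `g2h >= 11.1`). Values exactly on a threshold belong to the
higher category, since the diagnostic inequalities are all `>=` at lower
bounds. The tests verify this is a true partition (exactly one state per
point on a 10^6-point grid) and that raising either glucose value never
moves a record toward normal.

## Accuracy methodology

Positivity is `score >= cutoff` throughout (operating cutoffs are
conventionally reported as ">= k"). Confidence-interval methods are not
dictated by any published analysis we mirror, so the package uses standard
closed-form choices, all at level `1 - alpha` (default 95%):

* **Proportions** (Se, Sp, PPV, NPV): Wilson score interval — better
  coverage than Wald near the boundaries typical of specific screening
  cutoffs. Zero-denominator metrics are returned as `NA` with an `undefined`
  flag instead of propagating NaN.
* **Likelihood ratios**: Simel's log-transform interval. A perfectly
  specific table reports LR+ as infinite with a one-sided interval (0.5
  continuity correction for the lower bound).
* **AUC**: trapezoidal area over the threshold sweep (all distinct observed
  scores plus a `+Inf` sentinel). For a discrete score this equals the
  pairwise-comparison statistic P(case > control) + 0.5 P(tie) exactly; the
  test suite asserts agreement to 1e-12 and cross-checks against `pROC`. The
  standard error is Hanley--McNeil's; accuracy bands (excellent/very
  good/good/sufficient/poor/not useful at 0.9/0.8/0.7/0.6/0.5) are closed on
  the left.

Because these interval methods are a package choice, published intervals are
matched approximately, not bit-exactly. Reported tables round percentages to
1 decimal and kappa/AUC to 2 decimals; internal values keep full precision.

**Optimal cutoffs.** Two rules are provided because published "optimal"
cutoffs rarely state their criterion: the Youden maximum of `Se + Sp - 1`,
and a likelihood-ratio-constrained variant that first restricts to cutoffs
with LR+ > 2 and LR- < 0.5 (falling back to Youden, flagged, when the
feasible set is empty). Ties break toward the *lower* cutoff: in screening,
sensitivity is the priority. Degenerate inputs (single-class labels,
all-identical scores) are errors, not silently returned cutoffs.

A note on predictive values: published per-cutoff tables in this literature
sometimes print PPV/NPV that are not algebraically consistent with their own
Se/Sp and group totals (plausibly computed on subsample denominators). The
package always derives PPV/NPV from the 2-by-2 table itself, so such rows
are reproduced only up to that inconsistency; the likelihood ratios, which
depend on Se/Sp alone, are reproduced at display precision.

## Concordance

Scales are compared as *decisions*: at each cutoff, Cohen's kappa between
`reference >= k` and `variant >= k` on the same records. Two standard errors
are computed — the Fleiss-Cohen-Everitt large-sample SE (reported alongside
kappa) and the null-hypothesis SE (used for the test of kappa = 0). Strength
is interpreted on the Landis--Koch scale after rounding kappa half-up to two
decimals, so the printed strength always matches the printed kappa; with
that rule, values below 0.005 band as "poor" (they print as 0.00).

## The synthetic cohort generator

No raw screening dataset is shipped; `generate_cohort()` emulates one so the
pipeline is testable end to end. Its defaults describe a risk-factor-enriched
adult screening population: 58.7% women; age bands <45/45--54/55--64/>=65 at
34.7/19.9/19.3/26.1%; BMI bands <25/25--30/>30 at 46.5/35.9/17.6%; item
prevalences (physical activity 53.3%, daily fruit/vegetables 17.4%,
antihypertensives 47.5%, prior high glucose 35.5%, first-degree family
history 29.9%, second-degree 15% — the latter rarely reported, hence a
configurable package default); outcome mix
normal/AFG/AGT/AFG+AGT/DM2 = 65.5/21.4/3.5/3.2/6.4%, i.e. 34.5% dysglycemia.

Only two couplings beyond independent marginals are modelled, the simplest
structure that reproduces the qualitative behaviour of real screening data:

1. **Waist given sex and BMI band** — log-normal around per-sex locations
   (men 84/94/105 cm, women 78/88/100 cm across the three BMI bands,
   `sdlog` 0.07), so abdominal obesity tracks overall adiposity and sex.
2. **Outcome given score** — a cumulative-logit (proportional-odds) link on
   the FINDRISC total over the severity ordering
   normal < AFG < AGT < AFG+AGT < DM2. The slope (`link_slope`, log-odds per
   score point) is the discrimination dial; the four intercepts are
   *calibrated at generation time* by solving, per intercept, for the value
   that makes the cohort-averaged tail probability hit its configured
   marginal (monotone root-finding, so calibration always succeeds for valid
   outcome probabilities). The default slope 0.22 was fixed once by a
   calibration experiment targeting a FINDRISC-vs-dysglycemia AUC near 0.75
   — the discrimination regime of risk-factor-enriched screening cohorts —
   and is not a published quantity.

Ages are uniform within their band (20--44, 45--54, 55--64, 65--89); BMI is
truncated log-normal within its band. The glucose pair is drawn from
state-conditional truncated normals inside each state's threshold box (with
a 20%/20% share of diabetic records elevated in only the fasting or only the
2-hour measure), so `classify_ogtt()` recovers the latent state on *every*
record — an invariant the tests assert across seeds. The generator records
its seed, configuration and calibrated link as attributes (and in a sidecar
JSON when written to disk), which also lets tests compare the *estimated*
optimal cutoff with the generative optimum computed from the link itself.

`require_risk_factor` (default off) rejection-samples until every record
passes the eligibility screen (age >= 45, BMI >= 25, family history,
elevated waist, hypertension, sedentary lifestyle, plus optional
lipid/obstetric criteria). It is off by default deliberately: the configured
marginals already describe an *enriched* population, so re-filtering would
condition twice and visibly shift the marginals (e.g. physical activity by
about 0.7 percentage points).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: joint dependencies among questionnaire items beyond
the two modelled couplings, age--adiposity correlation, measurement error in
glucose or anthropometry, non-response and attrition, and any real
population's exact kappas or AUCs (unidentifiable from marginals alone).
Tests built on it establish *internal* correctness and qualitative regime,
not external validity.

## Problem sizes and numerical choices

Routine tests run on cohorts of 10^3--2x10^4 records; the marginal-recovery
check uses n = 100,000 (each configured prevalence within 3 binomial SEs)
and the cutoff-recovery experiment n = 50,000 at a fixed seed, sizes at
which Monte-Carlo error is well below the tolerances being asserted while
the whole suite stays fast. AUC equality with the pairwise statistic is
asserted at 1e-12 over 200 random instances of n <= 200 (the brute-force
oracle is quadratic). Root-finding for link calibration uses bisection
tolerance 1e-10 on the interval [-50, 50] of the logit intercept. Glucose
boxes keep a 1e-6 mmol/L margin below open upper thresholds so
floating-point quantile inversion cannot land exactly on a boundary.

## Limitations

* The three scales are assumed to share all non-waist items exactly; scales
  with different item structures can be registered via JSON but the
  cross-scale invariants tested here need not hold for them.
* Ten-year-risk percentages attached to score categories are reported labels
  from the original instrument, not predictions of this package; no
  longitudinal incidence modelling is attempted.
* HbA1c-based diagnosis and repeat-test confirmation are out of scope; the
  gold standard here is a single OGTT.
* Kappa is unweighted and two-rater; the concordance module does not
  generalize to multi-rater or ordinal agreement.
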