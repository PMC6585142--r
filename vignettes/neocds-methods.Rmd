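---
title: "Methods: newborn classification rules, form completeness, and method-comparison statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: newborn classification rules, form completeness, and method-comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neocds)
```

# The problem

Community health workers (CHWs) are often the first to examine newborns in
settings where most births happen outside facilities. Their assessments use
checklist-style guideline forms: measure vitals, check a fixed list of
danger signs, classify the infant (small, ill, or both), and decide on
referral, counseling and a follow-up visit. Two failure modes dominate in
practice: *incomplete* assessments (signs not checked or not recorded,
calculations skipped) and *incorrect classification* (a threshold applied
wrongly, a gestational age never computed). Guided mobile data entry
attacks both: it cannot advance past an unanswered required item, and it
computes the derived quantities itself.

`neocds` implements this whole loop as a tested library: the threshold
rule engine, the management rules, a schema-generic form engine with skip
logic and a completeness audit, the statistics used to compare two
assessment methods against a gold standard, and a synthetic cohort and
assessor-error simulator for end-to-end experiments.

# Classification rules

All thresholds live in `classification_config()` and are never hard-coded
at call sites. The defaults follow the national newborn-care guideline
thresholds:

| quantity | rule | default |
|---|---|---|
| low birth weight | birth weight `<` cut-off | 2500 g |
| small infant | low birth weight **or** foot length `<` cut-off | 74 mm |
| very low weight | birth *or* current weight `<` cut-off | 1500 g |
| preterm | gestational age `<` cut-off (strict) | 37.0 weeks |
| fast breathing | breaths/min `>` cut-off (strict) | 60 |
| fever | temperature `>` cut-off (strict) | 38.0 °C |
| hypothermia | temperature `<` cut-off (strict) | 35.5 °C |

Weight-loss severity depends on size: small infants are *moderate* at
8–10% loss and *severe* above 10%; non-small infants are moderate at
10–15% and severe above 15%. The printed band edges overlap ("8–10%" and
"> 10%"); we resolve the tie by making the moderate band closed and severe
strict, so a loss of exactly 10% (small) or 15% (non-small) is moderate.
This keeps the categories exclusive and matches the strict "greater than"
of the severe rule. When an infant's size cannot be resolved, the wider
non-small bands apply by default (`nonsmall_bands_when_size_unknown`);
there is no conservative choice without knowing size, so the choice is
explicit and configurable.

Every observation is tri-state: *present*, *absent*, or *not assessed*.
This distinction is load-bearing — a danger sign that was never checked is
not a negative finding, and downstream an unassessable condition can never
be scored as correctly classified. Composites (feeding intolerance over
five items, breastfeeding problems over five items) are positive on any
problematic item, negative only when every item is resolved and clear, and
unassessable otherwise. `small` resolves as soon as *any* criterion is
evaluable (it is never unassessable when a birth weight exists).

`any_danger_sign` is an OR over a configurable subset of conditions. The
guideline set we default to contains the eight observational signs plus
fast breathing, fever, hypothermia, severe weight loss, very low weight
and feeding intolerance; the exact app-internal set is not published, so
it is a documented, overridable default (`danger_sign_set`).

Two other places where the published material is silent and the package
makes its own documented choice:

* **Day counting.** Postnatal age is the floor of elapsed time in days (a
  6.9-day-old infant is "6 days"), matching the clinical age-in-days
  convention; eligibility for newborn care is a strict `< 28` days.
* **Gestational age.** Stored exactly as `days/7` and only rounded to one
  decimal for display; the preterm comparison uses the exact value.
  Temperatures are normalized to Celsius and stored at 0.1 °C resolution,
  the resolution at which thresholds are applied.

# Management rules

The published description names the counseling items (kangaroo mother
care, cup feeding, increased feeding frequency, thermal care,
breastfeeding support, cord care) and states that any single danger sign
triggers referral, with lower thresholds for small infants — but it does
not print the full mapping. `management_config()` therefore ships the
complete mapping as explicit defaults: every danger-sign condition refers;
a small infant additionally refers on moderate weight loss or
breastfeeding problems; counseling rules fire by predicate and union their
items; follow-up is +2 days for small infants or moderate findings, +7
days otherwise, and is suppressed entirely by referral. All of it is
overridable from a config file without code changes. This is the module's
central documented gap: the defaults are stand-ins with the published
behaviour's *shape*, not a reconstruction of the app's exact tables.

# The form engine

`form_schema()` items carry range constraints, soft plausibility bands,
double-entry flags, skip predicates (quoted expressions over earlier
items) and computed fields. The engine (`run_form()`) refuses to advance
past a rejected response and fills computed fields itself — this is the
structural mechanism that makes guided-entry records complete by
construction, and it is asymmetric on purpose: paper records are ingested
as-is, never enforced. "Check your response" prompts are modeled as
non-blocking plausibility warnings, distinct from blocking range
violations.

The bundled newborn schema (`cncp_form_schema()`) covers every field the
classifier and the completeness audit reference. The original form's exact
item list and ordering are not published; the schema is reconstructive and
nothing in the engine depends on it specifically.

The completeness audit (`completeness_report()`) computes the study's
eight indicators. *Full assessment* requires every danger-sign item
resolved yes/no plus recorded weight, temperature, respiratory rate and at
least one care recommendation. The gestational-age indicator is evaluated
only for records with a recorded LMP date and is `NA` (excluded from
denominators) otherwise. Records flagged as study day 1 are excluded from
the full-assessment denominator, mirroring the published study's form
revision after its first day (the first paper version had checkmarks only,
so non-response was indistinguishable from a negative finding).

# Evaluation statistics

Correctness is per condition against the gold profile: a call is correct
iff it is resolved and equal; *not assessable* counts as incorrect.
Per-condition results collapse to a method-by-correct 2×2 table, from
which the package computes:

* proportions and their difference in percentage points;
* Pearson's chi-squared test of independence, 1 df, **without** Yates
  continuity correction (the identity `X² = z²` with the pooled
  two-proportion z statistic holds exactly and is property-tested);
* the crude odds ratio (cross-product ratio) with a log-scale Wald 95% CI,
  applying the Haldane–Anscombe 0.5 correction only when a zero cell
  occurs, always flagged;
* the cluster-robust odds ratio: the population-averaged logistic model
  `correct ~ method` fitted by GEE with binomial family, logit link and
  independence working correlation — i.e. an ordinary logistic GLM score
  equation — with the model-based variance replaced by the CHW-cluster
  sandwich estimate (`sandwich::vcovCL`). With independence working
  correlation the point estimate equals the crude OR of the collapsed
  table for *any* cluster assignment; clustering moves only the interval
  and p-value. The published per-condition point estimates are reproduced
  exactly by the crude OR of the printed counts, which is what makes them
  desk-reproducible; the published confidence intervals are not, because
  the raw per-CHW clustering is unpublished.
* completion-time comparison by a two-sided Welch t-test (whether the
  original analysis pooled variances is unstated, so timing results are
  checked only against internally computed oracles, not published values).

Table rendering rounds half-up to one decimal, matching the usual printed
style (`round_half_up()`; base R's round-half-to-even differs on ties).

# The synthetic cohort and error model

`generate_cohort()` draws gold labels from condition prevalences (defaults
are the published paper-arm expert rates) and then samples raw
measurements from the matching side of each threshold: fever implies a
temperature drawn from (38.0, 40.5] on a 0.1 °C grid, severe weight loss
for a small infant implies a percent loss above 10.5, and so on. Windows
sit a margin (≥ 0.3 percentage points for weight loss) away from band
edges so integer-gram and decimal rounding can never flip a label; the
identity `classify_case(case) ≡ gold` is re-checked for every generated
infant. These conditional measurement windows are invented plumbing — the
published material gives prevalences and thresholds, not measurement
distributions — and their widths are documented here precisely because
they are choices, not data. Postnatal age is truncated-normal (mean 6.5,
SD 6.7 days, on [0, 27]); gestational age is normal (mean 40.1, SD 3.2
weeks); 31% of infants are female; an LMP date is available for 33% of
mothers (from the roughly one-third LMP-recording rate of the guided arm).
In the generated cohort *small* coincides with low birth weight (short
feet are assigned exactly to low-birth-weight infants), as in the
published cohort where both rates are identical.

The assessor error model gives each condition × method a sensitivity and
specificity — the probability the call matches a positive or negative gold
label — shifted per CHW by a normal random effect on the log-odds of a
correct call. Defaults are calibrated in closed form from the published
aggregates: with prevalence $p$, CHW positive-call rate $q$ and correct
rate $c$, the moment equations $q = p\,a + (1-p)(1-b)$ and
$c = p\,a + (1-p)\,b$ identify $b = ((c-q)/(1-p)+1)/2$ and
$a = (c-(1-p)b)/p$. For the paper arm the published rates are first
rescaled by field-missingness, since an unrecorded field can never be
correct. Small published cells push a few solutions outside $[0,1]$; these
are clamped to $[0.02, 0.995]$, and zero-prevalence conditions
(sensitivity unidentifiable) default to 0.9. The calibrated values ship as
a computed default, not as hard-coded truth.

Paper-arm missingness defaults follow the published audit: respiratory
rate unrecorded 54.8%, temperature 40.4%, weight 2.9%, written
recommendation absent 67.3%, the weight-loss calculation absent 4.8%, the
postnatal-age calculation absent 26%, the gestational-age calculation
absent 79.3% of LMP-recorded forms, and 10% per danger-sign item (the
item-level rate is not published; 10% makes sign-completeness the binding
constraint, as observed). Missingness draws are independent across fields,
which understates the real correlation between a CHW's diligence across
fields — simulated paper-arm *full assessment* rates are therefore lower
than the published 23.8%, and that indicator is validated through the
deterministic fixture instead (see below).

The crossover design assigns assessments to CHWs in rotation; odd-id CHWs
start on the mobile method, even-id on paper, switching every 6
assessments, so every CHW uses both methods. Three RNG streams (error,
missingness, times) are derived from one seed so changing one parameter
group does not perturb unrelated draws; the error draws are
uniform-coupled, which makes the simulated correct proportion provably
monotone in sensitivity at a fixed seed.

Two deliberate simulation simplifications, both visible in the code and
tests: (1) assessor error is simulated at the *condition* level, so a
record's raw measurements are the infant's true values even when the
simulated call disagrees — records stay audit-consistent, but a record's
measurements cannot be re-classified to recover the simulated call;
(2) composite conditions use a single condition-level missingness draw
rather than per-item draws.

# What passing tests do and do not show

The deterministic surface — thresholds, bands, management tables,
completeness arithmetic, chi-squared/OR identities — is checked against
independently coded oracles and hand-computed values, including a
brute-force threshold checker run over 10,000 random cases and exact
reproduction of the published odds ratios from the printed counts. The
stochastic surface is checked by parameter recovery: at 500 infants × 2
assessments with the CHW effect switched off, observed per-condition
correct proportions must fall within 3 binomial standard errors of the
error model's implied values (with clustering on, the implied value is
integrated over the random effect numerically, but the sampling variance
is inflated by a design effect, so the exact-recovery check conditions on
no assessor heterogeneity). None of this shows that real CHWs behave like
the error model — in particular real missingness is correlated within
assessor, real errors are correlated across conditions, and CHWs learn
over a study, none of which is modeled.

Problem sizes used by the test suite (10,000-case oracle sweeps,
10,000-infant prevalence recovery, 100-dataset cluster-OR equivalence,
500×2 recovery runs) were chosen so binomial noise is far below the
tolerances being asserted.

# Degenerate inputs and numerical corners

* Zero cells: the crude OR applies Haldane–Anscombe 0.5 and flags it; a
  zero margin makes the chi-squared undefined and it is reported `NA`.
* A single cluster makes the sandwich variance unreliable; the fit warns
  but still returns the (clustering-invariant) point estimate.
* Weight gain is never weight loss, at any magnitude.
* An identical birth/assessment datetime is age 0 and valid; assessment
  before birth is an ordering violation collected by `validate_case()`.
* Exact threshold values: 37.0 weeks, 60 breaths/min, 38.0 °C and 35.5 °C
  are all on the negative side of their strict inequalities.

# Known limitations

The management rule tables are documented stand-ins; local calendars and
time zones are out of scope (all datetimes UTC); referral is binary with
no urgency tiers; size-for-gestational-age classification is deliberately
not computed; and the simulator does not model CHW learning, site
differences, or the day-1 form revision beyond an exclusion flag.
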