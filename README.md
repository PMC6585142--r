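# neocds

Clinical decision support and method-comparison statistics for newborn
care in low-resource settings.

Community health workers (CHWs) assessing newborns with checklist-style
guideline forms frequently leave assessments incomplete and misapply
classification thresholds. Guided mobile data entry changes both failure
modes structurally: the form cannot advance past an unanswered required
item, and it auto-computes gestational age, postnatal age and percent
weight change. `neocds` implements, as a tested R library plus a small
CLI:

* **the rule engine** — tri-state (present / absent / not assessed)
  classification of 18 newborn conditions from raw measurements: low
  birth weight (< 2500 g), small infant (< 2500 g or foot length
  < 74 mm), very low weight (< 1500 g), size-dependent weight-loss bands
  (moderate 8–10% / severe > 10% for small infants; 10–15% / > 15%
  otherwise), fever (> 38.0 °C), hypothermia (< 35.5 °C), fast breathing
  (> 60 breaths/min), eight observational danger signs, and two
  five-item feeding composites;
* **management planning** — referral on any danger sign (with lower
  thresholds for small infants), counseling-item mapping (kangaroo
  mother care, cup feeding, thermal care, …) and follow-up dates;
* **a schema-generic form engine** — ordered items, skip logic, range
  constraints, double entry, computed fields, and the eight-indicator
  completeness audit (full assessment, calculations performed, fields
  recorded);
* **evaluation statistics** — per-condition correctness against a
  gold-standard assessor, method-by-correct 2×2 tables, Pearson
  chi-squared (no continuity correction), crude odds ratios with Wald
  CIs, and cluster-robust (GEE-independence + sandwich) odds ratios for
  CHW-clustered data:

  ```
  OR = (correct_mobile × incorrect_paper) / (incorrect_mobile × correct_paper)
  ```

* **a synthetic study simulator** — seeded cohorts whose measurements
  are generated on the correct side of every threshold (so the
  classifier reproduces the gold labels exactly), plus a crossover
  assessor-error model with per-condition sensitivity/specificity, CHW
  random effects and paper-arm field missingness, calibrated from the
  bundled published aggregate counts.

## Worked example

```r
library(neocds)

cs <- infant_case(
  infant_id = "demo-01", sex = "female",
  birth_datetime = "2017-03-01 08:00", assessment_datetime = "2017-03-07 10:00",
  lmp_date = as.Date("2016-06-15"),
  birth_weight_g = 2300, current_weight_g = 2080, foot_length_mm = 71,
  temperature = 35.1, temperature_unit = "C", breath_count_60s = 48,
  signs = setNames(rep("no", 8), sign_names()),
  feeding_intolerance = setNames(rep("no", 5), feeding_intolerance_items()),
  breastfeeding = setNames(c("yes", "no", "yes", "yes", "yes"), breastfeeding_items())
)
profile <- classify_case(cs)
plan <- build_plan(profile, as.Date(cs$assessment_datetime))
cat(summary_report(cs, profile, plan))
```

```
ASSESSMENT SUMMARY - infant demo-01
Postnatal age: 6 days
Gestational age: 37.0 weeks
Danger signs and conditions identified:
  - low birth weight
  - small
  - moderate weight loss
  - hypothermia
  - breastfeeding problems
REFER to facility. Reasons:
  - moderate weight loss
  - hypothermia
  - breastfeeding problems
Counseling for the mother:
  - kangaroo mother care
  - cup feeding
  - increase feeding frequency
  - thermal care
  - small infant breastfeeding advice
  - general breastfeeding support
```

Reading the output: the infant is 6 days old (floor of elapsed days);
259 days from LMP is exactly 37.0 weeks, so *not* preterm (the cut is
strict). A 9.6% weight loss falls in the small-infant moderate band
[8, 10]; 35.1 °C is below the strict 35.5 °C hypothermia threshold.
Hypothermia is a danger sign, so the infant is referred (which
suppresses the scheduled follow-up date), and the small + breastfeeding
findings drive the counseling set.

The diagnostic-accuracy surface works from 2×2 concordance counts:

```r
crude_odds_ratio(published_2x2("small"))
#> $or_point
#> [1] 20.75       # correct classification of "small", mobile vs paper
```

A full synthetic study (cohort → crossover assessments → completeness
and accuracy tables) runs in one call:

```r
run_end_to_end(out_dir = "study", seed = 17)
```

or from a shell via the bundled CLI: `exec/neocds run --seed 17 --out study`.

## Layout

```
R/                 rule engine, management, form engine, statistics, simulator
inst/extdata/      published aggregate counts (CSV), demo study config (YAML)
exec/neocds        command-line interface (validate/classify/manage/evaluate/simulate/run)
scripts/acceptance.R   recomputes the headline numbers, writes JSON
tests/testthat/    oracle-backed unit, property and acceptance tests
vignettes/         methods vignette: models, assumptions, calibration, limits
```
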