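---
title: "Methods: meal-plan composition, synthetic cohorts and neural triage"
author: "nutrikiosk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meal-plan composition, synthetic cohorts and neural triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrikiosk)
```

`nutrikiosk` implements the computational core of an offline nutritional
self-management kiosk for adults living with diabetes: a regional
food-composition database, conventional energy arithmetic, a deterministic
meal-plan composer, a synthetic patient-cohort simulator, a three-class
neural triage classifier with a fixed-rule comparison engine, and the
statistics used to audit such a system. This vignette explains each model and
the design decisions behind the parameters, so that a maintainer can judge
what the defaults mean and what the passing test suite does and does not
demonstrate.

## Energy requirements

Basal metabolic rate uses the sex-specific Harris-Benedict regression in its
1984 (Roza-Shizgal) revision, the most common reading of a "modified"
Harris-Benedict equation; the original 1919 coefficients remain available via
`basal_metabolic_rate(a, variant = "original")`. Total daily energy
expenditure multiplies BMR by the conventional activity factors 1.2 / 1.375 /
1.55 / 1.725 / 1.9 (sedentary through very active).

The recommendation engine operates on energy targets between 1200 and
2800 kcal/day. Requirements falling outside that range are *clamped* to the
nearest bound rather than rejected, with a `clamped` flag exposed so callers
can warn: every downstream component (cohort, classifier, planner) is defined
on that range, and pulling a 3100-kcal requirement to 2800 yields a usable,
conservative plan where a hard error would yield nothing.

Macronutrient targets are expressed as percent of energy inside the
acceptable macronutrient distribution ranges (carbohydrate 45–65%, protein
10–35%, fat 20–35%, summing to 100) and converted to grams with the Atwater
densities (4 kcal/g for carbohydrate and protein, 9 kcal/g for fat).
Rounding is fixed — BMI to 2 decimals, energies to 2, grams to 1 — so results
are exactly reproducible.

## The food database

Foods are ingested from CSV, validated, and stored in a single-file SQLite
database (tables `foods`, `recipes`, `recipe_components`). Validation
enforces an eight-group taxonomy patterned on Mexican dietary guidance
(NOM-043 plate categories), a strictly positive serving mass, a glycemic
index inside [0, 110] when present, and an *Atwater consistency check*:
`4·CHO + 4·protein + 9·fat` must lie within ±20% of the declared energy.
The 20% band absorbs fiber, water and rounding effects that make published
composition values deviate from pure macronutrient arithmetic; tighter bands
reject legitimate rows, looser ones stop catching unit errors.

Food exchanges follow the standard convention: an *equivalent* is a different
food of the same group whose per-serving energy lies within a relative
tolerance (default 10%) of the original. The bundled table
(`kiosk_foods_csv()`) is an illustrative, synthetic-but-plausible set of 47
regional Mexican foods with exchange-sized servings; it is not an
authoritative composition source, and its file name says so.

## The synthetic cohort

No patient data ship with the package; the simulator generates the training
population. Each record carries 15 variables — age, sex, height, weight, BMI,
diabetes type, glycemic control, physical activity, energy need, the three
macro percentages, predominant food group, dietary adherence, and food
preference — plus a triage label.

Sampling is stratified. The default strata follow a national-survey-like
shape for a population living with diabetes: 80% type 2 (older, heavier),
8% type 1 (younger, leaner), 12% prediabetes (better glycemic control), with
sex-specific heights around Mexican adult means and BMI drawn per stratum
(type 2 centred at 29.5 kg/m², SD 5). Counts per stratum are apportioned by
the largest-remainder method, so they are exact for exact weights. Energy
need is not sampled but *computed* from the record's own anthropometrics and
activity through the energy module, which keeps the joint distribution
internally consistent.

Two variables are sampled conditionally on glycemic control: dietary
adherence and the predominant food group. Poor control co-occurs with low
adherence and with sugar- or fat-predominant diets, reflecting the clinical
clustering of risk factors. These conditional probabilities are also the
calibration handle: they were set (once, analytically, then verified by
simulation) so that the labelling rule below produces approximately 55% /
30% / 15% of the three classes on the default strata, and then frozen.

Physiological filters remove records with BMI outside [15, 40] (bounds
inclusive — removal is defined by strict inequalities), impossible
anthropometrics, energy outside [1200, 2800], or macro percentages violating
their windows or not summing to 100; rejected draws are resampled from the
same stratum with a bounded retry budget, and a tally reports rejections by
reason.

**The labelling rule.** Reference labels come from an auditable
violation-point score: poor glycemic control (2 points); type 1 or
prediabetes with carbohydrate share above 55% (1); low adherence (1); BMI
outside [18.5, 30] (1); sugar/sweets or fats/oils as predominant group (2).
Totals of 0–1 map to `ADEQUATE`, 2–3 to `MINOR_ADJUSTMENT`, ≥4 to
`REQUIRES_CONSULTATION`. The rule is the package's own construction — chosen
to be deterministic and clinically plausible rather than validated against
expert panels — and that is precisely what makes it usable as a test oracle.

**Label noise.** Real expert labels are not a deterministic function of 15
coded variables. A configurable uniform flip (default rate 0.12; each
affected label is replaced by one of the other two classes, with a logged
flip list) models that disagreement and gives the classifier a realistic
ceiling: under uniform flips the best reachable test accuracy is about
1 − rate. The default is a calibration device, not an estimate of true
expert disagreement, and is documented as such.

One tension is worth recording: a uniform flip pulls class proportions
toward the centre of the simplex (the expected noisy share is
0.82·clean + 6 percentage points), so the pre-noise rule labels and the
final dataset labels cannot both sit arbitrarily close to 55/30/15. The
calibration targets the *final* labels, leaving the clean-rule shares about
two points higher on `ADEQUATE`.

What the generator does **not** emulate: measurement error in
anthropometrics, correlations between activity and BMI, seasonal or regional
diet variation, longitudinal visits, and any real ENSANUT microdata or
weighting. Passing tests therefore demonstrate that the pipeline behaves
correctly on a self-consistent population of the documented shape — not that
the classifier would reach the same operating point on clinic data.

## Feature encoding

Inputs to the classifier are exactly 15 values, one per variable.
Continuous variables are standardized to zero mean and unit variance using
training-set statistics (a constant column falls back to a unit divisor);
categorical variables are mapped to fixed ordinal scores in [0, 1] in
clinically meaningful orders — e.g. glycemic control good 0 / fair 0.5 /
poor 1; diabetes type type 2 0 / prediabetes 0.5 / type 1 1 (so the two
insulin-sensitive triage-relevant types are adjacent); food groups in the
taxonomy order, which places the two discouraged groups at the top of the
scale. Ordinal coding keeps the input dimension at 15 with no one-hot
expansion; the cost is an implied ordering, acceptable here because every
coded order is monotone in the construct it feeds.

## The triage network

`triage_mlp()` trains a multilayer perceptron with three hidden layers of 64
rectified-linear units, batch normalization, dropout 0.3 and a three-unit
softmax output, using Adam (learning rate 0.001), categorical cross-entropy
with an L2 penalty (1e-4), mini-batches of 32, and early stopping on
validation loss (patience 10) inside a 100-epoch budget, restoring the
weights of the best validation epoch. The layer order is dense →
batch-norm → ReLU → dropout. A plateau schedule halves the learning rate
after 4 epochs without validation improvement; it is conventional, cheap,
and config-exposed (`lr_reduce_factor = 1` disables it). The internal
validation split is 20% of the training data, stratified by label.

The network is implemented in plain R matrix code (no deep-learning
framework is required at run time), which buys exact, platform-stable
determinism: all randomness — initialization (He-normal), shuffling, dropout
masks, the validation split — flows from the single `seed` in `mlp_spec()`,
and training twice with the same seed reproduces the history bit for bit.
Batch-norm uses biased batch variance in training and running moments
(momentum 0.9) at inference; the analytic gradients, including the
batch-norm backward pass, are verified against finite differences in the
test suite.

Prediction is the argmax of the softmax probabilities with ties broken
toward the more conservative class (consultation over minor adjustment over
adequate) — the safety-first choice for a health device.

The comparison engine, `fixed_rule_baseline()`, is deliberately coarse: poor
control → consultation; fair control or BMI outside [18.5, 30] → minor
adjustment; otherwise adequate. It sees a strict subset of the oracle's
variables, which is what makes "the learned model beats fixed rules"
a falsifiable, reproducible claim on oracle-labelled data.

## The meal-plan composer

Daily energy is split across five slots — breakfast 25%, morning snack 10%,
lunch 30%, afternoon snack 10%, dinner 25% (a standard diabetes-education
split) — with largest-remainder rounding so slot targets sum exactly to the
day. Each slot is filled by a deterministic greedy procedure over the food
database:

1. **Priority order.** Diabetes-suitable foods first, then glycemic index
   ascending (foods without a GI after all foods with one), then fiber
   descending, then `food_id` as a total-order tie-break.
2. **Quotas.** Servings are added in 0.5-serving steps, at most 3 servings
   per food and bounded per food group (the food-exchange quota, e.g. at
   most 1.5 fat/oil and 0.5 sugar servings per slot). Without group quotas
   the order above lets low-GI, energy-dense foods — nuts, avocado — crowd
   out the plate and push the realized fat share far above its window.
3. **Caps.** A step is only accepted if the slot stays at or below
   `target·(1 + tol)` kcal (tolerance 5%) and at or below its carbohydrate
   cap (60 g at main meals, 25 g at snacks — carbohydrate-counting
   convention). Filling stops once the slot reaches `target·(1 − tol)`.
4. **Repair.** If the fill stalls below the window, a bounded repair loop
   tries single-serving-step exchanges: first a swap that lands the slot
   inside the window, otherwise a swap that strictly increases energy,
   followed by a re-fill (at most 8 rounds, so termination is guaranteed).
5. **Carbohydrate-bound fallback.** If the slot is still short — typically a
   tight snack cap — the whole pass is re-run with candidates ordered by
   carbohydrate per kcal (least first), the ordering a dietitian uses when
   the carb budget, not energy, is binding. The better of the two attempts
   is kept; an unreachable window yields a best-effort slot explicitly
   flagged `kcal_short`, never a silent failure.

`compose_plan()` additionally seeds required food groups into fixed slots
(cereal/tuber at breakfast, fruit at the morning snack, vegetable plus
legume-or-animal-protein at lunch, vegetable at dinner) so a compliant plan
covers the essential groups, and vegetarian profiles exclude the
animal-protein group. The composer is a pure function of the database,
profile and constraints: rendered JSON is byte-identical across runs.

Compliance evaluates four rules — daily energy within tolerance, every
slot's carbohydrate at or under its cap, required groups covered, and the
realized macro distribution inside the acceptable ranges widened by 5
percentage points. One structural fact follows from the defaults and is
deliberately reported rather than hidden: the per-meal carbohydrate caps
bound the day at 230 g (920 kcal) of carbohydrate, so for daily targets
above roughly 2300 kcal the 40% realized-carbohydrate floor is arithmetically
unreachable and plans carry a `macro_window:cho` violation. Resolving it
would mean either energy-scaled caps or a relaxed floor; the defaults keep
both conventions and surface the conflict in the compliance report.

The test suite compares the composer against an exhaustive-search oracle
(all serving combinations at the same granularity, serving and group caps)
on small candidate pools: on every shipped pool the composer finds a
compliant fill exactly when one exists. This equivalence is a property of
pools of realistic diversity, not a theorem — a fixed greedy order with
bounded repair can in principle be defeated by pathological pools, in which
case the non-compliant flag, not an overshoot, is the guaranteed behaviour.

## Evaluation statistics

Classification metrics follow the standard definitions (precision
`tp/(tp+fp)`, recall `tp/support`, F1 their harmonic mean; macro, weighted
and micro averages). Two conventions matter for exact reproduction of
printed tables: percentages round *half-up* to one decimal (banker's
rounding changes cells), and aggregates average the unrounded per-class
proportions before their own rounding. In the three-class single-label
setting weighted recall equals micro accuracy — kept as a property test. A
class that is never predicted has undefined precision; it is reported as 0
with a warning flag so macro averages stay defined on degenerate folds.

The Wilson score interval inverts the score test; a brute-force grid
inversion at 1e-6 resolution serves as its oracle in the tests. SUS scoring
is the standard rule (odd items `response − 1`, even items `5 − response`,
sum × 2.5), summarized with the arithmetic mean and the *sample* (n−1)
standard deviation, and graded on the Sauro–Lewis curved scale.

The load harness replays the full in-process recommendation path (validate →
energy → plan → triage) under forked concurrency and reports mean, sample SD
and maximum of the recorded per-request latencies plus best-effort CPU
readings. All such numbers are machine-dependent; the suite checks only the
bookkeeping (row counts, statistics recomputed from the recorded samples,
failure accounting), never absolute timings.

## Problem sizes and reproducibility

The acceptance-level checks run the study-scale configuration: cohorts of
10,000 records (80/20 split), classifier training under the full
100-epoch budget in both the noisy (rate 0.12) and noiseless regimes, a
5,000-record cohort for the engine comparison, and the full target × cap
grid for the planner oracle. Unit tests use smaller cohorts (300–2,000
records) and narrower networks where the property under test does not depend
on scale. `scripts/acceptance.R --seed <int> --out <path>` recomputes every
headline quantity from scratch; all randomness derives from the one seed.

## Known limitations

- The labelling rule and the stratum parameters are constructions, not
  estimates; agreement bands on synthetic data say nothing about expert
  agreement on real patients.
- The composer optimizes nothing; it satisfies constraints deterministically,
  and its menus repeat foods up to the quota caps rather than maximizing
  variety.
- Micronutrients, children, pregnancy, and diabetes-specific caloric
  deficits for high BMI are out of scope.
- High-energy plans (above ~2300 kcal/day) cannot simultaneously satisfy the
  default per-meal carbohydrate caps and the realized-carbohydrate floor;
  the violation is reported honestly.
- Whether a diabetes-specific caloric deficit should apply above a BMI
  threshold is left to the caller (the constraint objects accept a reduced
  target); no deficit is applied by default.
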