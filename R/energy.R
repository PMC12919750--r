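# Energy module: BMI, basal metabolic rate (revised Harris-Benedict),
# total daily energy expenditure with activity factors, macronutrient split.

#' Physical-activity factors
#'
#' Conventional Harris-Benedict multipliers applied to the basal metabolic
#' rate to obtain total daily energy expenditure.
#'
#' @format Named numeric vector, one multiplier per activity level.
#' @export
activity_factors <- c(
  sedentary   = 1.2,
  light       = 1.375,
  moderate    = 1.55,
  active      = 1.725,
  very_active = 1.9
)

#' Validate an anthropometric record
#'
#' Mirrors the kiosk's type-and-range checks: adult ranges for age, height in
#' metres, weight in kilograms, and a binary sex code used by the sex-specific
#' Harris-Benedict coefficients.
#'
#' @param age_years integer age, > 0 and < 120.
#' @param sex `"female"` or `"male"`.
#' @param height_m stature in metres, in (0.5, 2.5).
#' @param weight_kg body mass in kilograms, in (20, 300).
#' @return A list of class `"anthropometrics"` with the validated fields.
#' @examples
#' anthropometrics(40, "male", 1.75, 70)
#' @export
anthropometrics <- function(age_years, sex, height_m, weight_kg) {
  if (!is_number(age_years) || age_years <= 0 || age_years >= 120)
    fail("age_years must be in (0, 120)")
  sex <- match_enum(sex, c("female", "male"), "sex")
  if (!is_number(height_m) || height_m <= 0.5 || height_m >= 2.5)
    fail("height_m must be in (0.5, 2.5) metres")
  if (!is_number(weight_kg) || weight_kg <= 20 || weight_kg >= 300)
    fail("weight_kg must be in (20, 300) kilograms")
  structure(list(age_years = age_years, sex = sex,
                 height_m = height_m, weight_kg = weight_kg),
            class = "anthropometrics")
}

#' Body mass index
#'
#' @param a an [anthropometrics()] record.
#' @return BMI in kg/m^2, rounded to 2 decimals.
#' @examples
#' compute_bmi(anthropometrics(40, "male", 1.75, 70)) # 22.86
#' @export
compute_bmi <- function(a) {
  stopifnot(inherits(a, "anthropometrics"))
  round_half_up(a$weight_kg / a$height_m^2, 2)
}

#' Basal metabolic rate (Harris-Benedict)
#'
#' Sex-specific linear estimate of resting energy expenditure from weight,
#' height and age. The default is the 1984 Roza-Shizgal revision; the original
#' 1919 coefficients are available via `variant = "original"`.
#'
#' Revised coefficients (kcal/day; W kg, H cm, A years):
#' male `88.362 + 13.397 W + 4.799 H - 5.677 A`,
#' female `447.593 + 9.247 W + 3.098 H - 4.330 A`.
#'
#' @param a an [anthropometrics()] record.
#' @param variant `"revised"` (default, 1984) or `"original"` (1919).
#' @return BMR in kcal/day, rounded to 2 decimals.
#' @examples
#' basal_metabolic_rate(anthropometrics(40, "male", 1.75, 70)) # 1638.90
#' @export
basal_metabolic_rate <- function(a, variant = c("revised", "original")) {
  stopifnot(inherits(a, "anthropometrics"))
  variant <- match.arg(variant)
  w <- a$weight_kg
  h <- a$height_m * 100
  yr <- a$age_years
  bmr <- if (variant == "revised") {
    if (a$sex == "male") 88.362 + 13.397 * w + 4.799 * h - 5.677 * yr
    else                 447.593 + 9.247 * w + 3.098 * h - 4.330 * yr
  } else {
    if (a$sex == "male") 66.4730 + 13.7516 * w + 5.0033 * h - 6.7550 * yr
    else                 655.0955 + 9.5634 * w + 1.8496 * h - 4.6756 * yr
  }
  if (bmr <= 0) fail("non-positive BMR for the given anthropometrics")
  round_half_up(bmr, 2)
}

#' Total daily energy requirement
#'
#' Multiplies the basal metabolic rate by the physical-activity factor and
#' clamps the result into the 1200-2800 kcal/day operating range of the
#' recommendation engine, flagging when clamping occurred. Plans are only
#' composed inside this range, so out-of-range requirements are pulled to the
#' nearest bound rather than rejected.
#'
#' @param a an [anthropometrics()] record.
#' @param activity one of `names(activity_factors)`.
#' @param variant Harris-Benedict variant, see [basal_metabolic_rate()].
#' @return A list of class `"energy_requirement"`: `bmr_kcal`, `tdee_kcal`
#'   (clamped, kcal/day), `clamped` (logical), `activity`, `factor`.
#' @examples
#' total_energy(anthropometrics(40, "male", 1.75, 70), "sedentary")
#' @export
total_energy <- function(a, activity, variant = "revised") {
  activity <- match_enum(activity, names(activity_factors), "activity level")
  bmr <- basal_metabolic_rate(a, variant)
  raw <- bmr * activity_factors[[activity]]
  tdee <- min(max(raw, 1200), 2800)
  structure(list(bmr_kcal = bmr,
                 tdee_kcal = round_half_up(tdee, 2),
                 clamped = !isTRUE(all.equal(raw, tdee)),
                 activity = activity,
                 factor = activity_factors[[activity]]),
            class = "energy_requirement")
}

#' Macronutrient distribution (percent of energy)
#'
#' Validates a carbohydrate/protein/fat split against the acceptable
#' macronutrient distribution ranges used throughout the kiosk
#' (CHO 45-65, protein 10-35, fat 20-35, summing to 100).
#'
#' @param cho_pct,protein_pct,fat_pct percent of daily energy.
#' @return A list of class `"macro_distribution"`.
#' @export
macro_distribution <- function(cho_pct = 50, protein_pct = 20, fat_pct = 30) {
  if (!is_number(cho_pct) || cho_pct < 45 || cho_pct > 65)
    fail("cho_pct must be in [45, 65]")
  if (!is_number(protein_pct) || protein_pct < 10 || protein_pct > 35)
    fail("protein_pct must be in [10, 35]")
  if (!is_number(fat_pct) || fat_pct < 20 || fat_pct > 35)
    fail("fat_pct must be in [20, 35]")
  if (abs(cho_pct + protein_pct + fat_pct - 100) > 1e-9)
    fail("macro percentages must sum to exactly 100")
  structure(list(cho_pct = cho_pct, protein_pct = protein_pct,
                 fat_pct = fat_pct),
            class = "macro_distribution")
}

#' Convert an energy target and macro split into daily grams
#'
#' Uses the Atwater energy densities (4 kcal/g carbohydrate and protein,
#' 9 kcal/g fat).
#'
#' @param tdee_kcal daily energy target in kcal.
#' @param dist a [macro_distribution()].
#' @return Named numeric vector `c(cho_g, protein_g, fat_g)`, grams/day to
#'   1 decimal.
#' @examples
#' macro_split(2000, macro_distribution(50, 20, 30))
#' @export
macro_split <- function(tdee_kcal, dist = macro_distribution()) {
  stopifnot(inherits(dist, "macro_distribution"), is_number(tdee_kcal),
            tdee_kcal > 0)
  c(cho_g     = round_half_up(dist$cho_pct / 100 * tdee_kcal / 4, 1),
    protein_g = round_half_up(dist$protein_pct / 100 * tdee_kcal / 4, 1),
    fat_g     = round_half_up(dist$fat_pct / 100 * tdee_kcal / 9, 1))
}

#' @export
print.energy_requirement <- function(x, ...) {
  cat(sprintf("Energy requirement: BMR %.2f kcal/d x %s (%.3f) -> TDEE %.2f kcal/d%s\n",
              x$bmr_kcal, x$activity, x$factor, x$tdee_kcal,
              if (x$clamped) " [clamped to 1200-2800]" else ""))
  invisible(x)
}
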