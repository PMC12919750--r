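# Synthetic diabetic-cohort simulator: stratified sampling, physiological and
# consistency filters, deterministic triage labelling, label noise, splitting.

#' Triage classes, least to most conservative
#' @format Character vector of the three labels.
#' @export
cohort_labels <- c("ADEQUATE", "MINOR_ADJUSTMENT", "REQUIRES_CONSULTATION")

#' The 15 cohort feature variables, in encoding order
#' @format Character vector of column names.
#' @export
cohort_feature_names <- c(
  "age_years", "sex", "height_m", "weight_kg", "bmi", "diabetes_type",
  "glycemic_control", "activity_level", "kcal_need", "cho_pct", "protein_pct",
  "fat_pct", "predominant_food_group", "dietary_adherence", "food_preference")

diabetes_types    <- c("type2", "type1", "prediabetes")
glycemic_levels   <- c("good", "fair", "poor")
adherence_levels  <- c("low", "medium", "high")
preference_levels <- c("omnivore", "low_meat", "vegetarian")

# Default stratum specs. Weights follow the national-survey-like shape of the
# Mexican population living with type 2 diabetes (type 2 dominant, small
# type 1 and prediabetes strata). Per-stratum parameters encode the
# clinically expected clustering: type 2 older and heavier, type 1 younger
# and leaner, prediabetes with better glycemic control. Adherence and
# predominant food group are sampled conditionally on glycemic control (rows
# of the matrices are good/fair/poor) — poor control co-occurs with low
# adherence and sugar/fat-predominant diets.
.default_strata <- function() {
  adherence_by_control <- rbind(
    good = c(low = 0.08, medium = 0.47, high = 0.45),
    fair = c(low = 0.22, medium = 0.48, high = 0.30),
    poor = c(low = 0.50, medium = 0.36, high = 0.14))
  # predominant food group probabilities by glycemic control; the two
  # discouraged groups (fats_oils, sugar_sweet) grow with worse control
  group_by_control <- rbind(
    good = c(vegetable = 0.21, legume = 0.14, fruit = 0.10, cereal_tuber = 0.23,
             animal_protein = 0.16, dairy = 0.06, fats_oils = 0.04, sugar_sweet = 0.06),
    fair = c(vegetable = 0.15, legume = 0.12, fruit = 0.09, cereal_tuber = 0.21,
             animal_protein = 0.14, dairy = 0.06, fats_oils = 0.09, sugar_sweet = 0.14),
    poor = c(vegetable = 0.12, legume = 0.10, fruit = 0.08, cereal_tuber = 0.23,
             animal_protein = 0.11, dairy = 0.06, fats_oils = 0.12, sugar_sweet = 0.18))
  base <- list(adherence_by_control = adherence_by_control,
               group_by_control = group_by_control,
               sex_p_female = 0.54,
               activity_p = c(sedentary = 0.35, light = 0.30, moderate = 0.20,
                              active = 0.10, very_active = 0.05),
               preference_p = c(omnivore = 0.80, low_meat = 0.15, vegetarian = 0.05))
  list(
    type2 = c(base, list(
      name = "type2", weight = 0.80, diabetes_type = "type2",
      age_range = c(35, 79), bmi_mean = 29.5, bmi_sd = 5.0,
      control_p = c(good = 0.375, fair = 0.365, poor = 0.26))),
    type1 = c(base, list(
      name = "type1", weight = 0.08, diabetes_type = "type1",
      age_range = c(18, 59), bmi_mean = 24.5, bmi_sd = 3.8,
      control_p = c(good = 0.30, fair = 0.38, poor = 0.32))),
    prediabetes = c(base, list(
      name = "prediabetes", weight = 0.12, diabetes_type = "prediabetes",
      age_range = c(28, 69), bmi_mean = 28.0, bmi_sd = 4.5,
      control_p = c(good = 0.55, fair = 0.33, poor = 0.12))))
}

#' Cohort-generation configuration
#'
#' @param n_target number of surviving records to generate (default 10000).
#' @param seed integer seed driving all randomness.
#' @param strata list of stratum specs (see the package vignette); defaults
#'   to the built-in three-stratum diabetic population.
#' @param label_noise_rate probability in \[0, 0.5) that a record's label is
#'   replaced by one of the other two classes (default 0.12, chosen so a
#'   well-trained classifier plateaus in the high-80s rather than at 100%).
#' @param class_targets expected label proportions, summing to 1
#'   (default 0.55/0.30/0.15).
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_target = 10000, seed = 42, strata = .default_strata(),
                          label_noise_rate = 0.12,
                          class_targets = c(0.55, 0.30, 0.15)) {
  if (!is_number(n_target) || n_target <= 0) fail("n_target must be positive")
  if (!is_number(label_noise_rate) || label_noise_rate < 0 || label_noise_rate >= 0.5)
    fail("label_noise_rate must be in [0, 0.5)")
  w <- vapply(strata, function(s) s$weight, 0)
  if (abs(sum(w) - 1) > 1e-9) fail("stratum weights must sum to 1")
  if (abs(sum(class_targets) - 1) > 1e-9) fail("class_targets must sum to 1")
  structure(list(n_target = as.integer(n_target), seed = as.integer(seed),
                 strata = strata, label_noise_rate = label_noise_rate,
                 class_targets = class_targets),
            class = "cohort_config")
}

# Draw n raw records from one stratum spec (no filtering).
.sample_stratum <- function(spec, n) {
  if (n == 0) return(NULL)
  age <- sample(spec$age_range[1]:spec$age_range[2], n, replace = TRUE)
  sex <- ifelse(stats::runif(n) < spec$sex_p_female, "female", "male")
  height <- ifelse(sex == "female",
                   stats::rnorm(n, 1.55, 0.06), stats::rnorm(n, 1.67, 0.07))
  height <- round(height, 2)
  bmi_raw <- stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)
  weight <- round(bmi_raw * height^2, 1)
  control <- sample(glycemic_levels, n, replace = TRUE, prob = spec$control_p)
  activity <- sample(names(spec$activity_p), n, replace = TRUE,
                     prob = spec$activity_p)
  # adherence / predominant group conditional on glycemic control
  adherence <- character(n); group <- character(n)
  for (lvl in glycemic_levels) {
    idx <- which(control == lvl)
    if (!length(idx)) next
    adherence[idx] <- sample(adherence_levels, length(idx), replace = TRUE,
                             prob = spec$adherence_by_control[lvl, ])
    group[idx] <- sample(colnames(spec$group_by_control), length(idx),
                         replace = TRUE, prob = spec$group_by_control[lvl, ])
  }
  # macro split: integer percents, protein as the remainder inside its window
  cho <- sample(45:65, n, replace = TRUE)
  fat <- sample(20:35, n, replace = TRUE)
  protein <- 100 - cho - fat
  bad <- which(protein < 10 | protein > 35)
  while (length(bad)) {
    cho[bad] <- sample(45:65, length(bad), replace = TRUE)
    fat[bad] <- sample(20:35, length(bad), replace = TRUE)
    protein[bad] <- 100 - cho[bad] - fat[bad]
    bad <- bad[protein[bad] < 10 | protein[bad] > 35]
  }
  preference <- sample(preference_levels, n, replace = TRUE,
                       prob = spec$preference_p)
  # kcal need from the energy module (clamped into the operating range)
  kcal <- numeric(n)
  for (i in seq_len(n)) {
    kcal[i] <- if (height[i] > 0.5 && height[i] < 2.5 &&
                   weight[i] > 20 && weight[i] < 300) {
      total_energy(anthropometrics(age[i], sex[i], height[i], weight[i]),
                   activity[i])$tdee_kcal
    } else NA_real_  # impossible anthropometrics; removed by the filters
  }
  data.frame(
    age_years = age, sex = sex, height_m = height, weight_kg = weight,
    bmi = round_half_up(weight / height^2, 2),
    diabetes_type = spec$diabetes_type, glycemic_control = control,
    activity_level = activity, kcal_need = kcal, cho_pct = cho,
    protein_pct = protein, fat_pct = fat, predominant_food_group = group,
    dietary_adherence = adherence, food_preference = preference,
    stratum = spec$name, stringsAsFactors = FALSE)
}

#' Stratified raw sampling
#'
#' Apportions `n_target` across strata by the largest-remainder method and
#' draws that many raw (unfiltered) records per stratum. Fully deterministic
#' under the config seed.
#'
#' @param cfg a [cohort_config()].
#' @param n optional override of the total draw size.
#' @return data.frame of raw records with a `stratum` column.
#' @export
sample_stratified <- function(cfg, n = cfg$n_target) {
  stopifnot(inherits(cfg, "cohort_config"))
  w <- vapply(cfg$strata, function(s) s$weight, 0)
  counts <- largest_remainder(n, w)
  with_seed(cfg$seed, {
    out <- do.call(rbind, Map(function(spec, k) .sample_stratum(spec, k),
                              cfg$strata, counts))
  })
  rownames(out) <- NULL
  out
}

# Individual filter predicates; names are the rejection reason codes.
.cohort_filters <- list(
  bmi_out_of_range = function(r) r$bmi < 15 | r$bmi > 40,
  anthro_range = function(r) r$age_years <= 0 | r$age_years >= 120 |
    r$height_m <= 0.5 | r$height_m >= 2.5 | r$weight_kg <= 20 | r$weight_kg >= 300,
  kcal_range = function(r) is.na(r$kcal_need) | r$kcal_need < 1200 | r$kcal_need > 2800,
  macro_window = function(r) r$cho_pct < 45 | r$cho_pct > 65 |
    r$protein_pct < 10 | r$protein_pct > 35 | r$fat_pct < 20 | r$fat_pct > 35,
  macro_sum = function(r) abs(r$cho_pct + r$protein_pct + r$fat_pct - 100) > 1e-9
)

#' Physiological and consistency filters
#'
#' Removes records with BMI outside \[15, 40\] (inclusive bounds retained),
#' impossible anthropometrics, energy need outside \[1200, 2800\] kcal/day,
#' macronutrient percentages outside their windows or not summing to 100.
#'
#' @param records raw records from [sample_stratified()].
#' @return list with `records` (survivors) and `tally` (named integer vector
#'   of rejection counts by reason; a record is tallied under its first
#'   failing rule).
#' @export
apply_filters <- function(records) {
  reasons <- rep(NA_character_, nrow(records))
  for (nm in names(.cohort_filters)) {
    bad <- .cohort_filters[[nm]](records) & is.na(reasons)
    reasons[bad] <- nm
  }
  tally <- table(factor(reasons, levels = names(.cohort_filters)))
  list(records = records[is.na(reasons), , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(.cohort_filters)))
}

#' Deterministic triage label
#'
#' Violation-point score over the cohort variables:
#' poor glycemic control (2 points); type 1 or prediabetes with carbohydrate
#' share above 55% (1); low dietary adherence (1); BMI outside \[18.5, 30\]
#' (1); predominant food group sugar/sweets or fats/oils (2). Scores 0-1 map
#' to `ADEQUATE`, 2-3 to `MINOR_ADJUSTMENT`, 4 or more to
#' `REQUIRES_CONSULTATION`.
#'
#' @param records data.frame of filtered cohort records.
#' @return character vector of labels.
#' @export
assign_label <- function(records) {
  score <- 2 * (records$glycemic_control == "poor") +
    1 * (records$diabetes_type %in% c("type1", "prediabetes") & records$cho_pct > 55) +
    1 * (records$dietary_adherence == "low") +
    1 * (records$bmi < 18.5 | records$bmi > 30) +
    2 * (records$predominant_food_group %in% c("sugar_sweet", "fats_oils"))
  cohort_labels[cut(score, c(-Inf, 1, 3, Inf), labels = FALSE)]
}

#' Inject uniform label noise
#'
#' Each label is independently replaced, with probability `rate`, by one of
#' the other two classes chosen uniformly. The flip log makes the corruption
#' auditable.
#'
#' @param labels character vector of labels.
#' @param rate flip probability in \[0, 0.5).
#' @param seed integer seed.
#' @return list with `labels` (noisy) and `flips` (data.frame `index`,
#'   `from`, `to`).
#' @export
inject_label_noise <- function(labels, rate, seed = 42) {
  if (!is_number(rate) || rate < 0 || rate >= 0.5)
    fail("noise rate must be in [0, 0.5)")
  with_seed(seed, {
    flip <- stats::runif(length(labels)) < rate
    idx <- which(flip)
    new <- vapply(idx, function(i)
      sample(setdiff(cohort_labels, labels[i]), 1), "")
  })
  out <- labels
  out[idx] <- new
  list(labels = out,
       flips = data.frame(index = idx, from = labels[idx], to = new,
                          stringsAsFactors = FALSE))
}

#' Generate a complete synthetic cohort
#'
#' Runs the full pipeline: stratified sampling, filtering with per-stratum
#' resampling until `n_target` survivors exist (bounded retries), labelling,
#' and label-noise injection.
#'
#' @param cfg a [cohort_config()].
#' @param max_rounds resampling rounds before declaring a stratum infeasible.
#' @return list of class `"cohort"`: `records` (data.frame with the 15
#'   feature columns, `stratum`, and `label`), `tally` (rejection counts),
#'   `flips` (label-noise log), `config`.
#' @export
generate_cohort <- function(cfg = cohort_config(), max_rounds = 50) {
  stopifnot(inherits(cfg, "cohort_config"))
  w <- vapply(cfg$strata, function(s) s$weight, 0)
  need <- stats::setNames(largest_remainder(cfg$n_target, w), names(cfg$strata))
  tally <- stats::setNames(integer(length(.cohort_filters)), names(.cohort_filters))
  got <- vector("list", length(cfg$strata))
  names(got) <- names(cfg$strata)
  with_seed(cfg$seed, {
    for (snm in names(cfg$strata)) {
      spec <- cfg$strata[[snm]]
      acc <- NULL
      rounds <- 0
      while (is.null(acc) || nrow(acc) < need[[snm]]) {
        rounds <- rounds + 1
        if (rounds > max_rounds)
          fail("retry budget exhausted for stratum '", snm,
               "': filters reject too many records (infeasible spec)")
        draw <- .sample_stratum(spec, max(need[[snm]] - NROW(acc), 16L))
        f <- apply_filters(draw)
        tally <- tally + f$tally
        acc <- rbind(acc, f$records)
      }
      got[[snm]] <- acc[seq_len(need[[snm]]), , drop = FALSE]
    }
    records <- do.call(rbind, got)
    rownames(records) <- NULL
    records$label <- assign_label(records)
    noise_seed <- sample.int(.Machine$integer.max, 1)
  })
  noisy <- inject_label_noise(records$label, cfg$label_noise_rate, noise_seed)
  records$label <- noisy$labels
  structure(list(records = records, tally = tally, flips = noisy$flips,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d records, %d strata, label noise %.2f\n",
              nrow(x$records), length(x$config$strata),
              x$config$label_noise_rate))
  print(round_half_up(100 * prop.table(table(x$records$label)), 1))
  invisible(x)
}

#' Stratified train/test split
#'
#' Splits by label so the class mix is preserved: the training size is
#' `round(n * fraction)` overall, apportioned across labels by largest
#' remainder; the test set is the complement.
#'
#' @param records cohort data.frame with a `label` column.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames (disjoint, union = input).
#' @export
split_train_test <- function(records, fraction = 0.8, seed = 42) {
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1)
    fail("fraction must be in (0, 1)")
  counts <- table(records$label)
  if (any(counts < 2)) fail("every label class needs at least 2 records")
  n_train <- round(nrow(records) * fraction)
  per_label <- largest_remainder(n_train, as.numeric(counts))
  names(per_label) <- names(counts)
  with_seed(seed, {
    train_idx <- unlist(lapply(names(counts), function(lb) {
      idx <- which(records$label == lb)
      sample(idx, per_label[[lb]])
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = records[train_idx, , drop = FALSE],
       test = records[-train_idx, , drop = FALSE])
}

#' Export / import a cohort CSV
#'
#' Lossless round trip of the 15 feature columns plus `label` (the `stratum`
#' bookkeeping column is carried along when present). Import re-checks every
#' filter invariant and fails on the first violating row.
#'
#' @param records cohort data.frame.
#' @param path CSV path.
#' @return `export_cohort_csv` returns the path invisibly;
#'   `import_cohort_csv` returns the validated data.frame.
#' @export
export_cohort_csv <- function(records, path) {
  need <- c(cohort_feature_names, "label")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    fail("records missing column(s): ", paste(missing_cols, collapse = ", "))
  keep <- intersect(c(cohort_feature_names, "stratum", "label"), names(records))
  utils::write.csv(records[, keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_cohort_csv
#' @export
import_cohort_csv <- function(path) {
  if (!file.exists(path)) fail("cohort CSV not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(cohort_feature_names, "label")
  missing_cols <- setdiff(need, names(rec))
  if (length(missing_cols))
    fail("cohort CSV missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(rec$label %in% cohort_labels))
    fail("unknown label value(s): ",
         paste(setdiff(unique(rec$label), cohort_labels), collapse = ", "))
  for (nm in names(.cohort_filters)) {
    bad <- which(.cohort_filters[[nm]](rec))
    if (length(bad))
      fail(sprintf("row %d violates invariant '%s'", bad[1], nm))
  }
  rec
}
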