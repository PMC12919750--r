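# Cohort simulator: apportionment, filters, labelling rule, noise, split, CSV.

test_that("stratified sampling apportions counts by largest remainder", {
  cfg <- cohort_config(n_target = 100, seed = 1)
  # defaults 0.80/0.08/0.12
  raw <- sample_stratified(cfg)
  expect_equal(unname(table(raw$stratum)[names(cfg$strata)]),
               c(80, 8, 12), ignore_attr = TRUE)
  # hand-apportioned example: n=10, weights (0.55, 0.30, 0.15) -> (6, 3, 1)
  strata <- cfg$strata
  strata[[1]]$weight <- 0.55; strata[[2]]$weight <- 0.30
  strata[[3]]$weight <- 0.15
  raw10 <- sample_stratified(cohort_config(n_target = 10, seed = 1,
                                           strata = strata))
  expect_equal(unname(table(raw10$stratum)[names(strata)]),
               c(6, 3, 1), ignore_attr = TRUE)
  # exact weights: n=100, (0.5, 0.3, 0.2) -> (50, 30, 20)
  strata[[1]]$weight <- 0.5; strata[[2]]$weight <- 0.3; strata[[3]]$weight <- 0.2
  raw100 <- sample_stratified(cohort_config(n_target = 100, seed = 1,
                                            strata = strata))
  expect_equal(unname(table(raw100$stratum)[names(strata)]),
               c(50, 30, 20), ignore_attr = TRUE)
  # invalid weights rejected
  strata[[1]]$weight <- 0.5; strata[[2]]$weight <- 0.6; strata[[3]]$weight <- 0
  expect_error(cohort_config(strata = strata), "sum to 1")
  expect_error(cohort_config(n_target = 0), "positive")
})

test_that("same seed reproduces the identical raw stream", {
  cfg <- cohort_config(n_target = 300, seed = 99)
  expect_identical(sample_stratified(cfg), sample_stratified(cfg))
})

test_that("filters reject out-of-range records with the right reason codes", {
  rec <- rbind(make_record(), make_record(bmi = 14.2),
               make_record(bmi = 40.5), make_record(kcal_need = 2900),
               make_record(cho_pct = 48, protein_pct = 20, fat_pct = 30),
               make_record(cho_pct = 70))
  out <- apply_filters(rec)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$tally[["bmi_out_of_range"]], 2)
  expect_equal(out$tally[["kcal_range"]], 1)
  expect_equal(out$tally[["macro_sum"]], 1)      # 48+20+30 = 98
  expect_equal(out$tally[["macro_window"]], 1)   # cho 70
  # boundary BMIs are retained (inclusive bounds)
  keep <- apply_filters(rbind(make_record(bmi = 15), make_record(bmi = 40)))
  expect_equal(nrow(keep$records), 2)
})

test_that("the violation-point labelling rule matches hand evaluation", {
  # 0 points -> ADEQUATE
  expect_equal(assign_label(make_record()), "ADEQUATE")
  # poor control (2) + low adherence (1) = 3 -> MINOR_ADJUSTMENT
  expect_equal(assign_label(make_record(glycemic_control = "poor",
                                        dietary_adherence = "low")),
               "MINOR_ADJUSTMENT")
  # poor control (2) + sugar-predominant (2) = 4 -> REQUIRES_CONSULTATION
  expect_equal(assign_label(make_record(glycemic_control = "poor",
                                        predominant_food_group = "sugar_sweet")),
               "REQUIRES_CONSULTATION")
  # type1 with CHO 56 (1) alone stays ADEQUATE; adding BMI 31 (1) -> 2 points
  expect_equal(assign_label(make_record(diabetes_type = "type1", cho_pct = 56,
                                        protein_pct = 14)), "ADEQUATE")
  expect_equal(assign_label(make_record(diabetes_type = "type1", cho_pct = 56,
                                        protein_pct = 14, bmi = 31)),
               "MINOR_ADJUSTMENT")
  # type2 does not trigger the carbohydrate rule
  expect_equal(assign_label(make_record(diabetes_type = "type2", cho_pct = 60,
                                        protein_pct = 10)), "ADEQUATE")
})

test_that("label noise flips the expected fraction and logs every flip", {
  labels <- rep(cohort_labels, length.out = 9000)
  none <- inject_label_noise(labels, 0, seed = 3)
  expect_identical(none$labels, labels)
  expect_equal(nrow(none$flips), 0)
  noisy <- inject_label_noise(labels, 0.1, seed = 3)
  n_flip <- nrow(noisy$flips)
  # binomial(9000, 0.1): mean 900, SD ~28.5; allow 3 SD
  expect_lt(abs(n_flip - 900), 3 * sqrt(9000 * 0.1 * 0.9))
  expect_true(all(noisy$labels[noisy$flips$index] != labels[noisy$flips$index]))
  expect_identical(noisy$labels[-noisy$flips$index],
                   labels[-noisy$flips$index])
  # determinism
  expect_identical(inject_label_noise(labels, 0.1, seed = 3)$flips, noisy$flips)
  expect_error(inject_label_noise(labels, 0.6), "rate")
})

test_that("train/test split is stratified, disjoint and exhaustive", {
  co <- small_cohort(n = 1000, seed = 8)
  sp <- split_train_test(co$records, 0.8, seed = 8)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  # per-label test counts within 1 of the stratified share
  for (lb in unique(co$records$label)) {
    n_lb <- sum(co$records$label == lb)
    expect_lte(abs(sum(sp$test$label == lb) - 0.2 * n_lb), 1)
  }
  key <- function(d) do.call(paste, d[order(d$age_years, d$weight_kg,
                                            d$kcal_need), ])
  expect_setequal(c(key(sp$train), key(sp$test)), key(co$records))
  expect_identical(split_train_test(co$records, 0.8, seed = 8)$train,
                   sp$train)
})

test_that("generated cohorts satisfy every invariant", {
  co <- small_cohort(n = 1500, seed = 77)
  r <- co$records
  expect_equal(nrow(r), 1500)
  expect_true(all(r$bmi >= 15 & r$bmi <= 40))
  expect_true(all(r$kcal_need >= 1200 & r$kcal_need <= 2800))
  expect_true(all(r$cho_pct >= 45 & r$cho_pct <= 65))
  expect_true(all(r$protein_pct >= 10 & r$protein_pct <= 35))
  expect_true(all(r$fat_pct >= 20 & r$fat_pct <= 35))
  expect_true(all(r$cho_pct + r$protein_pct + r$fat_pct == 100))
  expect_equal(setdiff(cohort_feature_names, names(r)), character(0))
  expect_true(all(r$label %in% cohort_labels))
  # full determinism including the noise stage
  co2 <- small_cohort(n = 1500, seed = 77)
  expect_identical(co$records, co2$records)
  expect_identical(co$flips, co2$flips)
})

test_that("cohort CSV round-trips losslessly and import re-validates", {
  co <- small_cohort(n = 100, seed = 5)
  path <- tempfile(fileext = ".csv")
  export_cohort_csv(co$records, path)
  back <- import_cohort_csv(path)
  expect_equal(back, co$records)
  # missing label column
  broken <- co$records[, setdiff(names(co$records), "label")]
  p2 <- tempfile(fileext = ".csv")
  expect_error(export_cohort_csv(broken, p2), "label")
  write.csv(broken, p2, row.names = FALSE)
  expect_error(import_cohort_csv(p2), "label")
  # out-of-range value on import is caught with row and rule
  poisoned <- co$records
  poisoned$bmi[3] <- 50
  p3 <- tempfile(fileext = ".csv")
  export_cohort_csv(poisoned, p3)
  expect_error(import_cohort_csv(p3), "row 3.*bmi_out_of_range")
})
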