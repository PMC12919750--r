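# Shared fixtures and independent oracles, all built in code.

# --- food fixtures -----------------------------------------------------------

make_food_row <- function(food_id, group, kcal = NULL, cho = 0, prot = 0,
                          fat = 0, fiber = 0, gi = NA, suitable = TRUE,
                          name = food_id, serving_g = 100) {
  if (is.null(kcal)) kcal <- round(4 * cho + 4 * prot + 9 * fat)
  data.frame(food_id = food_id, name = name, group = group,
             serving_desc = "1 serving", serving_g = serving_g, kcal = kcal,
             cho_g = cho, protein_g = prot, fat_g = fat, fiber_g = fiber,
             glycemic_index = gi, diabetes_suitable = suitable,
             regional = TRUE, stringsAsFactors = FALSE)
}

# the small hand-checkable set used across food_db tests
fixture_foods <- function() {
  rbind(
    make_food_row("tortilla", "cereal_tuber", cho = 13.0, prot = 1.6, fat = 0.7, fiber = 1.5, gi = 46),   # 65 kcal
    make_food_row("bolillo",  "cereal_tuber", cho = 12.5, prot = 2.0, fat = 0.4, fiber = 0.7, gi = 73,
                  suitable = FALSE),                                                                       # 62 kcal
    make_food_row("arroz",    "cereal_tuber", cho = 14.8, prot = 1.4, fat = 0.2, fiber = 0.4, gi = 73,
                  suitable = FALSE),                                                                       # 67 kcal
    make_food_row("frijol",   "legume", cho = 20.0, prot = 7.5, fat = 0.5, fiber = 7.5, gi = 30),          # 114 kcal
    make_food_row("nopal",    "vegetable", cho = 3.3, prot = 1.4, fat = 0.1, fiber = 3.0, gi = 10),        # 20 kcal
    make_food_row("jitomate", "vegetable", cho = 4.8, prot = 1.1, fat = 0.2, fiber = 1.5, gi = 30),        # 25 kcal
    make_food_row("acelga",   "vegetable", cho = 3.4, prot = 2.7, fat = 0.2, fiber = 2.2, gi = 15),        # 26 kcal
    make_food_row("sandia",   "fruit", cho = 11.5, prot = 0.9, fat = 0.2, fiber = 0.6, gi = 76,
                  suitable = FALSE),                                                                       # 51 kcal
    make_food_row("guayaba",  "fruit", cho = 13.2, prot = 1.4, fat = 0.6, fiber = 5.9, gi = 29),           # 64 kcal
    make_food_row("pollo",    "animal_protein", prot = 7.0, fat = 1.0),                                    # 37 kcal
    make_food_row("huevo",    "animal_protein", cho = 0.6, prot = 6.3, fat = 5.3),                         # 75 kcal
    make_food_row("yogurt",   "dairy", cho = 11.5, prot = 8.5, fat = 3.8, gi = 35),                        # 114 kcal
    make_food_row("leche",    "dairy", cho = 12.0, prot = 8.0, fat = 4.6, gi = 31)                         # 121 kcal
  )
}

write_foods_csv <- function(foods, path = tempfile(fileext = ".csv")) {
  out <- foods
  out$diabetes_suitable <- tolower(as.character(out$diabetes_suitable))
  out$regional <- tolower(as.character(out$regional))
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

with_fixture_db <- function(foods, code) {
  path <- tempfile(fileext = ".sqlite")
  db <- init_db(foods, path)
  on.exit({ close_db(db); unlink(path) })
  code(db)
}

# --- cohort fixtures ---------------------------------------------------------

# a single valid cohort record with overridable fields
make_record <- function(...) {
  base <- data.frame(
    age_years = 50, sex = "female", height_m = 1.60, weight_kg = 61.4,
    bmi = 24, diabetes_type = "type2", glycemic_control = "good",
    activity_level = "light", kcal_need = 1800, cho_pct = 50,
    protein_pct = 20, fat_pct = 30, predominant_food_group = "vegetable",
    dietary_adherence = "high", food_preference = "omnivore",
    label = "ADEQUATE", stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

small_cohort <- function(n = 400, seed = 42, noise = 0.12) {
  generate_cohort(cohort_config(n_target = n, seed = seed,
                                label_noise_rate = noise))
}

# --- independent oracles -----------------------------------------------------

# brute-force meal-composition feasibility: is there ANY serving combination
# (granularity 0.5, up to max_serv per food, per-group serving quotas) with
# kcal in [target(1-tol), target(1+tol)] and CHO <= cap? Recursive
# enumeration with kcal pruning; independent of the greedy composer.
oracle_meal_feasible <- function(foods, target, cap, tol = 0.05,
                                 max_serv = 3, step = 0.5,
                                 group_caps = plan_constraints()$group_caps_servings) {
  lo <- target * (1 - tol); hi <- target * (1 + tol)
  n <- nrow(foods)
  recurse <- function(i, kcal, cho, used) {
    if (kcal > hi + 1e-9 || cho > cap + 1e-9) return(FALSE)
    if (any(used > group_caps[names(used)] + 1e-9)) return(FALSE)
    if (kcal >= lo - 1e-9) return(TRUE)
    if (i > n) return(FALSE)
    grp <- foods$group[i]
    for (s in seq(0, max_serv, by = step)) {
      u <- used
      u[[grp]] <- u[[grp]] + s
      if (recurse(i + 1, kcal + s * foods$kcal[i], cho + s * foods$cho_g[i], u))
        return(TRUE)
    }
    FALSE
  }
  used0 <- stats::setNames(numeric(length(food_groups)), food_groups)
  recurse(1, 0, 0, used0)
}

# brute-force confusion tally (per-sample loop, no vectorized reuse)
oracle_confusion <- function(truth, pred) {
  classes <- c("ADEQUATE", "MINOR_ADJUSTMENT", "REQUIRES_CONSULTATION")
  out <- list()
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0; support <- 0
    for (i in seq_along(truth)) {
      if (truth[i] == cl) support <- support + 1
      if (truth[i] == cl && pred[i] == cl) tp <- tp + 1
      if (truth[i] != cl && pred[i] == cl) fp <- fp + 1
      if (truth[i] == cl && pred[i] != cl) fn <- fn + 1
    }
    out[[cl]] <- c(tp = tp, fp = fp, fn = fn, support = support)
  }
  out
}

# Wilson interval by grid inversion of the score test: the interval is the
# set of p0 whose score statistic is below the normal quantile.
oracle_wilson_grid <- function(successes, trials, confidence = 0.95,
                               grid_step = 1e-6) {
  z <- qnorm(1 - (1 - confidence) / 2)
  phat <- successes / trials
  p0 <- seq(grid_step, 1 - grid_step, by = grid_step)
  stat <- abs(phat - p0) / sqrt(p0 * (1 - p0) / trials)
  inside <- p0[stat <= z]
  c(lower = min(inside), upper = max(inside))
}
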