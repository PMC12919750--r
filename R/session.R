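# Kiosk session flow: questionnaire validation and the end-to-end pipeline
# profile -> energy -> plan -> triage -> rendering. No per-session
# identifiers are stored anywhere.

.session_fields <- c("age", "weight", "height", "sex", "diabetes_type",
                     "glycemic_control", "activity", "food_preference")

#' Validate raw kiosk questionnaire input
#'
#' Applies type, range, enum-membership and semantic checks and collects
#' every rejection (not fail-fast). A height above 3 triggers the
#' plausible-centimetres hint, since stature is expected in metres.
#'
#' @param raw named list or vector of questionnaire answers: `age`,
#'   `weight` (kg), `height` (m), `sex`, `diabetes_type`,
#'   `glycemic_control`, `activity`, `food_preference`.
#' @return list with `ok` (logical), `input` (typed list when valid, else
#'   `NULL`) and `rejections` (data.frame `field`, `reason`, `hint`).
#' @export
validate_session_input <- function(raw) {
  raw <- as.list(raw)
  rej <- function(field, reason, hint = "") {
    data.frame(field = field, reason = reason, hint = hint,
               stringsAsFactors = FALSE)
  }
  rejections <- list()
  add <- function(r) rejections[[length(rejections) + 1]] <<- r
  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    if (is.null(raw[[field]])) { add(rej(field, "missing")); return(NA) }
    if (is.na(v)) { add(rej(field, "not_numeric")); return(NA) }
    v
  }
  age <- num("age")
  if (!is.na(age) && (age <= 0 || age >= 120))
    add(rej("age", "range", "expected years in (0, 120)"))
  weight <- num("weight")
  if (!is.na(weight) && (weight <= 20 || weight >= 300))
    add(rej("weight", "range", "expected kilograms in (20, 300)"))
  height <- num("height")
  if (!is.na(height)) {
    if (height > 3)
      add(rej("height", "range", "value > 3 suggests centimetres; expected metres"))
    else if (height <= 0.5 || height >= 2.5)
      add(rej("height", "range", "expected metres in (0.5, 2.5)"))
  }
  chk_enum <- function(field, choices) {
    v <- raw[[field]]
    if (is.null(v) || is.na(v) || !nzchar(v)) add(rej(field, "missing"))
    else if (!(v %in% choices))
      add(rej(field, "enum", paste("allowed:", paste(choices, collapse = ", "))))
  }
  chk_enum("sex", c("female", "male"))
  chk_enum("diabetes_type", diabetes_types)
  chk_enum("glycemic_control", glycemic_levels)
  chk_enum("activity", names(activity_factors))
  chk_enum("food_preference", preference_levels)
  rejections <- if (length(rejections)) do.call(rbind, rejections)
    else data.frame(field = character(0), reason = character(0),
                    hint = character(0), stringsAsFactors = FALSE)
  if (nrow(rejections))
    return(list(ok = FALSE, input = NULL, rejections = rejections))
  list(ok = TRUE,
       input = list(age = age, weight = weight, height = height,
                    sex = raw$sex, diabetes_type = raw$diabetes_type,
                    glycemic_control = raw$glycemic_control,
                    activity = raw$activity,
                    food_preference = raw$food_preference),
       rejections = rejections)
}

# Build the cohort-record row the classifier expects from a session input
# plus the energy outputs.
.session_record <- function(input, energy, dist,
                            predominant_food_group = "cereal_tuber",
                            dietary_adherence = "medium") {
  data.frame(
    age_years = input$age, sex = input$sex, height_m = input$height,
    weight_kg = input$weight,
    bmi = compute_bmi(anthropometrics(input$age, input$sex, input$height,
                                      input$weight)),
    diabetes_type = input$diabetes_type,
    glycemic_control = input$glycemic_control,
    activity_level = input$activity, kcal_need = energy$tdee_kcal,
    cho_pct = dist$cho_pct, protein_pct = dist$protein_pct,
    fat_pct = dist$fat_pct,
    predominant_food_group = predominant_food_group,
    dietary_adherence = dietary_adherence,
    food_preference = input$food_preference, stringsAsFactors = FALSE)
}

#' Run one complete kiosk session
#'
#' Deterministic pipeline: validate the questionnaire, compute BMI / energy
#' requirement / macro grams, compose the meal plan, triage it with the
#' classifier, and render the result. Aborts with the rejection list (no
#' partial plan) when validation fails.
#'
#' @param db an open `"food_db"` handle.
#' @param model a fitted [triage_mlp()].
#' @param raw_input raw questionnaire answers, see
#'   [validate_session_input()].
#' @param dist a [macro_distribution()] for the plan (default 50/20/30).
#' @param predominant_food_group,dietary_adherence self-reported dietary
#'   pattern answers (defaults `"cereal_tuber"`, `"medium"`).
#' @param constraints optional [plan_constraints()] overrides; the daily
#'   target is always replaced by the computed requirement.
#' @return list of class `"kiosk_session"`: `energy` (BMI, BMR, TDEE, macro
#'   grams), `plan`, `triage` (label + probabilities), `json` and `text`
#'   renderings, and `log` (per-stage timing).
#' @export
run_session <- function(db, model, raw_input, dist = macro_distribution(),
                        predominant_food_group = "cereal_tuber",
                        dietary_adherence = "medium", constraints = NULL) {
  if (!inherits(db, "food_db")) fail("configuration error: no food database")
  if (!inherits(model, "triage_mlp")) fail("configuration error: no model")
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    log[[name]] <<- proc.time()[["elapsed"]] - t0
    val
  }
  v <- stage("validate", validate_session_input(raw_input))
  if (!v$ok)
    return(structure(list(ok = FALSE, rejections = v$rejections, log = log),
                     class = "kiosk_session"))
  input <- v$input
  energy <- stage("energy", {
    a <- anthropometrics(input$age, input$sex, input$height, input$weight)
    req <- total_energy(a, input$activity)
    list(bmi = compute_bmi(a), bmr_kcal = req$bmr_kcal,
         tdee_kcal = req$tdee_kcal, clamped = req$clamped,
         macros_g = macro_split(req$tdee_kcal, dist))
  })
  cons <- if (is.null(constraints)) plan_constraints(
    daily_kcal_target = energy$tdee_kcal, dist = dist)
  else {
    constraints$daily_kcal_target <- energy$tdee_kcal
    constraints
  }
  plan <- stage("plan", compose_plan(db, cons, input$food_preference))
  triage <- stage("triage", {
    rec <- .session_record(input, energy, dist, predominant_food_group,
                           dietary_adherence)
    predict_class(model, rec)
  })
  out <- structure(list(ok = TRUE, energy = energy, plan = plan,
                        triage = triage,
                        json = render_plan(plan, "json", triage$label),
                        text = render_plan(plan, "text", triage$label),
                        log = log),
                   class = "kiosk_session")
  out
}

#' @export
print.kiosk_session <- function(x, ...) {
  if (!isTRUE(x$ok)) {
    cat("Session rejected:\n")
    print(x$rejections, row.names = FALSE)
    return(invisible(x))
  }
  cat(sprintf("BMI %.2f | BMR %.2f kcal/d | TDEE %.2f kcal/d%s\n",
              x$energy$bmi, x$energy$bmr_kcal, x$energy$tdee_kcal,
              if (x$energy$clamped) " (clamped)" else ""))
  cat(sprintf("Triage: %s (p = %s)\n", x$triage$label,
              paste(sprintf("%.3f", x$triage$probs), collapse = "/")))
  cat(x$text, "\n")
  invisible(x)
}
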