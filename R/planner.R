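# Deterministic meal-plan composer: per-slot calorie allocation, greedy
# low-GI/high-fiber food selection under calorie and carbohydrate caps,
# substitution via food exchanges, compliance checking and rendering.

#' The five meal slots of a daily plan
#' @format Character vector of slot names.
#' @export
meal_slots <- c("breakfast", "snack_am", "lunch", "snack_pm", "dinner")

#' Planner constraints
#'
#' @param daily_kcal_target daily energy target in kcal (1200-2800).
#' @param dist a [macro_distribution()] for the target split.
#' @param kcal_tolerance relative calorie tolerance (default 0.05, applied to
#'   the day and to each slot target).
#' @param slot_fractions calorie share per meal slot; must sum to 1. Default
#'   25/10/30/10/25% — the standard diabetes-education split.
#' @param cho_caps_g per-slot carbohydrate caps in grams (default 60 for main
#'   meals, 25 for snacks), the carbohydrate-counting thresholds.
#' @param required_groups list of food-group alternative sets that must be
#'   covered across the day (default vegetable, cereal/tuber,
#'   legume-or-animal-protein, fruit).
#' @param low_gi_threshold glycemic-index value under which a food counts as
#'   low-GI (default 55); used for prioritization, not exclusion.
#' @param serving_granularity smallest serving increment (default 0.5).
#' @param max_servings largest number of servings of one food in one slot.
#' @param group_caps_servings per-slot ceilings on total servings from each
#'   food group, the food-exchange quota that keeps single low-GI groups
#'   (nuts, oils) from crowding out the rest of the plate.
#' @return list of class `"plan_constraints"`.
#' @export
plan_constraints <- function(daily_kcal_target = 2000,
                             dist = macro_distribution(),
                             kcal_tolerance = 0.05,
                             slot_fractions = c(breakfast = 0.25, snack_am = 0.10,
                                                lunch = 0.30, snack_pm = 0.10,
                                                dinner = 0.25),
                             cho_caps_g = c(breakfast = 60, snack_am = 25,
                                            lunch = 60, snack_pm = 25,
                                            dinner = 60),
                             required_groups = list("vegetable", "cereal_tuber",
                                                    c("legume", "animal_protein"),
                                                    "fruit"),
                             low_gi_threshold = 55,
                             serving_granularity = 0.5,
                             max_servings = 3,
                             group_caps_servings = c(vegetable = 4, legume = 2,
                                                     fruit = 2, cereal_tuber = 3,
                                                     animal_protein = 3, dairy = 2,
                                                     fats_oils = 1.5,
                                                     sugar_sweet = 0.5)) {
  if (!is_number(daily_kcal_target) || daily_kcal_target < 1200 ||
      daily_kcal_target > 2800)
    fail("daily_kcal_target must be in [1200, 2800]")
  stopifnot(kcal_tolerance > 0, all(cho_caps_g > 0),
            serving_granularity > 0, max_servings > 0,
            identical(sort(names(slot_fractions)), sort(meal_slots)),
            identical(sort(names(cho_caps_g)), sort(meal_slots)))
  if (abs(sum(slot_fractions) - 1) > 1e-9) fail("slot_fractions must sum to 1")
  stopifnot(all(food_groups %in% names(group_caps_servings)))
  structure(list(daily_kcal_target = daily_kcal_target, dist = dist,
                 kcal_tolerance = kcal_tolerance,
                 slot_fractions = slot_fractions[meal_slots],
                 cho_caps_g = cho_caps_g[meal_slots],
                 required_groups = required_groups,
                 low_gi_threshold = low_gi_threshold,
                 serving_granularity = serving_granularity,
                 max_servings = max_servings,
                 group_caps_servings = group_caps_servings),
            class = "plan_constraints")
}

#' Allocate daily calories to meal slots
#'
#' Splits the daily target across the five slots by the constraint fractions,
#' rounded to whole kcal with the largest-remainder method so the slot
#' targets sum exactly to the input.
#'
#' @param daily_kcal daily energy in kcal (1200-2800).
#' @param constraints a [plan_constraints()] (only `slot_fractions` is used).
#' @return named integer vector of per-slot kcal targets.
#' @examples
#' allocate_meal_calories(2000)  # 500 200 600 200 500
#' @export
allocate_meal_calories <- function(daily_kcal, constraints = plan_constraints()) {
  if (!is_number(daily_kcal) || daily_kcal < 1200 || daily_kcal > 2800)
    fail("daily_kcal must be in [1200, 2800]")
  stats::setNames(largest_remainder(round(daily_kcal), constraints$slot_fractions),
                  meal_slots)
}

.as_food_table <- function(db) {
  if (inherits(db, "food_db")) db_foods(db)
  else if (is.data.frame(db)) db
  else fail("db must be a food_db handle or a foods data.frame")
}

# candidate priority: diabetes-suitable first, then GI ascending with missing
# GI last, then fiber descending, then food_id (total order).
.candidate_order <- function(foods) {
  gi <- foods$glycemic_index
  gi[is.na(gi)] <- Inf
  order(-foods$diabetes_suitable, gi, -foods$fiber_g, foods$food_id)
}

.slot_totals <- function(foods, servings) {
  ok <- servings > 0
  s <- servings[ok]
  f <- foods[ok, , drop = FALSE]
  c(kcal = sum(s * f$kcal), cho_g = sum(s * f$cho_g),
    protein_g = sum(s * f$protein_g), fat_g = sum(s * f$fat_g),
    fiber_g = sum(s * f$fiber_g))
}

#' Compose one meal slot
#'
#' Greedy deterministic selection: candidates are visited in priority order
#' (diabetes-suitable first, glycemic index ascending with missing GI last,
#' fiber descending, ties by `food_id`) and servings are added in
#' `serving_granularity` steps while the slot stays at or below
#' `target * (1 + tolerance)` kcal and at or below the carbohydrate cap,
#' stopping as soon as the slot reaches `target * (1 - tolerance)`. If no
#' compliant fill is reachable the best-effort slot is returned flagged
#' non-compliant with reasons, never silently dropped.
#'
#' @param db a `"food_db"` handle or a foods data.frame.
#' @param slot_kcal_target slot energy target in kcal.
#' @param slot_cho_cap slot carbohydrate cap in grams.
#' @param constraints a [plan_constraints()] (tolerance, granularity,
#'   max servings).
#' @param seed_groups optional list of food-group alternative sets; before
#'   the greedy pass, one serving of the best candidate of each set is placed
#'   if it fits, guaranteeing food-group coverage.
#' @param exclude_groups food groups removed from the candidate pool (dietary
#'   preference support).
#' @return list: `items` (data.frame `food_id`, `servings`), `totals`
#'   (kcal/macros/fiber), `compliant`, `reasons`.
#' @export
compose_meal <- function(db, slot_kcal_target, slot_cho_cap,
                         constraints = plan_constraints(),
                         seed_groups = NULL, exclude_groups = NULL) {
  foods <- .as_food_table(db)
  if (!is.null(exclude_groups))
    foods <- foods[!(foods$group %in% exclude_groups), , drop = FALSE]
  tol <- constraints$kcal_tolerance
  lo <- slot_kcal_target * (1 - tol)
  hi <- slot_kcal_target * (1 + tol)
  step <- constraints$serving_granularity
  serv <- stats::setNames(numeric(nrow(foods)), foods$food_id)
  group_used <- stats::setNames(numeric(length(food_groups)), food_groups)
  kcal <- 0; cho <- 0
  reasons <- character(0)
  if (nrow(foods) == 0) {
    return(list(items = data.frame(food_id = character(0), servings = numeric(0)),
                totals = .slot_totals(foods, serv), compliant = FALSE,
                reasons = "no_candidates"))
  }
  ord <- .candidate_order(foods)
  # fallback priority for carbohydrate-bound slots: least carbohydrate per
  # kcal first (energy density relief), then the usual low-GI order
  gi_na <- foods$glycemic_index
  gi_na[is.na(gi_na)] <- Inf
  ord_cho <- order(foods$cho_g / pmax(foods$kcal, 1), gi_na, foods$food_id)
  try_add <- function(i, amount) {
    add_kcal <- amount * foods$kcal[i]
    add_cho <- amount * foods$cho_g[i]
    grp <- foods$group[i]
    if (kcal + add_kcal <= hi + 1e-9 && cho + add_cho <= slot_cho_cap + 1e-9 &&
        serv[i] + amount <= constraints$max_servings + 1e-9 &&
        group_used[[grp]] + amount <=
          constraints$group_caps_servings[[grp]] + 1e-9) {
      serv[i] <<- serv[i] + amount
      group_used[[grp]] <<- group_used[[grp]] + amount
      kcal <<- kcal + add_kcal
      cho <<- cho + add_cho
      TRUE
    } else FALSE
  }
  # greedy fill pass in the given priority order
  fill <- function(order_idx) {
    for (i in order_idx) {
      while (kcal < lo - 1e-9) {
        if (!try_add(i, step)) break
      }
      if (kcal >= lo - 1e-9) break
    }
  }
  # single-exchange swap: remove one committed serving step, add one step of
  # another food (first combination in priority order that satisfies `accept`
  # wins); used both to land inside the window and to trade committed
  # servings for strictly more energy when the fill stalls below it
  swap_step <- function(order_idx, accept) {
    for (j in order_idx) {
      for (i2 in rev(order_idx)) {
        if (i2 == j || serv[i2] < step - 1e-9) next
        nk <- kcal - step * foods$kcal[i2] + step * foods$kcal[j]
        nc <- cho - step * foods$cho_g[i2] + step * foods$cho_g[j]
        gj <- foods$group[j]; gi2 <- foods$group[i2]
        gu <- group_used
        gu[[gi2]] <- gu[[gi2]] - step
        gu[[gj]] <- gu[[gj]] + step
        if (accept(nk) && nc <= slot_cho_cap + 1e-9 &&
            serv[j] + step <= constraints$max_servings + 1e-9 &&
            gu[[gj]] <= constraints$group_caps_servings[[gj]] + 1e-9) {
          serv[i2] <<- serv[i2] - step
          serv[j] <<- serv[j] + step
          group_used <<- gu
          kcal <<- nk
          cho <<- nc
          return(TRUE)
        }
      }
    }
    FALSE
  }
  # one full composition attempt under a candidate ordering: coverage
  # seeding, greedy fill, then a bounded exchange-repair loop
  run_pass <- function(order_idx) {
    serv <<- stats::setNames(numeric(nrow(foods)), foods$food_id)
    group_used <<- stats::setNames(numeric(length(food_groups)), food_groups)
    kcal <<- 0; cho <<- 0
    for (alt in seed_groups) {
      cand <- order_idx[foods$group[order_idx] %in% alt]
      for (i in cand) {
        if (try_add(i, 1) || try_add(i, step)) break
      }
    }
    fill(order_idx)
    rounds <- 0
    while (kcal < lo - 1e-9 && rounds < 8) {
      rounds <- rounds + 1
      if (swap_step(order_idx, function(nk) nk >= lo - 1e-9 && nk <= hi + 1e-9))
        break
      base <- kcal
      if (!swap_step(order_idx, function(nk) nk > base + 1e-9 && nk <= hi + 1e-9))
        break
      fill(order_idx)
    }
  }
  # missing required groups are independent of the ordering
  for (alt in seed_groups) {
    if (!any(foods$group %in% alt))
      reasons <- c(reasons, paste0("missing_group:", paste(alt, collapse = "|")))
  }
  run_pass(ord)
  if (kcal < lo - 1e-9) {
    # carbohydrate-bound slot: retry with the least-CHO-per-kcal ordering and
    # keep whichever attempt got closer to the window
    primary <- list(serv = serv, group_used = group_used, kcal = kcal, cho = cho)
    run_pass(ord_cho)
    if (kcal < lo - 1e-9 && primary$kcal >= kcal) {
      serv <- primary$serv
      group_used <- primary$group_used
      kcal <- primary$kcal
      cho <- primary$cho
    }
  }
  compliant <- kcal >= lo - 1e-9 && kcal <= hi + 1e-9 &&
    cho <= slot_cho_cap + 1e-9 && length(reasons) == 0
  if (kcal < lo - 1e-9) reasons <- c(reasons, "kcal_short")
  if (cho > slot_cho_cap + 1e-9) reasons <- c(reasons, "cho_cap")
  keep <- which(serv > 0)
  keep <- keep[order(match(keep, ord))]  # presentation in priority order
  list(items = data.frame(food_id = foods$food_id[keep],
                          name = foods$name[keep],
                          group = foods$group[keep],
                          servings = unname(serv[keep]),
                          stringsAsFactors = FALSE),
       totals = .slot_totals(foods, serv),
       compliant = compliant,
       reasons = reasons)
}

#' Compose a full daily meal plan
#'
#' Allocates the daily energy target over the five meal slots, composes each
#' slot with the greedy selector (seeding required food groups into fixed
#' slots: cereal/tuber at breakfast, fruit at the morning snack, vegetable
#' plus legume-or-animal-protein at lunch), aggregates totals and evaluates
#' compliance. Deterministic for fixed database, profile and constraints.
#'
#' @param db a `"food_db"` handle or foods data.frame.
#' @param constraints a [plan_constraints()] carrying the daily target and
#'   macro split.
#' @param food_preference `"omnivore"`, `"low_meat"` or `"vegetarian"`;
#'   vegetarian profiles exclude the animal-protein group.
#' @return Object of class `"meal_plan"`: `slots`, `slot_targets`,
#'   `slot_totals`, `daily`, `compliance`, `constraints`.
#' @export
compose_plan <- function(db, constraints = plan_constraints(),
                         food_preference = "omnivore") {
  foods <- .as_food_table(db)
  food_preference <- match_enum(food_preference, preference_levels,
                                "food preference")
  exclude <- if (food_preference == "vegetarian") "animal_protein" else NULL
  targets <- allocate_meal_calories(constraints$daily_kcal_target, constraints)
  seeds <- list(
    breakfast = list("cereal_tuber"),
    snack_am = list("fruit"),
    lunch = list("vegetable", c("legume", "animal_protein")),
    snack_pm = NULL,
    dinner = list("vegetable"))
  slots <- lapply(meal_slots, function(sl)
    compose_meal(foods, targets[[sl]], constraints$cho_caps_g[[sl]],
                 constraints, seed_groups = seeds[[sl]],
                 exclude_groups = exclude))
  names(slots) <- meal_slots
  slot_totals <- do.call(rbind, lapply(slots, function(s) s$totals))
  daily <- colSums(slot_totals)
  plan <- structure(list(slots = slots, slot_targets = targets,
                         slot_totals = slot_totals, daily = daily,
                         constraints = constraints,
                         food_preference = food_preference),
                    class = "meal_plan")
  plan$compliance <- check_compliance(plan, constraints)
  plan
}

#' Check plan compliance
#'
#' Evaluates the plan against (1) daily calories within tolerance of the
#' target, (2) every slot's carbohydrate load at or under its cap, (3) all
#' required food groups covered across the day, and (4) the realized macro
#' distribution within the acceptable ranges widened by 5 percentage points.
#' Overall status is the conjunction of all rules.
#'
#' @param plan a `"meal_plan"`.
#' @param constraints a [plan_constraints()].
#' @return list of class `"plan_compliance"`: logical per-rule results,
#'   `violations` (character codes), `status`.
#' @export
check_compliance <- function(plan, constraints = plan$constraints) {
  violations <- character(0)
  tol <- constraints$kcal_tolerance
  target <- constraints$daily_kcal_target
  kcal_ok <- abs(plan$daily[["kcal"]] - target) <= tol * target + 1e-9
  if (!kcal_ok) violations <- c(violations, "kcal_tolerance")
  cho_ok <- TRUE
  for (sl in meal_slots) {
    if (plan$slot_totals[sl, "cho_g"] > constraints$cho_caps_g[[sl]] + 1e-9) {
      cho_ok <- FALSE
      violations <- c(violations, paste0("cho_cap:", sl))
    }
  }
  groups_present <- unique(unlist(lapply(plan$slots, function(s) s$items$group)))
  groups_ok <- TRUE
  for (alt in constraints$required_groups) {
    if (!any(alt %in% groups_present)) {
      groups_ok <- FALSE
      violations <- c(violations,
                      paste0("missing_group:", paste(alt, collapse = "|")))
    }
  }
  macro_kcal <- c(cho = 4 * plan$daily[["cho_g"]],
                  protein = 4 * plan$daily[["protein_g"]],
                  fat = 9 * plan$daily[["fat_g"]])
  macro_pct <- 100 * macro_kcal / sum(macro_kcal)
  windows <- rbind(cho = c(45, 65), protein = c(10, 35), fat = c(20, 35))
  macro_ok <- TRUE
  for (m in rownames(windows)) {
    if (macro_pct[[m]] < windows[m, 1] - 5 || macro_pct[[m]] > windows[m, 2] + 5) {
      macro_ok <- FALSE
      violations <- c(violations, paste0("macro_window:", m))
    }
  }
  structure(list(kcal_within_tolerance = kcal_ok, cho_caps = cho_ok,
                 required_groups_covered = groups_ok,
                 macro_window = macro_ok,
                 realized_macro_pct = round_half_up(macro_pct, 1),
                 violations = violations,
                 status = kcal_ok && cho_ok && groups_ok && macro_ok),
            class = "plan_compliance")
}

#' Substitute one food in a plan by its nearest exchange equivalent
#'
#' Looks up [find_equivalents()] (same group, energy within 10%), replaces
#' the food keeping the serving count, and re-evaluates totals and
#' compliance. If no equivalent exists the plan is returned unchanged with a
#' `"no_equivalent"` notice.
#'
#' @param db an open `"food_db"` handle.
#' @param plan a `"meal_plan"`.
#' @param slot one of the five meal slots.
#' @param food_id the food to replace; must be present in the slot.
#' @return list with `plan` (new or unchanged) and `notice` (`"substituted"`
#'   with the replacement id, or `"no_equivalent"`).
#' @export
substitute_food <- function(db, plan, slot, food_id) {
  stopifnot(inherits(plan, "meal_plan"))
  slot <- match_enum(slot, meal_slots, "meal slot")
  items <- plan$slots[[slot]]$items
  if (!(food_id %in% items$food_id))
    fail("food '", food_id, "' is not in slot '", slot, "'")
  eq <- find_equivalents(db, food_id, 0.10)
  eq <- eq[!(eq$food_id %in% items$food_id), , drop = FALSE]
  if (nrow(eq) == 0)
    return(list(plan = plan, notice = "no_equivalent"))
  repl <- eq[1, ]
  foods <- db_foods(db)
  i <- which(items$food_id == food_id)
  items$food_id[i] <- repl$food_id
  items$name[i] <- repl$name
  items$group[i] <- repl$group
  plan$slots[[slot]]$items <- items
  serv <- stats::setNames(items$servings, items$food_id)
  sub_foods <- foods[match(items$food_id, foods$food_id), , drop = FALSE]
  plan$slots[[slot]]$totals <- .slot_totals(sub_foods, unname(serv))
  plan$slot_totals[slot, ] <- plan$slots[[slot]]$totals
  plan$daily <- colSums(plan$slot_totals)
  plan$compliance <- check_compliance(plan, plan$constraints)
  sl_tol <- plan$constraints$kcal_tolerance
  tgt <- plan$slot_targets[[slot]]
  plan$slots[[slot]]$compliant <-
    plan$slots[[slot]]$totals[["kcal"]] >= tgt * (1 - sl_tol) - 1e-9 &&
    plan$slots[[slot]]$totals[["kcal"]] <= tgt * (1 + sl_tol) + 1e-9 &&
    plan$slots[[slot]]$totals[["cho_g"]] <= plan$constraints$cho_caps_g[[slot]] + 1e-9
  list(plan = plan, notice = paste0("substituted:", repl$food_id))
}

#' Render a meal plan
#'
#' @param plan a `"meal_plan"`.
#' @param format `"json"` (canonical, machine-readable; parse back with
#'   [parse_plan_json()]) or `"text"` (one section per slot plus calorie
#'   summary and compliance notes).
#' @param triage_label optional triage class; `REQUIRES_CONSULTATION` adds a
#'   consultation advisory and foods-to-avoid notice to the text rendering.
#' @return character scalar (JSON string or formatted text).
#' @export
render_plan <- function(plan, format = c("json", "text"), triage_label = NULL) {
  stopifnot(inherits(plan, "meal_plan"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      slot_targets = as.list(plan$slot_targets),
      slots = lapply(plan$slots, function(s)
        list(items = s$items, totals = as.list(round(s$totals, 6)),
             compliant = s$compliant, reasons = s$reasons)),
      daily = as.list(round(plan$daily, 6)),
      daily_kcal_target = plan$constraints$daily_kcal_target,
      food_preference = plan$food_preference,
      compliance = list(
        kcal_within_tolerance = plan$compliance$kcal_within_tolerance,
        cho_caps = plan$compliance$cho_caps,
        required_groups_covered = plan$compliance$required_groups_covered,
        macro_window = plan$compliance$macro_window,
        realized_macro_pct = as.list(plan$compliance$realized_macro_pct),
        violations = plan$compliance$violations,
        status = plan$compliance$status),
      triage_label = triage_label)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, null = "null")))
  }
  lines <- c(sprintf("DAILY MEAL PLAN  (target %d kcal, realized %.0f kcal)",
                     round(plan$constraints$daily_kcal_target),
                     plan$daily[["kcal"]]),
             sprintf("Macros: CHO %.1f g, protein %.1f g, fat %.1f g, fiber %.1f g",
                     plan$daily[["cho_g"]], plan$daily[["protein_g"]],
                     plan$daily[["fat_g"]], plan$daily[["fiber_g"]]))
  for (sl in meal_slots) {
    s <- plan$slots[[sl]]
    lines <- c(lines, "", sprintf("== %s (target %d kcal, %.0f kcal) ==",
                                  toupper(sl), plan$slot_targets[[sl]],
                                  s$totals[["kcal"]]))
    if (nrow(s$items) == 0) {
      lines <- c(lines, "  (no items)")
    } else {
      lines <- c(lines, sprintf("  %-28s %4.1f serving(s)  [%s]",
                                s$items$name, s$items$servings, s$items$group))
    }
    if (!s$compliant)
      lines <- c(lines, sprintf("  ! non-compliant: %s",
                                paste(s$reasons, collapse = ", ")))
  }
  lines <- c(lines, "",
             sprintf("Plan status: %s",
                     if (plan$compliance$status) "COMPLIANT" else
                       paste("NON-COMPLIANT:",
                             paste(plan$compliance$violations, collapse = ", "))))
  if (identical(triage_label, "REQUIRES_CONSULTATION")) {
    lines <- c(lines,
      "ADVISORY: this plan requires review by a nutrition professional before use.",
      "Foods to avoid until consultation: sugary drinks and sweets, fried foods,",
      "refined flours; prefer vegetables, legumes and whole grains.")
  }
  paste(lines, collapse = "\n")
}

#' Parse a plan rendered as JSON
#'
#' Inverse of `render_plan(plan, "json")` for the structural fields (slots,
#' totals, compliance).
#'
#' @param json JSON string from [render_plan()].
#' @return list mirroring the rendered structure.
#' @export
parse_plan_json <- function(json) {
  jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
}

#' @export
print.meal_plan <- function(x, ...) {
  cat(render_plan(x, "text"), "\n")
  invisible(x)
}

#' @export
print.plan_compliance <- function(x, ...) {
  cat(sprintf("Plan compliance: %s\n", if (x$status) "OK" else "VIOLATIONS"))
  if (length(x$violations)) cat("  ", paste(x$violations, collapse = ", "), "\n")
  invisible(x)
}
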