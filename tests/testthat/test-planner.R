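# Meal-plan composer: calorie allocation, greedy selection vs brute force,
# full plans, substitution, compliance, rendering.

test_that("meal-calorie allocation follows the fixed fractions exactly", {
  expect_equal(unname(allocate_meal_calories(2000)),
               c(500, 200, 600, 200, 500))
  expect_equal(unname(allocate_meal_calories(1200)),
               c(300, 120, 360, 120, 300))
  # conservation for arbitrary targets (largest-remainder rounding)
  for (kcal in c(1200, 1499, 1777, 2043, 2800)) {
    expect_equal(sum(allocate_meal_calories(kcal)), round(kcal))
  }
  expect_error(allocate_meal_calories(900), "1200")
})

test_that("slot composition respects the priority order and all caps", {
  # carbohydrate-only pool: the 60 g CHO cap and the vegetable quota bound
  # the reachable energy below the 500 kcal window on this six-food set
  foods <- fixture_foods()[c(1, 4:8), ]  # tortilla frijol nopal jitomate acelga sandia
  res <- compose_meal(foods, 500, 60)
  expect_false(res$compliant)
  expect_true("kcal_short" %in% res$reasons)
  expect_lte(res$totals[["cho_g"]], 60)
  # with protein and dairy foods available the target is reachable
  res2 <- compose_meal(fixture_foods(), 500, 60)
  expect_true(res2$compliant)
  expect_gte(res2$totals[["kcal"]], 475)
  expect_lte(res2$totals[["kcal"]], 525)
  expect_lte(res2$totals[["cho_g"]], 60)
  # selection honours the priority order: the top pick of the pool (lowest
  # GI among diabetes-suitable, fiber as tie-break) is always used first
  expect_equal(res2$items$food_id[1], "nopal")
  # per-food and per-group serving ceilings hold
  expect_true(all(res2$items$servings <= 3))
  for (grp in unique(res2$items$group)) {
    expect_lte(sum(res2$items$servings[res2$items$group == grp]),
               plan_constraints()$group_caps_servings[[grp]])
  }
})

test_that("degenerate candidate sets are flagged, never silent", {
  empty <- fixture_foods()[0, ]
  res <- compose_meal(empty, 500, 60)
  expect_false(res$compliant)
  expect_equal(nrow(res$items), 0)
  expect_equal(res$reasons, "no_candidates")
  # all candidates exceed the CHO cap
  sugary <- make_food_row("azucar", "sugar_sweet", cho = 80, gi = 100)
  res2 <- compose_meal(sugary, 300, 20)
  expect_false(res2$compliant)
  expect_true("kcal_short" %in% res2$reasons)
})

test_that("greedy composition is compliant whenever brute force finds a fill", {
  # exhaustive-search oracle over serving combinations (granularity 0.5,
  # max 3 servings per food, group quotas) on the slot-style candidate pools
  foods_all <- fixture_foods()
  sets <- list(
    foods_all[c(1, 4, 5, 6, 10), ],              # tortilla frijol nopal jitomate pollo
    foods_all[c(5, 6, 7), ],                     # vegetables only
    foods_all[c(1, 4, 9, 10, 11, 5), ],          # mixed main-meal pool
    foods_all[c(4, 8, 9, 10, 11, 5, 1, 3), ],    # 8-food mixed pool
    foods_all[c(1, 4, 9, 10, 11), ],             # no vegetable filler
    foods_all[c(8, 9, 5, 6, 12, 13), ],          # snack pool: fruit/veg/dairy
    foods_all[c(1, 2, 3, 5, 7), ])               # cereal-heavy pool + 2 veg
  targets <- c(120, 150, 200, 250, 300, 400, 500, 600)
  caps <- c(25, 60)
  cons <- plan_constraints()
  for (foods in sets) {
    for (tg in targets) {
      for (cap in caps) {
        greedy <- compose_meal(foods, tg, cap, cons)
        feasible <- oracle_meal_feasible(foods, tg, cap)
        info <- sprintf("set={%s} target=%d cap=%d",
                        paste(foods$food_id, collapse = ","), tg, cap)
        if (greedy$compliant) {
          # greedy compliance implies oracle feasibility
          expect_true(feasible, info = info)
          expect_lte(greedy$totals[["cho_g"]], cap + 1e-9)
          expect_gte(greedy$totals[["kcal"]], tg * 0.95 - 1e-9)
          expect_lte(greedy$totals[["kcal"]], tg * 1.05 + 1e-9)
        } else {
          # whenever any combination works, greedy must have found one
          expect_false(feasible, info = info)
        }
      }
    }
  }
})

test_that("infeasible slots are flagged as shortfalls, never overshoot", {
  # single-food pools where the window is genuinely unreachable
  pool <- fixture_foods()[c(5, 6), ]    # two small vegetables, quota-bound
  res <- compose_meal(pool, 600, 60, plan_constraints())
  expect_false(res$compliant)
  expect_true("kcal_short" %in% res$reasons)
  expect_false(oracle_meal_feasible(pool, 600, 60))
  expect_lte(res$totals[["kcal"]], 600 * 1.05 + 1e-9)
})

test_that("full plans on the bundled database are compliant and deterministic", {
  foods <- load_foods_csv(kiosk_foods_csv())$foods
  path <- tempfile(fileext = ".sqlite")
  db <- init_db(foods, path)
  on.exit({ close_db(db); unlink(path) })
  cons <- plan_constraints(daily_kcal_target = 2000)
  plan <- compose_plan(db, cons)
  expect_s3_class(plan, "meal_plan")
  expect_true(plan$compliance$status)
  expect_gte(plan$daily[["kcal"]], 1900)
  expect_lte(plan$daily[["kcal"]], 2100)
  # slot totals sum exactly to daily totals
  expect_equal(unname(colSums(plan$slot_totals)), unname(plan$daily))
  # byte-identical JSON across repeated runs
  plan2 <- compose_plan(db, cons)
  expect_identical(render_plan(plan, "json"), render_plan(plan2, "json"))
  # compliant across the range where the per-meal CHO caps (230 g/day at
  # most) can still satisfy the realized-CHO floor of 40% of energy
  for (kcal in c(1200, 1600, 2100)) {
    p <- compose_plan(db, plan_constraints(daily_kcal_target = kcal))
    expect_true(p$compliance$status)
  }
  # above ~2300 kcal the CHO caps make the macro floor unreachable; the
  # violation must be reported, not hidden
  for (kcal in c(2400, 2800)) {
    p <- compose_plan(db, plan_constraints(daily_kcal_target = kcal))
    expect_false(p$compliance$status)
    expect_equal(p$compliance$violations, "macro_window:cho")
    expect_true(p$compliance$kcal_within_tolerance)
  }
  # vegetarian preference excludes animal protein
  veg <- compose_plan(db, cons, food_preference = "vegetarian")
  groups <- unlist(lapply(veg$slots, function(s) s$items$group))
  expect_false("animal_protein" %in% groups)
})

test_that("a database without vegetables yields a missing-group violation", {
  foods <- fixture_foods()
  foods <- foods[foods$group != "vegetable", ]
  plan <- compose_plan(foods, plan_constraints(daily_kcal_target = 1400))
  expect_false(plan$compliance$status)
  expect_true(any(grepl("missing_group:vegetable",
                        plan$compliance$violations)))
})

test_that("compliance report evaluates each rule like a hand check", {
  foods <- load_foods_csv(kiosk_foods_csv())$foods
  plan <- compose_plan(foods, plan_constraints(daily_kcal_target = 1800))
  rep <- check_compliance(plan, plan$constraints)
  # recompute every rule independently from the plan object
  expect_equal(rep$kcal_within_tolerance,
               abs(plan$daily[["kcal"]] - 1800) <= 0.05 * 1800 + 1e-9)
  hand_cho <- all(plan$slot_totals[, "cho_g"] <=
                    plan$constraints$cho_caps_g[rownames(plan$slot_totals)] + 1e-9)
  expect_equal(rep$cho_caps, hand_cho)
  groups <- unlist(lapply(plan$slots, function(s) s$items$group))
  expect_equal(rep$required_groups_covered,
               all(vapply(plan$constraints$required_groups,
                          function(alt) any(alt %in% groups), TRUE)))
  # an artificial CHO blow-out is reported against the right slot
  plan$slot_totals["lunch", "cho_g"] <- 75
  rep2 <- check_compliance(plan, plan$constraints)
  expect_true("cho_cap:lunch" %in% rep2$violations)
  expect_false(rep2$status)
})

test_that("substitution swaps the nearest equivalent and re-evaluates", {
  foods <- load_foods_csv(kiosk_foods_csv())$foods
  path <- tempfile(fileext = ".sqlite")
  db <- init_db(foods, path)
  on.exit({ close_db(db); unlink(path) })
  plan <- compose_plan(db, plan_constraints(daily_kcal_target = 2000))
  # find a slot food with an available equivalent
  sub_done <- FALSE
  for (sl in meal_slots) {
    for (id in plan$slots[[sl]]$items$food_id) {
      if (nrow(find_equivalents(db, id, 0.10)) > 0) {
        before <- plan$slots[[sl]]$items
        serv <- before$servings[before$food_id == id]
        old_kcal <- foods$kcal[foods$food_id == id]
        res <- substitute_food(db, plan, sl, id)
        expect_match(res$notice, "^substituted:")
        new_id <- sub("substituted:", "", res$notice)
        after <- res$plan$slots[[sl]]$items
        expect_false(id %in% after$food_id)
        expect_true(new_id %in% after$food_id)
        expect_equal(after$servings[after$food_id == new_id], serv)
        # kcal shift bounded by the 10% exchange tolerance
        new_kcal <- foods$kcal[foods$food_id == new_id]
        expect_lte(abs(new_kcal - old_kcal), 0.10 * old_kcal)
        sub_done <- TRUE
        break
      }
    }
    if (sub_done) break
  }
  expect_true(sub_done)
  # substituting a food that is not in the slot errors
  expect_error(substitute_food(db, plan, "breakfast", "ghost_food"), "not in slot")
})

test_that("substitution without an equivalent leaves the plan unchanged", {
  foods <- fixture_foods()
  path <- tempfile(fileext = ".sqlite")
  db <- init_db(foods, path)
  on.exit({ close_db(db); unlink(path) })
  plan <- compose_plan(db, plan_constraints(daily_kcal_target = 1400))
  # frijol is the only legume: no same-group alternative exists
  slot_with_frijol <- NULL
  for (sl in meal_slots)
    if ("frijol" %in% plan$slots[[sl]]$items$food_id) slot_with_frijol <- sl
  if (!is.null(slot_with_frijol)) {
    res <- substitute_food(db, plan, slot_with_frijol, "frijol")
    expect_equal(res$notice, "no_equivalent")
    expect_identical(render_plan(res$plan, "json"), render_plan(plan, "json"))
  } else {
    succeed("frijol not selected; nothing to substitute")
  }
})

test_that("plan rendering round-trips as JSON and structures the text", {
  foods <- load_foods_csv(kiosk_foods_csv())$foods
  plan <- compose_plan(foods, plan_constraints(daily_kcal_target = 2000))
  js <- render_plan(plan, "json")
  parsed <- parse_plan_json(js)
  expect_equal(parsed$daily$kcal, unname(plan$daily[["kcal"]]))
  expect_equal(sort(names(parsed$slots)), sort(meal_slots))
  expect_equal(parsed$compliance$status, plan$compliance$status)
  expect_equal(parsed$slots$lunch$items$food_id,
               plan$slots$lunch$items$food_id)
  txt <- render_plan(plan, "text")
  # one section per slot
  expect_equal(length(gregexpr("== ", txt)[[1]]), 5)
  expect_false(grepl("ADVISORY", txt))
  txt2 <- render_plan(plan, "text", triage_label = "REQUIRES_CONSULTATION")
  expect_match(txt2, "ADVISORY")
  expect_match(txt2, "Foods to avoid")
  expect_error(render_plan(plan, "xml"), "arg")
})
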