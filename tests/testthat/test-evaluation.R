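# Evaluation statistics: confusion counts, metric averaging, Wilson interval,
# SUS scoring, engine comparison, load harness bookkeeping.

test_that("confusion counts satisfy their identities on random predictions", {
  set.seed(14)
  for (rep in 1:5) {
    n <- 300
    truth <- sample(cohort_labels, n, replace = TRUE, prob = c(0.55, 0.3, 0.15))
    pred <- truth
    flip <- runif(n) < 0.2
    pred[flip] <- sample(cohort_labels, sum(flip), replace = TRUE)
    cc <- confusion_from_predictions(truth, pred)
    ref <- oracle_confusion(truth, pred)
    for (i in seq_len(3)) {
      expect_equal(unname(unlist(cc[i, c("tp", "fp", "fn", "support")])),
                   unname(ref[[cc$class[i]]]))
    }
    expect_equal(cc$tp + cc$fn, cc$support)
    expect_equal(sum(cc$tp) + sum(cc$fn), n)
    expect_equal(sum(cc$fp), sum(cc$fn))
  }
})

test_that("confusion edge cases behave", {
  truth <- rep(cohort_labels, 4)
  cc <- confusion_from_predictions(truth, truth)
  expect_true(all(cc$fp == 0) && all(cc$fn == 0))
  one <- confusion_from_predictions("ADEQUATE", "MINOR_ADJUSTMENT")
  expect_equal(one$fn[one$class == "ADEQUATE"], 1)
  expect_equal(one$fp[one$class == "MINOR_ADJUSTMENT"], 1)
  expect_error(confusion_from_predictions(truth, truth[-1]), "length")
  expect_error(confusion_from_predictions("ADEQUATE", "GOOD"), "class set")
})

test_that("metrics handle perfect and degenerate classifiers", {
  perfect <- confusion_counts(c(165, 90, 45), c(0, 0, 0), c(0, 0, 0),
                              c(165, 90, 45))
  m <- metrics(perfect)
  expect_true(all(m$per_class$precision == 100))
  expect_true(all(m$per_class$f1 == 100))
  expect_equal(m$micro_accuracy, 100)
  # a class never predicted: precision reported 0 with a warning flag
  degen <- confusion_counts(c(10, 5, 0), c(3, 5, 0), c(2, 3, 8), c(12, 8, 8))
  md <- metrics(degen)
  expect_equal(md$undefined_precision, "REQUIRES_CONSULTATION")
  expect_equal(md$per_class$precision[3], 0)
})

test_that("weighted recall equals micro accuracy for random confusion tables", {
  set.seed(15)
  for (rep in 1:25) {
    truth <- sample(cohort_labels, 200, replace = TRUE)
    pred <- sample(cohort_labels, 200, replace = TRUE)
    if (length(unique(truth)) < 3) next
    m <- metrics(confusion_from_predictions(truth, pred))
    expect_equal(m$weighted[["recall"]], m$micro_accuracy)
  }
})

test_that("Wilson interval matches the grid-inversion oracle", {
  cases <- list(c(59, 60), c(1, 10), c(25, 50), c(299, 300))
  for (cs in cases) {
    w <- wilson_interval(cs[1], cs[2], 0.95)
    ref <- oracle_wilson_grid(cs[1], cs[2], 0.95)
    # the grid oracle is exact to its 1e-6 step
    expect_lt(abs(w[["lower"]] - ref[["lower"]]), 2e-6)
    expect_lt(abs(w[["upper"]] - ref[["upper"]]), 2e-6)
  }
})

test_that("Wilson interval boundaries and monotonicity", {
  z <- wilson_interval(0, 20)
  expect_equal(unname(z[["lower"]]), 0)
  full <- wilson_interval(20, 20)
  expect_equal(unname(full[["upper"]]), 1)
  # monotone in successes and contains the point estimate
  prev <- c(lower = -1, upper = -1)
  for (k in 0:30) {
    w <- wilson_interval(k, 30)
    expect_gte(w[["lower"]] + 1e-12, prev[["lower"]])
    expect_gte(w[["upper"]] + 1e-12, prev[["upper"]])
    p <- k / 30
    expect_lte(w[["lower"]], p + 1e-12)
    expect_gte(w[["upper"]], p - 1e-12)
    prev <- w
  }
  expect_error(wilson_interval(5, 0), "trials")
  expect_error(wilson_interval(10, 5), "successes")
})

test_that("SUS scoring follows the odd/even rule", {
  expect_equal(sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)), 100)
  expect_equal(sus_score(rep(3, 10)), 50)
  # hand evaluation: odd (5,4,5,5,4) -> 18; even (2,1,2,1,2) -> 17; 35*2.5
  expect_equal(sus_score(c(5, 2, 4, 1, 5, 2, 5, 1, 4, 2)), 87.5)
  expect_error(sus_score(rep(3, 9)), "10")
  expect_error(sus_score(c(rep(3, 9), 6)), "1, 5")
})

test_that("SUS score is invariant to item order within parity groups", {
  set.seed(16)
  for (rep in 1:20) {
    resp <- sample(1:5, 10, replace = TRUE)
    base <- sus_score(resp)
    odd_perm <- sample(c(1, 3, 5, 7, 9))
    even_perm <- sample(c(2, 4, 6, 8, 10))
    shuffled <- resp
    shuffled[c(1, 3, 5, 7, 9)] <- resp[odd_perm]
    shuffled[c(2, 4, 6, 8, 10)] <- resp[even_perm]
    expect_equal(sus_score(shuffled), base)
  }
})

test_that("SUS summary uses the sample SD and the curved grade scale", {
  s <- summarize_sus(c(87.5, 92.5, 87.5))
  expect_equal(s$mean, 89.17)
  expect_equal(s$sd, 2.89)
  expect_equal(s$grade, "A+")
  expect_equal(summarize_sus(c(80, 90)), list(mean = 85, sd = 7.07,
                                              grade = "A+", n = 2))
  same <- summarize_sus(c(70, 70, 70))
  expect_equal(same$sd, 0)
  expect_equal(same$grade, "C")
  expect_error(summarize_sus(90), "at least 2")
})

test_that("engine comparison is consistent and reduces to zero against itself", {
  co <- small_cohort(n = 600, seed = 17, noise = 0)
  sp <- split_train_test(co$records, 0.8, seed = 17)
  fit <- triage_mlp(sp$train, mlp_spec(hidden = c(16, 16), max_epochs = 30,
                                       seed = 17))
  cmp <- compare_engines(sp$test, fit)
  # both reports computed on identical inputs
  expect_equal(sum(cmp$mlp$per_class$support),
               sum(cmp$baseline$per_class$support))
  # baseline against itself: deltas all zero
  base_counts <- confusion_from_predictions(sp$test$label,
                                            fixed_rule_baseline(sp$test))
  mb <- metrics(base_counts)
  expect_equal(unname(mb$macro - cmp$baseline$macro), c(0, 0, 0))
})

test_that("the load harness records per-request latencies and statistics", {
  res <- load_test(function() Sys.sleep(0.001), concurrency_levels = c(1, 2),
                   requests_per_level = 6, seed = 1)
  expect_equal(nrow(res), 2)
  expect_equal(res$concurrency, c(1, 2))
  lat <- attr(res, "latencies")
  expect_equal(lengths(lat), c(`1` = 6, `2` = 6))
  # statistics derive from the recorded samples
  expect_equal(res$mean_s[1], mean(lat[["1"]]))
  expect_equal(res$sd_s[1], sd(lat[["1"]]))
  expect_equal(res$failures, c(0, 0))
  # four standard levels mirror the evaluation design
  res4 <- load_test(function() NULL, concurrency_levels = c(5, 10, 20, 50),
                    requests_per_level = 4, seed = 1)
  expect_equal(nrow(res4), 4)
  # total failure is an error, not silence
  expect_error(load_test(function() stop("boom"), 1, 3), "failed")
})
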