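# Technical-evaluation suite: confusion counts, per-class and averaged
# classification metrics, Wilson score interval, SUS scoring and summary,
# engine comparison, concurrent-load harness.

#' Confusion counts from label sequences
#'
#' Tallies per-class true positives, false positives, false negatives and
#' support for the three triage classes.
#'
#' @param true_labels,predicted_labels equal-length character vectors over
#'   the triage classes.
#' @return data.frame of class `"confusion_counts"`: one row per class with
#'   `class`, `tp`, `fp`, `fn`, `support`.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels) {
  if (length(true_labels) != length(predicted_labels))
    fail("label sequences must have equal length")
  bad <- setdiff(unique(c(true_labels, predicted_labels)), cohort_labels)
  if (length(bad)) fail("label(s) outside the class set: ",
                        paste(bad, collapse = ", "))
  out <- data.frame(class = cohort_labels,
                    tp = NA_integer_, fp = NA_integer_, fn = NA_integer_,
                    support = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(cohort_labels)) {
    cl <- cohort_labels[i]
    out$tp[i] <- sum(true_labels == cl & predicted_labels == cl)
    out$fp[i] <- sum(true_labels != cl & predicted_labels == cl)
    out$fn[i] <- sum(true_labels == cl & predicted_labels != cl)
    out$support[i] <- sum(true_labels == cl)
  }
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Build confusion counts from printed per-class tallies
#'
#' @param tp,fp,fn,support integer vectors, one entry per class in the order
#'   adequate / minor adjustment / requires consultation.
#' @return `"confusion_counts"` data.frame.
#' @export
confusion_counts <- function(tp, fp, fn, support) {
  stopifnot(length(tp) == 3, length(fp) == 3, length(fn) == 3,
            length(support) == 3)
  if (any(tp + fn != support)) fail("tp + fn must equal support per class")
  out <- data.frame(class = cohort_labels, tp = as.integer(tp),
                    fp = as.integer(fp), fn = as.integer(fn),
                    support = as.integer(support), stringsAsFactors = FALSE)
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Classification metrics from confusion counts
#'
#' Per-class precision `tp/(tp+fp)`, recall `tp/support` and F1 (harmonic
#' mean), plus macro (unweighted class mean), weighted (support-weighted
#' mean) and micro (pooled accuracy) aggregates. All values are percentages
#' rounded half-up to one decimal; the underlying unrounded proportions feed
#' the aggregate averages before their own rounding. A class with
#' `tp + fp = 0` has precision reported as 0 with a warning flag.
#'
#' @param counts a `"confusion_counts"` data.frame with positive support.
#' @return list of class `"metrics_report"`: `per_class` (data.frame),
#'   `macro`, `weighted` (each precision/recall/f1), `micro_accuracy`,
#'   `undefined_precision` (classes with no positive predictions).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (any(counts$support <= 0)) fail("every class needs support > 0")
  denom_p <- counts$tp + counts$fp
  undefined <- counts$class[denom_p == 0]
  precision <- ifelse(denom_p == 0, 0, counts$tp / pmax(denom_p, 1))
  recall <- counts$tp / counts$support
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  w <- counts$support / sum(counts$support)
  micro <- sum(counts$tp) / sum(counts$support)
  pc <- data.frame(class = counts$class,
                   precision = round_half_up(100 * precision, 1),
                   recall = round_half_up(100 * recall, 1),
                   f1 = round_half_up(100 * f1, 1),
                   support = counts$support, stringsAsFactors = FALSE)
  agg <- function(x, weights = NULL) {
    v <- if (is.null(weights)) mean(x) else sum(weights * x)
    round_half_up(100 * v, 1)
  }
  structure(list(
    per_class = pc,
    macro = c(precision = agg(precision), recall = agg(recall), f1 = agg(f1)),
    weighted = c(precision = agg(precision, w), recall = agg(recall, w),
                 f1 = agg(f1, w)),
    micro_accuracy = round_half_up(100 * micro, 1),
    undefined_precision = undefined),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Macro    : precision %.1f, recall %.1f, F1 %.1f\n",
              x$macro[["precision"]], x$macro[["recall"]], x$macro[["f1"]]))
  cat(sprintf("Weighted : precision %.1f, recall %.1f, F1 %.1f\n",
              x$weighted[["precision"]], x$weighted[["recall"]],
              x$weighted[["f1"]]))
  cat(sprintf("Micro accuracy: %.1f\n", x$micro_accuracy))
  if (length(x$undefined_precision))
    cat("Warning: precision undefined (reported 0) for:",
        paste(x$undefined_precision, collapse = ", "), "\n")
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' Score-test inversion interval; better small-sample behaviour than the
#' Wald interval and never escapes \[0, 1\].
#'
#' @param successes,trials non-negative counts, `successes <= trials`,
#'   `trials > 0`.
#' @param confidence confidence level in (0, 1), default 0.95.
#' @return named numeric vector `c(lower, upper)` as proportions; the
#'   `"percent"` attribute carries both bounds in percent rounded to one
#'   decimal.
#' @examples
#' wilson_interval(59, 60)  # 0.911, 0.997
#' @export
wilson_interval <- function(successes, trials, confidence = 0.95) {
  if (!is_number(successes) || !is_number(trials) || trials <= 0 ||
      successes < 0 || successes > trials)
    fail("need 0 <= successes <= trials, trials > 0")
  if (!is_number(confidence) || confidence <= 0 || confidence >= 1)
    fail("confidence must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- successes / trials
  n <- trials
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  out <- c(lower = max(0, center - half), upper = min(1, center + half))
  attr(out, "percent") <- round_half_up(100 * out, 1)
  out
}

#' System Usability Scale score for one respondent
#'
#' Standard SUS scoring of the ten 5-point Likert items: odd items contribute
#' `response - 1`, even items `5 - response`, and the sum is scaled by 2.5
#' onto 0-100.
#'
#' @param item_responses integer vector of exactly ten values in \[1, 5\].
#' @return SUS score in \[0, 100\].
#' @examples
#' sus_score(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1))  # 100
#' @export
sus_score <- function(item_responses) {
  if (length(item_responses) != 10) fail("SUS needs exactly 10 item responses")
  if (any(!is.finite(item_responses)) || any(item_responses < 1) ||
      any(item_responses > 5) || any(item_responses != round(item_responses)))
    fail("SUS responses must be integers in [1, 5]")
  odd <- item_responses[c(1, 3, 5, 7, 9)]
  even <- item_responses[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

# Sauro-Lewis curved grading scale for SUS scores.
.sus_grade <- function(score) {
  bands <- data.frame(
    lo = c(84.1, 80.8, 78.9, 77.2, 74.1, 72.6, 71.1, 65.0, 62.7, 51.7, -Inf),
    grade = c("A+", "A", "A-", "B+", "B", "B-", "C+", "C", "C-", "D", "F"))
  bands$grade[which(score >= bands$lo)[1]]
}

#' Summarize per-evaluator SUS scores
#'
#' @param scores numeric vector (length >= 2) of SUS percentages in
#'   \[0, 100\].
#' @return list: `mean` and `sd` (sample SD, n-1 denominator; both rounded
#'   to 2 decimals), `grade` (Sauro-Lewis curved letter grade of the mean),
#'   `n`.
#' @examples
#' summarize_sus(c(87.5, 92.5, 87.5))  # mean 89.17, SD 2.89, grade A+
#' @export
summarize_sus <- function(scores) {
  if (length(scores) < 2) fail("need at least 2 SUS scores")
  if (any(scores < 0 | scores > 100)) fail("SUS scores must be in [0, 100]")
  m <- mean(scores)
  list(mean = round_half_up(m, 2),
       sd = round_half_up(stats::sd(scores), 2),
       grade = .sus_grade(m),
       n = length(scores))
}

#' Compare the MLP engine against the fixed-rule baseline
#'
#' Runs both engines on the same test records and reports paired metrics
#' plus per-metric deltas (MLP minus baseline).
#'
#' @param test_records labelled cohort data.frame.
#' @param model a fitted [triage_mlp()].
#' @return list of class `"engine_comparison"`: `mlp`, `baseline` (each a
#'   `"metrics_report"`), `delta` (macro/weighted/micro differences in
#'   percentage points).
#' @export
compare_engines <- function(test_records, model) {
  stopifnot(inherits(model, "triage_mlp"))
  truth <- test_records$label
  pred_mlp <- predict(model, test_records, type = "class")
  pred_base <- fixed_rule_baseline(test_records)
  m_mlp <- metrics(confusion_from_predictions(truth, pred_mlp))
  m_base <- metrics(confusion_from_predictions(truth, pred_base))
  delta <- list(macro = m_mlp$macro - m_base$macro,
                weighted = m_mlp$weighted - m_base$weighted,
                micro_accuracy = m_mlp$micro_accuracy - m_base$micro_accuracy)
  structure(list(mlp = m_mlp, baseline = m_base, delta = delta),
            class = "engine_comparison")
}

#' @export
print.engine_comparison <- function(x, ...) {
  cat(sprintf("MLP      macro-F1 %.1f, accuracy %.1f\n",
              x$mlp$macro[["f1"]], x$mlp$micro_accuracy))
  cat(sprintf("Baseline macro-F1 %.1f, accuracy %.1f\n",
              x$baseline$macro[["f1"]], x$baseline$micro_accuracy))
  cat(sprintf("Delta    macro-F1 %+.1f, accuracy %+.1f\n",
              x$delta$macro[["f1"]], x$delta$micro_accuracy))
  invisible(x)
}

#' Concurrent-load harness
#'
#' Issues batches of in-process recommendation requests (each request runs
#' `request_fn`) at the given concurrency levels using forked workers, and
#' records per-request wall-clock latency. CPU and memory are sampled
#' best-effort from `/proc`; all timings are machine-dependent and intended
#' for capacity exploration, not verification.
#'
#' @param request_fn zero-argument function executing one full request.
#' @param concurrency_levels integer vector of simultaneous users
#'   (default 5, 10, 20, 50).
#' @param requests_per_level requests issued at each level.
#' @param seed integer seed (forwarded to workers for reproducible request
#'   generation inside `request_fn` closures that consume randomness).
#' @return data.frame of class `"load_test_result"`: one row per level with
#'   `concurrency`, `requests`, `failures`, `mean_s`, `sd_s` (sample SD),
#'   `max_s`, `cpu_pct` (best effort, may be `NA`), plus a `latencies`
#'   attribute (list of per-level latency vectors).
#' @export
load_test <- function(request_fn, concurrency_levels = c(5, 10, 20, 50),
                      requests_per_level = 20, seed = 42) {
  stopifnot(is.function(request_fn), all(concurrency_levels >= 1),
            requests_per_level >= 1)
  rows <- list()
  lat_store <- list()
  for (level in concurrency_levels) {
    one <- function(i) {
      t0 <- proc.time()[["elapsed"]]
      ok <- tryCatch({ request_fn(); TRUE }, error = function(e) FALSE)
      c(latency = proc.time()[["elapsed"]] - t0, ok = as.numeric(ok))
    }
    res <- parallel::mclapply(seq_len(requests_per_level), one,
                              mc.cores = min(level, requests_per_level),
                              mc.set.seed = TRUE, mc.preschedule = FALSE)
    mat <- do.call(rbind, res)
    ok <- mat[, "ok"] == 1
    lat <- mat[ok, "latency"]
    if (!length(lat))
      fail("all requests failed at concurrency ", level)
    cpu <- tryCatch({
      stat <- readLines("/proc/loadavg", warn = FALSE)
      as.numeric(strsplit(stat, " ")[[1]][1]) * 100 /
        parallel::detectCores()
    }, error = function(e) NA_real_)
    rows[[as.character(level)]] <- data.frame(
      concurrency = level, requests = requests_per_level,
      failures = sum(!ok), mean_s = mean(lat),
      sd_s = if (length(lat) > 1) stats::sd(lat) else 0,
      max_s = max(lat), cpu_pct = cpu)
    lat_store[[as.character(level)]] <- unname(lat)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "latencies") <- lat_store
  class(out) <- c("load_test_result", "data.frame")
  out
}
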