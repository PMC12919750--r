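# Plan-triage classifier: feature encoding, the triage_mlp() fitting
# function and its S3 methods, and the coarse fixed-rule baseline.

# Ordinal codes in [0, 1] for each categorical variable. Orderings are
# clinically meaningful (severity / intensity); food groups follow the
# food_groups order, which places the two discouraged groups highest.
.categorical_codes <- local({
  codes <- list(
    sex = c(female = 0, male = 1),
    diabetes_type = c(type2 = 0, prediabetes = 0.5, type1 = 1),
    glycemic_control = c(good = 0, fair = 0.5, poor = 1),
    activity_level = c(sedentary = 0, light = 0.25, moderate = 0.5,
                       active = 0.75, very_active = 1),
    dietary_adherence = c(low = 0, medium = 0.5, high = 1),
    food_preference = c(omnivore = 0, low_meat = 0.5, vegetarian = 1)
  )
  codes$predominant_food_group <- stats::setNames(
    seq(0, 1, length.out = length(food_groups)), food_groups)
  codes
})

.continuous_features <- c("age_years", "height_m", "weight_kg", "bmi",
                          "kcal_need", "cho_pct", "protein_pct", "fat_pct")

#' Encode cohort records as a 15-column feature matrix
#'
#' Continuous variables are standardized to zero mean / unit variance using
#' training-set statistics (a constant column falls back to a unit divisor
#' and encodes as zeros); categorical variables are mapped to fixed ordinal
#' scores in \[0, 1\] (see the package vignette for the per-variable codes).
#' One value per variable keeps the input dimension at exactly 15.
#'
#' @param records cohort data.frame carrying the 15 feature columns.
#' @param stats optional encoder statistics from a previous call (inference
#'   mode: applied unchanged; unseen category values are an error). When
#'   `NULL`, statistics are computed from `records` (training mode).
#' @return list with `x` (numeric matrix, n x 15) and `stats` (per-feature
#'   means/SDs and category maps).
#' @export
encode_features <- function(records, stats = NULL) {
  missing_cols <- setdiff(cohort_feature_names, names(records))
  if (length(missing_cols))
    fail("records missing feature column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(stats)) {
    mu <- vapply(.continuous_features, function(v) mean(records[[v]]), 0)
    sd <- vapply(.continuous_features, function(v) stats::sd(records[[v]]), 0)
    sd[!is.finite(sd) | sd < 1e-12] <- 1  # constant column -> unit divisor
    stats <- list(mean = mu, sd = sd, codes = .categorical_codes)
  }
  x <- matrix(0, nrow(records), length(cohort_feature_names),
              dimnames = list(NULL, cohort_feature_names))
  for (v in cohort_feature_names) {
    if (v %in% .continuous_features) {
      x[, v] <- (records[[v]] - stats$mean[[v]]) / stats$sd[[v]]
    } else {
      map <- stats$codes[[v]]
      vals <- as.character(records[[v]])
      unseen <- setdiff(unique(vals), names(map))
      if (length(unseen))
        fail(sprintf("unseen category in '%s': %s", v,
                     paste(unseen, collapse = ", ")))
      x[, v] <- map[vals]
    }
  }
  if (!all(is.finite(x))) fail("non-finite encoded feature values")
  list(x = x, stats = stats)
}

#' Fit the MLP plan-triage classifier
#'
#' Trains the three-class triage network on labelled cohort records. An
#' internal validation split (stratified by label) drives early stopping on
#' validation loss; the weights from the best validation epoch are restored.
#'
#' @param data cohort data.frame with the 15 feature columns and a `label`
#'   column over `ADEQUATE` / `MINOR_ADJUSTMENT` / `REQUIRES_CONSULTATION`.
#' @param spec an [mlp_spec()].
#' @param validation_fraction fraction of `data` held out for early stopping
#'   (default 0.2).
#' @return Object of class `"triage_mlp"`: layers (weights), training
#'   history, encoder statistics, spec. Methods: `print`, `summary`,
#'   `predict`, `plot`, `coef`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_target = 600, seed = 1))
#' fit <- triage_mlp(cohort$records, mlp_spec(hidden = c(16, 16), max_epochs = 20))
#' predict(fit, cohort$records[1:5, ])
#' }
#' @export
triage_mlp <- function(data, spec = mlp_spec(), validation_fraction = 0.2) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (is.null(data$label) || nrow(data) == 0) fail("empty training set")
  if (length(unique(data$label)) < 3)
    fail("all three triage classes must be present in the training labels")
  if (!is_number(validation_fraction) || validation_fraction < 0 ||
      validation_fraction >= 1)
    fail("validation_fraction must be in [0, 1)")
  fitted <- with_seed(spec$seed, {
    if (validation_fraction > 0) {
      sp <- split_train_test(data, fraction = 1 - validation_fraction,
                             seed = sample.int(.Machine$integer.max, 1))
      tr <- sp$train; va <- sp$test
    } else {
      tr <- data; va <- NULL
    }
    enc <- encode_features(tr)
    y_tr <- match(tr$label, cohort_labels)
    if (!is.null(va)) {
      x_va <- encode_features(va, enc$stats)$x
      y_va <- match(va$label, cohort_labels)
    } else {
      x_va <- NULL; y_va <- NULL
    }
    fit <- .mlp_fit(enc$x, y_tr, length(cohort_labels), spec, x_va, y_va)
    fit$stats <- enc$stats
    fit$n_train <- nrow(tr)
    fit$n_val <- NROW(va)
    fit
  })
  structure(list(layers = fitted$layers, history = fitted$history,
                 encoder = fitted$stats, spec = spec,
                 best_epoch = fitted$best_epoch,
                 stopped_epoch = fitted$stopped_epoch,
                 n_train = fitted$n_train, n_val = fitted$n_val,
                 classes = cohort_labels),
            class = "triage_mlp")
}

#' Predict triage classes or probabilities
#'
#' @param object a fitted [triage_mlp()].
#' @param newdata cohort data.frame with the 15 feature columns.
#' @param type `"class"` for labels (argmax with ties broken toward the more
#'   conservative class: consultation over minor adjustment over adequate) or
#'   `"prob"` for the probability matrix.
#' @param ... unused.
#' @return character vector of labels, or an n x 3 probability matrix.
#' @export
predict.triage_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- encode_features(newdata, object$encoder)$x
  probs <- .mlp_forward(object$layers, x, object$spec, training = FALSE)$probs
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  apply(probs, 1, function(p) {
    top <- which(p >= max(p) - 1e-12)
    object$classes[max(top)]  # classes ordered least -> most conservative
  })
}

#' Classify one record with its probability triple
#'
#' @param model a fitted [triage_mlp()].
#' @param record single-row cohort data.frame.
#' @return list with `label` and `probs` (named probability triple).
#' @export
predict_class <- function(model, record) {
  stopifnot(inherits(model, "triage_mlp"))
  probs <- predict(model, record, type = "prob")[1, ]
  top <- which(probs >= max(probs) - 1e-12)
  list(label = model$classes[max(top)], probs = probs)
}

#' Fixed-rule triage baseline
#'
#' The comparison engine without personalization: poor glycemic control maps
#' to `REQUIRES_CONSULTATION`; fair control or BMI outside \[18.5, 30\] maps
#' to `MINOR_ADJUSTMENT`; everything else to `ADEQUATE`. Uses only glycemic
#' control and BMI.
#'
#' @param records cohort data.frame with `glycemic_control` and `bmi`.
#' @return character vector of labels.
#' @export
fixed_rule_baseline <- function(records) {
  ifelse(records$glycemic_control == "poor", "REQUIRES_CONSULTATION",
    ifelse(records$glycemic_control == "fair" |
             records$bmi < 18.5 | records$bmi > 30,
           "MINOR_ADJUSTMENT", "ADEQUATE"))
}

#' @export
print.triage_mlp <- function(x, ...) {
  dims <- c(nrow(x$layers[[1]]$W), vapply(x$layers, function(l) ncol(l$W), 0L))
  cat(sprintf("<triage_mlp> %s network, trained on %d records (val %d)\n",
              paste(dims, collapse = "-"), x$n_train, x$n_val))
  cat(sprintf("  stopped at epoch %d; best validation epoch %d (loss %.4f, acc %.3f)\n",
              x$stopped_epoch, x$best_epoch,
              x$history$val_loss[x$best_epoch],
              x$history$val_acc[x$best_epoch]))
  invisible(x)
}

#' @export
summary.triage_mlp <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$layers, function(ly)
    sum(vapply(intersect(names(ly), c("W", "b", "gamma", "beta")),
               function(p) length(ly[[p]]), 0)), 0))
  cat(sprintf("  parameters: %d; dropout %.2f, L2 %.1e, lr %.4g, batch %d\n",
              n_par, object$spec$dropout_rate, object$spec$l2_lambda,
              object$spec$learning_rate, object$spec$batch_size))
  invisible(object)
}

#' @export
coef.triage_mlp <- function(object, ...) {
  lapply(object$layers, function(ly)
    ly[intersect(names(ly), c("W", "b", "gamma", "beta"))])
}

#' @export
plot.triage_mlp <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss",
                    main = "triage_mlp training history", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
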