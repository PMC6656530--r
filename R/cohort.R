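#' Perseveration rate
#'
#' Fraction of responses that repeat an earlier response in the same list.
#' For a corpus, the mean over its lists.
#'
#' @param x a [fluency_list()], [fluency_corpus()], or character vector.
#' @return ratio in `[0, 1]`.
#' @export
perseveration_rate <- function(x) {
  if (inherits(x, "fluency_corpus"))
    return(mean(vapply(x$lists, perseveration_rate, numeric(1))))
  items <- if (inherits(x, "fluency_list")) x$items else as.character(x)
  if (length(items) < 1L) stop("empty list")
  sum(duplicated(items)) / length(items)
}

#' Two-group comparison with a variance-gated Welch correction
#'
#' An F test of variance equality at `var_alpha` (two-sided) decides
#' between the pooled-variance t test and the Welch two-sample t test; the
#' branch used is reported.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param var_alpha significance level of the variance gate.
#' @return list: `statistic`, `df`, `p_value`, `welch` (logical),
#'   `var_test_p`, `mean_x`, `mean_y`.
#' @export
group_ttest <- function(x, y, var_alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (sd(x) == 0 && sd(y) == 0)
    stop("zero variance in both groups; the comparison is degenerate")
  vt <- var.test(x, y)
  welch <- is.finite(vt$p.value) && vt$p.value < var_alpha
  tt <- t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, welch = welch, var_test_p = vt$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

# internal: build outcome ~ factors formula
factor_formula <- function(outcome, factors) {
  as.formula(paste(outcome, "~",
                   if (length(factors)) paste(factors, collapse = " + ") else "1"))
}

# internal: 0/1 outcome column for the positive class
binary_outcome <- function(table, outcome, positive) {
  y <- as.integer(as.character(table[[outcome]]) == positive)
  if (length(unique(y)) < 2L) stop("both diagnosis classes must be present")
  y
}

#' Logistic regression of diagnosis on cohort factors
#'
#' Maximum-likelihood binomial fit with intercept and main effects only
#' (no interactions). Perfect or quasi-perfect separation is detected via
#' the usual fitted-probability warning and surfaced in the result rather
#' than silently ignored.
#'
#' @param table cohort data frame; one row per participant network.
#' @param factors column names used as predictors.
#' @param outcome name of the diagnosis column.
#' @param positive level treated as the positive class (default `"PAD"`).
#' @return object of class `model_fit`: `model` (the glm), `factors`,
#'   `coefficients`, `z_values`, `p_values`, `aic`, `null_deviance`,
#'   `residual_deviance`, `separation`.
#' @export
fit_logistic <- function(table, factors, outcome = "diagnosis",
                         positive = "PAD") {
  if (any(!factors %in% names(table)))
    stop("unknown factor column(s): ",
         paste(setdiff(factors, names(table)), collapse = ", "))
  dat <- table[, factors, drop = FALSE]
  if (anyNA(dat)) stop("missing values among the chosen factors")
  dat$.y <- binary_outcome(table, outcome, positive)
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(factor_formula(".y", factors), family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  eps <- 1e-8
  if (any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps))
    separation <- TRUE
  if (separation)
    warning("possible separation: fitted probabilities numerically 0 or 1")
  sm <- summary(fit)$coefficients
  structure(list(model = fit, factors = factors,
                 coefficients = coef(fit),
                 z_values = sm[, "z value"], p_values = sm[, "Pr(>|z|)"],
                 aic = fit$aic, null_deviance = fit$null.deviance,
                 residual_deviance = fit$deviance,
                 separation = separation),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit: %d factors, AIC=%.2f, residual deviance=%.2f%s>\n",
              length(x$factors), x$aic, x$residual_deviance,
              if (x$separation) ", SEPARATION" else ""))
  print(round(cbind(coef = x$coefficients, z = x$z_values, p = x$p_values), 4))
  invisible(x)
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starting from the model on `start_factors`, repeatedly evaluates all
#' single-factor removals and single-factor additions from
#' `candidate_factors` and applies the best AIC-lowering move until none
#' remains (via [stats::step()]). Deterministic given the table.
#'
#' @inheritParams fit_logistic
#' @param start_factors factors of the starting model (e.g., the maximal
#'   model).
#' @param candidate_factors the full candidate pool (must contain
#'   `start_factors`).
#' @return a `model_fit` for the selected model.
#' @export
stepwise_aic <- function(table, start_factors, candidate_factors,
                         outcome = "diagnosis", positive = "PAD") {
  if (!all(start_factors %in% candidate_factors))
    stop("candidate_factors must contain start_factors")
  dat <- table[, candidate_factors, drop = FALSE]
  if (anyNA(dat)) stop("missing values among the candidate factors")
  dat$.y <- binary_outcome(table, outcome, positive)
  # anchor formula environments here so step()'s add1/drop1 refits see `dat`
  fml <- factor_formula(".y", start_factors)
  lower <- factor_formula(".y", character(0))
  upper <- factor_formula(".y", candidate_factors)
  environment(fml) <- environment(lower) <- environment(upper) <- environment()
  start <- suppressWarnings(glm(fml, family = binomial(), data = dat))
  scope <- list(lower = lower, upper = upper)
  sel <- suppressWarnings(step(start, scope = scope, direction = "both",
                               trace = 0))
  chosen <- attr(sel$terms, "term.labels")
  fit_logistic(table, chosen, outcome = outcome, positive = positive)
}

#' Summary statistics of averaged confusion counts
#'
#' @param hits,misses,false_alarms,correct_rejections (possibly fractional)
#'   confusion counts, e.g. averaged over cross-validation repetitions.
#'   `hits` may also be a length-4 vector of all four counts in the above
#'   order.
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`
#'   (accuracy as a proportion; precision is `NA` with a warning when
#'   `hits + false_alarms = 0`).
#' @export
confusion_summary <- function(hits, misses = NULL, false_alarms = NULL,
                              correct_rejections = NULL) {
  if (length(hits) == 4L && is.null(misses)) {
    misses <- hits[2]; false_alarms <- hits[3]
    correct_rejections <- hits[4]; hits <- hits[1]
  }
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0) || sum(counts) <= 0) stop("invalid confusion counts")
  accuracy <- (hits + correct_rejections) / sum(counts)
  precision <- if (hits + false_alarms > 0) hits / (hits + false_alarms) else {
    warning("no positive predictions; precision undefined"); NA_real_
  }
  recall <- if (hits + misses > 0) hits / (hits + misses) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  c(accuracy = unname(accuracy), precision = unname(precision),
    recall = unname(recall), f1 = unname(f1))
}

#' Stratified split-half cross-validation
#'
#' Per repetition: the rows are split into halves preserving the class
#' ratio (each class is halved separately), the model is fitted on the
#' training half and predicts the held-out half at probability threshold
#' 0.5; hits / misses / false alarms / correct rejections are accumulated
#' and finally averaged over repetitions. Repetitions whose training half
#' contains a single class are skipped and counted.
#'
#' @inheritParams fit_logistic
#' @param n_reps number of split-half repetitions (default 5000).
#' @param seed RNG seed.
#' @param threshold classification threshold on the predicted probability.
#' @return object of class `cv_result`: `counts` (averaged hits, misses,
#'   false_alarms, correct_rejections), `accuracy`, `f1`, `precision`,
#'   `recall`, `n_reps`, `n_skipped`.
#' @export
split_half_cv <- function(table, factors, outcome = "diagnosis",
                          positive = "PAD", n_reps = 5000, seed = NULL,
                          threshold = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  dat <- table[, factors, drop = FALSE]
  if (anyNA(dat)) stop("missing values among the chosen factors")
  dat$.y <- binary_outcome(table, outcome, positive)
  fml <- factor_formula(".y", factors)
  pos_idx <- which(dat$.y == 1L)
  neg_idx <- which(dat$.y == 0L)
  totals <- c(hits = 0, misses = 0, false_alarms = 0, correct_rejections = 0)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    tr <- c(sample(pos_idx, floor(length(pos_idx) / 2)),
            sample(neg_idx, floor(length(neg_idx) / 2)))
    te <- setdiff(seq_len(nrow(dat)), tr)
    if (length(unique(dat$.y[tr])) < 2L) { skipped <- skipped + 1L; next }
    fit <- suppressWarnings(glm(fml, family = binomial(),
                                data = dat[tr, , drop = FALSE]))
    pr <- suppressWarnings(
      predict(fit, newdata = dat[te, , drop = FALSE], type = "response"))
    pred <- as.integer(pr > threshold)
    truth <- dat$.y[te]
    totals <- totals + c(sum(pred == 1 & truth == 1),
                         sum(pred == 0 & truth == 1),
                         sum(pred == 1 & truth == 0),
                         sum(pred == 0 & truth == 0))
  }
  used <- n_reps - skipped
  if (used == 0L) stop("every repetition was skipped")
  counts <- totals / used
  s <- confusion_summary(counts[1], counts[2], counts[3], counts[4])
  structure(list(counts = counts, accuracy = s[["accuracy"]],
                 f1 = s[["f1"]], precision = s[["precision"]],
                 recall = s[["recall"]], n_reps = n_reps,
                 n_skipped = skipped),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result: %d reps (%d skipped), accuracy=%.3f, F1=%.3f>\n  counts: %s\n",
    x$n_reps, x$n_skipped, x$accuracy, x$f1,
    paste(sprintf("%s=%.2f", names(x$counts), x$counts), collapse = ", ")))
  invisible(x)
}

#' Assemble one cohort-table row for a participant
#'
#' Combines corpus summaries, the estimated network's measures, the fitted
#' emission probability and (optionally) delta metrics into the row format
#' consumed by [fit_logistic()] and friends.
#'
#' @param corpus the participant's [fluency_corpus()].
#' @param fit the participant's `estimation_result`.
#' @param measures one-row data frame from [compute_measures()]; computed
#'   from `fit$network` when NULL.
#' @param deltas named vector from [delta_measures()], or NULL.
#' @param diagnosis,education metadata columns.
#' @param smallworld optional small-world coefficient.
#' @return one-row data frame.
#' @export
participant_row <- function(corpus, fit, measures = NULL, deltas = NULL,
                            diagnosis = NA_character_, education = NA_real_,
                            smallworld = NA_real_) {
  if (is.null(measures)) measures <- compute_measures(fit$network)
  row <- data.frame(participant_id = corpus$participant_id,
                    diagnosis = diagnosis,
                    n_responses = mean_list_length(corpus),
                    perseveration = perseveration_rate(corpus),
                    education = education,
                    stringsAsFactors = FALSE)
  row <- cbind(row, measures)
  row$smallworld <- smallworld
  row$p_emit <- fit$p_emit
  if (!is.null(deltas)) row <- cbind(row, as.data.frame(as.list(deltas)))
  row
}
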