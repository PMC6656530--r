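test_that("perseveration rate counts within-list repeats", {
  expect_equal(perseveration_rate(c("dog", "cat", "hamster", "lion")), 0)
  expect_equal(perseveration_rate(c("dog", "cat", "dog", "cat")), 0.5)
  expect_equal(perseveration_rate(c("dog", "cat", "hamster", "cat", "lion")), 0.2)
  cp <- toy_corpus(list(c("dog", "cat", "dog", "cat"), c("a", "b")))
  expect_equal(perseveration_rate(cp), 0.25)
})

test_that("the t test is variance-gated and matches a hand-computed Welch statistic", {
  x <- c(1, 2, 3, 4, 5)
  r <- group_ttest(x, x)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$welch)
  # hand-computed Welch comparison
  x <- c(12.1, 14.3, 11.8, 13.9, 12.6)
  y <- c(9.5, 21.2, 15.8, 6.1, 24.9, 18.0)
  vx <- sum((x - mean(x))^2) / 4; vy <- sum((y - mean(y))^2) / 5
  tw <- (mean(x) - mean(y)) / sqrt(vx / 5 + vy / 6)
  dfw <- (vx / 5 + vy / 6)^2 / ((vx / 5)^2 / 4 + (vy / 6)^2 / 5)
  r2 <- group_ttest(x, y)
  expect_true(r2$welch)  # variances differ by the F gate
  expect_equal(r2$statistic, tw, tolerance = 1e-12)
  expect_equal(r2$df, dfw, tolerance = 1e-12)
  expect_error(group_ttest(c(1, 1), c(1, 1)), "zero variance")
})

test_that("the F gate picks the pooled branch about 95% of the time under equal variances", {
  set.seed(1234)
  pooled <- mean(replicate(300, {
    !group_ttest(rnorm(50), rnorm(50))$welch
  }))
  expect_gt(pooled, 0.88)
  expect_lt(pooled, 0.995)
})

make_cohort_df <- function(n = 60, effect = 2, seed = 1) {
  set.seed(seed)
  diag <- rep(c("NC", "PAD"), each = n / 2)
  data.frame(diagnosis = diag,
             strong = rnorm(n) + effect * (diag == "PAD"),
             strong2 = rnorm(n) + effect * (diag == "PAD"),
             noise = rnorm(n))
}

test_that("logistic fits report per-factor tests and flag separation", {
  tab <- make_cohort_df(effect = 1.5)
  fit <- fit_logistic(tab, c("strong", "noise"))
  expect_s3_class(fit, "model_fit")
  expect_gt(fit$coefficients[["strong"]], 0)
  expect_lt(fit$p_values[["strong"]], 0.01)
  expect_equal(fit$aic, fit$residual_deviance + 2 * 3)
  expect_false(fit$separation)
  tab$leak <- as.integer(tab$diagnosis == "PAD")
  expect_warning(fit_logistic(tab, "leak"), "separation")
})

test_that("a pure-noise factor is significant at about the nominal rate", {
  set.seed(77)
  hits <- mean(replicate(200, {
    tab <- data.frame(diagnosis = rep(c("NC", "PAD"), each = 100),
                      noise = rnorm(200))
    suppressWarnings(fit_logistic(tab, "noise")$p_values[["noise"]]) < 0.05
  }))
  expect_gt(hits, 0.005)
  expect_lt(hits, 0.12)
})

test_that("stepwise AIC selection removes useless factors and never raises AIC", {
  tab <- make_cohort_df(n = 80, effect = 2, seed = 3)
  full <- c("strong", "strong2", "noise")
  start_fit <- suppressWarnings(fit_logistic(tab, full))
  sel <- suppressWarnings(stepwise_aic(tab, full, full))
  expect_lte(sel$aic, start_fit$aic)
  expect_false("noise" %in% sel$factors)
  # a start that is already optimal is a fixed point
  again <- suppressWarnings(stepwise_aic(tab, sel$factors, full))
  expect_setequal(again$factors, sel$factors)
})

test_that("confusion summaries follow the standard formulas", {
  s <- confusion_summary(10, 0, 0, 10)
  expect_equal(s[["accuracy"]], 1)
  expect_equal(s[["f1"]], 1)
  s2 <- confusion_summary(c(30, 10, 5, 55))
  expect_equal(s2[["accuracy"]], 85 / 100)
  expect_equal(s2[["precision"]], 30 / 35)
  expect_equal(s2[["recall"]], 30 / 40)
  expect_equal(s2[["f1"]], 2 * (30 / 35) * (30 / 40) / ((30 / 35) + (30 / 40)))
  expect_warning(confusion_summary(0, 5, 0, 10), "precision")
  expect_error(confusion_summary(-1, 0, 0, 1), "invalid")
})

test_that("stratified split-half cross-validation separates what is separable", {
  tab <- make_cohort_df(n = 60, effect = 6, seed = 5)
  cv <- split_half_cv(tab, "strong", n_reps = 50, seed = 1)
  expect_gt(cv$accuracy, 0.95)
  expect_gt(cv$f1, 0.9)
  expect_equal(sum(cv$counts), 30)  # held-out half of 60 rows
  # label permutation drives accuracy to the majority-class rate
  set.seed(2)
  tab2 <- make_cohort_df(n = 60, effect = 6, seed = 5)
  tab2$diagnosis <- sample(rep(c("NC", "PAD"), c(40, 20)))
  cv2 <- suppressWarnings(split_half_cv(tab2, "strong", n_reps = 100, seed = 1))
  expect_lt(abs(cv2$accuracy - 2 / 3), 0.12)
  # single-rep runs are reproducible
  a <- split_half_cv(tab, "strong", n_reps = 1, seed = 42)
  b <- split_half_cv(tab, "strong", n_reps = 1, seed = 42)
  expect_equal(a$counts, b$counts)
})

test_that("participant rows assemble corpus, network and delta information", {
  net <- random_connected_net(8, 12, seed = 90)
  set.seed(90)
  cp <- simulate_corpus(net, 0.2, n_lists = 4, n_emissions = 6)
  fit <- estimate_network(cp, seed = 3, patience = 60)
  row <- participant_row(cp, fit, diagnosis = "NC", education = 16)
  expect_equal(nrow(row), 1)
  expect_equal(row$diagnosis, "NC")
  expect_equal(row$p_emit, fit$p_emit)
  expect_equal(row$n_responses, 6)
  expect_true(all(c("density", "aspl", "clustering") %in% names(row)))
})
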