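test_that("limits of agreement follow the adjusted-SD formula", {
  expect_equal(limits_of_agreement(0, 1), 1.96, tolerance = 1e-12)
  expect_equal(limits_of_agreement(0, 0), 0)
  expect_equal(limits_of_agreement(1, 3), 3.92, tolerance = 1e-12)
  expect_error(limits_of_agreement(-1, 1), ">= 0")
})

test_that("identical systems give zero bias, slope and limits", {
  d <- tibble::tibble(
    participant = rep(1:5, each = 4),
    reference_value = rnorm(20, 30, 10)
  )
  d$test_value <- d$reference_value
  fit <- fit_extended_ba(d)
  expect_equal(fit$bias_at_mean_reference, 0, tolerance = 1e-8)
  expect_equal(fit$bias_slope, 0, tolerance = 1e-8)
  expect_equal(fit$loa_half_width, 0, tolerance = 1e-6)
  # zero-variance differences: zero-width confidence intervals
  ci <- loa_confidence_intervals(fit)
  expect_equal(ci$conf.high - ci$conf.low, rep(0, 3), tolerance = 1e-6)
})

test_that("noiseless linear differences are recovered exactly", {
  set.seed(4)
  d <- tibble::tibble(
    participant = rep(1:6, each = 5),
    reference_value = rnorm(30, 40, 15)
  )
  d$test_value <- d$reference_value - 0.3 * d$reference_value + 4
  fit <- fit_extended_ba(d)
  expect_equal(fit$bias_slope, -0.3, tolerance = 1e-8)
  # intercept on the uncentered scale
  intercept <- fit$bias_at_mean_reference - fit$bias_slope * fit$mean_reference
  expect_equal(intercept, 4, tolerance = 1e-7)
  expect_equal(fit$loa_half_width, 0, tolerance = 1e-6)
})

test_that("swapping reference and test negates the bias at zero slope", {
  d <- simulate_event_samples(10, 8, fixed_bias = 3, proportional_slope = 0,
                              participant_sd = 1, residual_sd = 2, seed = 7)
  fit <- fit_extended_ba(d, include_slope = FALSE)
  swapped <- dplyr::rename(d, reference_value = test_value,
                           test_value = reference_value)
  fit_sw <- fit_extended_ba(swapped, include_slope = FALSE)
  expect_equal(fit_sw$bias_at_mean_reference, -fit$bias_at_mean_reference,
               tolerance = 1e-6)
  expect_equal(fit_sw$loa_half_width, fit$loa_half_width, tolerance = 1e-6)
})

test_that("one observation per participant reduces to classical Bland-Altman", {
  set.seed(15)
  d <- tibble::tibble(
    participant = 1:40,
    reference_value = rnorm(40, 30, 10)
  )
  d$test_value <- d$reference_value + rnorm(40, 2, 3)
  fit <- fit_extended_ba(d, include_slope = FALSE)
  diffs <- d$test_value - d$reference_value
  expect_equal(fit$bias_at_mean_reference, mean(diffs), tolerance = 1e-6)
  expect_equal(fit$loa_half_width, 1.96 * sd(diffs), tolerance = 1e-6)
  expect_equal(fit$model_type, "lm")
})

test_that("degenerate designs are rejected or repaired as specified", {
  d1 <- tibble::tibble(participant = rep(1, 10),
                       reference_value = rnorm(10),
                       test_value = rnorm(10))
  expect_error(fit_extended_ba(d1), "single participant")

  # zero reference variance: slope dropped with a warning, fit proceeds
  d2 <- tibble::tibble(participant = rep(1:4, each = 3),
                       reference_value = 25,
                       test_value = 25 + rnorm(12, 2, 1))
  expect_warning(fit2 <- fit_extended_ba(d2), "slope dropped")
  expect_equal(fit2$bias_slope, 0)
})

test_that("confidence intervals narrow with more participants", {
  base <- list(
    bias_at_mean_reference = 2, loa_lower = 2 - 7, loa_upper = 2 + 7,
    variance_between = 4, variance_within = 9, n_observations = 200,
    n_participants = 10
  )
  small <- structure(base, class = "ba_model")
  big <- base
  big$n_participants <- 20
  big$n_observations <- 400
  big <- structure(big, class = "ba_model")
  ci_small <- loa_confidence_intervals(small)
  ci_big <- loa_confidence_intervals(big)
  expect_true(all(ci_big$conf.high - ci_big$conf.low <
                    ci_small$conf.high - ci_small$conf.low))

  few <- base
  few$n_participants <- 2
  few <- structure(few, class = "ba_model")
  expect_true(all(is.na(loa_confidence_intervals(few)$conf.low)))
})

test_that("assumption checks apply the dual-condition thresholds", {
  set.seed(61)
  # strong monotone residual-fitted association: linearity flagged
  fitted <- seq(-2, 2, length.out = 200)
  res <- fitted + rnorm(200, 0, 0.8)
  rep1 <- check_assumptions(res, fitted)
  expect_true(rep1$linearity_violated)

  # significant but tiny heteroscedasticity slope: magnitude condition fails
  fitted2 <- seq(0, 100, length.out = 3000)
  res2 <- rnorm(3000, 0, 1 + 0.0005 * fitted2) * 1
  rep2 <- check_assumptions(res2, fitted2)
  if (!is.na(rep2$hetero_p) && rep2$hetero_p < 0.05) {
    expect_lt(abs(rep2$hetero_slope), 0.1)
  }
  expect_false(rep2$heteroscedasticity_violated)

  # constant residuals: undefined normality reported as non-violating
  expect_warning(rep3 <- check_assumptions(rep(1, 10), rnorm(10)),
                 "constant")
  expect_false(rep3$normality_violated)
})

test_that("no assumption is flagged under the null in most replicates", {
  set.seed(71)
  clean <- replicate(30, {
    res <- rnorm(500)
    fv <- rnorm(500)
    rep <- check_assumptions(res, fv)
    !rep$normality_violated && !rep$linearity_violated &&
      !rep$heteroscedasticity_violated
  })
  expect_gte(mean(clean), 0.9)
})

test_that("tidy and glance expose the model quantities", {
  d <- simulate_event_samples(8, 10, fixed_bias = 5, seed = 3)
  fit <- fit_extended_ba(d)
  td <- tidy(fit)
  expect_setequal(td$term, c("bias", "slope", "loa_lower", "loa_upper"))
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 8)
  expect_equal(nrow(gl), 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
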