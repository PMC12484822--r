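test_that("reference curves have a valid force channel and are reproducible", {
  c1 <- generate_reference_curve("knee", "sagittal", "90", seed = 11)
  c2 <- generate_reference_curve("knee", "sagittal", "90", seed = 11)
  expect_identical(c1, c2)
  # force crosses the 20 N threshold exactly twice: up then down
  above <- c1$force_N > 20
  transitions <- diff(above)
  expect_equal(sum(transitions == 1), 1)
  expect_equal(sum(transitions == -1), 1)
  expect_error(generate_reference_curve("knee", "sagittal", "30deg"),
               "Unknown direction")
  expect_error(generate_reference_curve("elbow", "sagittal", "90"),
               "Unknown angle")
})

test_that("generated sagittal knee curves stay within physiologic bounds", {
  set.seed(202)
  extremes <- replicate(1000, {
    v <- generate_reference_curve("knee", "sagittal",
                                  sample(c("straight", "45", "90",
                                           "135", "180"), 1))$angle_deg
    c(min(v), max(v))
  })
  expect_gt(min(extremes), -40)
  expect_lt(max(extremes), 120)
})

test_that("the error model reproduces its stated linear difference structure", {
  ref <- 30 + 20 * sin(pi * seq(0, 1, length.out = 101))

  expect_identical(apply_error_model(ref, zero_error_model()), ref)

  m5 <- error_model(fixed_bias = 5, proportional_slope = 0,
                    participant_sd = 0, residual_sd = 0)
  expect_equal(apply_error_model(ref, m5) - ref, rep(5, 101))

  msl <- error_model(fixed_bias = 0, proportional_slope = -0.3,
                     participant_sd = 0, residual_sd = 0)
  expect_equal(apply_error_model(rep(10, 101), msl) - rep(10, 101),
               rep(-3, 101))

  # sign convention: negating the fixed bias negates the difference exactly
  # at zero variance
  mneg <- error_model(fixed_bias = -5, proportional_slope = 0,
                      participant_sd = 0, residual_sd = 0)
  expect_equal(apply_error_model(ref, mneg) - ref,
               -(apply_error_model(ref, m5) - ref))
})

test_that("difference SD converges to sqrt(participant_sd^2 + residual_sd^2)", {
  psd <- 2
  rsd <- 3
  m <- error_model(fixed_bias = 0, proportional_slope = 0,
                   participant_sd = psd, residual_sd = rsd)
  ref <- rep(20, 101)
  set.seed(99)
  diffs <- replicate(800, {
    u <- rnorm(1, 0, psd)
    apply_error_model(ref, m, participant_intercept = u) - ref
  })
  expect_equal(sd(as.numeric(diffs)), sqrt(psd^2 + rsd^2), tolerance = 0.05)
  expect_equal(mean(diffs), 0, tolerance = 0.1)
})

test_that("simulated datasets are complete, seeded and truth-recording", {
  d <- tiny_design(n_participants = 2)
  ts1 <- simulate_trials(d, error_model(participant_sd = 2), seed = 5)
  ts2 <- simulate_trials(d, error_model(participant_sd = 2), seed = 5)
  expect_identical(ts1$trials, ts2$trials)
  expect_identical(ts1$speeds, ts2$speeds)

  keys <- dplyr::distinct(ts1$trials, participant, direction, intensity,
                          repetition)
  expect_equal(nrow(keys), nrow(design_trials(d)))
  sys_per_trial <- dplyr::count(
    dplyr::distinct(ts1$trials, participant, direction, intensity,
                    repetition, system),
    participant, direction, intensity, repetition)
  expect_true(all(sys_per_trial$n == 2))

  # degenerate participant variance gives all-zero intercepts
  ts0 <- simulate_trials(d, error_model(participant_sd = 0), seed = 5)
  expect_true(all(ts0$truth$intercepts$intercept == 0))

  # speeds decrease on average with sharper cutting angle
  mean_speed <- ts1$speeds %>%
    dplyr::group_by(direction) %>%
    dplyr::summarise(m = mean(speed_mps)) %>%
    dplyr::arrange(match(direction, c("straight", "45", "90", "135", "180")))
  expect_true(all(diff(mean_speed$m) < 0))
})

test_that("trial sets round-trip through the delimited text + sidecar format", {
  dir <- withr::local_tempdir()
  ts <- simulate_trials(tiny_design(), error_model(direction_sd_scale =
                                                     c("180" = 2)), seed = 8)
  write_trial_set(ts, dir)
  expect_true(all(file.exists(file.path(dir, c("trials.tsv", "speeds.tsv",
                                               "truth.json")))))
  back <- read_trial_set(dir)
  expect_equal(back$trials, ts$trials, tolerance = 1e-12)
  expect_equal(back$truth$model, ts$truth$model)
  expect_equal(back$design$directions, ts$design$directions)
})
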