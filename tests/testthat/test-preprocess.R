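test_that("stance detection finds the longest strictly-above run", {
  expect_equal(unname(detect_stance(c(0, 10, 25, 100, 25, 10, 0))), c(3, 5))
  expect_equal(unname(detect_stance(rep(1000, 50))), c(1, 50))

  # runs of length 3 and 7: brute-force oracle
  f <- c(0, 30, 30, 30, 0, 0, 40, 40, 40, 40, 40, 40, 40, 0)
  expect_equal(unname(detect_stance(f)), brute_longest_run(f, 20))

  # random profiles against the brute-force oracle
  set.seed(31)
  for (i in 1:25) {
    f <- round(runif(20, 0, 60))
    if (!any(f > 20)) next
    expect_equal(unname(detect_stance(f)), brute_longest_run(f, 20))
  }

  expect_error(detect_stance(c(0, 5, 10)), "No sample exceeds")
  expect_message(detect_stance(c(0, 30, 0, 30, 0)), "earliest")
})

test_that("zero-phase low-pass filter preserves DC and attenuates as designed", {
  expect_lt(max(abs(lowpass_filter(rep(30, 200), 20, 200) - 30)), 1e-6)

  t <- (0:999) / 200
  mid <- 300:700
  pass <- lowpass_filter(sin(2 * pi * 2 * t), 20, 200)
  expect_gt(max(abs(pass[mid])), 0.99)   # < 1% attenuation at 2 Hz
  stop <- lowpass_filter(sin(2 * pi * 60 * t), 20, 200)
  expect_lt(max(abs(stop[mid])), 0.10)   # > 90% attenuation at 60 Hz

  expect_error(lowpass_filter(rnorm(100), 100, 200), "Nyquist")
})

test_that("rate resampling preserves the interval, endpoints and linear data", {
  ramp <- seq(0, 10, length.out = 201)        # 1 s at 200 Hz
  out <- resample_to_rate(ramp, 200, 85, method = "linear")
  expect_length(out, 86)
  expect_equal(out, seq(0, 10, length.out = 86), tolerance = 1e-9)
  expect_identical(resample_to_rate(ramp, 200, 200), ramp)
  expect_equal(resample_to_rate(ramp, 200, 85)[c(1, 86)], c(0, 10),
               tolerance = 1e-12)  # cubic keeps endpoints too
  expect_error(resample_to_rate(1:3, 200, 85), "at least 4")
})

test_that("time normalization yields 101 points with exact endpoints", {
  seg <- seq(0, 100, length.out = 51)
  out <- time_normalize(seg, 1, 51)
  expect_length(out, 101)
  expect_equal(out, 0:100, tolerance = 1e-9)  # linear closed form

  expect_equal(time_normalize(rep(12, 40), 1, 40), rep(12, 101))

  # idempotence on an already-normalized full-span curve
  curve <- sin(seq(0, pi, length.out = 101)) * 30
  expect_equal(time_normalize(curve, 1, 101), curve, tolerance = 1e-9)

  expect_error(time_normalize(1:10, 4, 6), "too short")
})

test_that("event extraction returns endpoint and global-extremum values", {
  lin <- seq(5, 9, length.out = 101)
  ev <- extract_events(lin)
  expect_equal(unlist(ev), c(touchdown = 5, toeoff = 9, peak_min = 5,
                             peak_max = 9))
  expect_equal(unname(unlist(extract_events(rep(7, 101)))), rep(7, 4))

  dip <- rep(10, 101); dip[40] <- -3
  expect_equal(extract_events(dip)$peak_min, min(dip))

  # invariant over a random ensemble: peaks bound the endpoint events
  set.seed(12)
  for (i in 1:50) {
    v <- as.numeric(gp_curves(1, sd = 10, seed = NULL))
    ev <- extract_events(v)
    expect_lte(ev$peak_min, min(ev$touchdown, ev$toeoff))
    expect_gte(ev$peak_max, max(ev$touchdown, ev$toeoff))
  }
})

test_that("approach speed is the mean horizontal speed before touchdown", {
  p <- cumsum(rep(0.05, 100))  # 0.05 m / frame at 100 Hz = 5 m/s
  expect_equal(compute_approach_speed(p, 100, 60), 5.0)
  expect_equal(compute_approach_speed(rep(1, 100), 100, 60), 0)

  # piecewise 6 then 4 m/s, window covering equal halves
  steps <- c(rep(0.06, 50), rep(0.04, 10))
  p2 <- cumsum(steps)
  expect_equal(compute_approach_speed(p2, 100, 60), 5.0)

  expect_error(compute_approach_speed(p, 100, 10), "before the start")
})

test_that("the preprocessing pipeline yields 101-point curves for both systems", {
  ts <- simulate_trials(tiny_design(), error_model(residual_sd = 2), seed = 21)
  pre <- preprocess_trials(ts$trials)
  lens <- pre$curves %>%
    dplyr::count(participant, direction, intensity, repetition, system,
                 joint, plane)
  expect_true(all(lens$n == 101))
  expect_equal(nrow(pre$excluded), 0)
  # both systems present for every curve
  expect_setequal(unique(pre$curves$system), c("reference", "test"))

  # determinism: identical input gives identical output
  pre2 <- preprocess_trials(ts$trials)
  expect_identical(pre$curves, pre2$curves)
  expect_identical(pre$events, pre2$events)

  # paired structures line up
  pe <- paired_events(pre)
  expect_equal(pe$difference, pe$test_value - pe$reference_value)
  dc <- difference_curves(pre)
  expect_equal(nrow(dc), nrow(pre$curves) / 2)
})
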