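test_that("degenerate and symmetric ensembles give the expected bands", {
  flat <- matrix(rep(sin(seq(0, pi, length.out = 101)) * 10, 8),
                 nrow = 8, byrow = TRUE)
  expect_warning(bd <- bootstrap_band(flat, dependent = FALSE, seed = 1),
                 "degenerate")
  expect_true(bd$degenerate)
  expect_equal(bd$upper, bd$lower)
  expect_equal(bd$area, 0)

  # constant curves at -1, 0, +1: mean-bias curve is identically zero
  const <- matrix(rep(c(-1, 0, 1), each = 101 * 3), nrow = 9, byrow = TRUE)
  bd2 <- bootstrap_band(const, dependent = FALSE, seed = 2, n_bootstrap = 50,
                        n_harmonics = 4)
  expect_equal(bd2$mean_curve, rep(0, 101), tolerance = 1e-9)
})

test_that("bands are shift- and scale-equivariant", {
  y <- gp_curves(20, sd = 2, seed = 5)
  b0 <- bootstrap_band(y, dependent = FALSE, seed = 9, n_bootstrap = 100)
  b_shift <- bootstrap_band(y + 3, dependent = FALSE, seed = 9,
                            n_bootstrap = 100)
  expect_equal(b_shift$lower, b0$lower + 3, tolerance = 1e-9)
  expect_equal(b_shift$upper, b0$upper + 3, tolerance = 1e-9)
  expect_equal(b_shift$area, b0$area, tolerance = 1e-9)
  expect_equal(b_shift$max_width, b0$max_width, tolerance = 1e-9)
  expect_equal(b_shift$mean_bias, b0$mean_bias + 3, tolerance = 1e-9)

  b_scale <- bootstrap_band(y * 2, dependent = FALSE, seed = 9,
                            n_bootstrap = 100)
  expect_equal(b_scale$area, 2 * b0$area, tolerance = 1e-9)
  expect_equal(b_scale$max_width, 2 * b0$max_width, tolerance = 1e-9)
  expect_equal(b_scale$min_width, 2 * b0$min_width, tolerance = 1e-9)
})

test_that("a stricter alpha gives a wider band on the same resamples", {
  y <- gp_curves(25, seed = 6)
  b10 <- bootstrap_band(y, alpha = 0.10, dependent = FALSE, seed = 4,
                        n_bootstrap = 200)
  b01 <- bootstrap_band(y, alpha = 0.01, dependent = FALSE, seed = 4,
                        n_bootstrap = 200)
  expect_true(all(b01$lower <= b10$lower + 1e-12))
  expect_true(all(b01$upper >= b10$upper - 1e-12))
})

test_that("band metrics integrate the band geometry", {
  mk <- function(lower, upper) {
    structure(list(stance_pct = 0:100, lower = lower, upper = upper,
                   mean_curve = (lower + upper) / 2),
              class = "prediction_band")
  }
  m1 <- band_metrics(mk(rep(-1, 101), rep(1, 101)))
  expect_equal(m1$area, 200)
  expect_equal(m1$max_width, 2)
  expect_equal(m1$min_width, 2)

  expect_equal(band_metrics(mk(rep(0, 101), rep(0, 101)))$area, 0)

  # triangle: upper rises linearly 0 -> 2, lower at 0
  m3 <- band_metrics(mk(rep(0, 101), seq(0, 2, length.out = 101)))
  expect_equal(m3$area, 100)
})

test_that("pointwise band invariants hold and inputs are validated", {
  y <- gp_curves(12, seed = 8)
  bd <- bootstrap_band(y, dependent = FALSE, seed = 3, n_bootstrap = 100)
  expect_true(all(bd$upper >= bd$mean_curve & bd$mean_curve >= bd$lower))
  expect_gte(bd$min_width, 0)
  expect_gte(bd$max_width, bd$min_width)

  expect_error(bootstrap_band(y[1:3, ], dependent = FALSE), "at least 5")
  expect_error(bootstrap_band(y, dependent = TRUE), "cluster")
  expect_error(bootstrap_band(y, dependent = TRUE,
                              cluster = rep(1, 12)), "2 clusters")
  expect_error(bootstrap_band(y, alpha = 1.2, dependent = FALSE), "alpha")
})

test_that("cluster bootstrap accepts long data frames with participants", {
  y <- gp_curves(12, sd = 1, seed = 10) + 2
  long <- tibble::tibble(
    curve_id = rep(1:12, each = 101),
    participant = rep(rep(1:4, each = 3), each = 101),
    stance_pct = rep(0:100, 12),
    difference = as.numeric(t(y))
  )
  bd <- bootstrap_band(long, cluster = "participant", dependent = TRUE,
                       seed = 2, n_bootstrap = 100)
  expect_equal(bd$n_curves, 12)
  expect_equal(bd$mean_bias, 2, tolerance = 0.5)
  expect_s3_class(autoplot(bd), "ggplot")
  expect_equal(nrow(tidy(bd)), 101)
})
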