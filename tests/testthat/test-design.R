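test_that("factorial enumeration is complete and deterministic", {
  d <- cod_design()
  keys <- design_trials(d)
  expect_equal(nrow(keys), 19 * 5 * 3 * 3)
  per_part <- dplyr::count(keys, participant)
  expect_true(all(per_part$n == 45))
  expect_identical(keys, design_trials(d))

  # brute-force oracle for a non-default design
  d2 <- cod_design(n_participants = 2, directions = c("straight", "90"))
  n_expected <- 0L
  for (p in 1:2) for (dir in 1:2) for (int in 1:3) for (r in 1:3) {
    n_expected <- n_expected + 1L
  }
  expect_equal(nrow(design_trials(d2)), n_expected)  # 36

  d3 <- cod_design(n_participants = 1, directions = "straight",
                   intensities = "slow", repetitions = 1)
  expect_equal(nrow(design_trials(d3)), 1)
})

test_that("degenerate design configurations are rejected", {
  expect_error(cod_design(directions = character(0)), "non-empty")
  expect_error(cod_design(intensities = character(0)), "non-empty")
  expect_error(cod_design(n_participants = 0))
  expect_error(cod_design(angles = data.frame(x = 1)), "joint")
})
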