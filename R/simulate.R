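# Morphology parameters for the synthetic stance-phase angle curves.
# Offsets/amplitudes (degrees) differ by joint and plane so that the sagittal
# plane carries the largest excursions, exercising proportional-bias effects.
.angle_params <- function() {
  tibble(
    joint = rep(c("hip", "knee", "ankle"), each = 3),
    plane = rep(c("sagittal", "frontal", "transverse"), times = 3),
    offset = c(20, 5, 5, 35, 0, 5, 0, 2, -5),
    amplitude = c(22, 8, 10, 25, 6, 12, 18, 10, 8)
  )
}

# Stance duration range (s) and amplitude scaling per direction: sharper cuts
# take longer on the plate and move the joints through slightly larger ranges.
.direction_params <- function() {
  tibble(
    direction = c("straight", "45", "90", "135", "180"),
    stance_min = c(0.20, 0.22, 0.26, 0.30, 0.34),
    stance_max = c(0.26, 0.28, 0.34, 0.40, 0.45),
    amp_scale = c(1.00, 1.05, 1.12, 1.18, 1.25),
    speed_min = c(3.9, 3.8, 2.8, 2.1, 2.0),
    speed_max = c(6.3, 5.7, 3.8, 3.2, 3.0)
  )
}

.dir_row <- function(direction) {
  dp <- .direction_params()
  i <- match(direction, dp$direction)
  if (is.na(i)) {
    abort(sprintf("Unknown direction label '%s' (known: %s).",
                  direction, paste(dp$direction, collapse = ", ")))
  }
  dp[i, ]
}

.ang_row <- function(joint, plane) {
  ap <- .angle_params()
  i <- which(ap$joint == joint & ap$plane == plane)
  if (length(i) != 1) {
    abort(sprintf("Unknown angle (%s, %s).", joint, plane))
  }
  ap[i, ]
}

# Deterministic per-trial substream: subsets of a dataset are reproducible
# independently of generation order.
.trial_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 7919) %% 2147483629)
}

# Unit-variance smooth noise: white Gaussian noise convolved with a Gaussian
# kernel, giving (approximately) squared-exponential correlation with the
# requested length, exact unit marginal SD.
.smooth_noise <- function(n, ell_points) {
  if (ell_points < 0.5) return(rnorm(n))
  sk <- ell_points / sqrt(2)
  half <- max(1L, ceiling(4 * sk))
  w <- exp(-0.5 * ((-half:half) / sk)^2)
  z <- rnorm(n + 2 * half)
  sm <- stats::filter(z, w, sides = 2)
  as.numeric(sm[(half + 1):(half + n)]) / sqrt(sum(w^2))
}

# One draw of the standardized residual process (mean 0, pointwise SD 1).
.residual_process <- function(n, family, ell_points) {
  g <- .smooth_noise(n, ell_points)
  switch(family,
    normal = g,
    heavy = g * sqrt(4 / rchisq(1, 4)) / sqrt(2),
    skewed = {
      delta <- 0.9
      raw <- delta * abs(rnorm(1)) + sqrt(1 - delta^2) * g
      (raw - delta * sqrt(2 / pi)) / sqrt(1 - 2 * delta^2 / pi)
    }
  )
}

# Reference trial: time grid, force channel, and one column per angle.
# Trial = pre-flight, stance (force > 20 N by construction), post-flight.
.reference_trial <- function(angles, direction, rate,
                             pre_s = 0.1, post_s = 0.1) {
  dp <- .dir_row(direction)
  stance_s <- runif(1, dp$stance_min, dp$stance_max)
  f_max <- runif(1, 600, 1400)
  total <- pre_s + stance_s + post_s
  time_s <- seq(0, total, by = 1 / rate)
  s <- (time_s - pre_s) / stance_s  # stance fraction; <0 / >1 in flight
  in_stance <- s >= 0 & s <= 1
  force <- numeric(length(time_s))
  force[in_stance] <- 22 + f_max * sin(pi * s[in_stance])^1.5

  ang <- matrix(0, length(time_s), nrow(angles))
  colnames(ang) <- paste(angles$joint, angles$plane, sep = "_")
  w_base <- c(1, 0.25, 0.10, 0.04)
  for (j in seq_len(nrow(angles))) {
    p <- .ang_row(angles$joint[j], angles$plane[j])
    amp <- p$amplitude * dp$amp_scale
    off <- p$offset * runif(1, 0.9, 1.1)
    v <- rep(off, length(time_s))
    for (k in seq_along(w_base)) {
      phi <- if (k == 1) runif(1, -0.2, 0.2) else runif(1, -pi / 2, pi / 2)
      v <- v + amp * w_base[k] * runif(1, 0.85, 1.15) * sin(k * pi * s + phi)
    }
    ang[, j] <- v
  }
  list(time_s = time_s, force = force, angles = ang,
       stance_s = stance_s, pre_s = pre_s)
}

#' Generate one synthetic reference-system angle curve with its force channel
#'
#' Emulates the stance-phase morphology of a lower-limb joint angle during a
#' change-of-direction trial: a low-order harmonic mixture over a stance
#' duration drawn from a direction-dependent range, flanked by short flight
#' phases, together with a vertical ground-reaction-force channel that
#' exceeds 20 N exactly during stance and is 0 N outside it.
#'
#' @param joint One of `"hip"`, `"knee"`, `"ankle"`.
#' @param plane One of `"sagittal"`, `"frontal"`, `"transverse"`.
#' @param direction Direction label (`"straight"`, `"45"`, `"90"`, `"135"`,
#'   `"180"`); unknown labels are an error.
#' @param rate Sampling rate in Hz (default 200).
#' @param seed Optional integer seed; the same seed reproduces the same curve.
#'
#' @return A tibble with columns `time_s`, `angle_deg`, `force_N`.
#' @export
#' @examples
#' curve <- generate_reference_curve("knee", "sagittal", "90", seed = 1)
#' sum(diff(curve$force_N > 20) != 0)  # force crosses 20 N exactly twice
generate_reference_curve <- function(joint, plane, direction,
                                     rate = 200, seed = NULL) {
  .ang_row(joint, plane)  # validate labels early
  if (!is.null(seed)) set.seed(seed)
  tr <- .reference_trial(tibble(joint = joint, plane = plane), direction, rate)
  tibble(time_s = tr$time_s, angle_deg = as.numeric(tr$angles[, 1]),
         force_N = tr$force)
}

#' Derive a test-system waveform from a reference waveform
#'
#' Applies the generative difference structure of an [error_model()]:
#' `test = reference + fixed_bias + proportional_slope * reference +
#' participant_intercept + residual process`. The residual process is smooth
#' over the curve (squared-exponential correlation), with pointwise SD
#' `residual_sd * sd_scale * (1 + heteroscedasticity * |reference| / 10)`
#' and the configured marginal family.
#'
#' @param reference Numeric vector, the reference-system curve in degrees.
#' @param model An [error_model()].
#' @param participant_intercept Participant-level offset in degrees.
#' @param sd_scale Extra multiplier on the residual SD (used for
#'   direction-dependent noise).
#' @param seed Optional integer seed for the residual draw.
#'
#' @return Numeric vector of the same length: the test-system curve.
#' @export
#' @examples
#' ref <- rep(10, 101)
#' apply_error_model(ref, error_model(fixed_bias = 0, proportional_slope = -0.3,
#'                                    participant_sd = 0, residual_sd = 0))
#' # constant -3 degree difference
apply_error_model <- function(reference, model, participant_intercept = 0,
                              sd_scale = 1, seed = NULL) {
  stopifnot(inherits(model, "error_model"))
  if (!is.numeric(reference) || length(reference) < 1) {
    abort("`reference` must be a non-empty numeric vector.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(reference)
  test <- reference + model$fixed_bias +
    model$proportional_slope * reference + participant_intercept
  if (model$residual_sd > 0 && sd_scale > 0) {
    ell <- model$correlation_length / 100 * (n - 1)
    eps <- .residual_process(n, model$residual_family, ell)
    sd_point <- model$residual_sd * sd_scale *
      (1 + model$heteroscedasticity * abs(reference) / 10)
    test <- test + eps * sd_point
  }
  test
}

.direction_sd_scale <- function(model, direction) {
  if (is.null(model$direction_sd_scale)) return(1)
  s <- unname(model$direction_sd_scale[direction])
  if (length(s) != 1 || is.na(s)) 1 else s
}

#' Simulate a complete paired two-system trial dataset
#'
#' Generates every trial of a study design for both systems: the reference
#' system sampled at `design$rate_reference` with a force channel, the test
#' system derived through the error model and resampled to
#' `design$rate_test` (no force channel, mirroring a video-based system).
#' Approach speeds are drawn per trial from direction-dependent ranges
#' (sharper cuts are slower), partitioned by instructed intensity so that
#' speed tertiles are recoverable. Ground truth (the error model and the
#' realized participant intercepts) is recorded for parameter-recovery
#' validation. A fixed seed reproduces the dataset exactly; per-trial random
#' substreams are derived from a trial counter so subsets are reproducible
#' independently.
#'
#' @param design A [cod_design()].
#' @param model An [error_model()].
#' @param seed Integer seed.
#'
#' @return An object of class `trial_set`: a list with
#'   \describe{
#'     \item{trials}{long tibble, one row per participant / direction /
#'       intensity / repetition / system / frame, with `time_s`, `force_N`
#'       (NA for the test system) and one column per `joint_plane` angle.}
#'     \item{speeds}{tibble of per-trial approach speeds (m/s).}
#'     \item{truth}{list: the error model, participant intercepts, the seed.}
#'     \item{design}{the design used.}
#'   }
#' @export
#' @examples
#' ts <- simulate_trials(cod_design(n_participants = 1, repetitions = 1),
#'                       zero_error_model(), seed = 1)
#' dplyr::count(ts$trials, system)
simulate_trials <- function(design = cod_design(), model = error_model(),
                            seed = 1) {
  stopifnot(inherits(design, "cod_design"), inherits(model, "error_model"))
  keys <- design_trials(design)
  angle_cols <- paste(design$angles$joint, design$angles$plane, sep = "_")

  set.seed(seed)
  intercepts <- tibble(
    participant = seq_len(design$n_participants),
    intercept = if (model$participant_sd > 0) {
      rnorm(design$n_participants, 0, model$participant_sd)
    } else {
      rep(0, design$n_participants)
    }
  )

  n_trials <- nrow(keys)
  trial_frames <- vector("list", 2L * n_trials)
  speeds <- numeric(n_trials)
  n_int <- length(design$intensities)

  for (i in seq_len(n_trials)) {
    set.seed(.trial_seed(seed, i))
    k <- keys[i, ]
    dp <- .dir_row(k$direction)

    # approach speed: intensity labels occupy successive thirds of the
    # direction-specific range, so direction-wise tertiles recover them
    slot <- match(k$intensity, design$intensities) - 1L
    w <- (dp$speed_max - dp$speed_min) / n_int
    speeds[i] <- runif(1, dp$speed_min + slot * w,
                       dp$speed_min + (slot + 1L) * w)

    tr <- .reference_trial(design$angles, k$direction, design$rate_reference)
    u_i <- intercepts$intercept[k$participant]
    s_dir <- .direction_sd_scale(model, k$direction)

    test_ref_grid <- tr$angles
    for (j in seq_len(ncol(test_ref_grid))) {
      test_ref_grid[, j] <- apply_error_model(
        tr$angles[, j], model, participant_intercept = u_i, sd_scale = s_dir
      )
    }
    # test system records on its own (coarser) grid
    test_ang <- apply(test_ref_grid, 2, resample_to_rate,
                      rate_in = design$rate_reference,
                      rate_out = design$rate_test, method = "cubic")
    n_t <- nrow(test_ang)
    total <- (length(tr$time_s) - 1) / design$rate_reference

    base <- list(participant = k$participant, direction = k$direction,
                 intensity = k$intensity, repetition = k$repetition)
    ref_df <- c(base, list(system = "reference",
                           frame = seq_along(tr$time_s),
                           time_s = tr$time_s, force_N = tr$force),
                as.list(as.data.frame(tr$angles)))
    test_df <- c(base, list(system = "test",
                            frame = seq_len(n_t),
                            time_s = seq(0, total, length.out = n_t),
                            force_N = rep(NA_real_, n_t)),
                 as.list(as.data.frame(test_ang)))
    trial_frames[[2L * i - 1L]] <- as_tibble(ref_df)
    trial_frames[[2L * i]] <- as_tibble(test_df)
  }

  trials <- bind_rows(trial_frames)
  names(trials)[seq(9, 8 + length(angle_cols))] <- angle_cols

  structure(
    list(
      trials = trials,
      speeds = dplyr::bind_cols(keys, speed_mps = speeds),
      truth = list(model = model, intercepts = intercepts, seed = seed),
      design = design
    ),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>\n")
  cat("  trials: ", nrow(x$speeds), " (",
      x$design$n_participants, " participants x ",
      nrow(x$speeds) / x$design$n_participants, ")\n", sep = "")
  cat("  rows:   ", nrow(x$trials), "\n")
  cat("  angles: ", nrow(x$design$angles), " series per trial\n", sep = "")
  invisible(x)
}

#' Write / read a trial set as delimited text plus a ground-truth sidecar
#'
#' `write_trial_set()` writes `trials.tsv` (the long waveform table),
#' `speeds.tsv` and `truth.json` (error model, participant intercepts, seed,
#' and the design) into a directory; `read_trial_set()` reconstructs the
#' `trial_set` from such a directory.
#'
#' @param x A `trial_set`.
#' @param dir Directory path (created if missing).
#' @return `write_trial_set()` returns `dir` invisibly; `read_trial_set()`
#'   returns a `trial_set`.
#' @export
write_trial_set <- function(x, dir) {
  stopifnot(inherits(x, "trial_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(x$trials, file.path(dir, "trials.tsv"))
  readr::write_tsv(x$speeds, file.path(dir, "speeds.tsv"))
  model_fields <- unclass(x$truth$model)
  if (!is.null(model_fields$direction_sd_scale)) {
    # keep direction names through JSON (named vectors serialize unnamed)
    model_fields$direction_sd_scale <- as.list(model_fields$direction_sd_scale)
  }
  truth <- list(
    model = model_fields,
    intercepts = x$truth$intercepts,
    seed = x$truth$seed,
    design = list(
      n_participants = x$design$n_participants,
      directions = x$design$directions,
      intensities = x$design$intensities,
      repetitions = x$design$repetitions,
      angles = x$design$angles,
      rate_reference = x$design$rate_reference,
      rate_test = x$design$rate_test
    )
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  d <- truth$design
  design <- cod_design(
    n_participants = d$n_participants, directions = d$directions,
    intensities = d$intensities, repetitions = d$repetitions,
    angles = as_tibble(d$angles),
    rate_reference = d$rate_reference, rate_test = d$rate_test
  )
  m <- truth$model
  model <- error_model(
    fixed_bias = m$fixed_bias, proportional_slope = m$proportional_slope,
    participant_sd = m$participant_sd, residual_sd = m$residual_sd,
    heteroscedasticity = m$heteroscedasticity,
    residual_family = m$residual_family,
    correlation_length = m$correlation_length,
    direction_sd_scale = if (length(m$direction_sd_scale)) {
      unlist(m$direction_sd_scale)
    } else {
      NULL
    }
  )
  structure(
    list(
      trials = readr::read_tsv(file.path(dir, "trials.tsv"),
                               show_col_types = FALSE),
      speeds = readr::read_tsv(file.path(dir, "speeds.tsv"),
                               show_col_types = FALSE),
      truth = list(model = model,
                   intercepts = as_tibble(truth$intercepts),
                   seed = truth$seed),
      design = design
    ),
    class = "trial_set"
  )
}

#' Simulate paired event samples directly (no waveforms)
#'
#' Draws event-level paired measurements under the extended Bland-Altman
#' generative model: `difference = fixed_bias + proportional_slope *
#' (reference - mean reference) + participant intercept + residual`. This is
#' the fast path for validating the mixed-model estimator by parameter
#' recovery; the waveform generator exercises the same structure end-to-end.
#'
#' @param n_participants Number of participants.
#' @param trials_per_participant Observations per participant.
#' @param fixed_bias True bias in degrees (at the mean reference value).
#' @param proportional_slope True slope of the difference per degree of
#'   centered reference value.
#' @param participant_sd SD of participant intercepts (degrees).
#' @param residual_sd Residual SD (degrees).
#' @param reference_mean,reference_sd Distribution of reference values.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `participant`, `trial`, `reference_value`,
#'   `test_value`, `difference`.
#' @export
simulate_event_samples <- function(n_participants = 19,
                                   trials_per_participant = 45,
                                   fixed_bias = 0,
                                   proportional_slope = 0,
                                   participant_sd = 2,
                                   residual_sd = 3,
                                   reference_mean = 30,
                                   reference_sd = 10,
                                   seed = 1) {
  set.seed(seed)
  u <- rnorm(n_participants, 0, participant_sd)
  n <- n_participants * trials_per_participant
  participant <- rep(seq_len(n_participants), each = trials_per_participant)
  ref <- rnorm(n, reference_mean, reference_sd)
  diff <- fixed_bias + proportional_slope * (ref - mean(ref)) +
    u[participant] + rnorm(n, 0, residual_sd)
  tibble(
    participant = participant,
    trial = rep(seq_len(trials_per_participant), times = n_participants),
    reference_value = ref,
    test_value = ref + diff,
    difference = diff
  )
}
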