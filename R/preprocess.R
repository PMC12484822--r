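#' Detect the stance phase from a vertical force channel
#'
#' Finds the longest contiguous run of samples with force strictly above the
#' threshold (default 20 N) and returns its first and last indices, both
#' inclusive. If several runs tie for the longest, the earliest is chosen and
#' a message is emitted.
#'
#' @param force Numeric vector of vertical force in N.
#' @param threshold Force threshold in N (> 0, default 20).
#' @return Integer vector `c(start, end)` (inclusive indices).
#' @export
#' @examples
#' detect_stance(c(0, 10, 25, 100, 25, 10, 0))  # c(3, 4) ... c(3, 5)
detect_stance <- function(force, threshold = 20) {
  if (length(force) == 0) abort("`force` must be non-empty.")
  if (threshold <= 0) abort("`threshold` must be > 0.")
  above <- !is.na(force) & force > threshold
  if (!any(above)) {
    abort("No sample exceeds the force threshold: no stance phase detected.")
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  lens <- r$lengths[runs]
  best <- runs[which.max(lens)]  # which.max takes the earliest tie
  if (sum(lens == max(lens)) > 1) {
    inform("Multiple equal-length stance candidates; using the earliest.")
  }
  c(start = starts[best], end = ends[best])
}

# Zero-phase IIR filtering: odd-reflection padding at both ends plus
# steady-state initial filter history (the signal is treated as having been
# at its first value forever), applied forward and backward. This removes
# the startup transients of a plain two-pass filter; a constant signal
# passes through unchanged to machine precision.
.filtfilt0 <- function(b, a, x) {
  n <- length(x)
  nf <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  g <- sum(b) / sum(a)  # DC gain
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], length(b) - 1),
                              init.y = rep(z[1] * g, length(a) - 1)))
  }
  pre <- 2 * x[1] - x[(nf + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - nf)]
  xp <- c(pre, x, post)
  y <- one_pass(xp)
  y <- rev(one_pass(rev(y)))
  y[(nf + 1):(nf + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters a uniformly sampled signal with a Butterworth low-pass filter
#' applied forward and backward (zero phase). The default 4th order with a
#' 20 Hz cutoff is the dominant convention for lower-limb kinematics and
#' force data.
#'
#' @param x Numeric signal.
#' @param cutoff Cutoff frequency in Hz (must be below the Nyquist rate).
#' @param rate Sampling rate in Hz.
#' @param order Filter order per pass (default 4).
#' @return Filtered signal of the same length.
#' @export
#' @examples
#' lowpass_filter(rep(30, 100), cutoff = 20, rate = 200)  # unchanged
lowpass_filter <- function(x, cutoff, rate, order = 4) {
  if (cutoff >= rate / 2) {
    abort("`cutoff` must be below the Nyquist frequency (rate / 2).")
  }
  if (cutoff <= 0 || rate <= 0) abort("`cutoff` and `rate` must be > 0.")
  if (length(x) < 2 * (order + 1)) {
    abort("Signal too short to filter at this order.")
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  .filtfilt0(bf$b, bf$a, x)
}

#' Resample a signal onto a uniform grid at a new rate
#'
#' Interpolates the signal onto a uniform grid at `rate_out` spanning exactly
#' the same time interval (both endpoints preserved). Intended for matching
#' the reference-system rate (e.g. 200 Hz) to the test-system rate (85 Hz)
#' after low-pass filtering, so no separate anti-aliasing step is applied.
#'
#' @param x Numeric signal sampled uniformly at `rate_in`.
#' @param rate_in,rate_out Sampling rates in Hz (> 0).
#' @param method `"linear"` or `"cubic"` (natural spline) interpolation.
#' @return Numeric signal at the new rate.
#' @export
#' @examples
#' length(resample_to_rate(seq(0, 10, length.out = 201), 200, 85))  # 86
resample_to_rate <- function(x, rate_in, rate_out,
                             method = c("cubic", "linear")) {
  method <- match.arg(method)
  if (rate_in <= 0 || rate_out <= 0) abort("Rates must be > 0.")
  if (length(x) < 4) abort("Need at least 4 samples to resample.")
  if (rate_in == rate_out) return(x)
  total <- (length(x) - 1) / rate_in
  t_in <- seq(0, total, length.out = length(x))
  # complete output intervals fitting in the span, tolerant to floating-point
  # drift in rates derived from time stamps
  n_out <- floor(total * rate_out + 1e-6) + 1
  t_out <- seq(0, total, length.out = n_out)
  if (method == "linear") {
    approx(t_in, x, xout = t_out)$y
  } else {
    spline(t_in, x, xout = t_out, method = "natural")$y
  }
}

#' Time-normalize a curve segment to a fixed number of points
#'
#' Interpolates the segment between `start_index` and `end_index` (inclusive;
#' fractional indices allowed) onto `n_points` equally spaced points —
#' by default the 101-point stance-percent grid 0, 1, ..., 100%. The first
#' and last normalized values equal the segment's endpoint values.
#'
#' @param x Numeric curve.
#' @param start_index,end_index Segment bounds as (possibly fractional)
#'   indices into `x`; `end_index - start_index` must be at least 3.
#' @param n_points Number of output points (default 101).
#' @param method `"linear"` (default) or `"cubic"` interpolation.
#' @return Numeric vector of length `n_points`.
#' @export
#' @examples
#' time_normalize(0:100, 1, 101)[51]  # 50
time_normalize <- function(x, start_index, end_index, n_points = 101,
                           method = c("linear", "cubic")) {
  method <- match.arg(method)
  if (end_index - start_index < 3) {
    abort("Stance segment too short to normalize (need end - start >= 3).")
  }
  if (start_index < 1 || end_index > length(x)) {
    abort("Segment indices out of range.")
  }
  xout <- seq(start_index, end_index, length.out = n_points)
  if (method == "linear") {
    approx(seq_along(x), x, xout = xout)$y
  } else {
    spline(seq_along(x), x, xout = xout, method = "natural")$y
  }
}

#' Extract the four discrete event values from a normalized curve
#'
#' Touchdown is the value at the first stance point, toe-off the value at the
#' last, and the peak minimum / maximum are the global extrema over the whole
#' stance phase.
#'
#' @param x Numeric normalized curve (typically 101 points).
#' @return A one-row tibble with columns `touchdown`, `toeoff`, `peak_min`,
#'   `peak_max`.
#' @export
extract_events <- function(x) {
  if (length(x) < 2 || anyNA(x)) {
    abort("`x` must be a complete curve with at least 2 points.")
  }
  tibble(
    touchdown = x[1],
    toeoff = x[length(x)],
    peak_min = min(x),
    peak_max = max(x)
  )
}

#' Mean approach speed over a window before touchdown
#'
#' Computes the mean horizontal speed of a point (e.g. the pelvis centre)
#' over a fixed window ending at touchdown, from frame-to-frame
#' displacements.
#'
#' @param positions Numeric vector (one horizontal coordinate, metres) or a
#'   matrix / data frame with one column per horizontal coordinate.
#' @param rate Sampling rate in Hz.
#' @param touchdown_index Index of the touchdown frame.
#' @param window_s Window length in seconds before touchdown (default 0.2).
#' @return Approach speed in m/s.
#' @export
#' @examples
#' compute_approach_speed(cumsum(rep(0.05, 100)), 100, 60)  # 5 m/s
compute_approach_speed <- function(positions, rate, touchdown_index,
                                   window_s = 0.2) {
  p <- as.matrix(positions)
  w <- max(1L, round(window_s * rate))
  if (touchdown_index - w < 1) {
    abort("Approach-speed window extends before the start of the recording.")
  }
  if (touchdown_index > nrow(p)) abort("`touchdown_index` out of range.")
  steps <- (touchdown_index - w + 1L):touchdown_index
  disp <- sqrt(rowSums((p[steps, , drop = FALSE] -
                          p[steps - 1L, , drop = FALSE])^2))
  mean(disp) * rate
}

#' Preprocess a paired trial dataset into normalized curves and events
#'
#' Replicates the study processing chain for every trial of a long-format
#' two-system dataset: the reference system's angle and force channels are
#' low-pass filtered (zero-phase Butterworth, default 20 Hz), the stance
#' phase is detected from the filtered force (> 20 N, longest run), the
#' reference angles are resampled to the test-system rate, and the stance
#' segment of every angle curve of both systems is time-normalized to
#' 101 points, from which the four discrete events are extracted. The test
#' system (which has no force channel) uses the stance window detected on the
#' reference force; its curves are not filtered, mirroring a test system
#' whose filtering happens upstream. Trials whose stance cannot be detected
#' or is too short are excluded and counted, never imputed.
#'
#' @param trials Long-format tibble as produced by [simulate_trials()] (or an
#'   equivalently formatted export): columns `participant`, `direction`,
#'   `intensity`, `repetition`, `system`, `frame`, `time_s`, `force_N`, plus
#'   one column per `joint_plane` angle.
#' @param threshold Stance force threshold in N (default 20).
#' @param cutoff Low-pass cutoff in Hz (default 20); `NA` skips filtering.
#' @param n_points Points per normalized curve (default 101).
#' @param rate_test Test-system rate in Hz the reference is matched to;
#'   `NA` keeps the reference at its native rate (default 85).
#'
#' @return A list of class `preprocessed` with
#'   \describe{
#'     \item{curves}{tibble: trial key, `system`, `joint`, `plane`,
#'       `stance_pct` (0-100), `angle_deg`.}
#'     \item{events}{tibble: trial key, `system`, `joint`, `plane`, `event`
#'       (`touchdown`, `toeoff`, `peak_min`, `peak_max`), `angle_deg`.}
#'     \item{excluded}{tibble of dropped trials with a `reason` column.}
#'   }
#' @export
preprocess_trials <- function(trials, threshold = 20, cutoff = 20,
                              n_points = 101, rate_test = 85) {
  needed <- c("participant", "direction", "intensity", "repetition",
              "system", "frame", "time_s", "force_N")
  if (!all(needed %in% names(trials))) {
    abort(paste("`trials` must contain columns:",
                paste(needed, collapse = ", ")))
  }
  angle_cols <- setdiff(names(trials), needed)
  if (length(angle_cols) == 0) abort("No angle columns found.")

  key_cols <- c("participant", "direction", "intensity", "repetition")
  keys <- distinct(trials[key_cols])

  curve_out <- list()
  event_out <- list()
  excluded <- list()
  stance_grid <- seq(0, 100, length.out = n_points)

  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    tr <- trials[trials$participant == k$participant &
                   trials$direction == k$direction &
                   trials$intensity == k$intensity &
                   trials$repetition == k$repetition, ]
    ref <- tr[tr$system == "reference", ]
    ref <- ref[order(ref$frame), ]
    if (nrow(ref) < 8) {
      excluded[[length(excluded) + 1]] <-
        dplyr::bind_cols(k, reason = "reference recording too short")
      next
    }
    rate_ref <- 1 / median(diff(ref$time_s))

    force <- ref$force_N
    if (!is.na(cutoff)) force <- lowpass_filter(force, cutoff, rate_ref)
    win <- tryCatch(detect_stance(force, threshold), error = function(e) NULL)
    if (is.null(win) || win["end"] - win["start"] < 3) {
      excluded[[length(excluded) + 1]] <-
        dplyr::bind_cols(k, reason = "no usable stance phase")
      next
    }
    t_start <- ref$time_s[win["start"]]
    t_end <- ref$time_s[win["end"]]

    per_system <- list()
    ok <- TRUE
    for (sys in unique(tr$system)) {
      sdat <- tr[tr$system == sys, ]
      sdat <- sdat[order(sdat$frame), ]
      t0 <- sdat$time_s[1]
      span <- sdat$time_s[nrow(sdat)] - t0
      norm <- matrix(NA_real_, n_points, length(angle_cols))
      for (j in seq_along(angle_cols)) {
        v <- sdat[[angle_cols[j]]]
        if (sys == "reference") {
          if (!is.na(cutoff)) v <- lowpass_filter(v, cutoff, rate_ref)
          if (!is.na(rate_test) && abs(rate_ref - rate_test) > 1e-9) {
            v <- resample_to_rate(v, rate_ref, rate_test)
          }
        }
        # stance window in time units -> (fractional) sample indices on the
        # system's own uniform grid
        rate_v <- (length(v) - 1) / span
        i0 <- (t_start - t0) * rate_v + 1
        i1 <- (t_end - t0) * rate_v + 1
        i0 <- max(1, i0)
        i1 <- min(length(v), i1)
        if (i1 - i0 < 3) { ok <- FALSE; break }
        norm[, j] <- time_normalize(v, i0, i1, n_points = n_points)
      }
      if (!ok) break
      per_system[[sys]] <- norm
    }
    if (!ok) {
      excluded[[length(excluded) + 1]] <-
        dplyr::bind_cols(k, reason = "stance segment too short after resampling")
      next
    }

    for (sys in names(per_system)) {
      norm <- per_system[[sys]]
      jp <- strsplit(angle_cols, "_", fixed = TRUE)
      curve_out[[length(curve_out) + 1]] <- dplyr::bind_cols(
        k[rep(1, n_points * length(angle_cols)), ],
        tibble(
          system = sys,
          joint = rep(vapply(jp, `[`, "", 1), each = n_points),
          plane = rep(vapply(jp, `[`, "", 2), each = n_points),
          stance_pct = rep(stance_grid, length(angle_cols)),
          angle_deg = as.numeric(norm)
        )
      )
      ev <- lapply(seq_along(angle_cols), function(j) extract_events(norm[, j]))
      ev <- bind_rows(ev)
      event_out[[length(event_out) + 1]] <- dplyr::bind_cols(
        k[rep(1, 4 * length(angle_cols)), ],
        tibble(
          system = sys,
          joint = rep(vapply(jp, `[`, "", 1), each = 4),
          plane = rep(vapply(jp, `[`, "", 2), each = 4),
          event = rep(c("touchdown", "toeoff", "peak_min", "peak_max"),
                      length(angle_cols)),
          angle_deg = as.numeric(t(as.matrix(ev)))
        )
      )
    }
  }

  structure(
    list(
      curves = bind_rows(curve_out),
      events = bind_rows(event_out),
      excluded = if (length(excluded)) bind_rows(excluded) else
        tibble(participant = integer(), direction = character(),
               intensity = character(), repetition = integer(),
               reason = character())
    ),
    class = "preprocessed"
  )
}

#' @export
print.preprocessed <- function(x, ...) {
  cat("<preprocessed>\n")
  cat("  curves:  ", nrow(x$curves), "rows\n")
  cat("  events:  ", nrow(x$events), "rows\n")
  cat("  excluded:", nrow(x$excluded), "trials\n")
  invisible(x)
}

#' Paired difference waveforms from preprocessed curves
#'
#' Pivots the normalized curves to one row per trial / angle / stance point
#' with the two systems side by side and their difference (test - reference).
#'
#' @param pre A `preprocessed` object (or its `curves` tibble).
#' @return A tibble with `reference`, `test` and `difference` columns.
#' @export
difference_curves <- function(pre) {
  curves <- if (inherits(pre, "preprocessed")) pre$curves else pre
  tidyr::pivot_wider(curves, names_from = "system",
                     values_from = "angle_deg") %>%
    mutate(difference = .data$test - .data$reference)
}

#' Paired event samples from preprocessed events
#'
#' @param pre A `preprocessed` object (or its `events` tibble).
#' @return A tibble with one row per trial / angle / event holding
#'   `reference_value`, `test_value` and `difference` (test - reference).
#' @export
paired_events <- function(pre) {
  events <- if (inherits(pre, "preprocessed")) pre$events else pre
  tidyr::pivot_wider(events, names_from = "system",
                     values_from = "angle_deg") %>%
    rename(reference_value = "reference", test_value = "test") %>%
    mutate(difference = .data$test_value - .data$reference_value)
}
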