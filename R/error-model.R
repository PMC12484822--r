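#' Generative difference structure between test and reference systems
#'
#' Defines how the test (markerless) waveform is derived from the reference
#' (marker-based) waveform:
#'
#' \deqn{test(t) = ref(t) + b_0 + b_1 \, ref(t) + u_i + \epsilon(t)}
#'
#' where `b0` is the fixed bias, `b1` the proportional-bias slope per degree
#' of reference angle, `u_i` a participant random intercept with SD
#' `participant_sd`, and `eps(t)` a smooth residual process with pointwise SD
#' `residual_sd` and squared-exponential correlation over the curve. With all
#' parameters zero the test curve equals the reference curve exactly.
#'
#' @param fixed_bias Systematic offset in degrees (positive means the test
#'   system reads larger angles on average).
#' @param proportional_slope Change in the difference per degree of reference
#'   angle (dimensionless). The study-scale default is -0.3.
#' @param participant_sd SD of the participant random intercept of the
#'   difference, degrees (>= 0).
#' @param residual_sd Pointwise SD of the residual process, degrees (>= 0).
#' @param heteroscedasticity Fractional increase of the residual SD per 10
#'   degrees of absolute reference angle; 0 = homoscedastic.
#' @param residual_family `"normal"`, `"skewed"` (skew-normal, shape delta =
#'   0.9) or `"heavy"` (multivariate t, 4 df), all standardized to the stated
#'   SD. The non-normal families exist to exercise the normality-violation
#'   path of the assumption checks.
#' @param correlation_length Correlation length of the residual process as a
#'   percentage of the curve span (default 10, i.e. smooth kinematic-like
#'   error); 0 gives white noise.
#' @param direction_sd_scale Optional named numeric vector of per-direction
#'   multipliers applied to `residual_sd` (names must be direction labels);
#'   lets the random error grow with cutting angle.
#'
#' @return An object of class `error_model`.
#' @seealso [apply_error_model()], [simulate_trials()]
#' @export
error_model <- function(fixed_bias = 4,
                        proportional_slope = -0.3,
                        participant_sd = 2.5,
                        residual_sd = 5,
                        heteroscedasticity = 0,
                        residual_family = c("normal", "skewed", "heavy"),
                        correlation_length = 10,
                        direction_sd_scale = NULL) {
  residual_family <- match.arg(residual_family)
  if (participant_sd < 0) abort("`participant_sd` must be >= 0.")
  if (residual_sd < 0) abort("`residual_sd` must be >= 0.")
  if (correlation_length < 0) abort("`correlation_length` must be >= 0.")
  if (!is.null(direction_sd_scale)) {
    if (is.null(names(direction_sd_scale)) || any(direction_sd_scale < 0)) {
      abort("`direction_sd_scale` must be a named non-negative numeric vector.")
    }
  }
  structure(
    list(
      fixed_bias = fixed_bias,
      proportional_slope = proportional_slope,
      participant_sd = participant_sd,
      residual_sd = residual_sd,
      heteroscedasticity = heteroscedasticity,
      residual_family = residual_family,
      correlation_length = correlation_length,
      direction_sd_scale = direction_sd_scale
    ),
    class = "error_model"
  )
}

#' An error model under which both systems agree exactly
#'
#' Convenience constructor for the identity difference structure (zero bias,
#' zero slope, zero variance components).
#'
#' @return An `error_model` with all parameters zero.
#' @export
zero_error_model <- function() {
  error_model(
    fixed_bias = 0, proportional_slope = 0,
    participant_sd = 0, residual_sd = 0,
    heteroscedasticity = 0, correlation_length = 10
  )
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model>\n")
  cat(sprintf("  fixed bias: %g deg, proportional slope: %g per deg\n",
              x$fixed_bias, x$proportional_slope))
  cat(sprintf("  participant SD: %g deg, residual SD: %g deg (%s)\n",
              x$participant_sd, x$residual_sd, x$residual_family))
  cat(sprintf("  heteroscedasticity: %g per 10 deg, correlation length: %g%%\n",
              x$heteroscedasticity, x$correlation_length))
  if (!is.null(x$direction_sd_scale)) {
    cat("  residual SD scaling:",
        paste(names(x$direction_sd_scale), "=", x$direction_sd_scale,
              collapse = ", "), "\n")
  }
  invisible(x)
}
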