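#' Limits of agreement from variance components
#'
#' For repeated measures the SD of a single between-system difference
#' decomposes into a between-participant and a within-participant component;
#' the limits of agreement are +/- 1.96 times the adjusted SD
#' `sqrt(variance_between + variance_within)`.
#'
#' @param variance_between Between-participant variance of the differences
#'   (degrees^2, >= 0).
#' @param variance_within Within-participant (residual) variance
#'   (degrees^2, >= 0).
#' @return The half-width of the limits of agreement in degrees.
#' @export
#' @examples
#' limits_of_agreement(0, 1)  # 1.96
#' limits_of_agreement(1, 3)  # 3.92
limits_of_agreement <- function(variance_between, variance_within) {
  if (variance_between < 0 || variance_within < 0) {
    abort("Variance components must be >= 0.")
  }
  1.96 * sqrt(variance_between + variance_within)
}

#' Check the three model assumptions of the extended Bland-Altman analysis
#'
#' Applies the study's dual-condition rules to model residuals:
#' \itemize{
#'   \item normality: Shapiro-Wilk test, violated when p < 0.05;
#'   \item linearity: Spearman rank correlation between fitted values and
#'     residuals, violated when p < 0.05 AND |rho| > 0.3;
#'   \item heteroscedasticity: regression of |residuals| on fitted values,
#'     violated when p < 0.05 AND |slope| > 0.1.
#' }
#' A significant p-value alone never flags linearity or heteroscedasticity;
#' the magnitude condition must hold as well. Constant residuals leave the
#' normality test undefined and are reported as non-violating with a note.
#'
#' @param residuals Numeric vector of model residuals (>= 3 values).
#' @param fitted_values Numeric vector of fitted values, same length.
#' @return A one-row tibble with the underlying statistics
#'   (`shapiro_p`, `spearman_rho`, `spearman_p`, `hetero_slope`, `hetero_p`)
#'   and the flags `normality_violated`, `linearity_violated`,
#'   `heteroscedasticity_violated`, plus a `note` column.
#' @export
check_assumptions <- function(residuals, fitted_values) {
  if (length(residuals) < 3) abort("Need at least 3 residuals.")
  if (length(residuals) != length(fitted_values)) {
    abort("`residuals` and `fitted_values` must have the same length.")
  }
  note <- NA_character_

  res_const <- sd(residuals) == 0 || !is.finite(sd(residuals))
  if (res_const) {
    shapiro_p <- NA_real_
    note <- "constant residuals: normality test undefined, not flagged"
    warn(note)
  } else {
    r <- residuals
    if (length(r) > 5000) {
      # Shapiro-Wilk is defined for at most 5000 values: deterministic
      # evenly spaced subsample
      r <- r[round(seq(1, length(r), length.out = 5000))]
    }
    shapiro_p <- shapiro.test(r)$p.value
  }

  if (res_const || sd(fitted_values) == 0) {
    spearman_rho <- NA_real_
    spearman_p <- NA_real_
    hetero_slope <- NA_real_
    hetero_p <- NA_real_
  } else {
    ct <- suppressWarnings(
      cor.test(fitted_values, residuals, method = "spearman", exact = FALSE)
    )
    spearman_rho <- unname(ct$estimate)
    spearman_p <- ct$p.value
    hfit <- summary(lm(abs(residuals) ~ fitted_values))$coefficients
    if (nrow(hfit) >= 2) {
      hetero_slope <- hfit[2, 1]
      hetero_p <- hfit[2, 4]
    } else {
      hetero_slope <- NA_real_
      hetero_p <- NA_real_
    }
  }

  tibble(
    shapiro_p = shapiro_p,
    spearman_rho = spearman_rho,
    spearman_p = spearman_p,
    hetero_slope = hetero_slope,
    hetero_p = hetero_p,
    normality_violated = isTRUE(shapiro_p < 0.05),
    linearity_violated = isTRUE(spearman_p < 0.05 && abs(spearman_rho) > 0.3),
    heteroscedasticity_violated =
      isTRUE(hetero_p < 0.05 && abs(hetero_slope) > 0.1),
    note = note
  )
}

#' Extended Bland-Altman analysis for repeated measures
#'
#' Fits the between-system difference as a linear mixed-effects model with a
#' participant random intercept and (optionally) a fixed effect for the
#' reference value:
#' \deqn{d_{ij} = \beta_0 + \beta_1 (x_{ij} - \bar x) + u_i + e_{ij}}
#' The fixed-effect line is the bias line; because the reference covariate is
#' centered, `beta0` is the bias at the mean reference value. The limits of
#' agreement are +/- 1.96 times the adjusted SD
#' `sqrt(var(u) + var(e))`, combining the between-participant and residual
#' variance components. Confidence intervals and assumption checks are
#' computed alongside.
#'
#' Degenerate designs are handled explicitly: with a single observation per
#' participant the participant effect is inseparable from the residual and a
#' fixed-effects (classical Bland-Altman) fit is used; with zero variance in
#' the reference values the slope is dropped. Non-convergence of the mixed
#' model triggers one refit with a different optimizer, after which the
#' result is flagged rather than raised.
#'
#' @param data Data frame with columns `participant`, `reference_value`,
#'   `test_value` (a `difference` column is recomputed as test - reference).
#' @param include_slope Include the reference-value fixed effect (default
#'   TRUE). Set FALSE for the classical constant-bias model.
#' @return An object of class `ba_model`; see [tidy.ba_model()] and
#'   [glance.ba_model()] for tabular summaries.
#' @export
#' @examples
#' d <- simulate_event_samples(8, 10, fixed_bias = 5, seed = 1)
#' fit <- fit_extended_ba(d)
#' tidy(fit)
fit_extended_ba <- function(data, include_slope = TRUE) {
  need <- c("participant", "reference_value", "test_value")
  if (!all(need %in% names(data))) {
    abort(paste("`data` must contain columns:", paste(need, collapse = ", ")))
  }
  d <- tibble(
    participant = data$participant,
    ref = data$reference_value,
    diff = data$test_value - data$reference_value
  )
  d <- d[stats::complete.cases(d), ]
  n_part <- n_distinct(d$participant)
  n_obs <- nrow(d)
  if (n_obs < 3) abort("Need at least 3 paired observations.")
  if (n_part < 2) {
    abort("Degenerate design: all differences come from a single participant.")
  }
  mean_ref <- mean(d$ref)
  d$ref_c <- d$ref - mean_ref

  slope_dropped <- FALSE
  if (include_slope && sd(d$ref) == 0) {
    include_slope <- FALSE
    slope_dropped <- TRUE
    warn("Zero variance in reference values: slope dropped (intercept-only).")
  }

  max_per_part <- max(table(d$participant))
  converged <- TRUE
  model_type <- "lmm"
  fit <- NULL

  if (max_per_part >= 2) {
    form <- if (include_slope) diff ~ ref_c + (1 | participant)
            else diff ~ 1 + (1 | participant)
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(form, data = d, REML = TRUE),
        warning = function(w) invokeRestart("muffleWarning"),
        message = function(m) invokeRestart("muffleMessage")
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && length(fit@optinfo$conv$lme4$messages) > 0) {
      refit <- tryCatch(
        withCallingHandlers(
          lme4::lmer(form, data = d, REML = TRUE,
                     control = lme4::lmerControl(optimizer = "bobyqa")),
          warning = function(w) invokeRestart("muffleWarning"),
          message = function(m) invokeRestart("muffleMessage")
        ),
        error = function(e) NULL
      )
      if (!is.null(refit)) fit <- refit
      converged <- length(fit@optinfo$conv$lme4$messages) == 0
    }
    if (is.null(fit)) model_type <- "lm" else model_type <- "lmm"
  } else {
    model_type <- "lm"
  }

  if (model_type == "lmm") {
    fe <- lme4::fixef(fit)
    bias <- unname(fe[1])
    slope <- if (include_slope) unname(fe["ref_c"]) else 0
    vc <- as.data.frame(lme4::VarCorr(fit))
    var_between <- vc$vcov[vc$grp == "participant"]
    var_within <- vc$vcov[vc$grp == "Residual"]
    res <- residuals(fit)
    fit_vals <- fitted(fit)
  } else {
    form <- if (include_slope) diff ~ ref_c else diff ~ 1
    fit <- lm(form, data = d)
    cf <- coef(fit)
    bias <- unname(cf[1])
    slope <- if (include_slope) unname(cf["ref_c"]) else 0
    var_between <- 0
    var_within <- summary(fit)$sigma^2
    if (!is.finite(var_within)) var_within <- 0
    res <- residuals(fit)
    fit_vals <- fitted(fit)
  }

  loa_half <- limits_of_agreement(var_between, var_within)
  assumptions <- check_assumptions(res, fit_vals)

  out <- structure(
    list(
      bias_at_mean_reference = bias,
      bias_slope = slope,
      mean_reference = mean_ref,
      loa_half_width = loa_half,
      loa_lower = bias - loa_half,
      loa_upper = bias + loa_half,
      variance_between = var_between,
      variance_within = var_within,
      n_participants = n_part,
      n_observations = n_obs,
      assumptions = assumptions,
      converged = converged,
      model_type = model_type,
      slope_dropped = slope_dropped,
      data = tibble(participant = d$participant, reference_value = d$ref,
                    difference = d$diff)
    ),
    class = "ba_model"
  )
  out$ci <- loa_confidence_intervals(out)
  out
}

#' Confidence intervals for the bias and the limits of agreement
#'
#' Symmetric 95% intervals based on the repeated-measures variance
#' decomposition: with `n` participants, `N` observations, `m = N/n`
#' observations per participant on average, between-participant variance
#' `sb2` and within variance `sw2`,
#' \deqn{var(\hat d) = s_b^2/n + s_w^2/N}
#' and the variance of the estimated total variance `s^2 = sb2 + sw2` follows
#' from the chi-square sampling distributions of the between- and
#' within-participant mean squares, giving
#' \deqn{var(\widehat{LoA}) = var(\hat d) + 1.96^2 \, var(\hat s)}
#' with `var(s) = var(s^2) / (4 s^2)`. Normal (1.96) quantiles are used
#' throughout, matching the limit multiplier. Interval widths shrink as the
#' number of participants grows.
#'
#' @param x A `ba_model` from [fit_extended_ba()].
#' @return A tibble with rows `bias`, `loa_lower`, `loa_upper` and columns
#'   `estimate`, `conf.low`, `conf.high` (NA when `n_participants < 3`).
#' @export
loa_confidence_intervals <- function(x) {
  stopifnot(inherits(x, "ba_model"))
  n <- x$n_participants
  N <- x$n_observations
  sb2 <- x$variance_between
  sw2 <- x$variance_within
  est <- c(bias = x$bias_at_mean_reference,
           loa_lower = x$loa_lower, loa_upper = x$loa_upper)
  if (n < 3) {
    return(tibble(quantity = names(est), estimate = unname(est),
                  conf.low = NA_real_, conf.high = NA_real_))
  }
  m <- N / n
  var_bias <- sb2 / n + sw2 / N
  s2 <- sb2 + sw2
  if (s2 > 0) {
    var_s2 <- 2 * (sw2 + m * sb2)^2 / (m^2 * (n - 1))
    if (N > n) {
      var_s2 <- var_s2 + 2 * (1 - 1 / m)^2 * sw2^2 / (N - n)
    }
    var_s <- var_s2 / (4 * s2)
  } else {
    var_s <- 0
  }
  var_limit <- var_bias + 1.96^2 * var_s
  half <- 1.96 * sqrt(c(var_bias, var_limit, var_limit))
  tibble(
    quantity = names(est),
    estimate = unname(est),
    conf.low = unname(est) - half,
    conf.high = unname(est) + half
  )
}

#' @export
print.ba_model <- function(x, ...) {
  cat("<ba_model> extended Bland-Altman fit (", x$model_type, ")\n", sep = "")
  cat(sprintf("  bias at mean reference (%.2f deg): %.3f deg\n",
              x$mean_reference, x$bias_at_mean_reference))
  cat(sprintf("  bias slope: %.3f per deg\n", x$bias_slope))
  cat(sprintf("  limits of agreement: %.3f +/- %.3f deg [%.3f, %.3f]\n",
              x$bias_at_mean_reference, x$loa_half_width,
              x$loa_lower, x$loa_upper))
  cat(sprintf("  variance components: between %.3f, within %.3f\n",
              x$variance_between, x$variance_within))
  cat(sprintf("  %d participants, %d observations%s\n",
              x$n_participants, x$n_observations,
              if (x$converged) "" else " (NOT converged)"))
  a <- x$assumptions
  cat(sprintf("  assumption violations: normality %s, linearity %s, heteroscedasticity %s\n",
              a$normality_violated, a$linearity_violated,
              a$heteroscedasticity_violated))
  invisible(x)
}

#' Tidy an extended Bland-Altman fit
#'
#' @param x A `ba_model`.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`bias`, `slope`, `loa_lower`,
#'   `loa_upper`) and columns `estimate`, `conf.low`, `conf.high`.
#' @method tidy ba_model
#' @export
tidy.ba_model <- function(x, ...) {
  ci <- x$ci
  bind_rows(
    ci[ci$quantity == "bias", ] %>% rename(term = "quantity"),
    tibble(term = "slope", estimate = x$bias_slope,
           conf.low = NA_real_, conf.high = NA_real_),
    ci[ci$quantity != "bias", ] %>% rename(term = "quantity")
  )
}

#' One-row summary of an extended Bland-Altman fit
#'
#' @param x A `ba_model`.
#' @param ... Unused.
#' @return A one-row tibble with the variance components, limits, sample
#'   sizes, convergence flag and assumption flags.
#' @method glance ba_model
#' @export
glance.ba_model <- function(x, ...) {
  tibble(
    bias = x$bias_at_mean_reference,
    slope = x$bias_slope,
    loa_half_width = x$loa_half_width,
    variance_between = x$variance_between,
    variance_within = x$variance_within,
    n_participants = x$n_participants,
    n_observations = x$n_observations,
    converged = x$converged,
    model_type = x$model_type,
    normality_violated = x$assumptions$normality_violated,
    linearity_violated = x$assumptions$linearity_violated,
    heteroscedasticity_violated = x$assumptions$heteroscedasticity_violated
  )
}

#' Bland-Altman plot of an extended fit
#'
#' Difference against reference value with the fitted bias line and the
#' limits of agreement centered on the bias at the mean reference value.
#'
#' @param object A `ba_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ba_model
#' @export
autoplot.ba_model <- function(object, ...) {
  d <- object$data
  bias_line <- tibble(
    reference_value = range(d$reference_value),
    difference = object$bias_at_mean_reference +
      object$bias_slope * (range(d$reference_value) - object$mean_reference)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reference_value,
                                  y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = bias_line, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "#b2182b") +
    ggplot2::labs(
      x = "Reference (marker-based) value [deg]",
      y = "Difference test - reference [deg]",
      title = sprintf("Bias %.2f deg, LoA +/- %.2f deg",
                      object$bias_at_mean_reference, object$loa_half_width)
    ) +
    ggplot2::theme_minimal()
}
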