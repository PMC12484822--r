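# Truncated harmonic (Fourier) basis with a linear trend term so that
# non-periodic curves keep their endpoints; evaluated on [0, 1].
.harmonic_basis <- function(n_points, n_harmonics) {
  g <- seq(0, 1, length.out = n_points)
  X <- cbind(1, g)
  for (k in seq_len(n_harmonics)) {
    X <- cbind(X, sin(2 * pi * k * g), cos(2 * pi * k * g))
  }
  X
}

.as_curve_matrix <- function(data, values, id, cluster) {
  if (is.matrix(data)) {
    return(list(curves = data, clusters = cluster))
  }
  stopifnot(is.data.frame(data))
  if (!all(c(values, id) %in% names(data))) {
    abort(sprintf("`data` must contain columns '%s' and '%s'.", id, values))
  }
  d <- arrange(data, .data[[id]])
  ids <- unique(d[[id]])
  n_pt <- nrow(d) / length(ids)
  if (n_pt != round(n_pt)) {
    abort("All curves must be sampled on the same grid.")
  }
  curves <- matrix(d[[values]], nrow = length(ids), ncol = n_pt, byrow = TRUE)
  cl <- NULL
  if (!is.null(cluster) && is.character(cluster) && length(cluster) == 1 &&
      cluster %in% names(d)) {
    cl <- d[[cluster]][!duplicated(d[[id]])]
  } else if (!is.null(cluster)) {
    cl <- cluster
  }
  list(curves = curves, clusters = cl)
}

#' Bootstrapped functional prediction band for an ensemble of curves
#'
#' Computes a prediction band expected to contain a fraction `1 - alpha` of
#' new whole curves from the same process. Each curve is first smoothed with
#' a truncated harmonic basis (plus linear trend). The band is
#' `mean(t) +/- c * SD(t)` on the observed grid, where the multiplier `c` is
#' the upper `1 - alpha` quantile of a bootstrap reference distribution of
#' the maximum standardized deviation: in each of `n_bootstrap` iterations
#' the curves (or, when `dependent = TRUE`, whole participants with all
#' their curves) are resampled with replacement, the resample's mean and SD
#' functions are computed, and the maximum over the grid of
#' `|curve(t) - mean_b(t)| / SD_b(t)` is recorded for one picked curve.
#' Picks alternate between a curve inside the resample and one outside it,
#' which calibrates the band to nominal prediction coverage for a new curve
#' while accounting for estimation error in the mean and SD functions.
#'
#' @param data Either an n x p matrix (one row per curve) or a long data
#'   frame with one row per curve point.
#' @param values,id Column names holding the curve values and the curve
#'   identifier when `data` is a data frame.
#' @param cluster Cluster (participant) assignment: a column name when
#'   `data` is a data frame, or a vector with one entry per curve. Required
#'   when `dependent = TRUE`.
#' @param alpha Significance level (default 0.05 for a 95% band).
#' @param n_bootstrap Bootstrap iterations (default 400).
#' @param dependent Resample clusters rather than individual curves
#'   (default TRUE: trials from one participant are dependent).
#' @param n_harmonics Harmonics in the smoothing basis (default 12).
#' @param seed Optional integer seed for reproducible bands.
#'
#' @return An object of class `prediction_band` with elements `stance_pct`,
#'   `lower`, `upper`, `mean_curve`, `multiplier`, `alpha`, `n_bootstrap`,
#'   `n_curves`, `degenerate`, and the summary metrics `area` (deg.stance%),
#'   `max_width`, `min_width`, `mean_bias`.
#' @seealso [band_metrics()], [autoplot.prediction_band()]
#' @export
#' @examples
#' curves <- gp_curves(30, seed = 1)
#' bd <- bootstrap_band(curves, dependent = FALSE, seed = 2, n_bootstrap = 100)
#' band_metrics(bd)
bootstrap_band <- function(data, values = "difference", id = "curve_id",
                           cluster = NULL, alpha = 0.05, n_bootstrap = 400,
                           dependent = TRUE, n_harmonics = 12, seed = NULL) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (n_bootstrap < 1) abort("`n_bootstrap` must be >= 1.")
  cm <- .as_curve_matrix(data, values, id, cluster)
  Y <- cm$curves
  clusters <- cm$clusters
  n <- nrow(Y)
  p <- ncol(Y)
  if (n < 5) abort("Need at least 5 curves for a prediction band.")
  if (dependent) {
    if (is.null(clusters) || length(clusters) != n) {
      abort("`cluster` (one entry per curve) is required when dependent = TRUE.")
    }
    if (n_distinct(clusters) < 2) {
      abort("Need at least 2 clusters when dependent = TRUE.")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  X <- .harmonic_basis(p, n_harmonics)
  H <- X %*% solve(crossprod(X), t(X))
  S <- Y %*% t(H)  # smoothed curves

  mean_curve <- colMeans(S)
  sd_curve <- sqrt(pmax(colMeans(S^2) - mean_curve^2, 0) * n / (n - 1))

  grid_pct <- seq(0, 100, length.out = p)
  if (all(sd_curve < 1e-12)) {
    band <- .new_band(grid_pct, mean_curve, mean_curve, mean_curve, 0,
                      alpha, n_bootstrap, n, degenerate = TRUE)
    warn("Zero pointwise variance everywhere: degenerate band.")
    return(band)
  }

  cluster_idx <- if (dependent) split(seq_len(n), clusters) else NULL
  n_cl <- if (dependent) length(cluster_idx) else n

  M <- numeric(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    if (dependent) {
      cl_pick <- sample.int(n_cl, n_cl, replace = TRUE)
      idx <- unlist(cluster_idx[cl_pick], use.names = FALSE)
    } else {
      idx <- sample.int(n, n, replace = TRUE)
    }
    nb <- length(idx)
    Sb <- S[idx, , drop = FALSE]
    mb <- colMeans(Sb)
    sb <- sqrt(pmax(colMeans(Sb^2) - mb^2, 0) * nb / max(1, nb - 1))
    # alternate in-bag / out-of-bag picks (see Details)
    pick <- if (b %% 2L == 0L) {
      sample.int(n, 1)
    } else {
      out <- setdiff(seq_len(n), idx)
      if (length(out)) out[sample.int(length(out), 1)] else sample.int(n, 1)
    }
    dev <- abs(S[pick, ] - mb)
    ratio <- ifelse(sb > 0, dev / sb, ifelse(dev > 0, Inf, 0))
    M[b] <- max(ratio)
  }
  M <- M[is.finite(M)]
  if (!length(M)) abort("Bootstrap reference distribution degenerate.")
  c_mult <- sort(M)[ceiling((1 - alpha) * length(M))]

  .new_band(grid_pct, mean_curve - c_mult * sd_curve,
            mean_curve + c_mult * sd_curve, mean_curve, c_mult,
            alpha, n_bootstrap, n, degenerate = FALSE)
}

.new_band <- function(stance_pct, lower, upper, mean_curve, multiplier,
                      alpha, n_bootstrap, n_curves, degenerate) {
  band <- structure(
    list(stance_pct = stance_pct, lower = lower, upper = upper,
         mean_curve = mean_curve, multiplier = multiplier, alpha = alpha,
         n_bootstrap = n_bootstrap, n_curves = n_curves,
         degenerate = degenerate),
    class = "prediction_band"
  )
  m <- band_metrics(band)
  band$area <- m$area
  band$max_width <- m$max_width
  band$min_width <- m$min_width
  band$mean_bias <- m$mean_bias
  band
}

#' Summary metrics of a prediction band
#'
#' The area between the band edges is the trapezoidal integral of
#' `upper - lower` over the stance-percent grid, in deg.stance%; the widths
#' are the pointwise extremes of `upper - lower`; the mean bias is the mean
#' of the mean-difference curve.
#'
#' @param band A `prediction_band`.
#' @return A one-row tibble with `area`, `max_width`, `min_width`,
#'   `mean_bias`.
#' @export
band_metrics <- function(band) {
  stopifnot(inherits(band, "prediction_band"))
  w <- band$upper - band$lower
  dx <- diff(band$stance_pct)
  tibble(
    area = sum((w[-1] + w[-length(w)]) / 2 * dx),
    max_width = max(w),
    min_width = min(w),
    mean_bias = mean(band$mean_curve)
  )
}

#' Fraction of curves lying entirely inside a band
#'
#' @param curves Matrix (one row per curve) or long data frame as accepted by
#'   [bootstrap_band()].
#' @param band A `prediction_band`.
#' @param values,id Column names when `curves` is a data frame.
#' @return Proportion of curves with every point inside `[lower, upper]`.
#' @export
band_coverage <- function(curves, band, values = "difference",
                          id = "curve_id") {
  stopifnot(inherits(band, "prediction_band"))
  Y <- .as_curve_matrix(curves, values, id, NULL)$curves
  inside <- Y >= rep(band$lower, each = nrow(Y)) &
    Y <= rep(band$upper, each = nrow(Y))
  mean(rowSums(!inside) == 0)
}

#' Smooth Gaussian-process curve ensemble
#'
#' Draws independent curves from a Gaussian process with squared-exponential
#' covariance over the stance-percent grid — the reference process used to
#' validate prediction-band coverage.
#'
#' @param n Number of curves.
#' @param n_points Points per curve (default 101).
#' @param sd Marginal SD (degrees).
#' @param correlation_length Correlation length in stance% (default 10).
#' @param mean Mean level (scalar or length-`n_points` vector).
#' @param seed Optional integer seed.
#' @return An `n` x `n_points` matrix, one curve per row.
#' @export
gp_curves <- function(n, n_points = 101, sd = 1, correlation_length = 10,
                      mean = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- seq(0, 100, length.out = n_points)
  d <- outer(g, g, "-")
  K <- sd^2 * exp(-0.5 * (d / correlation_length)^2) +
    diag(1e-8 * max(sd^2, 1), n_points)
  L <- chol(K)
  Z <- matrix(rnorm(n * n_points), n, n_points)
  sweep(Z %*% L, 2, rep_len(mean, n_points), "+")
}

#' @export
print.prediction_band <- function(x, ...) {
  cat(sprintf("<prediction_band> %d%% band from %d curves (%d bootstrap iterations)\n",
              round((1 - x$alpha) * 100), x$n_curves, x$n_bootstrap))
  cat(sprintf("  multiplier: %.3f%s\n", x$multiplier,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  cat(sprintf("  area: %.1f deg.stance%%, width %.2f-%.2f deg, mean bias %.2f deg\n",
              x$area, x$min_width, x$max_width, x$mean_bias))
  invisible(x)
}

#' Tidy a prediction band
#'
#' @param x A `prediction_band`.
#' @param ... Unused.
#' @return A tibble with columns `stance_pct`, `lower`, `mean`, `upper`.
#' @method tidy prediction_band
#' @export
tidy.prediction_band <- function(x, ...) {
  tibble(stance_pct = x$stance_pct, lower = x$lower,
         mean = x$mean_curve, upper = x$upper)
}

#' Plot a prediction band
#'
#' Shaded band with the mean-difference (bias) curve, in the conventional
#' difference-waveform layout.
#'
#' @param object A `prediction_band`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_band
#' @export
autoplot.prediction_band <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stance_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "#b2182b", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), colour = "#b2182b") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linetype = "dotted",
                       linewidth = 0.9) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60",
                        linewidth = 0.3) +
    ggplot2::labs(
      x = "Stance phase [%]", y = "Difference test - reference [deg]",
      title = sprintf("%d%% prediction band (area %.0f deg.stance%%)",
                      round((1 - object$alpha) * 100), object$area)
    ) +
    ggplot2::theme_minimal()
}
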