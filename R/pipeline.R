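#' Analysis configuration for the three-level study pipeline
#'
#' Collects every tunable threshold of the analysis chain with the study
#' defaults: 20 N stance threshold, 20 Hz low-pass cutoff, 101 normalized
#' points, 95% bands from 400 bootstrap iterations, direction-specific speed
#' tertiles.
#'
#' @param threshold Stance force threshold in N.
#' @param cutoff Low-pass cutoff in Hz (`NA` skips filtering).
#' @param n_points Points per normalized curve.
#' @param alpha Significance level of the prediction bands.
#' @param n_bootstrap Bootstrap iterations per band.
#' @param per_direction_tertiles Compute speed tertiles per direction
#'   (default TRUE) rather than pooled.
#' @param dependent Treat trials of one participant as dependent in the
#'   band bootstrap (default TRUE).
#' @param min_observations Minimum paired events to fit one model.
#' @param min_curves Minimum difference curves to fit one band.
#' @param seed Integer seed controlling the band bootstrap streams.
#' @return A list of class `study_config`.
#' @export
study_config <- function(threshold = 20, cutoff = 20, n_points = 101,
                         alpha = 0.05, n_bootstrap = 400,
                         per_direction_tertiles = TRUE, dependent = TRUE,
                         min_observations = 6, min_curves = 5, seed = 1) {
  structure(
    list(threshold = threshold, cutoff = cutoff, n_points = n_points,
         alpha = alpha, n_bootstrap = n_bootstrap,
         per_direction_tertiles = per_direction_tertiles,
         dependent = dependent, min_observations = min_observations,
         min_curves = min_curves, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Tertile boundaries of approach speeds
#'
#' Empirical 1/3 and 2/3 quantiles of the approach speed, either pooled over
#' all trials or per direction.
#'
#' @param speeds Tibble with columns `direction` and `speed_mps`.
#' @param per_direction Compute boundaries per direction (default TRUE).
#' @return A tibble with columns `direction` (`"all"` when pooled), `lower`,
#'   `upper`.
#' @export
tertile_boundaries <- function(speeds, per_direction = TRUE) {
  stopifnot(all(c("direction", "speed_mps") %in% names(speeds)))
  groups <- if (per_direction) split(speeds, speeds$direction)
            else list(all = speeds)
  out <- purrr::imap(groups, function(g, nm) {
    if (nrow(g) < 3) {
      abort(sprintf("Categorization group '%s' has fewer than 3 trials.", nm))
    }
    q <- quantile(g$speed_mps, c(1 / 3, 2 / 3), names = FALSE, type = 7)
    tibble(direction = nm, lower = q[1], upper = q[2])
  })
  bind_rows(out)
}

#' Categorize trials into slow / medium / fast by approach-speed tertiles
#'
#' Empirical tertile boundaries are computed (pooled, or per direction so
#' every direction contributes trials to each category), and each trial is
#' assigned `slow` when its speed is at or below the first boundary, `fast`
#' when strictly above the second, `medium` otherwise.
#'
#' @param speeds Tibble with columns `direction` and `speed_mps` (plus any
#'   identifying columns, which are preserved).
#' @param per_direction Per-direction tertiles (default TRUE).
#' @return `speeds` with an added `speed_category` column; the boundaries
#'   are attached as attribute `"boundaries"`.
#' @export
#' @examples
#' sp <- tibble::tibble(direction = "straight",
#'                      speed_mps = c(4.0, 4.2, 4.5, 5.0, 5.55, 5.8, 6.1))
#' categorize_intensity(sp)$speed_category
categorize_intensity <- function(speeds, per_direction = TRUE) {
  b <- tertile_boundaries(speeds, per_direction)
  if (per_direction) {
    sp <- left_join(speeds, b, by = "direction")
  } else {
    sp <- dplyr::bind_cols(speeds, b[rep(1, nrow(speeds)), c("lower", "upper")])
  }
  sp <- mutate(sp,
    speed_category = dplyr::case_when(
      .data$speed_mps <= .data$lower ~ "slow",
      .data$speed_mps > .data$upper ~ "fast",
      TRUE ~ "medium"
    )
  ) %>% select(-"lower", -"upper")
  attr(sp, "boundaries") <- b
  sp
}

#' Enumerate every model specification of the three-level analysis
#'
#' The analysis runs at three levels: pooled over everything, per direction,
#' and per direction x intensity. Crossing the strata with every joint-plane
#' angle and the four discrete events yields the full set of extended
#' Bland-Altman model specifications — 21 x 9 x 4 = 756 under the default
#' design.
#'
#' @param design A [cod_design()].
#' @param events Character vector of event names (default the four study
#'   events).
#' @return A tibble with columns `level`, `direction`, `intensity`, `joint`,
#'   `plane`, `event`; `"all"` marks an unrestricted dimension.
#' @export
#' @examples
#' nrow(enumerate_strata(cod_design()))  # 756
enumerate_strata <- function(design,
                             events = c("touchdown", "toeoff",
                                        "peak_min", "peak_max")) {
  stopifnot(inherits(design, "cod_design"))
  strata <- bind_rows(
    tibble(level = "pooled", direction = "all", intensity = "all"),
    tibble(level = "direction", direction = design$directions,
           intensity = "all"),
    tidyr::expand_grid(direction = design$directions,
                       intensity = design$intensities) %>%
      mutate(level = "direction_intensity") %>%
      select("level", "direction", "intensity")
  )
  if (length(events) == 0) {
    return(tidyr::expand_grid(strata, design$angles,
                              event = character(0)))
  }
  tidyr::expand_grid(strata, design$angles, event = events)
}

.filter_stratum <- function(data, direction, intensity) {
  if (direction != "all") data <- data[data$direction == direction, ]
  if (intensity != "all") data <- data[data$speed_category == intensity, ]
  data
}

#' Run the full three-level agreement study
#'
#' Orchestrates the complete analysis on a paired trial dataset:
#' preprocessing (filtering, stance detection, 101-point normalization,
#' event extraction), speed-tertile categorization, one extended
#' Bland-Altman model per stratum x angle x event, one bootstrapped
#' prediction band per stratum x angle, and the aggregation into
#' joint / plane / direction / intensity summary tables plus the assumption
#' tally. Deterministic given the configuration seed.
#'
#' @param x A `trial_set` from [simulate_trials()] / [read_trial_set()], or
#'   a list with elements `trials` and `speeds` in the same format.
#' @param config A [study_config()].
#' @param rate_test Test-system rate the reference is matched to (taken from
#'   the design when `x` is a `trial_set`).
#' @return An object of class `cod_study`: a list with tibbles `ba`
#'   (one row per fitted model), `bands` (one row per stratum x angle),
#'   `assumption_tally`, the summary tables `summary_joint`,
#'   `summary_plane`, `summary_direction`, `summary_intensity`, the
#'   `excluded` trials, the skipped (insufficient-data) specifications in
#'   `skipped`, and the `config`.
#' @export
run_study <- function(x, config = study_config(), rate_test = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (inherits(x, "trial_set")) {
    trials <- x$trials
    speeds <- x$speeds
    design <- x$design
    if (is.null(rate_test)) rate_test <- design$rate_test
  } else {
    trials <- x$trials
    speeds <- x$speeds
    if (is.null(rate_test)) rate_test <- NA
    angle_cols <- setdiff(names(trials),
                          c("participant", "direction", "intensity",
                            "repetition", "system", "frame", "time_s",
                            "force_N"))
    jp <- strsplit(angle_cols, "_", fixed = TRUE)
    design <- cod_design(
      n_participants = n_distinct(trials$participant),
      directions = unique(trials$direction),
      intensities = unique(trials$intensity),
      repetitions = max(trials$repetition),
      angles = tibble(joint = vapply(jp, `[`, "", 1),
                      plane = vapply(jp, `[`, "", 2))
    )
  }

  pre <- preprocess_trials(trials, threshold = config$threshold,
                           cutoff = config$cutoff,
                           n_points = config$n_points,
                           rate_test = rate_test)

  key <- c("participant", "direction", "intensity", "repetition")
  speeds_cat <- categorize_intensity(speeds, config$per_direction_tertiles)
  events <- paired_events(pre) %>%
    left_join(speeds_cat[c(key, "speed_category")], by = key)
  curves <- difference_curves(pre) %>%
    left_join(speeds_cat[c(key, "speed_category")], by = key)

  specs <- enumerate_strata(design)

  ba_rows <- vector("list", nrow(specs))
  skipped <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    d <- .filter_stratum(events, sp$direction, sp$intensity)
    d <- d[d$joint == sp$joint & d$plane == sp$plane & d$event == sp$event, ]
    if (nrow(d) < config$min_observations ||
        n_distinct(d$participant) < 2) {
      skipped[[length(skipped) + 1]] <-
        dplyr::bind_cols(sp, reason = "insufficient data")
      next
    }
    fit <- fit_extended_ba(d)
    ba_rows[[i]] <- dplyr::bind_cols(sp, glance(fit),
                                     fit$ci[fit$ci$quantity == "bias",
                                            c("conf.low", "conf.high")])
  }
  ba <- bind_rows(ba_rows)

  band_specs <- distinct(specs[c("level", "direction", "intensity",
                                 "joint", "plane")])
  band_rows <- vector("list", nrow(band_specs))
  for (i in seq_len(nrow(band_specs))) {
    sp <- band_specs[i, ]
    d <- .filter_stratum(curves, sp$direction, sp$intensity)
    d <- d[d$joint == sp$joint & d$plane == sp$plane, ]
    if (nrow(d) == 0) next
    d$curve_id <- interaction(d$participant, d$direction, d$intensity,
                              d$repetition, drop = TRUE)
    n_curves <- n_distinct(d$curve_id)
    if (n_curves < config$min_curves ||
        (config$dependent && n_distinct(d$participant) < 2)) {
      skipped[[length(skipped) + 1]] <-
        dplyr::bind_cols(sp, event = NA_character_,
                         reason = "insufficient curves for band")
      next
    }
    bd <- suppressWarnings(bootstrap_band(
      d, values = "difference", id = "curve_id", cluster = "participant",
      alpha = config$alpha, n_bootstrap = config$n_bootstrap,
      dependent = config$dependent,
      seed = (config$seed + 7919L * i) %% 2147483629L
    ))
    band_rows[[i]] <- dplyr::bind_cols(
      sp,
      tibble(n_curves = n_curves, area = bd$area, max_width = bd$max_width,
             min_width = bd$min_width, mean_bias = bd$mean_bias,
             multiplier = bd$multiplier, degenerate = bd$degenerate)
    )
  }
  bands <- bind_rows(band_rows)

  tally <- if (nrow(ba)) {
    tibble(
      n_models = nrow(ba),
      n_converged = sum(ba$converged),
      n_normality = sum(ba$normality_violated),
      n_linearity = sum(ba$linearity_violated),
      n_heteroscedasticity = sum(ba$heteroscedasticity_violated),
      n_all_met = sum(!ba$normality_violated & !ba$linearity_violated &
                        !ba$heteroscedasticity_violated),
      pct_normality = 100 * mean(ba$normality_violated),
      pct_linearity = 100 * mean(ba$linearity_violated),
      pct_heteroscedasticity = 100 * mean(ba$heteroscedasticity_violated),
      pct_all_met = 100 * mean(!ba$normality_violated &
                                 !ba$linearity_violated &
                                 !ba$heteroscedasticity_violated)
    )
  } else {
    tibble(n_models = 0L)
  }

  structure(
    list(
      ba = ba,
      bands = bands,
      assumption_tally = tally,
      summary_joint = summarise_agreement(ba, bands, "joint"),
      summary_plane = summarise_agreement(ba, bands, "plane"),
      summary_direction = summarise_agreement(
        filter(ba, .data$level == "direction"),
        filter(bands, .data$level == "direction"), "direction"),
      summary_intensity = summarise_agreement(
        filter(ba, .data$level == "direction_intensity"),
        filter(bands, .data$level == "direction_intensity"), "intensity"),
      excluded = pre$excluded,
      skipped = if (length(skipped)) bind_rows(skipped) else tibble(),
      speed_boundaries = attr(speeds_cat, "boundaries"),
      config = config
    ),
    class = "cod_study"
  )
}

#' Aggregate agreement results over a grouping
#'
#' Means of the absolute and signed bias, the limits of agreement and the
#' slope from the model results, joined with mean band area and mean band
#' bias, per level of a grouping column — the structure of the study's
#' summary tables.
#'
#' @param ba Model-results tibble (as in `cod_study$ba`).
#' @param bands Band-results tibble (as in `cod_study$bands`).
#' @param by Grouping column name (e.g. `"joint"`, `"plane"`,
#'   `"direction"`, `"intensity"`).
#' @return A tibble with one row per group.
#' @export
summarise_agreement <- function(ba, bands, by) {
  if (!nrow(ba)) return(tibble())
  ba_sum <- ba %>%
    group_by(across(all_of(by))) %>%
    summarise(
      n_models = n(),
      mean_abs_bias = mean(abs(.data$bias)),
      mean_bias = mean(.data$bias),
      mean_loa = mean(.data$loa_half_width),
      mean_slope = mean(.data$slope),
      .groups = "drop"
    )
  if (nrow(bands) && by %in% names(bands)) {
    band_sum <- bands %>%
      group_by(across(all_of(by))) %>%
      summarise(
        mean_area = mean(.data$area),
        mean_band_bias = mean(.data$mean_bias),
        mean_abs_band_bias = mean(abs(.data$mean_bias)),
        .groups = "drop"
      )
    ba_sum <- left_join(ba_sum, band_sum, by = by)
  }
  ba_sum
}

#' @export
print.cod_study <- function(x, ...) {
  cat("<cod_study>\n")
  cat("  models fitted:", nrow(x$ba),
      sprintf("(%d skipped, %d trials excluded)\n",
              nrow(x$skipped), nrow(x$excluded)))
  if (nrow(x$ba)) {
    t <- x$assumption_tally
    cat(sprintf("  assumptions met in full: %.0f%% (%d/%d); normality violated %.0f%%, linearity %.0f%%, heteroscedasticity %.0f%%\n",
                t$pct_all_met, t$n_all_met, t$n_models, t$pct_normality,
                t$pct_linearity, t$pct_heteroscedasticity))
    cat(sprintf("  mean |bias| %.2f deg, mean LoA +/- %.2f deg\n",
                mean(abs(x$ba$bias)), mean(x$ba$loa_half_width)))
  }
  if (nrow(x$bands)) {
    cat(sprintf("  bands: %d, mean area %.1f deg.stance%%\n",
                nrow(x$bands), mean(x$bands$area)))
  }
  invisible(x)
}

#' One-row summary of a study run
#'
#' @param x A `cod_study`.
#' @param ... Unused.
#' @return A one-row tibble with model counts, assumption percentages and
#'   grand means.
#' @method glance cod_study
#' @export
glance.cod_study <- function(x, ...) {
  dplyr::bind_cols(
    x$assumption_tally,
    tibble(
      mean_abs_bias = if (nrow(x$ba)) mean(abs(x$ba$bias)) else NA_real_,
      mean_loa = if (nrow(x$ba)) mean(x$ba$loa_half_width) else NA_real_,
      mean_area = if (nrow(x$bands)) mean(x$bands$area) else NA_real_,
      n_bands = nrow(x$bands),
      n_skipped = nrow(x$skipped),
      n_excluded_trials = nrow(x$excluded)
    )
  )
}

#' Write study results as delimited tables plus a structured summary
#'
#' Writes `ba_results.tsv`, `band_results.tsv`, per-level model tables
#' (`level1_pooled.tsv`, `level2_direction.tsv`,
#' `level3_direction_intensity.tsv`), the four summary tables, a
#' machine-readable `summary.json` and a `run_log.txt` recording the
#' configuration, exclusions and skipped specifications. Rerunning the same
#' study writes identical files.
#'
#' @param study A `cod_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(study, dir) {
  stopifnot(inherits(study, "cod_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) readr::write_tsv(d, file.path(dir, f))
  w(study$ba, "ba_results.tsv")
  w(study$bands, "band_results.tsv")
  w(filter(study$ba, .data$level == "pooled"), "level1_pooled.tsv")
  w(filter(study$ba, .data$level == "direction"), "level2_direction.tsv")
  w(filter(study$ba, .data$level == "direction_intensity"),
    "level3_direction_intensity.tsv")
  w(study$summary_joint, "summary_joint.tsv")
  w(study$summary_plane, "summary_plane.tsv")
  w(study$summary_direction, "summary_direction.tsv")
  w(study$summary_intensity, "summary_intensity.tsv")
  jsonlite::write_json(
    list(
      assumption_tally = study$assumption_tally,
      summary_joint = study$summary_joint,
      summary_plane = study$summary_plane,
      summary_direction = study$summary_direction,
      summary_intensity = study$summary_intensity,
      speed_boundaries = study$speed_boundaries,
      config = unclass(study$config)
    ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA
  )
  log_lines <- c(
    "kinagree study run",
    sprintf("seed: %d", study$config$seed),
    sprintf("force threshold: %g N, cutoff: %g Hz, points: %d",
            study$config$threshold, study$config$cutoff,
            study$config$n_points),
    sprintf("band alpha: %g, bootstrap iterations: %d, dependent: %s",
            study$config$alpha, study$config$n_bootstrap,
            study$config$dependent),
    sprintf("per-direction tertiles: %s", study$config$per_direction_tertiles),
    sprintf("models fitted: %d", nrow(study$ba)),
    sprintf("specifications skipped: %d", nrow(study$skipped)),
    sprintf("trials excluded in preprocessing: %d", nrow(study$excluded))
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
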