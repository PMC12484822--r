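#' Study design for a paired two-system change-of-direction protocol
#'
#' Describes the factorial collection protocol: participants run a straight
#' line plus four cutting directions, each at three instructed intensities,
#' each repeated a fixed number of times, while two motion-capture systems
#' (a marker-based reference and a markerless test system) record the same
#' joint angles. The default design has 19 participants x 5 directions x
#' 3 intensities x 3 repetitions = 45 trials per participant and 9 angle
#' series (3 joints x 3 planes) per trial.
#'
#' @param n_participants Number of participants (default 19).
#' @param directions Character vector of direction labels. The defaults are
#'   `"straight"`, `"45"`, `"90"`, `"135"`, `"180"` (cutting angle in degrees).
#' @param intensities Character vector of instructed intensity labels.
#' @param repetitions Repetitions per direction x intensity cell (default 3).
#' @param angles Data frame with columns `joint` and `plane` naming the angle
#'   series recorded per trial; defaults to hip/knee/ankle x
#'   sagittal/frontal/transverse.
#' @param rate_reference Sampling rate of the reference system in Hz
#'   (default 200).
#' @param rate_test Sampling rate of the test system in Hz (default 85).
#'
#' @return An object of class `cod_design` (a list with the validated fields).
#' @seealso [design_trials()] for the factorial trial enumeration,
#'   [simulate_trials()] to generate data under a design.
#' @export
#' @examples
#' d <- cod_design(n_participants = 2)
#' nrow(design_trials(d))  # 2 x 5 x 3 x 3 = 90
cod_design <- function(n_participants = 19,
                       directions = c("straight", "45", "90", "135", "180"),
                       intensities = c("slow", "medium", "fast"),
                       repetitions = 3,
                       angles = default_angles(),
                       rate_reference = 200,
                       rate_test = 85) {
  if (length(directions) < 1) abort("`directions` must be non-empty.")
  if (length(intensities) < 1) abort("`intensities` must be non-empty.")
  if (anyDuplicated(directions)) abort("`directions` must be unique.")
  if (anyDuplicated(intensities)) abort("`intensities` must be unique.")
  stopifnot(
    n_participants >= 1, repetitions >= 1,
    rate_reference > 0, rate_test > 0
  )
  angles <- as_tibble(angles)
  if (!all(c("joint", "plane") %in% names(angles)) || nrow(angles) < 1) {
    abort("`angles` must be a data frame with columns `joint` and `plane`.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      directions = as.character(directions),
      intensities = as.character(intensities),
      repetitions = as.integer(repetitions),
      angles = angles,
      rate_reference = rate_reference,
      rate_test = rate_test
    ),
    class = "cod_design"
  )
}

#' Default angle set: three lower-limb joints in three planes
#'
#' @return A tibble with columns `joint` and `plane` (9 rows).
#' @export
default_angles <- function() {
  tidyr::expand_grid(
    joint = c("hip", "knee", "ankle"),
    plane = c("sagittal", "frontal", "transverse")
  )
}

#' Enumerate every trial of a study design
#'
#' Produces the complete factorial enumeration of trial keys
#' (participant x direction x intensity x repetition). The enumeration is
#' deterministic given the design.
#'
#' @param design A [cod_design()].
#' @return A tibble with columns `participant`, `direction`, `intensity`,
#'   `repetition`, one row per trial.
#' @export
#' @examples
#' design_trials(cod_design(n_participants = 1))  # 45 rows
design_trials <- function(design) {
  stopifnot(inherits(design, "cod_design"))
  tidyr::expand_grid(
    participant = seq_len(design$n_participants),
    direction = design$directions,
    intensity = design$intensities,
    repetition = seq_len(design$repetitions)
  )
}

#' @export
print.cod_design <- function(x, ...) {
  cat("<cod_design>\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  directions:  ", paste(x$directions, collapse = ", "), "\n")
  cat("  intensities: ", paste(x$intensities, collapse = ", "), "\n")
  cat("  repetitions: ", x$repetitions,
      sprintf("(%d trials per participant)",
              length(x$directions) * length(x$intensities) * x$repetitions),
      "\n")
  cat("  angles:      ", nrow(x$angles), "joint-plane series\n")
  cat("  rates:       ", x$rate_reference, "Hz reference,",
      x$rate_test, "Hz test\n")
  invisible(x)
}
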