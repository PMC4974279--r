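#' Pinhole eye model
#'
#' Small-angle optical model of the eye used to convert between physical
#' extent on the stimulus screen and visual angle on the retina. With an eye
#' whose optical radius approximately equals its diameter, one radian of
#' visual angle (taken as 57.3 degrees) corresponds to one eye diameter on
#' the retinal surface.
#'
#' @param eye_diameter_mm Eye diameter in mm. Default 13, typical for an
#'   adult cat.
#' @param degrees_per_radian Degrees in one radian of visual angle. Fixed at
#'   57.3 by default; kept configurable because some sources round to 57.
#' @return An object of class `eye_model`.
#' @examples
#' eye_model()
#' @export
eye_model <- function(eye_diameter_mm = 13, degrees_per_radian = 57.3) {
  check_positive(eye_diameter_mm, "eye_diameter_mm")
  check_positive(degrees_per_radian, "degrees_per_radian")
  structure(
    list(eye_diameter_mm = eye_diameter_mm,
         degrees_per_radian = degrees_per_radian),
    class = "eye_model"
  )
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf("<eye_model> diameter %.4g mm, %.4g deg/radian\n",
              x$eye_diameter_mm, x$degrees_per_radian))
  invisible(x)
}

#' Set of gratings used to test one neuron
#'
#' Builds the descriptor table for the gratings of a two- (or three-) grating
#' test: the second grating has half the physical period of the first (twice
#' its spatial frequency at any distance), the third a third of the period.
#'
#' @param period_1f_mm Physical period of the low-frequency grating in mm on
#'   the screen (38 mm for the distant-space protocol, 12 mm for near space).
#' @param n_gratings Number of gratings, 2 or 3.
#' @param orientation_deg Grating orientation (informational).
#' @return A tibble with columns `label` (`"1F"`, `"2F"`, `"3F"`),
#'   `period_mm` and `orientation_deg`.
#' @examples
#' grating_set(38)
#' grating_set(12, n_gratings = 3)
#' @export
grating_set <- function(period_1f_mm = 38, n_gratings = 2,
                        orientation_deg = 0) {
  check_positive(period_1f_mm, "period_1f_mm")
  if (!n_gratings %in% 2:3) {
    abort("`n_gratings` must be 2 or 3.",
          class = "approachscan_invalid_argument")
  }
  k <- seq_len(n_gratings)
  tibble::tibble(
    label = c("1F", "2F", "3F")[k],
    period_mm = period_1f_mm / k,
    orientation_deg = orientation_deg
  )
}

#' Validate the period ratios of a grating set
#'
#' Checks that within one neuron's test set the 2F period equals half the 1F
#' period and the 3F period a third of it, to a relative tolerance.
#'
#' @param gratings A tibble as returned by [grating_set()].
#' @param tol Relative tolerance, default 1%.
#' @return `gratings`, invisibly; errors if the ratios are violated.
#' @export
validate_grating_set <- function(gratings, tol = 0.01) {
  stopifnot(is.data.frame(gratings),
            all(c("label", "period_mm") %in% names(gratings)))
  if (any(gratings$period_mm <= 0)) {
    abort("Grating periods must be positive.",
          class = "approachscan_invalid_argument")
  }
  p1 <- gratings$period_mm[gratings$label == "1F"]
  if (length(p1) != 1) {
    abort("Grating set must contain exactly one 1F grating.",
          class = "approachscan_invalid_argument")
  }
  for (k in 2:3) {
    lab <- paste0(k, "F")
    pk <- gratings$period_mm[gratings$label == lab]
    if (length(pk) == 1 && abs(pk - p1 / k) > tol * p1 / k) {
      abort(sprintf("Period of %s must equal the 1F period / %d (tol %g%%).",
                    lab, k, 100 * tol),
            class = "approachscan_invalid_argument")
    }
  }
  invisible(gratings)
}

grating_period <- function(grating) {
  if (is.numeric(grating)) return(grating)
  if (is.list(grating) && !is.null(grating$period_mm)) {
    return(grating$period_mm)
  }
  abort("`grating` must be a period in mm or have a `period_mm` field.",
        class = "approachscan_invalid_argument")
}

#' Retinal spatial frequency of a physical grating
#'
#' Under the small-angle model, one degree of visual angle subtends
#' `distance_mm / degrees_per_radian` millimetres on the screen, so a grating
#' with physical period `period_mm` viewed from `distance_mm` has spatial
#' frequency `distance_mm / (period_mm * degrees_per_radian)` cycles per
#' degree. The frequency grows linearly with viewing distance and is
#' inversely proportional to the period.
#'
#' @param grating A grating period in mm, or a list/row with a `period_mm`
#'   field (e.g. one row of [grating_set()]).
#' @param distance_mm Eye-to-screen distance in mm (may be a vector).
#' @param eye An [eye_model()].
#' @return Spatial frequency in cycles per degree.
#' @examples
#' spatial_frequency(12, 1030)  # ~1.5 c/deg
#' spatial_frequency(38, 200)   # ~0.09 c/deg
#' @export
spatial_frequency <- function(grating, distance_mm, eye = eye_model()) {
  period_mm <- grating_period(grating)
  check_positive(period_mm, "period_mm")
  check_positive(distance_mm, "distance_mm")
  distance_mm / (period_mm * eye$degrees_per_radian)
}

#' Distance at which a grating reaches a given spatial frequency
#'
#' Inverse of [spatial_frequency()]: the eye-to-screen distance at which a
#' grating of physical period `period_mm` attains `sf_cpd` cycles per degree.
#' For a purely frequency-tuned cell with optimum `sf_cpd` this is the
#' predicted location of its response maximum, and halving the period halves
#' the predicted distance.
#'
#' @param sf_cpd Spatial frequency in cycles per degree.
#' @inheritParams spatial_frequency
#' @return Distance in mm.
#' @examples
#' sf_peak_distance(0.7, 38)  # ~1524 mm
#' @export
sf_peak_distance <- function(sf_cpd, grating, eye = eye_model()) {
  period_mm <- grating_period(grating)
  check_positive(sf_cpd, "sf_cpd")
  check_positive(period_mm, "period_mm")
  sf_cpd * period_mm * eye$degrees_per_radian
}

#' Retinal drift speed of a stationary scene during approach
#'
#' When the observer moves toward the screen at `trolley_speed_mm_s`, the
#' projection of an off-axis point drifts radially over the retina. For a
#' receptive field at eccentricity `eccentricity_mm` (measured on the screen)
#' and eye-to-screen distance `distance_mm`, the drift speed on the retinal
#' surface is `V2 * E * D1 / D2^2` mm/s, where `D1` is the eye diameter.
#' Conversion to degrees per second divides by the retinal extent of one
#' degree, i.e. multiplies by `degrees_per_radian / D1` (about 4.4 deg/s per
#' mm/s for the default eye). Drift accelerates sharply as the screen is
#' approached (quadratic in 1/D2).
#'
#' @param trolley_speed_mm_s Approach speed V2 in mm/s (>= 0).
#' @param eccentricity_mm Distance of the receptive field from the centre of
#'   gaze, measured on the screen, in mm (>= 0).
#' @param distance_mm Eye-to-screen distance in mm (> 0); vectorised.
#' @param eye An [eye_model()].
#' @return A tibble with columns `distance_mm`, `mm_per_s`, `deg_per_s`.
#' @examples
#' retinal_drift_speed(10, 493, c(2800, 600, 200))
#' @export
retinal_drift_speed <- function(trolley_speed_mm_s, eccentricity_mm,
                                distance_mm, eye = eye_model()) {
  check_nonnegative(trolley_speed_mm_s, "trolley_speed_mm_s")
  check_nonnegative(eccentricity_mm, "eccentricity_mm")
  check_positive(distance_mm, "distance_mm")
  mm_per_s <- trolley_speed_mm_s * eccentricity_mm * eye$eye_diameter_mm /
    distance_mm^2
  tibble::tibble(
    distance_mm = distance_mm,
    mm_per_s = mm_per_s,
    deg_per_s = mm_per_s * eye$degrees_per_radian / eye$eye_diameter_mm
  )
}

#' Convert angular eccentricity to screen millimetres
#'
#' Convenience converter for specifying receptive-field eccentricity as a
#' visual angle: the on-screen offset of a point at `ecc_deg` degrees from
#' the centre of gaze is `distance_mm * tan(ecc_deg)`.
#'
#' @param ecc_deg Eccentricity in degrees.
#' @param distance_mm Eye-to-screen distance in mm.
#' @return Eccentricity on the screen in mm.
#' @export
screen_eccentricity_mm <- function(ecc_deg, distance_mm) {
  check_nonnegative(ecc_deg, "ecc_deg")
  check_positive(distance_mm, "distance_mm")
  distance_mm * tan(ecc_deg * pi / 180)
}

#' Predicted maximum position after frequency doubling
#'
#' For a purely spatial-frequency-tuned cell, doubling the grating's spatial
#' frequency moves the response maximum half way closer to the screen: the
#' predicted 2F maximum lies at half the 1F maximum distance, equivalent to a
#' 100% value of the shift statistic.
#'
#' @param m1_distance_mm Distance of the 1F response maximum from the screen
#'   (mm, > 0).
#' @return Predicted 2F maximum distance in mm.
#' @examples
#' expected_shift_distance(2200)  # 1100
#' @export
expected_shift_distance <- function(m1_distance_mm) {
  check_positive(m1_distance_mm, "m1_distance_mm")
  m1_distance_mm / 2
}
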