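# Oxygen microsensor reductions: three-point calibration, probe depth
# geometry and slice-core localization.

#' Three-point O2 sensor calibration
#'
#' Linear least squares mapping raw sensor signal to O2 concentration
#' from recording solutions saturated at known O2 fractions (0%, 20%,
#' 95%). Warns (does not error) when r^2 < 0.99.
#'
#' @param points `data.frame` with columns `o2_fraction` (%, the known
#'   saturation levels) and `raw_signal`; a `concentration` column may
#'   give the target scale, otherwise `o2_fraction` itself is used
#'   (% air saturation convention).
#' @return List of class `sensor_calibration`: `slope`, `intercept`
#'   (raw -> concentration), `r2`, `points`.
#' @export
calibrate_o2 <- function(points) {
  if (!all(c("o2_fraction", "raw_signal") %in% names(points)))
    stop_field("points", "needs columns `o2_fraction` and `raw_signal`")
  if (nrow(points) < 3)
    stop("three-point calibration needs >= 3 points", call. = FALSE)
  if (anyDuplicated(points$o2_fraction))
    stop("duplicate saturation levels in calibration", call. = FALSE)
  target <- if ("concentration" %in% names(points)) points$concentration
  else points$o2_fraction
  fit <- lm(target ~ raw_signal, data = points)
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (r2 < 0.99)
    warning(sprintf("sensor calibration r^2 = %.4f (< 0.99)", r2),
            call. = FALSE)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r2, points = points),
            class = "sensor_calibration")
}

#' Apply a sensor calibration
#'
#' @param calibration A [calibrate_o2()] result.
#' @param raw_signal Raw sensor readings.
#' @return Calibrated concentrations.
#' @export
apply_calibration <- function(calibration, raw_signal) {
  calibration$intercept + calibration$slope * raw_signal
}

#' Sensor drift check between pre- and post-experiment calibrations
#'
#' Sensors are calibrated before and after each experiment; a slope
#' change beyond `max_rel` (default 10%) flags drift.
#'
#' @param pre,post [calibrate_o2()] results.
#' @param max_rel Maximal tolerated relative slope change.
#' @return List: `drift` (logical), `rel_change`.
#' @export
calibration_drift <- function(pre, post, max_rel = 0.1) {
  rel <- abs(post$slope - pre$slope) / abs(pre$slope)
  list(drift = rel > max_rel, rel_change = rel)
}

#' Vertical depth axis of an angled probe
#'
#' The sensor advances in `step_advance_um` steps along its axis at
#' `angle_deg` from the horizontal, so each step descends
#' `step_advance_um * sin(angle)` vertically (~16 um for 20 um steps at
#' 55 degrees).
#'
#' @param n_steps Number of steps.
#' @param step_advance_um Advance per step, um.
#' @param angle_deg Probe angle from the horizontal, in (0, 90].
#' @return Cumulative vertical depths (um) after steps 1..n_steps.
#' @export
#' @examples
#' depth_axis(1)       # 16.38 um: the printed ~16 um per step
#' max(depth_axis(6))  # 98.3 um
depth_axis <- function(n_steps, step_advance_um = 20, angle_deg = 55) {
  n_steps <- check_count(n_steps, "n_steps", lower = 1)
  check_scalar(step_advance_um, "step_advance_um", lower = 0,
               strict_lower = TRUE)
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg > 90)
    stop_field("angle_deg", "must lie in (0, 90]")
  seq_len(n_steps) * step_advance_um * sin(angle_deg * pi / 180)
}

#' Locate the slice core of an O2 depth profile
#'
#' The core is the profile point of minimal O2 concentration. Ties
#' resolve to the shallowest point with a degeneracy flag; a minimum at
#' the deepest point is flagged as possibly not reached.
#'
#' @param profile `data.frame` with a `concentration` column (e.g. from
#'   [gen_o2_profile()]).
#' @return List: `core_index` (1-based), `concentration`, `flag`
#'   (`"none"`, `"tie"`, `"boundary"`).
#' @export
locate_slice_core <- function(profile) {
  conc <- profile$concentration
  if (!length(conc)) stop("empty profile", call. = FALSE)
  i <- which.min(conc)  # first index on ties
  flag <- "none"
  if (sum(conc == conc[i]) > 1) flag <- "tie"
  else if (i == length(conc)) flag <- "boundary"
  list(core_index = i, concentration = conc[i], flag = flag)
}
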