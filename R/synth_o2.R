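# Synthetic oxygen microsensor depth profiles with a planted
# concentration minimum at the slice core.

#' Specification of a synthetic O2 depth profile
#'
#' @param n_steps Number of sensor advances.
#' @param step_advance_um Advance per step along the sensor axis, um.
#' @param angle_deg Sensor angle from the horizontal, degrees; the
#'   vertical depth per step is `step_advance_um * sin(angle)` (~16 um
#'   for the default 20 um at 55 degrees).
#' @param surface_conc Concentration at the slice surface (% air
#'   saturation or uM, caller's convention).
#' @param core_conc Minimal concentration at the core (< surface).
#' @param core_step_index Step (1-based) of the planted minimum.
#' @param noise_sd Additive Gaussian noise.
#' @param seed Integer seed.
#' @return List of class `o2_profile_spec`.
#' @export
o2_profile_spec <- function(n_steps, step_advance_um = 20, angle_deg = 55,
                            surface_conc = 150, core_conc = 60,
                            core_step_index = NULL, noise_sd = 0,
                            seed = 1) {
  check_count(n_steps, "n_steps", lower = 2)
  check_scalar(step_advance_um, "step_advance_um", lower = 0,
               strict_lower = TRUE)
  check_scalar(angle_deg, "angle_deg", lower = 0, upper = 90,
               strict_lower = TRUE)
  check_scalar(surface_conc, "surface_conc", lower = 0)
  check_scalar(core_conc, "core_conc", lower = 0)
  if (core_conc > surface_conc)
    stop_field("core_conc", "must not exceed surface_conc")
  if (is.null(core_step_index)) core_step_index <- ceiling(n_steps * 0.7)
  core_step_index <- check_count(core_step_index, "core_step_index",
                                 lower = 1)
  if (core_step_index > n_steps)
    stop_field("core_step_index", "must be <= n_steps")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_count(seed, "seed")
  structure(list(n_steps = n_steps, step_advance_um = step_advance_um,
                 angle_deg = angle_deg, surface_conc = surface_conc,
                 core_conc = core_conc, core_step_index = core_step_index,
                 noise_sd = noise_sd, seed = seed),
            class = "o2_profile_spec")
}

#' Generate a synthetic O2 depth profile
#'
#' The noiseless profile is a parabola in step index with its unique
#' minimum (`core_conc`) at `core_step_index`, reaching `surface_conc`
#' at the far end of the longer branch; the depth axis follows the probe
#' geometry. Flat profiles (surface == core) are permitted and flagged
#' downstream by [locate_slice_core()].
#'
#' @param spec An [o2_profile_spec()].
#' @return `data.frame` (class `o2_profile`) with columns `step_index`,
#'   `depth_um`, `concentration`.
#' @export
#' @examples
#' pr <- gen_o2_profile(o2_profile_spec(6, core_step_index = 4))
#' locate_slice_core(pr)$core_index  # 4
gen_o2_profile <- function(spec) {
  i <- seq_len(spec$n_steps)
  c0 <- spec$core_step_index
  w <- max(c0 - 1, spec$n_steps - c0)
  conc <- if (w == 0 || spec$surface_conc == spec$core_conc)
    rep(spec$core_conc, spec$n_steps)
  else
    spec$core_conc + (spec$surface_conc - spec$core_conc) *
      ((i - c0) / w)^2
  with_private_seed(spec$seed, {
    conc <- conc + rnorm(spec$n_steps, 0, spec$noise_sd)
    data.frame(step_index = i,
               depth_um = depth_axis(spec$n_steps, spec$step_advance_um,
                                     spec$angle_deg),
               concentration = conc) |>
      structure(class = c("o2_profile", "data.frame"))
  })
}
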