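# Parameterization of the reduced single-neuron energy-metabolism model.
#
# The model tracks cytosolic and mitochondrial compartments with lumped
# reactions: GLUT glucose transport, two-stage glycolysis (ATP-investing
# upper stage and ATP/NADH-producing lower stage, composed at quasi-steady
# state into one flux), reversible LDH, H+-coupled MCT2 lactate transport,
# Ca-modulated pyruvate oxidation + citric acid cycle, malate-aspartate and
# glycerol-3-phosphate NADH shuttles, NADH- and FADH2-fed respiratory-chain
# proton pumping with saturable O2 dependence, proton-motive-force-driven
# ATP synthase, the adenine nucleotide translocator, a proton leak, and
# mitochondrial Ca2+ treated as a fast membrane-potential-driven modulator.
# Units: mM and seconds; mV for membrane potential; mmHg for O2.

#' Default calibrated model parameters
#'
#' Returns the frozen default parameter set of the reduced neuronal
#' energy-metabolism model, read from the versioned configuration file
#' shipped with the package (`inst/params/default_parameters.yaml`).
#'
#' The calibration protocol is: (1) parameters scaled so that the steady
#' state on 5 mM glucose / 0 lactate at low energy demand holds cytosolic
#' ATP near 2.5 mM with realistic fluxes; (2) the three named demand levels
#' are fixed fractions (10 / 45 / 85 %) of the model's maximal steady ATP
#' turnover on 5 mM glucose (frozen in the file as `t_max_atp`); (3) MCT2
#' capacity and the effective GLUT half-saturation were set once so that
#' the glucose-fitness thresholds emerge from the model rather than being
#' imposed. See the methods vignette.
#'
#' @param file Optional path to an alternative YAML parameter file.
#' @return A named list of class `neuro_params`. All entries are positive
#'   scalars (rate capacities in mM/s, half-saturations in mM, potentials
#'   in mV, conserved pool totals in mM).
#' @export
#' @examples
#' p <- default_parameters()
#' p$pool_a_cyt  # total cytosolic adenine pool (mM)
default_parameters <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("params", "default_parameters.yaml",
                        package = "neuroenergetics", mustWork = TRUE)
  p <- yaml::read_yaml(file)
  p <- lapply(p, as.numeric)
  validate_parameters(p)
  structure(p, class = "neuro_params")
}

validate_parameters <- function(p) {
  required <- c(
    "pool_a_cyt", "pool_a_mit", "pool_n_cyt", "pool_n_mit", "pool_fad",
    "glut_vmax", "glut_km",
    "gly_vmax", "gly_km_glc", "gly_km_atp", "gly_km_adp", "gly_km_nad",
    "ldh_k", "ldh_keq",
    "mct_vmax", "mct_km",
    "tca_vmax", "tca_km_pyr", "tca_km_nad", "tca_ca_act", "tca_ca_km",
    "mas_vmax", "mas_km_nadh", "mas_km_nad",
    "g3p_vmax", "g3p_km_nadh", "g3p_km_fad",
    "c1_vmax", "c1_km", "c2_vmax", "c2_km", "km_o2",
    "chain_psi_half", "chain_psi_slope",
    "syn_vmax", "syn_km_adp", "syn_pmf_half", "syn_pmf_slope",
    "ant_vmax", "ant_km", "ant_psi_half", "ant_psi_slope",
    "leak_g", "leak_scale", "c_psi",
    "ph_frac", "ph_relax", "ph_cyt",
    "ca_max", "ca_psi_half", "ca_psi_slope", "ca_relax",
    "h_per_nadh", "h_per_fadh2", "h_per_atp_syn",
    "atpase_km", "t_max_atp",
    "demand_frac_low", "demand_frac_intermediate", "demand_frac_high")
  missing <- setdiff(required, names(p))
  if (length(missing))
    stop("parameter file is missing entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- names(p)[!vapply(p, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("parameters must be positive finite scalars; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Write a parameter set to YAML
#'
#' @param params A `neuro_params` list.
#' @param file Output path.
#' @export
write_parameters <- function(params, file) {
  yaml::write_yaml(lapply(unclass(params), as.numeric), file)
  invisible(file)
}

#' External substrate conditions
#'
#' Bundles the extracellular milieu seen by the model neuron. Oxygen
#' defaults to 60 mmHg, a saturating level relative to the respiratory
#' chain's O2 half-saturation (~1 mmHg), and extracellular pH to 7.3
#' (H+-cotransport driving force of MCT2; cytosolic pH is fixed at 7.0).
#'
#' @param glc_ext Extracellular glucose, mM.
#' @param lac_ext Extracellular lactate, mM.
#' @param po2 Extracellular oxygen partial pressure, mmHg.
#' @param ph_ext Extracellular pH.
#' @return A list of class `neuro_conditions`.
#' @export
external_conditions <- function(glc_ext, lac_ext, po2 = 60, ph_ext = 7.3) {
  check_scalar(glc_ext, "glc_ext", lower = 0)
  check_scalar(lac_ext, "lac_ext", lower = 0)
  check_scalar(po2, "po2", lower = 0, strict_lower = TRUE)
  check_scalar(ph_ext, "ph_ext", lower = 6, upper = 8.5)
  structure(list(glc_ext = glc_ext, lac_ext = lac_ext,
                 po2 = po2, ph_ext = ph_ext),
            class = "neuro_conditions")
}

#' Energy-demand specification
#'
#' ATP consumption is modelled as a single Michaelis-Menten ATPase,
#' v = k * ATP / (ATP + Km); raising the rate constant `k` raises energy
#' demand.
#'
#' @param k Maximal ATP hydrolysis rate, mM/s.
#' @param km_atp Half-saturation of the ATPase, mM.
#' @return A list of class `neuro_demand`.
#' @export
demand_spec <- function(k, km_atp) {
  check_scalar(k, "k", lower = 0)
  check_scalar(km_atp, "km_atp", lower = 0, strict_lower = TRUE)
  structure(list(k = k, km_atp = km_atp), class = "neuro_demand")
}

#' ATPase rate law
#'
#' Hyperbolic energy-demand rate: `k * atp / (atp + km_atp)`. Monotone
#' increasing in ATP and bounded by `k`.
#'
#' @param atp Cytosolic ATP concentration, mM (non-negative).
#' @param demand A [demand_spec()].
#' @return ATP hydrolysis rate, mM/s.
#' @export
#' @examples
#' atpase_rate(0.5, demand_spec(k = 1, km_atp = 0.5))  # half-saturation: 0.5
atpase_rate <- function(atp, demand) {
  if (!is.numeric(atp) || any(!is.finite(atp)) || any(atp < 0))
    stop("`atp` must be finite and non-negative", call. = FALSE)
  demand$k * atp / (atp + demand$km_atp)
}

#' Named energy-demand levels
#'
#' Maps the three named demand levels to ATPase rate constants defined as
#' fixed fractions of the model's maximal steady ATP turnover on 5 mM
#' glucose / 0 lactate (frozen in the parameter file as `t_max_atp`):
#' 10% (low), 45% (intermediate) and 85% (high).
#'
#' @param level One of `"low"`, `"intermediate"`, `"high"`.
#' @param params Model parameters.
#' @return A [demand_spec()].
#' @export
#' @examples
#' p <- default_parameters()
#' demand_level("low", p)$k < demand_level("high", p)$k
demand_level <- function(level = c("low", "intermediate", "high"),
                         params = default_parameters()) {
  level <- match.arg(level)
  frac <- switch(level,
                 low = params$demand_frac_low,
                 intermediate = params$demand_frac_intermediate,
                 high = params$demand_frac_high)
  demand_spec(k = frac * params$t_max_atp, km_atp = params$atpase_km)
}

#' Maximal steady ATP turnover on glucose
#'
#' Recomputes the calibration quantity behind the named demand levels:
#' the largest steady-state ATPase flux attainable on 5 mM glucose / 0
#' lactate over a grid of demand rate constants. The frozen value lives in
#' the parameter file (`t_max_atp`); this function exists so the
#' calibration can be audited.
#'
#' @param params Model parameters.
#' @param k_grid Demand rate constants to scan, mM/s.
#' @return Maximal steady ATPase flux, mM/s.
#' @export
max_atp_turnover <- function(params = default_parameters(),
                             k_grid = c(0.25, 0.5, 0.75, 1, 1.5, 2, 3)) {
  cond <- external_conditions(glc_ext = 5, lac_ext = 0)
  best <- 0
  for (k in k_grid) {
    ss <- steady_state(params, cond, demand_spec(k, params$atpase_km))
    best <- max(best, ss$fluxes$j_atpase)
  }
  best
}
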