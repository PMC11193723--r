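# Right-hand side of the reduced neuronal energy-metabolism ODE system.

STATE_FIELDS <- c("glc_cyt", "pyr_cyt", "lac_cyt",
                  "atp_cyt", "adp_cyt", "nadh_cyt", "nad_cyt",
                  "atp_mit", "adp_mit", "nadh_mit", "nad_mit",
                  "fadh2_equiv_mit", "dpsi", "dph", "ca_mit")

# Independent states solved for at steady state; the partner of each
# conserved pair is reconstructed from the pool totals.
REDUCED_FIELDS <- c("glc_cyt", "pyr_cyt", "lac_cyt", "atp_cyt", "nadh_cyt",
                    "atp_mit", "nadh_mit", "fadh2_equiv_mit",
                    "dpsi", "dph", "ca_mit")

# mV per pH unit at ~310 K, used to fold the transmembrane pH gradient
# into the proton-motive force.
Z_MV_PER_PH <- 61.5

#' Construct a full metabolic state
#'
#' @param ... Named state fields (see Details); unspecified conserved-pool
#'   partners are filled from the pool totals in `params`.
#' @param params Model parameters (supplies pool totals).
#' @details Fields: `glc_cyt`, `pyr_cyt`, `lac_cyt`, `atp_cyt`, `adp_cyt`,
#'   `nadh_cyt`, `nad_cyt`, `atp_mit`, `adp_mit`, `nadh_mit`, `nad_mit`,
#'   `fadh2_equiv_mit` (all mM), `dpsi` (mV), `dph` (pH units), `ca_mit`
#'   (uM). Adenine and NAD pools per compartment are conserved.
#' @return Named numeric vector of class `neuro_state`.
#' @export
metabolic_state <- function(..., params = default_parameters()) {
  args <- list(...)
  unknown <- setdiff(names(args), STATE_FIELDS)
  if (length(unknown))
    stop("unknown state fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  s <- c(glc_cyt = 0.5, pyr_cyt = 0.05, lac_cyt = 1,
         atp_cyt = 2.5, adp_cyt = NA, nadh_cyt = 0.005, nad_cyt = NA,
         atp_mit = 2.5, adp_mit = NA, nadh_mit = 0.15, nad_mit = NA,
         fadh2_equiv_mit = 0.05, dpsi = 150, dph = 0.4, ca_mit = 0.5)
  for (nm in names(args)) s[nm] <- args[[nm]]
  if (is.na(s["adp_cyt"])) s["adp_cyt"] <- params$pool_a_cyt - s["atp_cyt"]
  if (is.na(s["nad_cyt"])) s["nad_cyt"] <- params$pool_n_cyt - s["nadh_cyt"]
  if (is.na(s["adp_mit"])) s["adp_mit"] <- params$pool_a_mit - s["atp_mit"]
  if (is.na(s["nad_mit"])) s["nad_mit"] <- params$pool_n_mit - s["nadh_mit"]
  if (any(s[setdiff(STATE_FIELDS, c("dpsi", "dph"))] < 0))
    stop("state concentrations must be non-negative", call. = FALSE)
  structure(s[STATE_FIELDS], class = "neuro_state")
}

# All reaction fluxes at a given state. Returns a named list in mM/s
# (proton fluxes in mM charge/s).
model_fluxes <- function(state, params, cond, demand) {
  p <- params
  s <- as.list(state)
  fad <- max(p$pool_fad - s$fadh2_equiv_mit, 0)

  # GLUT: saturable gradient-driven carrier (net influx >= 0 whenever
  # extracellular glucose exceeds cytosolic).
  v_glut <- p$glut_vmax *
    (cond$glc_ext / (cond$glc_ext + p$glut_km) -
     s$glc_cyt / (s$glc_cyt + p$glut_km))

  # Glycolysis, upper and lower stages composed at quasi-steady state:
  # one flux per glucose needing ATP (hexokinase/PFK), ADP and NAD+.
  v_gly <- p$gly_vmax *
    s$glc_cyt / (s$glc_cyt + p$gly_km_glc) *
    s$atp_cyt / (s$atp_cyt + p$gly_km_atp) *
    s$adp_cyt / (s$adp_cyt + p$gly_km_adp) *
    s$nad_cyt / (s$nad_cyt + p$gly_km_nad)

  # LDH: reversible mass action toward its equilibrium constant
  # (positive direction pyruvate + NADH -> lactate + NAD+).
  v_ldh <- p$ldh_k *
    (s$pyr_cyt * s$nadh_cyt - s$lac_cyt * s$nad_cyt / p$ldh_keq)

  # MCT2: H+-coupled carrier; the proton gradient (pH_ext 7.3 vs
  # cytosolic 7.0) scales the outward-facing lactate term. Positive =
  # uptake into the cytosol.
  lac_out_eff <- cond$lac_ext * 10^(p$ph_cyt - cond$ph_ext)
  v_mct <- p$mct_vmax *
    (lac_out_eff / (lac_out_eff + p$mct_km) -
     s$lac_cyt / (s$lac_cyt + p$mct_km))

  # Pyruvate oxidation + citric acid cycle, lumped and Ca-activated.
  f_ca <- 1 + p$tca_ca_act * s$ca_mit / (s$ca_mit + p$tca_ca_km)
  v_tca <- p$tca_vmax *
    s$pyr_cyt / (s$pyr_cyt + p$tca_km_pyr) *
    s$nad_mit / (s$nad_mit + p$tca_km_nad) * f_ca

  # NADH shuttles into the matrix.
  v_mas <- p$mas_vmax *
    s$nadh_cyt / (s$nadh_cyt + p$mas_km_nadh) *
    s$nad_mit / (s$nad_mit + p$mas_km_nad)
  v_g3p <- p$g3p_vmax *
    s$nadh_cyt / (s$nadh_cyt + p$g3p_km_nadh) *
    fad / (fad + p$g3p_km_fad)

  # Respiratory chain: NADH- and FADH2-fed proton pumping, Michaelis O2
  # dependence, exponential-sigmoid back-pressure from the membrane
  # potential.
  o2f <- cond$po2 / (cond$po2 + p$km_o2)
  psif <- 1 / (1 + exp((s$dpsi - p$chain_psi_half) / p$chain_psi_slope))
  v_c1 <- p$c1_vmax * s$nadh_mit / (s$nadh_mit + p$c1_km) * o2f * psif
  v_c2 <- p$c2_vmax * s$fadh2_equiv_mit /
    (s$fadh2_equiv_mit + p$c2_km) * o2f * psif

  # ATP synthase driven by the proton-motive force; ANT exchange driven
  # by the membrane potential (electrogenic, 1 charge per exchange).
  pmf <- s$dpsi + Z_MV_PER_PH * s$dph
  v_syn <- p$syn_vmax * s$adp_mit / (s$adp_mit + p$syn_km_adp) /
    (1 + exp(-(pmf - p$syn_pmf_half) / p$syn_pmf_slope))
  v_ant <- p$ant_vmax *
    s$atp_mit / (s$atp_mit + p$ant_km) *
    s$adp_cyt / (s$adp_cyt + p$ant_km) /
    (1 + exp(-(s$dpsi - p$ant_psi_half) / p$ant_psi_slope))

  v_leak <- p$leak_g * (exp(s$dpsi / p$leak_scale) - 1)
  v_atpase <- demand$k * s$atp_cyt / (s$atp_cyt + demand$km_atp)

  # Mitochondrial Ca2+: fast quasi-steady modulator driven by dpsi.
  ca_ss <- p$ca_max / (1 + exp(-(s$dpsi - p$ca_psi_half) / p$ca_psi_slope))
  v_ca <- p$ca_relax * (ca_ss - s$ca_mit)  # uM/s

  list(v_glut = v_glut, v_gly = v_gly, v_ldh = v_ldh, v_mct = v_mct,
       v_tca = v_tca, v_mas = v_mas, v_g3p = v_g3p,
       v_c1 = v_c1, v_c2 = v_c2, v_syn = v_syn, v_ant = v_ant,
       v_leak = v_leak, v_atpase = v_atpase, v_ca = v_ca, pmf = pmf)
}

#' Time derivatives of the metabolic state
#'
#' Evaluates the model right-hand side. Conserved pairs (cytosolic and
#' mitochondrial ATP/ADP and NADH/NAD) receive exactly opposite
#' derivatives, so every pool is invariant by construction. Membrane
#' potential follows a capacitance balance of pumped versus consumed
#' charge; the pH gradient relaxes toward a fixed fraction of the
#' membrane potential (see vignette).
#'
#' @param state A [metabolic_state()].
#' @param params Model parameters.
#' @param cond [external_conditions()].
#' @param demand [demand_spec()].
#' @return Named numeric vector of derivatives (mM/s; mV/s; uM/s).
#' @export
rhs <- function(state, params, cond, demand) {
  if (any(!is.finite(state)))
    stop("non-finite state", call. = FALSE)
  v <- model_fluxes(state, params, cond, demand)
  p <- params

  d_glc  <- v$v_glut - v$v_gly
  d_pyr  <- 2 * v$v_gly - v$v_ldh - v$v_tca
  d_lac  <- v$v_ldh + v$v_mct
  d_atpc <- 2 * v$v_gly + v$v_ant - v$v_atpase
  d_nadhc <- 2 * v$v_gly - v$v_ldh - v$v_mas - v$v_g3p
  d_atpm <- v$v_syn - v$v_ant
  d_nadhm <- 4 * v$v_tca + v$v_mas - v$v_c1
  d_fadh2 <- v$v_tca + v$v_g3p - v$v_c2
  net_h <- p$h_per_nadh * v$v_c1 + p$h_per_fadh2 * v$v_c2 -
    p$h_per_atp_syn * v$v_syn - v$v_ant - v$v_leak -
    2e-3 * v$v_ca  # uniporter charge, uM -> mM
  d_dpsi <- net_h / p$c_psi
  d_dph  <- p$ph_relax * (p$ph_frac * state[["dpsi"]] / Z_MV_PER_PH -
                            state[["dph"]])
  d_ca   <- v$v_ca

  c(glc_cyt = d_glc, pyr_cyt = d_pyr, lac_cyt = d_lac,
    atp_cyt = d_atpc, adp_cyt = -d_atpc,
    nadh_cyt = d_nadhc, nad_cyt = -d_nadhc,
    atp_mit = d_atpm, adp_mit = -d_atpm,
    nadh_mit = d_nadhm, nad_mit = -d_nadhm,
    fadh2_equiv_mit = d_fadh2, dpsi = d_dpsi, dph = d_dph, ca_mit = d_ca)
}

# Reduced system used by the steady-state solver: conserved partners are
# reconstructed from pool totals so the Jacobian is non-singular.
full_from_reduced <- function(x, params) {
  s <- c(glc_cyt = x[[1]], pyr_cyt = x[[2]], lac_cyt = x[[3]],
         atp_cyt = x[[4]], adp_cyt = params$pool_a_cyt - x[[4]],
         nadh_cyt = x[[5]], nad_cyt = params$pool_n_cyt - x[[5]],
         atp_mit = x[[6]], adp_mit = params$pool_a_mit - x[[6]],
         nadh_mit = x[[7]], nad_mit = params$pool_n_mit - x[[7]],
         fadh2_equiv_mit = x[[8]], dpsi = x[[9]], dph = x[[10]],
         ca_mit = x[[11]])
  s
}

reduced_rhs <- function(x, params, cond, demand) {
  d <- rhs(full_from_reduced(x, params), params, cond, demand)
  unname(d[REDUCED_FIELDS])
}

#' Integrate the model in time
#'
#' Stiff integration (lsoda) of the full 15-dimensional state. Used for
#' trajectory studies and conservation checks; the steady-state solver
#' uses the reduced system internally.
#'
#' @param state Initial [metabolic_state()].
#' @param times Output time points, seconds.
#' @param params,cond,demand Model inputs.
#' @param rtol,atol Solver tolerances.
#' @return A `deSolve` matrix (time in column 1, state fields after).
#' @export
integrate_model <- function(state, times, params, cond, demand,
                            rtol = 1e-10, atol = 1e-12) {
  f <- function(t, y, parms) list(unname(rhs(y, params, cond, demand)))
  out <- deSolve::lsoda(y = unclass(state), times = times, func = f,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  colnames(out) <- c("time", STATE_FIELDS)
  out
}
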