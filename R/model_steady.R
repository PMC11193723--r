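# Steady-state solution and flux bookkeeping.

#' Initial conditions for the steady-state solver
#'
#' Two documented starting points: a fully energized neuron (high ATP,
#' polarized mitochondria) and a fully de-energized one (low ATP,
#' depolarized). The steady state is required to agree from both.
#'
#' @param which `"energized"` or `"deenergized"`.
#' @param params Model parameters.
#' @return A [metabolic_state()].
#' @export
initial_state <- function(which = c("energized", "deenergized"),
                          params = default_parameters()) {
  which <- match.arg(which)
  if (which == "energized")
    metabolic_state(glc_cyt = 1, pyr_cyt = 0.1, lac_cyt = 1,
                    atp_cyt = 0.85 * params$pool_a_cyt,
                    nadh_cyt = 0.01 * params$pool_n_cyt,
                    atp_mit = 0.85 * params$pool_a_mit,
                    nadh_mit = 0.2 * params$pool_n_mit,
                    fadh2_equiv_mit = 0.1 * params$pool_fad,
                    dpsi = 160, dph = 0.5, ca_mit = 1, params = params)
  else
    metabolic_state(glc_cyt = 0.01, pyr_cyt = 0.01, lac_cyt = 0.01,
                    atp_cyt = 0.05 * params$pool_a_cyt,
                    nadh_cyt = 0.001 * params$pool_n_cyt,
                    atp_mit = 0.05 * params$pool_a_mit,
                    nadh_mit = 0.01 * params$pool_n_mit,
                    fadh2_equiv_mit = 0.01 * params$pool_fad,
                    dpsi = 20, dph = 0.05, ca_mit = 0.05, params = params)
}

# Steady fluxes reported to users. Sign convention for lactate follows
# the phase-diagram legend: positive = release, negative = uptake.
flux_vector <- function(state, params, cond, demand) {
  v <- model_fluxes(state, params, cond, demand)
  list(j_glc = v$v_glut,
       j_lac = -v$v_mct,
       j_o2 = 0.5 * (v$v_c1 + v$v_c2),
       j_atpase = v$v_atpase,
       j_synthase = v$v_syn,
       j_glycolysis = v$v_gly,
       j_tca = v$v_tca,
       j_shuttle = v$v_mas + v$v_g3p,
       j_leak = v$v_leak,
       j_ldh = v$v_ldh,
       j_ant = v$v_ant)
}

#' Solve the model to steady state
#'
#' Stiff integration (1000 s of model time by default) followed by damped
#' Newton root refinement on the reduced system. Convergence demands the
#' infinity norm of the full right-hand side below `tol` in native units
#' (mM/s, mV/s). Non-convergence raises an error of class
#' `neuro_nonconvergence` carrying the last state; it is never returned
#' silently.
#'
#' @param params Model parameters.
#' @param cond [external_conditions()].
#' @param demand A [demand_spec()] or a level name understood by
#'   [demand_level()].
#' @param init Starting point: `"energized"` (default), `"deenergized"`,
#'   or a [metabolic_state()] (used by warm-started sweeps).
#' @param tol Residual tolerance, native units.
#' @param t_integrate Integration horizon, s.
#' @return List with `state` (the steady [metabolic_state()]), `fluxes`
#'   (list of steady fluxes, mM/s), `residual` (achieved norm), and
#'   `converged` (always `TRUE` on return).
#' @export
#' @examples
#' \donttest{
#' p <- default_parameters()
#' ss <- steady_state(p, external_conditions(5, 0), demand_level("low", p))
#' ss$state[["atp_cyt"]]   # ~2.5 mM: energetically fit resting neuron
#' ss$fluxes$j_lac > 0     # net lactate release on glucose
#' }
steady_state <- function(params, cond, demand, init = "energized",
                         tol = 1e-9, t_integrate = 1000) {
  if (is.character(demand)) demand <- demand_level(demand, params)
  if (is.character(init)) init <- initial_state(init, params)

  f <- function(t, y, parms) list(unname(rhs(y, params, cond, demand)))
  g <- function(x) reduced_rhs(x, params, cond, demand)
  conc_idx <- 1:8

  # Damped Newton with non-negativity projection on concentrations.
  newton <- function(x, res) {
    for (iter in seq_len(40)) {
      if (max(abs(res)) < tol) break
      J <- tryCatch(pracma::jacobian(g, x), error = function(e) NULL)
      step <- if (is.null(J)) NULL else
        tryCatch(solve(J, -res), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      improved <- FALSE
      for (h in seq_len(12)) {
        xn <- x + lambda * step
        xn[conc_idx] <- pmax(xn[conc_idx], 0)
        rn <- tryCatch(g(xn), error = function(e) rep(Inf, length(x)))
        if (all(is.finite(rn)) && max(abs(rn)) < max(abs(res))) {
          x <- xn; res <- rn; improved <- TRUE; break
        }
        lambda <- lambda / 2
      }
      if (!improved) break
    }
    list(x = x, res = res)
  }

  integrate_to <- function(y0, t_end) {
    traj <- deSolve::lsoda(y = y0, times = c(0, t_end), func = f,
                           parms = NULL, rtol = 1e-10, atol = 1e-12,
                           maxsteps = 500000)
    y <- traj[nrow(traj), -1]
    names(y) <- STATE_FIELDS
    y
  }

  # Alternate stiff integration and Newton refinement, doubling the
  # horizon while slow pools (e.g. the FAD redox state) still crawl.
  y0 <- unclass(init)
  t_end <- t_integrate
  x <- NULL; res <- Inf
  for (round in seq_len(5)) {
    y0 <- tryCatch(integrate_to(y0, t_end), error = function(e) y0)
    cand <- newton(unname(y0[REDUCED_FIELDS]), g(unname(y0[REDUCED_FIELDS])))
    if (is.null(x) || max(abs(cand$res)) < max(abs(res))) {
      x <- cand$x; res <- cand$res
    }
    if (max(abs(res)) < tol) break
    y0 <- full_from_reduced(cand$x, params)
    t_end <- 2 * t_end
  }

  if (max(abs(res)) >= tol) {
    # Approach from the de-energized side: reaches the collapsed branch
    # quickly when the energized start crawls past a saddle-node ghost.
    alt <- tryCatch({
      y3 <- integrate_to(unclass(initial_state("deenergized", params)),
                         20 * t_integrate)
      newton(unname(y3[REDUCED_FIELDS]), g(unname(y3[REDUCED_FIELDS])))
    }, error = function(e) NULL)
    if (!is.null(alt) && max(abs(alt$res)) < max(abs(res))) {
      x <- alt$x; res <- alt$res
    }
  }

  state <- structure(full_from_reduced(x, params), class = "neuro_state")
  if (max(abs(res)) >= tol) {
    cnd <- structure(
      class = c("neuro_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "steady state did not converge (residual %.3g > tol %.3g)",
        max(abs(res)), tol),
        call = sys.call(-1), state = state, residual = max(abs(res))))
    stop(cnd)
  }
  list(state = state,
       fluxes = flux_vector(state, params, cond, demand),
       residual = max(abs(res)),
       converged = TRUE)
}

#' Stoichiometric balance residuals of a steady flux vector
#'
#' Closure checks of the lumped stoichiometry at steady state:
#' * carbon: `6 j_glc - 3 j_lac - 3 j_tca` (glucose carbons vs lactate
#'   export and pyruvate oxidation; pyruvate and lactate carry 3 C),
#' * redox: electron pairs produced by glycolysis (2 per glucose) and
#'   pyruvate oxidation (5 per pyruvate: 4 NADH + 1 FADH2) minus pairs
#'   exported on released lactate (1 each) and pairs delivered to the
#'   respiratory chain (2 per O2),
#' * phosphate: `j_synthase + 2 j_glycolysis - j_atpase` (net glycolytic
#'   yield 2 ATP per glucose; no separate maintenance term).
#'
#' All three vanish (|residual| < 1e-6 mM/s) at a converged steady state.
#'
#' @param fluxes Flux list from [steady_state()].
#' @return Named numeric vector `c(carbon, redox, phosphate)`, mM/s.
#' @export
balance_residuals <- function(fluxes) {
  c(carbon = 6 * fluxes$j_glc - 3 * fluxes$j_lac - 3 * fluxes$j_tca,
    redox = 2 * fluxes$j_glycolysis + 5 * fluxes$j_tca -
      fluxes$j_lac - 2 * fluxes$j_o2,
    phosphate = fluxes$j_synthase + 2 * fluxes$j_glycolysis -
      fluxes$j_atpase)
}
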