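# Phase-diagram sweeps over extracellular glucose x lactate and
# glucose-fitness threshold localization.

#' Default substrate grid
#'
#' Glucose and lactate axes covering the physiological recording-solution
#' range (5 mM glucose; 2 mM lactate supplements) with fine resolution
#' near the low-glucose fitness thresholds.
#'
#' @return List with `glc_values` and `lac_values` (mM, ascending).
#' @export
default_grid <- function() {
  v <- c(0, 0.05, 0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4, 5)
  sweep_grid(v, v)
}

#' Construct a sweep grid
#'
#' @param glc_values,lac_values Strictly ascending non-negative mM values
#'   (at least 2 each).
#' @return List of class `neuro_grid`.
#' @export
sweep_grid <- function(glc_values, lac_values) {
  for (nm in c("glc_values", "lac_values")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) < 2 || any(!is.finite(v)) ||
        any(v < 0) || any(diff(v) <= 0))
      stop_field(nm, "must be >= 2 non-negative strictly ascending values")
  }
  structure(list(glc_values = glc_values, lac_values = lac_values),
            class = "neuro_grid")
}

#' Run a substrate phase-map sweep
#'
#' One steady-state solution per (glucose, lactate) grid cell at a fixed
#' demand level, warm-starting each cell from its neighbor along the
#' glucose axis (descending from the best-fuelled cell) for speed. Cells
#' whose solver fails are recorded as non-converged and carry `NA` maps;
#' the sweep aborts only if more than 20% of cells fail.
#'
#' @param grid A [sweep_grid()].
#' @param params Model parameters.
#' @param demand_level `"low"`, `"intermediate"` or `"high"`.
#' @param warm_start Reuse the neighboring cell's solution as the next
#'   starting point (`TRUE`, default).
#' @param po2 Oxygen partial pressure, mmHg.
#' @return A `neuro_phasemap`: list with the grid, matrices `j_glc_map`,
#'   `j_lac_map`, `atp_map` (rows = glucose, columns = lactate),
#'   `converged_map`, and the demand label.
#' @export
run_sweep <- function(grid, params = default_parameters(),
                      demand_level = c("low", "intermediate", "high"),
                      warm_start = TRUE, po2 = 60) {
  demand_level <- match.arg(demand_level)
  demand <- demand_level(demand_level, params)
  ng <- length(grid$glc_values); nl <- length(grid$lac_values)
  dimn <- list(glc = as.character(grid$glc_values),
               lac = as.character(grid$lac_values))
  j_glc <- j_lac <- atp <- matrix(NA_real_, ng, nl, dimnames = dimn)
  conv <- matrix(FALSE, ng, nl, dimnames = dimn)

  for (j in seq_len(nl)) {
    carry <- "energized"
    for (i in rev(seq_len(ng))) {  # descend from highest glucose
      cond <- external_conditions(grid$glc_values[i], grid$lac_values[j],
                                  po2 = po2)
      ss <- tryCatch(
        steady_state(params, cond, demand,
                     init = if (warm_start) carry else "energized"),
        neuro_nonconvergence = function(e) NULL)
      if (is.null(ss) && warm_start)  # retry cold before recording failure
        ss <- tryCatch(steady_state(params, cond, demand),
                       neuro_nonconvergence = function(e) NULL)
      if (!is.null(ss)) {
        j_glc[i, j] <- ss$fluxes$j_glc
        j_lac[i, j] <- ss$fluxes$j_lac
        atp[i, j] <- ss$state[["atp_cyt"]]
        conv[i, j] <- TRUE
        if (warm_start) carry <- ss$state
      }
    }
  }
  if (mean(conv) < 0.8)
    stop(sprintf("sweep aborted: %.0f%% of cells failed to converge",
                 100 * (1 - mean(conv))), call. = FALSE)
  structure(list(grid = grid, j_glc_map = j_glc, j_lac_map = j_lac,
                 atp_map = atp, converged_map = conv,
                 demand = demand_level),
            class = "neuro_phasemap")
}

#' Classify energy-deficit cells of a phase map
#'
#' A cell is in energy deficit when its steady-state cytosolic ATP falls
#' below `atp_min` (default 1 mM, the operational criterion for failed
#' neuronal energy fitness). Non-converged cells give `NA`.
#'
#' @param map A `neuro_phasemap` from [run_sweep()].
#' @param atp_min Deficit criterion, mM.
#' @return Logical matrix, same shape as the maps.
#' @export
classify_deficit <- function(map, atp_min = 1.0) {
  check_scalar(atp_min, "atp_min", lower = 0)
  out <- map$atp_map < atp_min
  out[!map$converged_map] <- NA
  out
}

#' Phase map as a long-format data frame
#'
#' @param map A `neuro_phasemap`.
#' @param atp_min Deficit criterion passed to [classify_deficit()].
#' @return `data.frame` with columns glc, lac, demand, j_glc, j_lac, atp,
#'   converged, deficit.
#' @export
phasemap_table <- function(map, atp_min = 1.0) {
  g <- map$grid
  deficit <- classify_deficit(map, atp_min)
  data.frame(
    glc = rep(g$glc_values, times = length(g$lac_values)),
    lac = rep(g$lac_values, each = length(g$glc_values)),
    demand = map$demand,
    j_glc = as.vector(map$j_glc_map),
    j_lac = as.vector(map$j_lac_map),
    atp = as.vector(map$atp_map),
    converged = as.vector(map$converged_map),
    deficit = as.vector(deficit))
}

#' Locate the glucose-fitness threshold by bisection
#'
#' Finds the minimal extracellular glucose sustaining energy fitness
#' (steady-state cytosolic ATP >= `atp_min`) at a fixed lactate level and
#' demand, by bisection on the glucose axis. If the neuron is already fit
#' at zero glucose the threshold is 0 (degenerate bracket, flagged); if
#' it is unfit even at the upper bracket end the result is flagged
#' `no_fitness`.
#'
#' @param demand_level `"low"`, `"intermediate"` or `"high"`.
#' @param lac_ext Fixed extracellular lactate, mM.
#' @param params Model parameters.
#' @param tol Bracket width target, mM.
#' @param glc_hi Upper bracket end, mM.
#' @param atp_min Fitness criterion, mM.
#' @return List of class `neuro_threshold`: `demand`, `lac_ext`,
#'   `glc_star`, `bracket` (lo, hi), `achieved_tol`, `degenerate` flag.
#' @export
#' @examples
#' \donttest{
#' # Fit even without glucose at low demand under abundant lactate:
#' glucose_threshold("low", lac_ext = 5)$glc_star == 0
#' }
glucose_threshold <- function(demand_level, lac_ext,
                              params = default_parameters(),
                              tol = 0.01, glc_hi = 5, atp_min = 1.0) {
  check_scalar(lac_ext, "lac_ext", lower = 0)
  check_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  demand <- demand_level(demand_level, params)

  atp_at <- function(glc, init) {
    cond <- external_conditions(glc, lac_ext)
    ss <- tryCatch(steady_state(params, cond, demand, init = init),
                   neuro_nonconvergence = function(e) NULL)
    if (is.null(ss) && !is.character(init))  # warm start failed: go cold
      ss <- steady_state(params, cond, demand)
    list(atp = ss$state[["atp_cyt"]], state = ss$state)
  }

  hi <- atp_at(glc_hi, "energized")
  if (hi$atp < atp_min)
    return(structure(list(demand = demand_level, lac_ext = lac_ext,
                          glc_star = NA_real_, bracket = c(NA, NA),
                          achieved_tol = NA_real_,
                          degenerate = "no_fitness"),
                     class = "neuro_threshold"))
  lo <- atp_at(0, "energized")
  if (lo$atp >= atp_min)
    return(structure(list(demand = demand_level, lac_ext = lac_ext,
                          glc_star = 0, bracket = c(0, 0),
                          achieved_tol = 0, degenerate = "fit_at_zero"),
                     class = "neuro_threshold"))

  a <- 0; b <- glc_hi
  carry <- hi$state
  while (b - a > tol) {
    mid <- (a + b) / 2
    res <- atp_at(mid, carry)
    carry <- res$state
    if (res$atp >= atp_min) b <- mid else a <- mid
  }
  # Verify monotone fitness across the final bracket ends.
  if (atp_at(b, "energized")$atp < atp_min ||
      atp_at(a, "energized")$atp >= atp_min)
    stop("non-monotone fitness across the threshold bracket", call. = FALSE)
  structure(list(demand = demand_level, lac_ext = lac_ext,
                 glc_star = (a + b) / 2, bracket = c(a, b),
                 achieved_tol = b - a, degenerate = "none"),
            class = "neuro_threshold")
}
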