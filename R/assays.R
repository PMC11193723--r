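# Plate-assay standard curves: serial dilutions, least-squares fits
# (linear for nitrite/lactate, quadratic for the IL-6 ELISA) and
# monotone in-domain inversion for unknown wells.

#' Serial dilution series
#'
#' Concentrations `top / factor^i` for i = 0..n-1, e.g. the eight-point
#' two-fold series from an 8000 pg/mL stock: 8000, 4000, ..., 62.5.
#'
#' @param top Top standard concentration.
#' @param factor Dilution factor (> 1).
#' @param n Number of points (>= 1).
#' @return Numeric vector, descending.
#' @export
#' @examples
#' dilution_series(8000, 2, 8)
#' dilution_series(80, 2, 9)[9]  # 0.3125
dilution_series <- function(top, factor, n) {
  check_scalar(top, "top", lower = 0, strict_lower = TRUE)
  check_scalar(factor, "factor", lower = 1, strict_lower = TRUE)
  n <- check_count(n, "n", lower = 1)
  top / factor^(seq_len(n) - 1)
}

#' Fit a standard curve
#'
#' Least-squares regression of signal on concentration, linear or
#' quadratic. The fitted curve must be monotone over the standards'
#' concentration range (checked numerically); a non-monotone fit is an
#' error since it cannot be inverted for quantification.
#'
#' @param standards `data.frame` with columns `conc` and `signal` (e.g.
#'   the standard wells of [gen_plate()]).
#' @param model `"linear"` or `"quadratic"`.
#' @return List of class `standard_curve`: `assay`, `model`,
#'   `coefficients` (lowest order first), `concentration_domain`,
#'   `signal_range`, `fit_stats` (r.squared, sigma).
#' @export
fit_standard_curve <- function(standards, model = c("linear", "quadratic")) {
  model <- match.arg(model)
  if (!all(c("conc", "signal") %in% names(standards)))
    stop_field("standards", "needs columns `conc` and `signal`")
  standards <- standards[stats::complete.cases(standards[c("conc",
                                                           "signal")]), ]
  npar <- if (model == "linear") 2L else 3L
  if (nrow(standards) < npar + 1L)
    stop(sprintf("need at least %d standards for a %s fit", npar + 1L,
                 model), call. = FALSE)
  fit <- if (model == "linear")
    lm(signal ~ conc, data = standards)
  else
    lm(signal ~ conc + I(conc^2), data = standards)
  cf <- unname(coef(fit))
  dom <- range(standards$conc)
  # numerical monotonicity check over the domain
  grid <- seq(dom[1], dom[2], length.out = 257)
  vals <- plate_signal(grid, cf)
  d <- diff(vals)
  if (any(d > 0) && any(d < 0))
    stop("fitted curve is not monotone over the standard range; cannot ",
         "be used for inversion", call. = FALSE)
  s <- suppressWarnings(summary(fit))  # noiseless fits warn
  structure(list(model = model, coefficients = cf,
                 concentration_domain = dom,
                 signal_range = range(vals),
                 fit_stats = list(r.squared = s$r.squared,
                                  sigma = s$sigma)),
            class = "standard_curve")
}

#' Invert a standard curve for an unknown well
#'
#' Maps a measured signal back to concentration through the fitted
#' curve, restricted to the standards' concentration domain (no
#' extrapolation), and multiplies by the sample dilution factor (e.g. 5
#' for medium diluted 1:5 before the assay).
#'
#' @param curve A [fit_standard_curve()] result.
#' @param signal Measured signal (scalar or vector).
#' @param dilution_factor Pre-assay sample dilution (>= 1).
#' @return Concentration(s) on the undiluted-sample scale.
#' @export
#' @examples
#' std <- data.frame(conc = dilution_series(1000, 2, 6))
#' std$signal <- 0.02 + 0.001 * std$conc
#' cv <- fit_standard_curve(std, "linear")
#' concentration_from_signal(cv, 0.02 + 0.001 * 100, dilution_factor = 5)
#' # 500: a 100 uM-equivalent well from a 1:5-diluted sample
concentration_from_signal <- function(curve, signal, dilution_factor = 1) {
  check_scalar(dilution_factor, "dilution_factor", lower = 1)
  vapply(signal, function(sig) {
    lo <- min(curve$signal_range); hi <- max(curve$signal_range)
    if (sig < lo - 1e-9 * max(1, abs(lo)) ||
        sig > hi + 1e-9 * max(1, abs(hi)))
      stop("signal outside the standard-curve range; refusing to ",
           "extrapolate", call. = FALSE)
    cf <- curve$coefficients
    dom <- curve$concentration_domain
    roots <- if (curve$model == "linear") {
      (sig - cf[1]) / cf[2]
    } else {
      disc <- cf[2]^2 - 4 * cf[3] * (cf[1] - sig)
      if (disc < 0 && disc > -1e-12 * max(1, cf[2]^2)) disc <- 0
      if (disc < 0)
        stop("no real root for this signal", call. = FALSE)
      (-cf[2] + c(1, -1) * sqrt(disc)) / (2 * cf[3])
    }
    tol <- 1e-9 * max(1, diff(dom))
    inside <- roots[roots >= dom[1] - tol & roots <= dom[2] + tol]
    if (length(inside) == 0)
      stop("no in-domain root for this signal", call. = FALSE)
    if (length(unique(round(inside / tol))) > 1)
      stop("two in-domain roots: curve not invertible here", call. = FALSE)
    min(max(inside[1], dom[1]), dom[2]) * dilution_factor
  }, numeric(1))
}
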