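# Synthetic microplate optical-density tables (dilution-series standards
# plus unknowns) and qPCR Ct tables for the six-group transient-
# inflammation design, with known ground truth.

#' Specification of a synthetic plate assay
#'
#' @param assay One of `"IL6_ELISA"`, `"griess_nitrite"`, `"lactate"`.
#' @param top_standard Concentration of the top standard (pg/mL or uM).
#' @param n_standards Number of standards (top included).
#' @param dilution_factor Serial dilution factor (2 = two-fold).
#' @param curve_truth Coefficients of the true signal model, lowest order
#'   first: `c(intercept, slope)` or `c(intercept, slope, quad)`.
#' @param noise_sd Additive Gaussian noise on the signal (OD units).
#' @param unknowns_truth Concentrations of unknown wells.
#' @param replicates Wells per standard/unknown.
#' @param seed Integer seed.
#' @return List of class `plate_spec`.
#' @export
plate_spec <- function(assay = c("IL6_ELISA", "griess_nitrite", "lactate"),
                       top_standard, n_standards = 8, dilution_factor = 2,
                       curve_truth = c(0.05, 1e-4), noise_sd = 0,
                       unknowns_truth = numeric(0), replicates = 1,
                       seed = 1) {
  assay <- match.arg(assay)
  check_scalar(top_standard, "top_standard", lower = 0, strict_lower = TRUE)
  check_count(n_standards, "n_standards", lower = 3)
  check_scalar(dilution_factor, "dilution_factor", lower = 1,
               strict_lower = TRUE)
  if (!is.numeric(curve_truth) || !length(curve_truth) %in% c(2, 3))
    stop_field("curve_truth", "must have 2 (linear) or 3 (quadratic) terms")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (length(unknowns_truth) && any(unknowns_truth < 0))
    stop_field("unknowns_truth", "must be non-negative")
  check_count(replicates, "replicates", lower = 1)
  check_count(seed, "seed")
  structure(list(assay = assay, top_standard = top_standard,
                 n_standards = n_standards,
                 dilution_factor = dilution_factor,
                 curve_truth = curve_truth, noise_sd = noise_sd,
                 unknowns_truth = unknowns_truth, replicates = replicates,
                 seed = seed),
            class = "plate_spec")
}

plate_signal <- function(conc, coefs) {
  s <- coefs[1] + coefs[2] * conc
  if (length(coefs) == 3) s <- s + coefs[3] * conc^2
  s
}

#' Generate a synthetic plate
#'
#' Standard wells at `top / factor^i`, i = 0..n-1, plus unknown wells;
#' signals follow the true curve plus Gaussian noise.
#'
#' @param spec A [plate_spec()].
#' @return `data.frame` (class `plate_data`) with columns `well`, `role`
#'   (standard/unknown), `conc` (truth; `NA` for unknowns in the `known`
#'   column sense), `signal`; the truth for unknowns is kept in attribute
#'   `unknowns_truth`.
#' @export
#' @examples
#' pd <- gen_plate(plate_spec("IL6_ELISA", top_standard = 8000, seed = 3))
#' unique(pd$conc[pd$role == "standard"])  # 8000, 4000, ..., 62.5
gen_plate <- function(spec) {
  stds <- dilution_series(spec$top_standard, spec$dilution_factor,
                          spec$n_standards)
  conc <- c(rep(stds, each = spec$replicates),
            rep(spec$unknowns_truth, each = spec$replicates))
  role <- c(rep("standard", spec$n_standards * spec$replicates),
            rep("unknown", length(spec$unknowns_truth) * spec$replicates))
  with_private_seed(spec$seed, {
    signal <- plate_signal(conc, spec$curve_truth) +
      rnorm(length(conc), sd = spec$noise_sd)
    out <- data.frame(well = sprintf("W%02d", seq_along(conc)),
                      role = role,
                      conc = ifelse(role == "standard", conc, NA_real_),
                      signal = signal)
    attr(out, "assay") <- spec$assay
    attr(out, "unknowns_truth") <- spec$unknowns_truth
    class(out) <- c("plate_data", "data.frame")
    out
  })
}

#' Six-group transient-inflammation Ct design
#'
#' Groups follow the slice-culture paradigm: control (CTL), 24 h LPS
#' (LPS), and 24/48/72/96 h of LPS-free resolution (RES24..RES96).
#' Per-gene, per-group log2 fold changes are planted; the reference gene
#' must have zero effect everywhere, and effects in RES96 default to
#' zero so the resolution of the inflammatory response is reproducible.
#'
#' @param genes Gene labels (reference gene included).
#' @param reference_gene Endogenous control (default `"ACTB"`).
#' @param effect_logfc Numeric matrix `genes x groups` of planted log2
#'   fold changes (positive = upregulated). Default: zeros.
#' @param baseline_ct Named baseline Ct per gene (default 24 for all
#'   targets, 18 for the reference).
#' @param ct_noise_sd Technical noise, cycles.
#' @param replicates Samples per group (>= 2).
#' @param seed Integer seed.
#' @return List of class `ct_design`.
#' @export
ct_design <- function(genes, reference_gene = "ACTB",
                      effect_logfc = NULL, baseline_ct = NULL,
                      ct_noise_sd = 0, replicates = 3, seed = 1) {
  groups <- c("CTL", "LPS", "RES24", "RES48", "RES72", "RES96")
  if (!reference_gene %in% genes)
    stop("reference gene missing from gene list", call. = FALSE)
  if (is.null(effect_logfc))
    effect_logfc <- matrix(0, length(genes), length(groups),
                           dimnames = list(genes, groups))
  if (!all(dim(effect_logfc) == c(length(genes), length(groups))))
    stop_field("effect_logfc", "must be a genes x groups matrix")
  dimnames(effect_logfc) <- list(genes, groups)
  if (any(effect_logfc[reference_gene, ] != 0))
    stop_field("effect_logfc", "reference gene must have zero effect")
  if (is.null(baseline_ct)) {
    baseline_ct <- stats::setNames(rep(24, length(genes)), genes)
    baseline_ct[reference_gene] <- 18
  }
  check_scalar(ct_noise_sd, "ct_noise_sd", lower = 0)
  check_count(replicates, "replicates", lower = 2)
  check_count(seed, "seed")
  structure(list(groups = groups, genes = genes,
                 reference_gene = reference_gene,
                 effect_logfc = effect_logfc, baseline_ct = baseline_ct,
                 ct_noise_sd = ct_noise_sd, replicates = replicates,
                 seed = seed),
            class = "ct_design")
}

#' Planted log2 fold-change matrix of the transient-inflammation pattern
#'
#' Convenience default emulating the qualitative expression pattern of
#' the paradigm: inflammation- and stress-related genes up at LPS and
#' decaying through resolution; microglial homeostatic genes down at LPS
#' and recovering; everything back to baseline by RES96.
#'
#' @param genes Gene labels.
#' @param reference_gene Left at zero effect.
#' @param up Genes upregulated by LPS (default: inflammation set).
#' @param down Genes downregulated by LPS (default: homeostatic set).
#' @param amplitude Peak |log2 FC| at the LPS time point.
#' @return Matrix `genes x groups`.
#' @export
inflammation_effects <- function(genes, reference_gene = "ACTB",
                                 up = intersect(genes, c("IL6", "IL1B",
                                                         "TNF", "NOS2",
                                                         "IRG1", "CD74",
                                                         "SOD2", "IL10")),
                                 down = intersect(genes, c("P2RY12",
                                                           "TMEM119",
                                                           "CX3CR1")),
                                 amplitude = 3) {
  groups <- c("CTL", "LPS", "RES24", "RES48", "RES72", "RES96")
  decay <- c(CTL = 0, LPS = 1, RES24 = 0.5, RES48 = 0.25, RES72 = 0.1,
             RES96 = 0)
  m <- matrix(0, length(genes), length(groups),
              dimnames = list(genes, groups))
  for (g in setdiff(up, reference_gene)) m[g, ] <- amplitude * decay
  for (g in setdiff(down, reference_gene)) m[g, ] <- -amplitude / 2 * decay
  m
}

#' Generate a synthetic Ct table
#'
#' Ct = baseline - effect_logfc + per-sample loading offset + noise.
#' The loading offset applies to every gene of a sample (including the
#' reference gene) and therefore cancels in comparative quantification.
#'
#' @param design A [ct_design()].
#' @return `data.frame` (class `ct_table`) with columns `sample`,
#'   `group`, `gene`, `ct`.
#' @export
#' @examples
#' d <- ct_design(c("IL6", "ACTB"),
#'                effect_logfc = matrix(c(0, 3, 0, 0, 0, 0, rep(0, 6)),
#'                                      2, 6, byrow = TRUE,
#'                                      dimnames = list(c("IL6", "ACTB"),
#'                                                      NULL)))
#' ct <- gen_ct_table(d)
#' # relative expression of IL6 in LPS vs CTL is 2^3 = 8
gen_ct_table <- function(design) {
  with_private_seed(design$seed, {
    rows <- list()
    for (grp in design$groups) {
      for (r in seq_len(design$replicates)) {
        sample_id <- sprintf("%s_%d", grp, r)
        offset <- rnorm(1, 0, 0.3)  # loading/efficiency offset
        for (gene in design$genes) {
          ct <- design$baseline_ct[[gene]] -
            design$effect_logfc[gene, grp] + offset +
            rnorm(1, 0, design$ct_noise_sd)
          rows[[length(rows) + 1L]] <-
            data.frame(sample = sample_id, group = grp, gene = gene,
                       ct = ct)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "reference_gene") <- design$reference_gene
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
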