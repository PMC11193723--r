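# Relative gene expression (comparative Ct), control normalization,
# metabolite ratios, and the heatmap reduction (row z-scores + Ward
# clustering).

#' Comparative Ct relative expression
#'
#' Classic 2^-ddCt quantification: per sample, dCt = Ct_gene -
#' Ct_reference; ddCt references each gene's dCt to the control-group
#' mean dCt; relative expression = 2^-ddCt. Samples lacking a reference
#' measurement are dropped with a warning.
#'
#' @param ct A [gen_ct_table()]-style `data.frame` (columns `sample`,
#'   `group`, `gene`, `ct`).
#' @param reference_gene Endogenous control gene (default `"ACTB"`).
#' @param control_group Reference condition (default `"CTL"`).
#' @return List of class `expression_matrix`: `values` (genes x samples
#'   matrix of relative expression), `groups` (named by sample).
#' @export
#' @examples
#' d <- ct_design(c("IL6", "ACTB"))
#' e <- ddct_expression(gen_ct_table(d))
#' all(abs(e$values - 1) < 1e-12)  # null design: everything at 1
ddct_expression <- function(ct, reference_gene = "ACTB",
                            control_group = "CTL") {
  if (!reference_gene %in% ct$gene)
    stop("reference gene absent from the Ct table", call. = FALSE)
  if (!control_group %in% ct$group)
    stop("control group absent from the Ct table", call. = FALSE)
  samples <- unique(ct$sample)
  genes <- setdiff(unique(ct$gene), reference_gene)
  groups <- stats::setNames(ct$group[match(samples, ct$sample)], samples)

  ref_ct <- stats::setNames(rep(NA_real_, length(samples)), samples)
  ref_rows <- ct[ct$gene == reference_gene, ]
  ref_agg <- tapply(ref_rows$ct, ref_rows$sample, mean)
  ref_ct[names(ref_agg)] <- ref_agg
  dropped <- samples[is.na(ref_ct)]
  if (length(dropped)) {
    warning("dropping samples without reference-gene Ct: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    samples <- setdiff(samples, dropped)
    groups <- groups[samples]
  }

  dct <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (g in genes) {
    rows <- ct[ct$gene == g & ct$sample %in% samples, ]
    agg <- tapply(rows$ct, rows$sample, mean)
    dct[g, names(agg)] <- agg - ref_ct[names(agg)]
  }
  ctrl <- samples[groups == control_group]
  ddct <- dct - rowMeans(dct[, ctrl, drop = FALSE], na.rm = TRUE)
  structure(list(values = 2^(-ddct), groups = groups),
            class = "expression_matrix")
}

#' Normalize a measurement matrix to the control group
#'
#' Divides each row by its control-group mean, so control samples
#' average 1 per row (the convention used for metabolite content).
#'
#' @param values Numeric matrix (rows = analytes, columns = samples) or
#'   an `expression_matrix`.
#' @param groups Group label per column (taken from the object when
#'   omitted).
#' @param control_group Label of the control condition.
#' @return Same shape as the input, control-normalized.
#' @export
normalize_to_control <- function(values, groups = NULL,
                                 control_group = "CTL") {
  if (inherits(values, "expression_matrix")) {
    if (is.null(groups)) groups <- values$groups
    values <- values$values
  }
  if (is.null(groups) || length(groups) != ncol(values))
    stop_field("groups", "must label every column")
  ctrl <- which(groups == control_group)
  if (!length(ctrl)) stop("control group empty", call. = FALSE)
  m <- rowMeans(values[, ctrl, drop = FALSE])
  if (any(m <= 0))
    stop("control mean must be positive in every row", call. = FALSE)
  sweep(values, 1, m, "/")
}

#' Ratio of two analyte rows
#'
#' Pairwise per-sample ratio on the un-normalized matrix, e.g. the
#' alpha-ketoglutarate / citrate ratio used as a proxy for carbon flow
#' through isocitrate dehydrogenase.
#'
#' @param values Numeric matrix with named rows.
#' @param numerator,denominator Row names.
#' @return Named numeric vector (per sample).
#' @export
row_ratio <- function(values, numerator, denominator) {
  if (!numerator %in% rownames(values) ||
      !denominator %in% rownames(values))
    stop("both analytes must be rows of the matrix", call. = FALSE)
  values[numerator, ] / values[denominator, ]
}

#' Row z-scores and Ward clustering for heatmap display
#'
#' Each row is centered and scaled to unit standard deviation (sample
#' sd, n-1 denominator), expressing every entry as the number of
#' standard deviations a sample lies from the row mean. Rows and columns
#' are then ordered by agglomerative clustering with Euclidean distance
#' and classic Ward linkage (`ward.D` on unsquared distances). Constant
#' rows are set to z = 0 and flagged.
#'
#' @param values Numeric matrix (or `expression_matrix`).
#' @return List: `z` (z-scored matrix), `row_order`, `col_order` (leaf
#'   orders), `row_hclust`, `col_hclust`, `constant_rows`.
#' @export
zscore_cluster <- function(values) {
  if (inherits(values, "expression_matrix")) values <- values$values
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  mu <- rowMeans(values)
  sdv <- apply(values, 1, sd)
  constant <- sdv == 0
  z <- (values - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  rh <- hclust(dist(z, method = "euclidean"), method = "ward.D")
  ch <- hclust(dist(t(z), method = "euclidean"), method = "ward.D")
  list(z = z, row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch,
       constant_rows = rownames(values)[constant])
}
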