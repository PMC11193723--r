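# Automated two-channel microglia counting: z-projection, background
# subtraction, automatic thresholding, nuclear gating, mask cleaning and
# size-filtered particle counting — the stages of the published macro,
# in the published order.

#' Z-project and background-subtract a two-channel stack
#'
#' Maximum-intensity projection per channel; the Iba1 projection is then
#' background-subtracted with a grayscale morphological opening (disc of
#' `ball_radius` pixels) serving as the rolling-ball background
#' estimate. The DAPI projection is left as acquired.
#'
#' @param stack An `image_stack` (list with `dapi`, `iba1` arrays
#'   H x W x n_slices) as produced by [gen_image_stack()].
#' @param ball_radius Background structuring-element radius, px.
#' @param projection `"max"` (default) or `"mean"`.
#' @return List: `dapi_2d`, `iba1_2d` matrices.
#' @export
preprocess <- function(stack, ball_radius = 50,
                       projection = c("max", "mean")) {
  projection <- match.arg(projection)
  if (is.null(stack$dapi) || is.null(stack$iba1) ||
      !length(stack$dapi) || !length(stack$iba1))
    stop("empty stack", call. = FALSE)
  proj <- function(a) {
    if (length(dim(a)) == 2) return(a)
    if (projection == "max") apply(a, c(1, 2), max)
    else apply(a, c(1, 2), mean)
  }
  dapi2 <- proj(stack$dapi)
  iba2 <- proj(stack$iba1)
  # replicate-pad before the opening so the background estimate has no
  # border roll-off, then crop back
  r <- ceiling(ball_radius)
  H <- nrow(iba2); W <- ncol(iba2)
  padded <- iba2[c(rep(1, r), seq_len(H), rep(H, r)),
                 c(rep(1, r), seq_len(W), rep(W, r))]
  brush <- EBImage::makeBrush(2 * r + 1, "disc")
  # grayscale morphology needs the [0, 1] range
  sc <- max(padded, 1)
  bg <- EBImage::dilate(EBImage::erode(padded / sc, brush), brush) * sc
  background <- bg[r + seq_len(H), r + seq_len(W)]
  list(dapi_2d = dapi2, iba1_2d = pmax(iba2 - background, 0))
}

#' Automatic threshold: iterative intermeans ("default dark")
#'
#' The historical default automatic threshold: on a 256-bin histogram,
#' iterate t <- (mean below t + mean above t) / 2 to convergence.
#' Pixels strictly above the threshold are foreground (dark-background
#' convention). Shifting an image by a constant shifts the threshold
#' identically, leaving the mask unchanged.
#'
#' @param img Numeric matrix.
#' @return Binary (0/1) integer matrix with attribute `threshold`.
#' @export
threshold_default_dark <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0)
    stop("constant image: no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(img, breaks, all.inside = TRUE), nbins = 256)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  t_idx <- 128
  for (iter in seq_len(100)) {
    lo <- seq_len(t_idx); hi <- seq(t_idx + 1, 256)
    m_lo <- sum(h[lo] * mids[lo]) / max(sum(h[lo]), 1)
    m_hi <- sum(h[hi] * mids[hi]) / max(sum(h[hi]), 1)
    new_t <- which.min(abs(mids - (m_lo + m_hi) / 2))
    if (new_t == t_idx) break
    t_idx <- new_t
  }
  thr <- mids[t_idx]
  structure((img > thr) + 0L, threshold = thr, dim = dim(img))
}

#' Gate an intensity image by a nuclear mask
#'
#' Zeroes every Iba1 pixel outside a dilated selection around the binary
#' DAPI signal, removing marker signal that does not colocalize with a
#' nucleus.
#'
#' @param iba1_img Intensity matrix.
#' @param dapi_mask Binary matrix (same shape).
#' @param dilate_radius Selection expansion around the nuclear mask, px.
#' @return Gated intensity matrix.
#' @export
dapi_gate <- function(iba1_img, dapi_mask, dilate_radius = 5) {
  if (!all(dim(iba1_img) == dim(dapi_mask)))
    stop("image and mask shapes differ", call. = FALSE)
  sel <- dapi_mask
  if (dilate_radius > 0 && any(sel > 0)) {
    brush <- EBImage::makeBrush(2 * ceiling(dilate_radius) + 1, "disc")
    sel <- EBImage::dilate(sel, brush)
  }
  iba1_img * (sel > 0)
}

#' Clean a binary mask (despeckle + remove outliers)
#'
#' 3x3 median filter (despeckle) followed by bright-outlier removal:
#' pixels deviating from the local median (disc of `outlier_radius`) by
#' more than `outlier_threshold` are replaced by that median.
#'
#' @param mask Binary (0/1) matrix.
#' @param outlier_radius Neighborhood radius, px.
#' @param outlier_threshold Deviation triggering replacement (on the
#'   0/1 scale).
#' @return Cleaned binary matrix.
#' @export
clean_mask <- function(mask, outlier_radius = 2, outlier_threshold = 0.5) {
  m <- EBImage::medianFilter(matrix(as.numeric(mask), nrow(mask)), 1)
  med <- EBImage::medianFilter(m, outlier_radius)
  out <- ifelse(m - med > outlier_threshold, med, m)
  structure((out > 0.5) + 0L, dim = dim(mask))
}

# 8-connected labeling: 4-connected labels from EBImage::bwlabel, then
# union-find merging of diagonally adjacent labels.
label_8conn <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  H <- nrow(lab); W <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(H - 1), if (dd[2] == 1) seq_len(W - 1) else 2:W]
    b <- lab[2:H, if (dd[2] == 1) 2:W else seq_len(W - 1)]
    pairs <- unique(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]))
    if (length(pairs))
      for (r in seq_len(nrow(pairs)))
        if (pairs[r, 1] != pairs[r, 2]) union(pairs[r, 1], pairs[r, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, unique(roots))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Count particles above a size cutoff
#'
#' Connected-component labeling with 8-connectivity; components of area
#' at least `min_area_px` (the published 400-px cutoff excludes small
#' specks where other cell types' nuclei colocalize with microglial
#' ramifications) are counted.
#'
#' @param mask Binary matrix.
#' @param min_area_px Minimal particle area, px.
#' @return List of class `count_result`: `count`, `particle_areas_px`,
#'   `mask_fraction`.
#' @export
#' @examples
#' m <- matrix(0L, 60, 60); m[5:29, 5:29] <- 1L   # 625 px
#' count_particles(m)$count  # 1
count_particles <- function(mask, min_area_px = 400) {
  min_area_px <- check_count(min_area_px, "min_area_px")
  lab <- label_8conn(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- areas[areas >= min_area_px]
  structure(list(count = length(keep), particle_areas_px = keep,
                 mask_fraction = mean(mask > 0)),
            class = "count_result")
}

#' Count microglia in a two-channel stack
#'
#' End-to-end macro: z-project and background-subtract, threshold the
#' DAPI projection, gate the Iba1 projection by the dilated nuclear
#' selection, threshold the gated image, despeckle/remove outliers, and
#' count particles of at least `min_area_px`.
#'
#' @param stack An `image_stack`.
#' @param min_area_px Particle cutoff (default 400 px).
#' @param dilate_radius Nuclear-selection expansion, px.
#' @param ball_radius Background radius for [preprocess()].
#' @param verbose Return per-stage intermediates.
#' @return A `count_result`; with `verbose = TRUE` also `stages`.
#' @export
count_microglia <- function(stack, min_area_px = 400, dilate_radius = 5,
                            ball_radius = 50, verbose = FALSE) {
  pp <- preprocess(stack, ball_radius = ball_radius)
  if (diff(range(pp$dapi_2d)) == 0 || diff(range(pp$iba1_2d)) == 0) {
    res <- structure(list(count = 0L, particle_areas_px = integer(0),
                          mask_fraction = 0),
                     class = "count_result")
    if (verbose) res$stages <- pp
    return(res)
  }
  dapi_mask <- threshold_default_dark(pp$dapi_2d)
  gated <- dapi_gate(pp$iba1_2d, dapi_mask, dilate_radius)
  if (diff(range(gated)) == 0) {
    res <- structure(list(count = 0L, particle_areas_px = integer(0),
                          mask_fraction = 0),
                     class = "count_result")
    if (verbose) res$stages <- c(pp, list(dapi_mask = dapi_mask))
    return(res)
  }
  iba_mask <- threshold_default_dark(gated)
  cleaned <- clean_mask(iba_mask)
  res <- count_particles(cleaned, min_area_px)
  if (verbose)
    res$stages <- c(pp, list(dapi_mask = dapi_mask, gated = gated,
                             iba_mask = iba_mask, cleaned = cleaned))
  res
}
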