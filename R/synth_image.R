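# Synthetic two-channel fluorescence stacks: nuclei (DAPI channel) and
# ramified microglia (Iba1 channel) with known planted counts.

#' Specification of a synthetic two-channel image stack
#'
#' @param shape `c(height, width)` in pixels.
#' @param n_slices Stack depth (1-16; acquisitions use 5-7).
#' @param n_microglia Planted microglia (somata overlap a nucleus).
#' @param n_other_nuclei Additional plain nuclei (no Iba1 signal).
#' @param soma_radius_px Microglial soma radius; nuclei are Gaussian
#'   blobs of sigma `soma_radius_px / 2`.
#' @param n_arms Ramifications per microglia (3-5 typical).
#' @param arm_length_px Ramification length.
#' @param background_level Constant background intensity (8-bit scale).
#' @param noise_sd Additive Gaussian noise sd (8-bit scale).
#' @param seed Integer seed.
#' @return List of class `image_spec`.
#' @export
image_spec <- function(shape = c(320, 320), n_slices = 6, n_microglia = 10,
                       n_other_nuclei = 15, soma_radius_px = 12,
                       n_arms = 4, arm_length_px = 22,
                       background_level = 20, noise_sd = 6, seed = 1) {
  if (length(shape) != 2 || any(shape < 64))
    stop_field("shape", "must be (height, width), each >= 64")
  n_slices <- check_count(n_slices, "n_slices", lower = 1)
  if (n_slices > 16) stop_field("n_slices", "must be <= 16")
  n_microglia <- check_count(n_microglia, "n_microglia")
  n_other_nuclei <- check_count(n_other_nuclei, "n_other_nuclei")
  check_scalar(soma_radius_px, "soma_radius_px", lower = 3)
  n_arms <- check_count(n_arms, "n_arms", lower = 0)
  check_scalar(arm_length_px, "arm_length_px", lower = 0)
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_count(seed, "seed")
  margin <- soma_radius_px + arm_length_px + 3
  if (2 * margin >= min(shape))
    stop_field("shape", "too small for the requested object geometry")
  structure(list(shape = shape, n_slices = n_slices,
                 n_microglia = n_microglia,
                 n_other_nuclei = n_other_nuclei,
                 soma_radius_px = soma_radius_px, n_arms = n_arms,
                 arm_length_px = arm_length_px,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = seed),
            class = "image_spec")
}

# Paint an additive Gaussian blob onto a matrix.
paint_blob <- function(img, cy, cx, sigma, peak) {
  r <- ceiling(3 * sigma)
  ys <- max(1, cy - r):min(nrow(img), cy + r)
  xs <- max(1, cx - r):min(ncol(img), cx + r)
  g <- outer(ys, xs, function(y, x)
    peak * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)))
  img[ys, xs] <- pmax(img[ys, xs], g)
  img
}

paint_disc <- function(img, cy, cx, radius, value) {
  r <- ceiling(radius)
  ys <- max(1, cy - r):min(nrow(img), cy + r)
  xs <- max(1, cx - r):min(ncol(img), cx + r)
  m <- outer(ys, xs, function(y, x) (y - cy)^2 + (x - cx)^2 <= radius^2)
  img[ys, xs][m] <- pmax(img[ys, xs][m], value)
  img
}

paint_arm <- function(img, cy, cx, angle, from, to, value) {
  steps <- seq(from, to, by = 0.5)
  for (s in steps) {
    y <- round(cy + s * sin(angle)); x <- round(cx + s * cos(angle))
    ys <- max(1, y - 1):min(nrow(img), y + 1)
    xs <- max(1, x - 1):min(ncol(img), x + 1)
    img[ys, xs] <- pmax(img[ys, xs], value)
  }
  img
}

#' Generate a synthetic two-channel stack with ground truth
#'
#' Channel 1 (DAPI) holds `n_microglia + n_other_nuclei` nuclei rendered
#' as Gaussian blobs; channel 2 (Iba1) holds ramified microglia whose
#' soma disks overlap their nuclei. Object intensity is distributed over
#' slices with a Gaussian axial profile so a maximum projection recovers
#' it. Placement uses rejection sampling with bounded retries; an
#' overcrowded specification errors.
#'
#' @param spec An [image_spec()].
#' @return List: `stack` (list `dapi`, `iba1`: arrays H x W x n_slices,
#'   8-bit scale) and `truth` (`data.frame` of centers and types, plus
#'   `n_microglia`).
#' @export
#' @examples
#' out <- gen_image_stack(image_spec(n_microglia = 3, n_other_nuclei = 2,
#'                                   noise_sd = 0, seed = 5))
#' out$truth$n_microglia  # 3
gen_image_stack <- function(spec) {
  H <- spec$shape[1]; W <- spec$shape[2]
  n_obj <- spec$n_microglia + spec$n_other_nuclei
  margin <- ceiling(spec$soma_radius_px + spec$arm_length_px + 3)
  # Somata/nuclei must stay disjoint after mask dilation; ramifications
  # may approach other nuclei (the size cutoff excludes such specks).
  min_sep <- 3 * spec$soma_radius_px

  with_private_seed(spec$seed, {
    centers <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centers) < n_obj) {
      tries <- tries + 1
      if (tries > 200 * max(n_obj, 1))
        stop("overcrowded image spec: cannot place objects without ",
             "overlap", call. = FALSE)
      cand <- c(runif(1, margin, H - margin), runif(1, margin, W - margin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= min_sep))
        centers <- rbind(centers, cand)
    }
    centers <- round(centers)

    dapi2d <- matrix(0, H, W)
    iba2d <- matrix(0, H, W)
    sigma_nuc <- spec$soma_radius_px / 2
    arm_dirs <- list()
    for (i in seq_len(n_obj)) {
      dapi2d <- paint_blob(dapi2d, centers[i, 1], centers[i, 2],
                           sigma_nuc, 200)
      if (i <= spec$n_microglia) {
        iba2d <- paint_disc(iba2d, centers[i, 1], centers[i, 2],
                            spec$soma_radius_px, 180)
        k <- if (spec$n_arms > 0) spec$n_arms else 0
        angles <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(k) / max(k, 1)
        for (a in angles)
          iba2d <- paint_arm(iba2d, centers[i, 1], centers[i, 2], a,
                             spec$soma_radius_px - 1,
                             spec$soma_radius_px + spec$arm_length_px, 120)
        arm_dirs[[i]] <- angles
      }
    }

    # Axial profile: every object centered on a random slice; per-slice
    # weight Gaussian in slice distance (max projection recovers 1).
    ns <- spec$n_slices
    dapi <- array(0, c(H, W, ns))
    iba <- array(0, c(H, W, ns))
    z0 <- if (ns == 1) 1 else sample(ns, 1)
    wz <- exp(-((seq_len(ns) - z0)^2) / 2)
    for (s in seq_len(ns)) {
      dapi[, , s] <- dapi2d * wz[s]
      iba[, , s] <- iba2d * wz[s]
    }

    if (spec$background_level > 0 || spec$noise_sd > 0) {
      dapi <- dapi + spec$background_level +
        array(rnorm(length(dapi), 0, spec$noise_sd), dim(dapi))
      iba <- iba + spec$background_level +
        array(rnorm(length(iba), 0, spec$noise_sd), dim(iba))
    }
    dapi <- pmin(pmax(dapi, 0), 255)
    iba <- pmin(pmax(iba, 0), 255)

    truth <- data.frame(
      y = centers[, 1], x = centers[, 2],
      type = rep(c("microglia", "nucleus"),
                 c(spec$n_microglia, spec$n_other_nuclei)))
    list(stack = structure(list(dapi = dapi, iba1 = iba),
                           class = "image_stack"),
         truth = structure(list(centers = truth,
                                n_microglia = spec$n_microglia),
                           class = "image_truth"))
  })
}
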