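#' Volumetric image container
#'
#' @param voxels 3-D numeric intensity array.
#' @param voxel_volume volume of one voxel in mm^3 (> 0); the acquisition
#'   here corresponds to 1.44 mm^3.
#' @param brain_mask 3-D logical array of in-brain voxels; defaults to all
#'   `TRUE`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, voxel_volume = 1.44, brain_mask = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array")
  }
  if (voxel_volume <= 0) stop("`voxel_volume` must be positive")
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim(voxels))
  }
  if (!identical(dim(brain_mask), dim(voxels))) {
    stop("`brain_mask` dimensions must match `voxels`")
  }
  structure(list(voxels = voxels, voxel_volume = voxel_volume,
                 brain_mask = brain_mask),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s, %.3g mm^3/voxel, %d in-mask voxels\n",
              paste(dim(x$voxels), collapse = "x"), x$voxel_volume,
              sum(x$brain_mask)))
  invisible(x)
}

#' Fit a Gaussian model to the brain intensity histogram
#'
#' Models the in-mask intensity distribution as a single Gaussian.  With
#' `robust = TRUE`, location and scale are first estimated by median/MAD
#' (which a moderate bright-lesion load barely moves), voxels above
#' `mu + k * sigma` of that estimate are excluded, and the Gaussian moments
#' are re-fit on the retained voxels.  A re-fit anchored on the plain
#' first-pass moments is not robust: with a substantial lesion load the
#' first-pass threshold sits above the lesion intensities.
#'
#' @param volume a [volume_image()].
#' @param k threshold multiplier retained with the model (default 3.5).
#' @param robust logical; median/MAD-anchored upper-tail exclusion.
#' @return list of class `gaussian_model`: `mu`, `sigma`, `k`.
#' @export
fit_background <- function(volume, k = 3.5, robust = FALSE) {
  stopifnot(inherits(volume, "volume_image"))
  x <- volume$voxels[volume$brain_mask]
  if (length(x) < 100L) stop("brain mask must contain at least 100 voxels")
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sigma == 0) stop("degenerate intensity distribution (sigma = 0)")
  if (robust) {
    mu_r <- stats::median(x)
    sigma_r <- stats::mad(x)
    if (sigma_r == 0) stop("degenerate intensity distribution (MAD = 0)")
    keep <- x <= mu_r + k * sigma_r
    mu <- mean(x[keep])
    sigma <- stats::sd(x[keep])
    if (!is.finite(sigma) || sigma == 0) {
      stop("degenerate intensity distribution after re-fit")
    }
  }
  structure(list(mu = mu, sigma = sigma, k = k), class = "gaussian_model")
}

#' Segment white-matter hyperintensities
#'
#' Classifies in-brain voxels whose intensity exceeds `mu + k * sigma` of
#' the Gaussian background model as WMH.
#'
#' @param volume a [volume_image()].
#' @param model a [fit_background()] result.
#' @param k threshold multiplier; defaults to the model's `k` (3.5).
#' @return 3-D logical mask.
#' @export
segment_wmh <- function(volume, model, k = model$k) {
  stopifnot(inherits(volume, "volume_image"), inherits(model, "gaussian_model"))
  volume$brain_mask & (volume$voxels > model$mu + k * model$sigma)
}

#' Lesion volume in mm^3
#'
#' @param mask logical lesion mask.
#' @param voxel_volume voxel size in mm^3 (default 1.44).
#' @return total lesion volume (voxel count times voxel size).
#' @export
lesion_volume <- function(mask, voxel_volume = 1.44) {
  if (!is.logical(mask)) stop("`mask` must be logical")
  sum(mask) * voxel_volume
}

# 26-connected component labelling of a 3-D logical mask.
# Returns an integer array, 0 = background, 1..n = component ids.
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  # relative offsets of the 26 neighbours
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  current <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    lab[seed] <- current
    while (length(queue) > 0L) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      vc <- arrayInd(v, d)
      nb <- sweep(off, 2L, as.integer(vc), `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      nl <- nb[, 1L] + (nb[, 2L] - 1L) * d[1L] + (nb[, 3L] - 1L) * d[1L] * d[2L]
      nl <- nl[mask[nl] & lab[nl] == 0L]
      if (length(nl) > 0L) {
        lab[nl] <- current
        queue <- c(queue, nl)
      }
    }
  }
  lab
}

#' Replace lesion intensities by their normal-appearing surround
#'
#' For each 26-connected lesion component, estimates the normal white-matter
#' intensity as the mean of non-lesion, in-brain voxels within a 2-voxel
#' (Chebyshev) shell around the component and replaces the component's
#' voxels in the T1 by that estimate.  Voxels outside the mask are never
#' modified.  Components with an empty shell are left unchanged and flagged.
#'
#' @param t1 a [volume_image()] aligned with the lesion mask.
#' @param wmh_mask logical lesion mask.
#' @param shell_radius Chebyshev radius of the surround shell (default 2).
#' @return list with `volume` (corrected [volume_image()]) and
#'   `flagged_components` (integer ids with empty shells).
#' @export
correct_t1_intensity <- function(t1, wmh_mask, shell_radius = 2L) {
  stopifnot(inherits(t1, "volume_image"))
  if (!identical(dim(wmh_mask), dim(t1$voxels))) {
    stop("mask dimensions must match the T1 volume")
  }
  d <- dim(t1$voxels)
  lab <- label_components_26(wmh_mask)
  ncomp <- max(lab)
  out <- t1
  flagged <- integer(0L)
  if (ncomp == 0L) return(list(volume = out, flagged_components = flagged))
  r <- shell_radius
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  for (comp in seq_len(ncomp)) {
    vox <- which(lab == comp)
    vc <- arrayInd(vox, d)
    cand <- NULL
    for (i in seq_len(nrow(off))) {
      nb <- sweep(vc, 2L, off[i, ], `+`)
      ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
            nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
            nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
      nb <- nb[ok, , drop = FALSE]
      cand <- c(cand, nb[, 1L] + (nb[, 2L] - 1L) * d[1L] +
                      (nb[, 3L] - 1L) * d[1L] * d[2L])
    }
    cand <- unique(cand)
    shell <- cand[!wmh_mask[cand] & t1$brain_mask[cand]]
    if (length(shell) == 0L) {
      flagged <- c(flagged, comp)
      next
    }
    out$voxels[vox] <- mean(t1$voxels[shell])
  }
  list(volume = out, flagged_components = flagged)
}

#' Optional low-pass bias-field division
#'
#' Divides the volume by a heavily smoothed copy of itself (separable
#' Gaussian, default sigma 25 mm), a crude stand-in for radio-frequency
#' inhomogeneity filtering.  Off by default in the pipeline.
#'
#' @param volume a [volume_image()].
#' @param sigma_mm Gaussian sigma in mm.
#' @param voxel_mm linear voxel dimension in mm (default
#'   `voxel_volume^(1/3)`).
#' @return bias-corrected [volume_image()].
#' @export
bias_correct <- function(volume, sigma_mm = 25,
                         voxel_mm = volume$voxel_volume^(1 / 3)) {
  stopifnot(inherits(volume, "volume_image"))
  sig <- sigma_mm / voxel_mm
  half <- max(1L, as.integer(ceiling(2 * sig)))
  kern <- stats::dnorm(-half:half, sd = sig)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    dm <- dim(ap)
    m <- matrix(ap, nrow = dm[1L])
    padded <- rbind(m[rep(1L, half), , drop = FALSE], m,
                    m[rep(nrow(m), half), , drop = FALSE])
    sm <- apply(padded, 2L, function(col) stats::filter(col, kern, sides = 2))
    sm <- sm[(half + 1L):(half + dm[1L]), , drop = FALSE]
    arr <- array(sm, dm)
    aperm(arr, order(perm))
  }
  bias <- volume$voxels
  for (ax in 1:3) bias <- smooth_axis(bias, ax)
  bias[bias <= 0 | !is.finite(bias)] <- 1
  volume$voxels <- volume$voxels / bias * mean(bias[volume$brain_mask])
  volume
}
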