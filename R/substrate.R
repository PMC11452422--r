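# Crossing-fiber ground-truth substrate: Gaussian compartments, true tensors
# and true scalar metrics.

#' Axially symmetric diffusion tensor from axial/radial diffusivities
#'
#' @param ad axial diffusivity (eigenvalue along `axis`), mm^2/s.
#' @param rd radial diffusivity (doubly degenerate eigenvalue), mm^2/s.
#' @param axis principal axis (unit 3-vector; renormalized).
#' @return Symmetric 3x3 tensor `rd * I + (ad - rd) * axis axis'`.
#' @examples
#' compartment_tensor(1.4e-3, 0.1e-3, c(1, 0, 0))
#' @export
compartment_tensor <- function(ad, rd, axis) {
  if (rd > ad) stop("radial diffusivity exceeds axial diffusivity")
  if (rd < 0) stop("diffusivities must be non-negative")
  axis <- axis / sqrt(sum(axis^2))
  rd * diag(3) + (ad - rd) * tcrossprod(axis)
}

#' Crossing-fiber substrate with intra- and extra-cellular compartments
#'
#' Builds the white-matter-like ground truth used throughout the simulation
#' study: two fiber populations crossing at `angle` degrees, each modeled by
#' an intra-cellular and an extra-cellular Gaussian compartment, all four
#' with equal volume fractions. Defaults follow common single-voxel DKI
#' simulation practice: intra-cellular AD/RD = 1.4/0.1 x 10^-3 mm^2/s,
#' extra-cellular AD/RD = 2.0/0.5 x 10^-3 mm^2/s, crossing angle 60 degrees.
#' The whole substrate can be rotated rigidly (both fibers together, so the
#' crossing angle is preserved) either by a supplied rotation matrix or by a
#' seeded uniformly random rotation.
#'
#' @param angle crossing angle between the two fiber axes, degrees.
#' @param ad_intra,rd_intra intra-cellular axial/radial diffusivity, mm^2/s.
#' @param ad_extra,rd_extra extra-cellular axial/radial diffusivity, mm^2/s.
#' @param fractions volume fractions of (fiber1-intra, fiber1-extra,
#'   fiber2-intra, fiber2-extra); must sum to 1.
#' @param rotation 3x3 rotation matrix applied to the canonical frame
#'   (fiber 1 along x, fiber 2 in the xy-plane), or `NULL`.
#' @param seed if `rotation` is `NULL` and `seed` is given, a seeded
#'   uniformly random rotation is drawn.
#' @return A `fiber_substrate` object: list of compartment tensors,
#'   fractions, fiber axes, crossing angle and rotation.
#' @export
fiber_substrate <- function(angle = 60,
                            ad_intra = 1.4e-3, rd_intra = 0.1e-3,
                            ad_extra = 2.0e-3, rd_extra = 0.5e-3,
                            fractions = rep(0.25, 4),
                            rotation = NULL, seed = NULL) {
  if (abs(sum(fractions) - 1) > 1e-12 || any(fractions < 0))
    stop("`fractions` must be non-negative and sum to 1")
  if (is.null(rotation)) {
    rotation <- if (is.null(seed)) diag(3) else
      .with_seed(seed, .random_rotation())
  }
  rotation <- as.matrix(rotation)
  a <- angle * pi / 180
  ax1 <- as.vector(rotation %*% c(1, 0, 0))
  ax2 <- as.vector(rotation %*% c(cos(a), sin(a), 0))
  tensors <- list(compartment_tensor(ad_intra, rd_intra, ax1),
                  compartment_tensor(ad_extra, rd_extra, ax1),
                  compartment_tensor(ad_intra, rd_intra, ax2),
                  compartment_tensor(ad_extra, rd_extra, ax2))
  structure(list(tensors = tensors, fractions = fractions,
                 axes = rbind(ax1, ax2), angle = angle, rotation = rotation),
            class = "fiber_substrate")
}

#' @export
print.fiber_substrate <- function(x, ...) {
  cat("Crossing-fiber substrate:", length(x$tensors), "Gaussian compartments,",
      sprintf("crossing angle %g deg\n", x$angle))
  md <- sum(mapply(function(D, f) f * sum(diag(D)), x$tensors, x$fractions)) / 3
  cat(sprintf("  mixture mean diffusivity: %.5g mm^2/s\n", md))
  invisible(x)
}

# n'D_k n for all compartments: returns length(f) x nrow(dirs) matrix.
.compartment_adc <- function(substrate, dirs) {
  adc <- vapply(substrate$tensors,
                function(D) rowSums((dirs %*% D) * dirs),
                numeric(nrow(dirs)))
  if (is.null(dim(adc))) adc <- matrix(adc, nrow = 1L)  # single direction
  t(adc)
}

# Directional kurtosis of the Gaussian mixture (no exchange):
# K(n) = 3 (sum_k f_k D_k(n)^2 - Dbar(n)^2) / Dbar(n)^2
.mixture_kurtosis <- function(substrate, dirs) {
  adc <- .compartment_adc(substrate, dirs)
  f <- substrate$fractions
  dbar <- as.vector(f %*% adc)
  m2 <- as.vector(f %*% adc^2)
  3 * (m2 - dbar^2) / dbar^2
}

# Mean diffusion tensor of the mixture.
.mixture_dt <- function(substrate) {
  Reduce(`+`, Map(`*`, substrate$tensors, substrate$fractions))
}

# Ground-truth DKI tensors of the mixture: the 3x3 mean diffusion tensor and
# the 15 unique kurtosis-tensor components scaled by MD^2 (the natural
# regression parameterization). W(n) is exactly a quartic form in n, so the
# components are recovered exactly from a linear solve on 45 directions.
.substrate_dki_tensors <- function(substrate) {
  Dbar <- .mixture_dt(substrate)
  dirs <- .sphere_dirs(45L)
  adc <- .compartment_adc(substrate, dirs)
  f <- substrate$fractions
  dbar <- as.vector(f %*% adc)
  m2 <- as.vector(f %*% adc^2)
  qhat <- 3 * (m2 - dbar^2)        # = MD^2 * W(n), a quartic form
  w15 <- qr.solve(.quartic_basis(dirs), qhat)
  list(dt = Dbar, kt_md2 = w15)
}

# FA/MD/AD/RD and principal axis from a symmetric 3x3 tensor.
.tensor_scalars <- function(D) {
  ev <- eigen(D, symmetric = TRUE)
  l <- ev$values
  md <- mean(l)
  fa <- sqrt(1.5 * sum((l - md)^2) / sum(l^2))
  list(fa = fa, md = md, ad = l[1], rd = mean(l[2:3]), e1 = ev$vectors[, 1])
}

#' Ground-truth scalar metrics of a substrate
#'
#' Computes the seven DKI scalar parameters implied by the Gaussian-mixture
#' substrate: FA, MD, AD and RD from the eigenvalues of the mixture mean
#' diffusion tensor, and MK, AK, RK from the directional kurtosis
#' \eqn{K(n) = 3(\sum_k f_k (n'D_k n)^2 - (n'\bar D n)^2)/(n'\bar D n)^2}
#' averaged over a dense quasi-uniform sphere (MK), evaluated along the
#' principal eigenvector (AK), and averaged over 36 equally spaced
#' directions in the perpendicular plane (RK).
#'
#' @param substrate a [fiber_substrate()].
#' @param sphere_n number of quasi-uniform sphere directions for MK.
#' @return Named numeric vector `c(FA, MD, AD, RD, MK, AK, RK)`.
#' @export
ground_truth_metrics <- function(substrate, sphere_n = 10242L) {
  stopifnot(inherits(substrate, "fiber_substrate"))
  Dbar <- .mixture_dt(substrate)
  if (sum(diag(Dbar)) <= 0) stop("degenerate mixture tensor")
  s <- .tensor_scalars(Dbar)
  mk <- mean(.mixture_kurtosis(substrate, .sphere_dirs(sphere_n)))
  ak <- .mixture_kurtosis(substrate, matrix(s$e1, 1))
  rk <- mean(.mixture_kurtosis(substrate, .perp_circle(s$e1)))
  c(FA = s$fa, MD = s$md, AD = s$ad, RD = s$rd, MK = mk, AK = ak, RK = rk)
}
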