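# Scalar DKI parameters derived from a fitted model.

#' Diffusion-tensor scalars of a DKI fit
#'
#' Eigen-decomposes the fitted diffusion tensor (eigenvalues sorted
#' descending) and returns fractional anisotropy, mean, axial and radial
#' diffusivity:
#' \eqn{MD = \bar\lambda}, \eqn{AD = \lambda_1},
#' \eqn{RD = (\lambda_2+\lambda_3)/2},
#' \eqn{FA = \sqrt{3/2}\,\|\lambda-\bar\lambda\|/\|\lambda\|}.
#'
#' @param fit a `dki_fit`, or a symmetric 3x3 diffusion tensor.
#' @return Named vector `c(FA, MD, AD, RD)` (diffusivities in mm^2/s).
#' @export
dt_scalars <- function(fit) {
  D <- if (inherits(fit, "dki_fit")) fit$dt else as.matrix(fit)
  s <- .tensor_scalars(D)
  if (!all(is.finite(c(s$fa, s$md)))) stop("non-finite eigenvalues")
  c(FA = s$fa, MD = s$md, AD = s$ad, RD = s$rd)
}

#' Kurtosis scalars of a DKI fit
#'
#' Mean kurtosis is the average apparent kurtosis over `sphere_n`
#' quasi-uniform sphere directions; axial kurtosis is the apparent kurtosis
#' along the diffusion tensor's principal eigenvector; radial kurtosis is
#' the average over 36 equally spaced directions in the perpendicular
#' plane. Numerical spherical averaging is used throughout (no closed
#' form), so `sphere_n` controls the MK quadrature error.
#'
#' @param fit a `dki_fit`.
#' @param sphere_n number of sphere directions for the MK average.
#' @return Named vector `c(MK, AK, RK)` (dimensionless).
#' @export
kurtosis_scalars <- function(fit, sphere_n = 10242L) {
  stopifnot(inherits(fit, "dki_fit"))
  m <- .metrics_batch(matrix(fit$coefficients, ncol = 1), sphere_n)
  c(MK = unname(m["MK", 1]), AK = unname(m["AK", 1]),
    RK = unname(m["RK", 1]))
}

#' All seven DKI scalar parameters of a fit
#'
#' @inheritParams kurtosis_scalars
#' @return Named vector `c(FA, MD, AD, RD, MK, AK, RK)`.
#' @export
dki_metrics <- function(fit, sphere_n = 10242L) {
  stopifnot(inherits(fit, "dki_fit"))
  m <- .metrics_batch(matrix(fit$coefficients, ncol = 1), sphere_n)
  setNames(m[, 1], rownames(m))
}

# Cached sphere design blocks, keyed by resolution, since the quartic basis
# over ten thousand directions is reused across every fitted instance.
.sphere_cache <- new.env(parent = emptyenv())
.sphere_design <- function(sphere_n) {
  key <- as.character(sphere_n)
  if (is.null(.sphere_cache[[key]])) {
    dirs <- .sphere_dirs(sphere_n)
    .sphere_cache[[key]] <- list(quad = .quad_basis(dirs),
                                 quartic = .quartic_basis(dirs))
  }
  .sphere_cache[[key]]
}

# Batch scalar metrics from a 22 x m coefficient matrix. MK is computed by
# chunked matrix products over the sphere; AK/RK need the per-instance
# principal axis, so they run in a light per-instance loop.
.metrics_batch <- function(beta, sphere_n = 10242L, chunk = 256L) {
  m <- ncol(beta)
  sph <- .sphere_design(sphere_n)
  out <- matrix(NA_real_, 7L, m,
                dimnames = list(c("FA", "MD", "AD", "RD", "MK", "AK", "RK"),
                                NULL))
  dt6 <- beta[2:7, , drop = FALSE]
  kt15 <- beta[8:22, , drop = FALSE]
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    dapp <- sph$quad %*% dt6[, lo:hi, drop = FALSE]
    qhat <- sph$quartic %*% kt15[, lo:hi, drop = FALSE]
    out["MK", lo:hi] <- colMeans(qhat / pmax(dapp, 1e-300)^2)
  }
  for (j in seq_len(m)) {
    D <- .dt_matrix(dt6[, j])
    s <- .tensor_scalars(D)
    out["FA", j] <- s$fa; out["MD", j] <- s$md
    out["AD", j] <- s$ad; out["RD", j] <- s$rd
    if (s$md <= 0) next
    e1 <- s$e1
    q1 <- as.vector(.quartic_basis(matrix(e1, 1)) %*% kt15[, j])
    out["AK", j] <- q1 / s$ad^2
    perp <- .perp_circle(e1)
    dp <- as.vector(.quad_basis(perp) %*% dt6[, j])
    qp <- as.vector(.quartic_basis(perp) %*% kt15[, j])
    out["RK", j] <- mean(qp / dp^2)
  }
  out
}
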