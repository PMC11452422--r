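# DKI model fitting: log-linear design, two-pass weighted least squares and
# the positivity-constrained (quadratic-programming) variant.

#' Design matrix of the log-linear DKI model
#'
#' One row per volume (b, n):
#' `[1, -b * quadratic(n), (b^2/6) * quartic(n)]`, so that with coefficient
#' vector `(ln S0, D_6, MD^2 W_15)` the model is
#' \eqn{\ln S = \ln S_0 - b D_{app}(n) + \tfrac{b^2}{6} MD^2 W(n)}. The
#' kurtosis block is parameterized as `MD^2 * W` to keep the system linear;
#' the conversion to the dimensionless kurtosis tensor happens at
#' metric-derivation time.
#'
#' @param scheme a [gradient_scheme()] with at least 22 volumes spanning at
#'   least two non-zero shells.
#' @return N x 22 matrix with named columns.
#' @export
dki_design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  if (nrow(scheme) < 22L)
    stop("DKI fitting needs at least 22 volumes")
  if (length(unique(scheme$bval[scheme$shell > 0L])) < 2L)
    stop("DKI fitting needs at least two non-zero shells")
  dirs <- as.matrix(scheme[, c("x", "y", "z")])
  b <- scheme$bval
  X <- cbind(1, -b * .quad_basis(dirs), (b^2 / 6) * .quartic_basis(dirs))
  colnames(X) <- .coef_names
  if (qr(X)$rank < 22L)
    stop("ill-posed scheme: design matrix is rank deficient")
  X
}

# Quartic constraint rows (positivity of apparent kurtosis) at the scheme's
# acquired diffusion directions, acting on the 15 kurtosis coefficients.
.constraint_rows <- function(scheme, dense = FALSE) {
  dirs <- scheme_directions(scheme)
  dirs <- unique(round(dirs, 12))
  if (dense) dirs <- rbind(dirs, .sphere_dirs(60L))
  .quartic_basis(dirs)
}

# Batch fitting engine. X: N x 22 design; S: N x m matrix of signal
# amplitudes (one column per instance); A: constraint rows on the kurtosis
# block (or NULL for unconstrained). Returns 22 x m coefficients and a
# per-instance convergence flag (0 ok, 1 constrained_active, 2 failed).
.fit_batch <- function(X, S, A = NULL, floor_frac = 1e-10, s0 = NULL) {
  S <- as.matrix(S)
  m <- ncol(S)
  if (is.null(s0)) s0 <- max(S)
  y <- log(pmax(S, floor_frac * s0))
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))            # OLS pass, all instances
  flag <- integer(m)
  kt_idx <- 8:22
  Amat <- if (!is.null(A)) t(cbind(matrix(0, nrow(A), 7L), A))
  for (j in seq_len(m)) {
    w <- exp(2 * as.vector(X %*% beta[, j]))     # predicted-signal^2 weights
    w <- pmin(pmax(w, 1e-12), 1e12)
    Xw <- X * w
    H <- crossprod(Xw, X)
    g <- as.vector(crossprod(Xw, y[, j]))
    bj <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(bj)) { flag[j] <- 2L; next }
    if (!is.null(A)) {
      viol <- A %*% bj[kt_idx]
      if (any(viol < -1e-8)) {
        sc <- mean(diag(H))                      # scale for QP conditioning
        qp <- tryCatch(
          quadprog::solve.QP(H / sc, g / sc, Amat, rep(0, ncol(Amat))),
          error = function(e) NULL)
        if (is.null(qp)) {
          ridge <- diag(1e-10 * mean(diag(H)), nrow(H))
          qp <- tryCatch(
            quadprog::solve.QP((H + ridge) / sc, g / sc, Amat,
                               rep(0, ncol(Amat))),
            error = function(e) NULL)
        }
        if (is.null(qp)) { flag[j] <- 2L; next }
        bj <- qp$solution
        flag[j] <- 1L
      }
    }
    beta[, j] <- bj
  }
  rownames(beta) <- .coef_names
  list(coef = beta, flag = flag)
}

#' Fit the diffusional kurtosis model to a signal dataset
#'
#' Estimates the 22 DKI parameters (log baseline, 6 diffusion-tensor and 15
#' kurtosis-tensor components) from the log-signals by two-pass weighted
#' least squares: an ordinary least-squares pass followed by one reweighting
#' with weights equal to the squared predicted signals. With
#' `method = "constrained"` the weighted problem is solved subject to
#' non-negative apparent directional kurtosis along every acquired diffusion
#' direction (a linear inequality on the kurtosis block, solved as a
#' quadratic program); the constrained solution equals the unconstrained one
#' whenever no constraint is active. The constrained variant is the robust
#' choice at low SNR, where noise frequently drives apparent kurtosis
#' negative.
#'
#' @param signals a `signal_dataset` from [simulate_signal()] /
#'   [add_rician_noise()], or a numeric vector of amplitudes (then `scheme`
#'   is required).
#' @param scheme a [gradient_scheme()]; ignored when `signals` carries one.
#' @param method `"constrained"` (default) or `"wls"` (unconstrained).
#' @param dense_constraints also constrain 60 extra quasi-uniform sphere
#'   directions beyond the acquired ones.
#' @param floor_frac signals are floored at `floor_frac * s0` before the
#'   log, guarding against non-positive noisy amplitudes.
#' @return A `dki_fit` object with elements `coefficients` (named
#'   22-vector; kurtosis block is `MD^2 * W`), `dt` (3x3 tensor), `kt`
#'   (15 dimensionless kurtosis-tensor components `W`), `log_s0`,
#'   `convergence` (`"ok"`, `"constrained_active"` or `"failed"`), `scheme`,
#'   `signals`, `method`.
#' @seealso [dki_metrics()], [apparent_values()]
#' @export
dki_fit <- function(signals, scheme = NULL,
                    method = c("constrained", "wls"),
                    dense_constraints = FALSE, floor_frac = 1e-10) {
  method <- match.arg(method)
  s0 <- NULL
  if (inherits(signals, "signal_dataset")) {
    scheme <- signals$scheme
    s0 <- signals$s0
    signals <- signals$signals
  }
  if (is.null(scheme)) stop("`scheme` is required for a bare signal vector")
  X <- dki_design_matrix(scheme)
  A <- if (method == "constrained") .constraint_rows(scheme, dense_constraints)
  res <- .fit_batch(X, matrix(signals, ncol = 1), A,
                    floor_frac = floor_frac, s0 = s0)
  beta <- res$coef[, 1]
  md <- mean(beta[2:4])
  structure(list(coefficients = beta,
                 log_s0 = beta[[1]],
                 dt = .dt_matrix(beta[2:7]),
                 kt = beta[8:22] / md^2,
                 convergence = c("ok", "constrained_active",
                                 "failed")[res$flag[1] + 1L],
                 method = method, scheme = scheme, signals = signals,
                 design = X),
            class = "dki_fit")
}

#' @export
print.dki_fit <- function(x, digits = 4, ...) {
  cat("DKI fit (", x$method, "), ", length(x$signals), " volumes, convergence: ",
      x$convergence, "\n", sep = "")
  s <- .tensor_scalars(x$dt)
  cat(sprintf("  MD = %.*g mm^2/s, FA = %.*g\n",
              digits, s$md, digits, s$fa))
  invisible(x)
}

#' @export
coef.dki_fit <- function(object, ...) object$coefficients

#' @export
fitted.dki_fit <- function(object, ...) {
  as.vector(exp(object$design %*% object$coefficients))
}

#' @export
residuals.dki_fit <- function(object, ...) {
  object$signals - fitted(object)
}

#' Predicted signal amplitudes from a DKI fit
#'
#' @param object a `dki_fit`.
#' @param scheme optional [gradient_scheme()] at which to predict; defaults
#'   to the fitted scheme.
#' @param ... unused.
#' @return Numeric vector of predicted amplitudes.
#' @export
predict.dki_fit <- function(object, scheme = NULL, ...) {
  X <- if (is.null(scheme)) object$design else dki_design_matrix(scheme)
  as.vector(exp(X %*% object$coefficients))
}

#' @export
summary.dki_fit <- function(object, sphere_n = 10242L, ...) {
  out <- list(fit = object,
              metrics = dki_metrics(object, sphere_n = sphere_n),
              rmse = sqrt(mean(residuals(object)^2)))
  class(out) <- "summary.dki_fit"
  out
}

#' @export
print.summary.dki_fit <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("  scalar metrics:\n")
  print(signif(x$metrics, digits))
  cat(sprintf("  signal-domain RMSE: %.*g\n", digits, x$rmse))
  invisible(x)
}

#' Apparent diffusivity and kurtosis along a direction
#'
#' \eqn{D_{app}(n) = n' D n} and
#' \eqn{K_{app}(n) = (MD/D_{app})^2 \sum n_i n_j n_k n_l W_{ijkl}}.
#'
#' @param fit a `dki_fit`.
#' @param direction unit 3-vector.
#' @return List with `D_app` (mm^2/s) and `K_app` (dimensionless).
#' @export
apparent_values <- function(fit, direction) {
  stopifnot(inherits(fit, "dki_fit"))
  n <- matrix(direction / sqrt(sum(direction^2)), 1)
  beta <- fit$coefficients
  d_app <- as.vector(.quad_basis(n) %*% beta[2:7])
  if (d_app <= 0) stop("apparent kurtosis undefined: non-positive D_app")
  qhat <- as.vector(.quartic_basis(n) %*% beta[8:22])  # = MD^2 W(n)
  list(D_app = d_app, K_app = qhat / d_app^2)
}
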