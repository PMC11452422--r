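# Multi-shell gradient scheme container and design/ordering/subsampling tools.

#' Construct a multi-shell gradient scheme
#'
#' A gradient scheme is the ordered list of diffusion-MRI volumes to acquire:
#' one unit gradient direction and one b-value per volume. Volumes with
#' b-values below `b0_threshold` are treated as non-diffusion-weighted (b = 0)
#' and carry a zero direction vector. Equal b-values share a shell label
#' (shell 0 is reserved for b = 0); the row order is the acquisition order.
#'
#' @param directions numeric N x 3 matrix of gradient directions. Rows for
#'   diffusion-weighted volumes must have (close to) unit norm; they are
#'   renormalized. Rows for b = 0 volumes are ignored and stored as zeros.
#' @param bvalues numeric vector of N b-values in s/mm^2.
#' @param b0_threshold b-values at or below this are treated as b = 0.
#' @return A `gradient_scheme`: a data frame with columns `x`, `y`, `z`,
#'   `bval`, `shell` and `order` (0-based acquisition index).
#' @examples
#' sch <- gradient_scheme(rbind(c(0, 0, 0), diag(3)), c(0, 1000, 1000, 2000))
#' table(sch$shell)
#' @export
gradient_scheme <- function(directions, bvalues, b0_threshold = 50) {
  directions <- as.matrix(directions)
  storage.mode(directions) <- "double"
  if (ncol(directions) != 3L)
    stop("`directions` must have 3 columns")
  bvalues <- as.numeric(bvalues)
  if (nrow(directions) != length(bvalues))
    stop("`directions` and `bvalues` lengths disagree")
  b0 <- bvalues <= b0_threshold
  bvalues[b0] <- 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(!b0 & nrm < 1e-12))
    stop("zero direction vector on a diffusion-weighted volume")
  # renormalize genuinely non-unit rows; rows that are unit up to 6-decimal
  # fixed-point rounding are kept verbatim so gradient tables round-trip
  renorm <- !b0 & abs(nrm - 1) > 5e-6
  directions[renorm, ] <- directions[renorm, , drop = FALSE] / nrm[renorm]
  directions[b0, ] <- 0
  shells <- sort(unique(bvalues[!b0]))
  shell <- integer(length(bvalues))
  shell[!b0] <- match(bvalues[!b0], shells)
  out <- data.frame(x = directions[, 1], y = directions[, 2],
                    z = directions[, 3], bval = bvalues, shell = shell,
                    order = seq_along(bvalues) - 1L)
  class(out) <- c("gradient_scheme", "data.frame")
  out
}

#' @export
print.gradient_scheme <- function(x, ...) {
  dw <- x$shell > 0L
  cat("Multi-shell gradient scheme:", nrow(x), "volumes\n")
  for (s in sort(unique(x$shell[dw])))
    cat(sprintf("  shell %d: b = %g s/mm^2, %d directions\n",
                s, x$bval[x$shell == s][1], sum(x$shell == s)))
  cat("  b = 0 volumes:", sum(!dw), "\n")
  invisible(x)
}

# N x 3 matrix of directions; optionally restricted to one shell.
scheme_directions <- function(scheme, shell = NULL) {
  keep <- if (is.null(shell)) scheme$shell > 0L else scheme$shell == shell
  as.matrix(scheme[keep, c("x", "y", "z")])
}

.check_dirs <- function(directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  if (nrow(directions) < 2L) stop("need at least 2 directions")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-5)) stop("directions must have unit norm")
  directions
}

#' Number of directions retained in a truncated shell
#'
#' When a fraction of an acquisition is retained, the per-shell number of
#' diffusion-weighted directions is the fraction of the full count rounded to
#' the nearest integer (ties round up). At least 6 directions must remain for
#' the diffusion tensor to be estimable.
#'
#' @param n_dirs full number of directions in the shell.
#' @param fraction fraction of the shell retained, in (0, 1].
#' @return Integer number of retained directions.
#' @examples
#' subset_sizes(32, 0.95) # 30
#' subset_sizes(60, 0.70) # 42
#' @export
subset_sizes <- function(n_dirs, fraction) {
  if (length(n_dirs) > 1L || length(fraction) > 1L)
    return(mapply(subset_sizes, n_dirs, fraction))
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]")
  n_dirs <- as.integer(n_dirs)
  k <- as.integer(floor(fraction * n_dirs + 0.5))  # round half up
  if (k < 6L)
    stop("infeasible subset: fewer than 6 directions would remain")
  k
}

#' Bipolar electrostatic repulsion energy of a direction set
#'
#' The electrostatic repulsion model (EEM) scores the uniformity of a set of
#' gradient directions by placing a unit charge at each direction and its
#' antipode and summing Coulomb potentials over unordered pairs:
#' \eqn{\sum_{i<j} 1/\|u_i-u_j\| + 1/\|u_i+u_j\|}. Lower energy means more
#' uniform angular coverage.
#'
#' @param directions n x 3 matrix of unit vectors (n >= 2).
#' @return The scalar energy.
#' @examples
#' electrostatic_energy(rbind(c(1, 0, 0), c(0, 1, 0))) # sqrt(2)
#' @export
electrostatic_energy <- function(directions) {
  u <- .check_dirs(directions)
  n <- nrow(u)
  g <- tcrossprod(u)                     # u_i . u_j
  d1 <- sqrt(pmax(2 - 2 * g, 0))         # ||u_i - u_j||
  d2 <- sqrt(pmax(2 + 2 * g, 0))         # ||u_i + u_j||
  up <- upper.tri(d1)
  if (any(d1[up] < 1e-12) || any(d2[up] < 1e-12))
    stop("singular configuration: coincident or antipodal pair of directions")
  sum(1 / d1[up] + 1 / d2[up])
}

#' Covering radius (minimum pairwise line-angle) of a direction set
#'
#' The angular resolution of a sampling scheme: the smallest angle between
#' any two sampled lines on the sphere, treating each direction and its
#' antipode as the same line. Larger is better; always in [0, 90] degrees.
#'
#' @param directions n x 3 matrix of unit vectors (n >= 2).
#' @return Minimum pairwise line-angle in degrees.
#' @examples
#' covering_radius(diag(3)) # 90
#' @export
covering_radius <- function(directions) {
  u <- .check_dirs(directions)
  g <- abs(tcrossprod(u))
  gmax <- max(g[upper.tri(g)])
  acos(min(gmax, 1)) * 180 / pi
}

# ---- EEM optimizer -------------------------------------------------------

# Energy and Riemannian gradient of the weighted bipolar Coulomb objective.
# wmat[i, j] is the weight of pair (i, j).
.eem_energy_grad <- function(u, wmat, grad = TRUE) {
  g <- tcrossprod(u)
  d1 <- sqrt(pmax(2 - 2 * g, 1e-300))
  d2 <- sqrt(pmax(2 + 2 * g, 1e-300))
  diag(d1) <- Inf
  e <- sum(wmat * (1 / d1 + 1 / d2)) / 2
  if (!grad) return(list(energy = e))
  a <- wmat / d1^3
  b <- wmat / d2^3
  diag(a) <- 0; diag(b) <- 0
  gr <- -(u * (rowSums(a) + rowSums(b)) - a %*% u + b %*% u)
  # project onto the sphere's tangent space
  gr <- gr - u * rowSums(gr * u)
  list(energy = e, grad = gr)
}

# Joint local descent for all shells: objective = sum of per-shell bipolar
# energies + `coupling` times the energy of the union of all shells.
.optimize_dirs <- function(counts, coupling = 0.5, max_iter = 400L,
                           tol = 1e-10, init = NULL) {
  shell_of <- rep(seq_along(counts), counts)
  n <- sum(counts)
  same <- outer(shell_of, shell_of, `==`)
  wmat <- ifelse(same, 1 + coupling, coupling)
  diag(wmat) <- 0
  u <- if (is.null(init)) {
    m <- matrix(stats::rnorm(3 * n), n, 3)
    m / sqrt(rowSums(m^2))
  } else init
  eg <- .eem_energy_grad(u, wmat)
  step <- 1e-3
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (tries in 1:30) {
      cand <- u - step * eg$grad
      cand <- cand / sqrt(rowSums(cand^2))
      ec <- .eem_energy_grad(cand, wmat, grad = FALSE)$energy
      if (ec < eg$energy) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    rel <- (eg$energy - ec) / abs(eg$energy)
    u <- cand
    eg <- .eem_energy_grad(u, wmat)
    step <- step * 1.5
    if (rel < tol) break
  }
  list(dirs = u, shell = shell_of, energy = eg$energy, iterations = it)
}

#' Generate an optimized multi-shell sampling scheme
#'
#' Places the requested number of directions on each shell by minimizing the
#' bipolar electrostatic repulsion energy of every shell plus a coupling term
#' (weight `coupling`) on the energy of the union of all shells, so that both
#' each shell and the combined direction set cover the sphere uniformly. The
#' search is a seeded random start followed by projected gradient descent,
#' repeated `n_restarts` times, keeping the lowest-energy configuration.
#' The b = 0 volumes are appended with zero vectors; use
#' [order_scheme_eem()] to produce the interruption-robust acquisition order.
#'
#' @param n_per_shell integer vector of directions per shell (each >= 6).
#' @param bvalues b-value of each shell, s/mm^2.
#' @param n_b0 number of b = 0 volumes.
#' @param seed integer seed making the optimization deterministic.
#' @param coupling weight of the combined-shell energy term.
#' @param n_restarts number of random restarts.
#' @param max_iter descent iterations per restart.
#' @return A [gradient_scheme()] with b = 0 volumes first, then each shell's
#'   directions (unordered within shell; see [order_scheme_eem()]).
#' @export
generate_scheme <- function(n_per_shell = c(32L, 60L),
                            bvalues = c(1000, 2000), n_b0 = 8L,
                            seed = 1L, coupling = 0.5,
                            n_restarts = 20L, max_iter = 2000L) {
  n_per_shell <- as.integer(n_per_shell)
  if (any(n_per_shell < 6L)) stop("each shell needs at least 6 directions")
  if (length(bvalues) != length(n_per_shell))
    stop("`bvalues` and `n_per_shell` lengths disagree")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    res <- .with_seed(.derive_seed(seed, 7001L, r),
                      .optimize_dirs(n_per_shell, coupling, max_iter))
    if (is.null(best) || res$energy < best$energy) best <- res
  }
  if (best$iterations >= max_iter)
    warning("EEM optimization did not fully converge; best-found returned")
  dirs <- rbind(matrix(0, n_b0, 3), best$dirs)
  bv <- c(rep(0, n_b0), bvalues[best$shell])
  gradient_scheme(dirs, bv)
}

# ---- Interruption-robust ordering ---------------------------------------

#' Reorder a scheme for robustness to acquisition interruption
#'
#' Rebuilds the acquisition order by incrementally appending diffusion
#' volumes: at each step the shell whose running count is furthest below its
#' share of the full scheme is chosen (largest-remainder rule, so every
#' prefix keeps the shells' relative proportions within one volume), and
#' within that shell the not-yet-placed direction that minimizes the bipolar
#' electrostatic energy of the prefix is appended. The b = 0 volumes are
#' interleaved at evenly spaced positions, the first at the start of the
#' acquisition. Truncating an acquisition ordered this way leaves a
#' near-uniform direction set on every shell.
#'
#' @param scheme a [gradient_scheme()].
#' @return The same volumes as a `gradient_scheme` in the new order.
#' @export
order_scheme_eem <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  dw_idx <- which(scheme$shell > 0L)
  b0_idx <- which(scheme$shell == 0L)
  shells <- sort(unique(scheme$shell[dw_idx]))
  n_s <- vapply(shells, function(s) sum(scheme$shell == s), 0L)
  prop <- n_s / sum(n_s)
  dirs <- as.matrix(scheme[, c("x", "y", "z")])
  placed <- integer(0)
  count <- setNames(rep(0L, length(shells)), shells)
  remaining <- split(dw_idx, scheme$shell[dw_idx])
  for (step in seq_along(dw_idx)) {
    deficit <- (length(placed) + 1L) * prop - count
    deficit[vapply(remaining, length, 0L) == 0L] <- -Inf
    s <- which.max(deficit)           # ties: lowest shell id (which.max)
    cand <- remaining[[s]]
    if (length(placed) == 0L) {
      pick <- cand[1L]
    } else {
      up <- dirs[placed, , drop = FALSE]
      uc <- dirs[cand, , drop = FALSE]
      g <- up %*% t(uc)
      d1 <- sqrt(pmax(2 - 2 * g, 1e-300))
      d2 <- sqrt(pmax(2 + 2 * g, 1e-300))
      add <- colSums(1 / d1 + 1 / d2)
      pick <- cand[which.min(add)]    # ties: lowest original index
    }
    placed <- c(placed, pick)
    remaining[[s]] <- setdiff(remaining[[s]], pick)
    count[s] <- count[s] + 1L
  }
  n_total <- nrow(scheme)
  pos_b0 <- 1L + floor((seq_along(b0_idx) - 1L) * n_total / length(b0_idx))
  new_order <- integer(n_total)
  new_order[pos_b0] <- b0_idx
  new_order[-pos_b0] <- placed
  out <- scheme[new_order, ]
  out$order <- seq_len(n_total) - 1L
  rownames(out) <- NULL
  class(out) <- c("gradient_scheme", "data.frame")
  out
}

# ---- Subsampling ---------------------------------------------------------

# 0.5 * mean per-shell covering radius + 0.5 * union covering radius,
# computed from a precomputed |u_i . u_j| matrix over candidate directions.
.sc_objective <- function(gabs, sel_by_shell) {
  cr <- function(idx) {
    if (length(idx) < 2L) return(90)
    sub <- gabs[idx, idx]
    acos(min(max(sub[upper.tri(sub)]), 1)) * 180 / pi
  }
  per_shell <- vapply(sel_by_shell, cr, 0)
  union_cr <- cr(unlist(sel_by_shell, use.names = FALSE))
  0.5 * mean(per_shell) + 0.5 * union_cr
}

# Greedy removal to the target counts, then pairwise-exchange refinement.
# All indices are row indices of `scheme`; the available pool per shell is
# the parent subset's directions (enforcing nesting along a chain).
.subsample_sc_idx <- function(scheme, pool_by_shell, target) {
  all_pool <- unlist(pool_by_shell, use.names = FALSE)
  dirs <- as.matrix(scheme[, c("x", "y", "z")])
  gabs <- abs(tcrossprod(dirs))
  gabs[gabs > 1] <- 1
  sel <- pool_by_shell
  repeat {
    counts <- vapply(sel, length, 0L)
    over <- which(counts > target)
    if (length(over) == 0L) break
    best_obj <- -Inf; best_s <- NA; best_i <- NA
    for (s in over) {
      for (i in sel[[s]]) {
        trial <- sel
        trial[[s]] <- setdiff(trial[[s]], i)
        o <- .sc_objective(gabs, trial)
        if (o > best_obj + 1e-12) { best_obj <- o; best_s <- s; best_i <- i }
      }
    }
    sel[[best_s]] <- setdiff(sel[[best_s]], best_i)
  }
  # pairwise exchange to a local optimum
  repeat {
    cur <- .sc_objective(gabs, sel)
    best_gain <- 1e-9; best <- NULL
    for (s in seq_along(sel)) {
      out_pool <- setdiff(pool_by_shell[[s]], sel[[s]])
      for (i in sel[[s]]) for (j in out_pool) {
        trial <- sel
        trial[[s]] <- sort(c(setdiff(trial[[s]], i), j))
        o <- .sc_objective(gabs, trial)
        if (o - cur > best_gain) { best_gain <- o - cur; best <- trial }
      }
    }
    if (is.null(best)) break
    sel <- best
  }
  sel
}

#' Subsample a gradient scheme
#'
#' Produces the reduced scheme retaining `fraction` of each shell's
#' diffusion-weighted volumes (per-shell counts from [subset_sizes()]); all
#' b = 0 volumes are always kept. Three strategies are available:
#' \describe{
#'   \item{`"eem"`}{truncation of the electrostatic-repulsion-ordered
#'     acquisition: the first retained volumes of each shell in acquisition
#'     order (requires a scheme ordered with [order_scheme_eem()] to be
#'     meaningful). Subsets are nested prefixes by construction.}
#'   \item{`"sc"`}{spherical-code selection: maximizes
#'     0.5 x mean per-shell covering radius + 0.5 x union covering radius by
#'     greedy removal followed by pairwise-exchange refinement. Pass the
#'     previous (larger) subset as `previous` to build the nested chain in
#'     which each level removes volumes from the preceding one.}
#'   \item{`"random"`}{seeded random shuffle of the diffusion-weighted
#'     volumes followed by truncation (the non-optimized reference
#'     strategy). By default all shells are shuffled jointly, so the
#'     per-shell split of the retained volumes is itself random
#'     (hypergeometric) — exactly what truncating a shuffled acquisition
#'     does; `balance_shells = TRUE` instead shuffles within each shell,
#'     keeping the per-shell counts at their nominal values. Subsets at
#'     different fractions under the same seed are nested (one shuffle,
#'     several truncation points).}
#' }
#'
#' @param scheme a [gradient_scheme()] (the full scheme).
#' @param fraction fraction of each shell retained, in (0, 1].
#' @param method one of `"eem"`, `"sc"`, `"random"`.
#' @param seed integer seed, required for `method = "random"`.
#' @param previous for `method = "sc"`, the scheme returned for the previous
#'   (larger) fraction, enforcing nesting; `NULL` starts from `scheme`.
#' @param balance_shells for `method = "random"`: shuffle within shells,
#'   fixing the per-shell counts (see Details).
#' @return A `gradient_scheme` with the retained volumes in their original
#'   acquisition order.
#' @export
subsample_scheme <- function(scheme, fraction,
                             method = c("eem", "sc", "random"),
                             seed = NULL, previous = NULL,
                             balance_shells = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "gradient_scheme"))
  shells <- sort(unique(scheme$shell[scheme$shell > 0L]))
  n_full <- vapply(shells, function(s) sum(scheme$shell == s), 0L)
  target <- vapply(seq_along(shells),
                   function(i) subset_sizes(n_full[i], fraction), 0L)
  parent <- if (is.null(previous)) scheme else previous
  stopifnot(inherits(parent, "gradient_scheme"))
  pool <- lapply(shells, function(s)
    which(scheme$order %in% parent$order[parent$shell == s]))
  if (any(vapply(pool, length, 0L) < target))
    stop("infeasible subset: parent has fewer directions than target")
  keep_dw <- switch(method,
    eem = unlist(lapply(seq_along(shells), function(i)
      pool[[i]][seq_len(target[i])]), use.names = FALSE),
    sc = unlist(.subsample_sc_idx(scheme, pool, target), use.names = FALSE),
    random = {
      if (is.null(seed)) stop("`seed` is required for random subsampling")
      if (balance_shells) {
        unlist(lapply(seq_along(shells), function(i)
          .with_seed(.derive_seed(seed, 31L, i), {
            perm <- sample(pool[[i]])
            sort(perm[seq_len(target[i])])
          })), use.names = FALSE)
      } else {
        dw <- which(scheme$shell > 0L)
        perm <- .with_seed(.derive_seed(seed, 31L, 0L), sample(dw))
        kept <- sort(perm[seq_len(sum(target))])
        cnt <- vapply(shells, function(s) sum(scheme$shell[kept] == s), 0L)
        if (any(cnt < 6L))
          stop("random truncation left a shell with fewer than 6 directions")
        kept
      }
    })
  keep <- sort(c(which(scheme$shell == 0L), keep_dw))
  out <- scheme[keep, ]
  rownames(out) <- NULL
  class(out) <- c("gradient_scheme", "data.frame")
  out
}

#' Build the nested chain of subsampled schemes for one strategy
#'
#' Convenience wrapper producing the subsets for several retained fractions.
#' For the spherical-code strategy each level is derived from the previous
#' one, so the chain is nested; for the other strategies each level is
#' derived from the full scheme (truncation chains are nested by
#' construction).
#'
#' @inheritParams subsample_scheme
#' @param fractions decreasing vector of retained fractions.
#' @return Named list of `gradient_scheme` objects (names are the fractions).
#' @export
subsample_chain <- function(scheme, fractions = c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5),
                            method = c("eem", "sc", "random"), seed = NULL) {
  method <- match.arg(method)
  fractions <- sort(fractions, decreasing = TRUE)
  out <- vector("list", length(fractions))
  names(out) <- format(fractions)
  prev <- NULL
  for (i in seq_along(fractions)) {
    out[[i]] <- subsample_scheme(scheme, fractions[i], method, seed = seed,
                                 previous = if (method == "sc") prev)
    prev <- out[[i]]
  }
  out
}
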