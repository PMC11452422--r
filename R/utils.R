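# Internal numerical helpers shared across modules.

#' @importFrom stats setNames
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library functions never disturb user RNG.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-task seed derived from a master seed and two indices.
# 131071 and 8191 are distinct Mersenne primes, so (a, b) pairs with
# a, b < 8191 map to distinct seeds; the modulus keeps the result a valid
# 32-bit seed.
.derive_seed <- function(master, a, b = 0L) {
  s <- (as.double(master) %% 1e6) * 1009 + a * 131071 + b * 8191
  as.integer(s %% 2147483629) + 1L
}

# Quasi-uniform directions on the unit sphere (Fibonacci lattice).
.sphere_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Quadratic-form basis: row i gives n'Dn as basis %*% c(dxx,dyy,dzz,dxy,dxz,dyz)
.quad_basis <- function(n) {
  cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
        2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
}

# Quartic-form basis over the 15 unique fourth-order tensor components,
# multinomial multiplicities included, so row i gives
# sum_{ijkl} n_i n_j n_k n_l W_ijkl as basis %*% w15.
.quartic_basis <- function(n) {
  x <- n[, 1]; y <- n[, 2]; z <- n[, 3]
  cbind(x^4, y^4, z^4,
        4 * x^3 * y, 4 * x^3 * z, 4 * x * y^3, 4 * y^3 * z,
        4 * x * z^3, 4 * y * z^3,
        6 * x^2 * y^2, 6 * x^2 * z^2, 6 * y^2 * z^2,
        12 * x^2 * y * z, 12 * x * y^2 * z, 12 * x * y * z^2)
}

.kt_names <- c("w1111", "w2222", "w3333",
               "w1112", "w1113", "w1222", "w2223", "w1333", "w2333",
               "w1122", "w1133", "w2233",
               "w1123", "w1223", "w1233")
.dt_names <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
.coef_names <- c("log_s0", .dt_names, .kt_names)

# Symmetric 3x3 from 6-vector (xx, yy, zz, xy, xz, yz).
.dt_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

# Two orthonormal vectors spanning the plane perpendicular to unit vector e1,
# with a deterministic choice of in-plane frame.
.perp_frame <- function(e1) {
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * e1) * e1
  u <- u / sqrt(sum(u^2))
  v <- c(e1[2] * u[3] - e1[3] * u[2],
         e1[3] * u[1] - e1[1] * u[3],
         e1[1] * u[2] - e1[2] * u[1])
  list(u = u, v = v)
}

# k directions equally spaced in the plane perpendicular to e1.
.perp_circle <- function(e1, k = 36L) {
  fr <- .perp_frame(e1)
  ang <- (seq_len(k) - 1) * pi / k
  cos(ang) %o% fr$u + sin(ang) %o% fr$v
}

# Uniformly random rotation matrix via a normalized Gaussian quaternion.
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
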