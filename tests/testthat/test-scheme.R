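# Scheme design: subset sizes, uniformity measures, optimization, ordering
# and subsampling.

test_that("per-shell subset counts reproduce the truncation table", {
  fr <- c(0.95, 0.9, 0.8, 0.7, 0.6, 0.5)
  expect_identical(vapply(fr, function(f) subset_sizes(32, f), 0L),
                   c(30L, 29L, 26L, 22L, 19L, 16L))
  expect_identical(vapply(fr, function(f) subset_sizes(60, f), 0L),
                   c(57L, 54L, 48L, 42L, 36L, 30L))
  expect_identical(subset_sizes(32, 1), 32L)
  expect_error(subset_sizes(32, 0), "fraction")
  expect_error(subset_sizes(32, 1.2), "fraction")
  expect_error(subset_sizes(8, 0.5), "infeasible")
})

test_that("electrostatic energy matches analytic pair values", {
  expect_equal(electrostatic_energy(rbind(c(1, 0, 0), c(0, 1, 0))), sqrt(2))
  expect_equal(electrostatic_energy(diag(3)), 3 * sqrt(2))
  expect_error(electrostatic_energy(rbind(c(1, 0, 0), c(1, 0, 0))),
               "singular")
  expect_error(electrostatic_energy(rbind(c(1, 0, 0), c(-1, 0, 0))),
               "singular")
  expect_error(electrostatic_energy(matrix(c(1, 0, 0), 1)), "at least 2")
})

test_that("electrostatic energy is invariant under rotation and sign flips", {
  u <- random_unit_dirs(15, seed = 4)
  e0 <- electrostatic_energy(u)
  rot <- fiber_substrate(seed = 9)$rotation
  expect_equal(electrostatic_energy(u %*% t(rot)), e0)
  flip <- u
  flip[c(2, 5, 11), ] <- -flip[c(2, 5, 11), ]
  expect_equal(electrostatic_energy(flip), e0)
})

test_that("covering radius is the minimum pairwise line-angle in degrees", {
  expect_equal(covering_radius(diag(3)), 90)
  expect_equal(covering_radius(rbind(c(1, 0, 0),
                                     c(cos(pi / 3), sin(pi / 3), 0))), 60)
  expect_equal(covering_radius(rbind(c(1, 0, 0), c(-1, 0, 0))), 0)
  expect_error(covering_radius(matrix(c(1, 0, 0), 1)), "at least 2")
})

test_that("covering radius never increases as directions are added", {
  u <- random_unit_dirs(25, seed = 2)
  cr <- vapply(3:25, function(k) covering_radius(u[1:k, ]), 0)
  expect_true(all(diff(cr) <= 1e-12))
})

test_that("optimized shells beat seeded-random baselines", {
  sch <- ref_scheme()
  expect_equal(nrow(sch), 100L)
  expect_equal(sum(sch$shell == 0), 8L)
  expect_equal(sum(sch$shell == 1), 32L)
  expect_equal(sum(sch$shell == 2), 60L)
  # all diffusion directions unit norm, b0 rows zero
  dw <- sch$shell > 0
  expect_true(all(abs(rowSums(sch[dw, c("x", "y", "z")]^2) - 1) < 1e-9))
  expect_true(all(sch[!dw, c("x", "y", "z")] == 0))
  # optimized 60-direction shell: lower energy than the best of 100 random
  e_opt <- electrostatic_energy(scheme_directions(sch, 2))
  e_rand <- vapply(1:100, function(i)
    electrostatic_energy(random_unit_dirs(60, seed = i)), 0)
  expect_lt(e_opt, min(e_rand))
})

test_that("a 6-direction optimized shell is near-octahedral", {
  s6 <- generate_scheme(n_per_shell = 6, bvalues = 1000, n_b0 = 1,
                        seed = 3, n_restarts = 5, max_iter = 1000)
  u <- scheme_directions(s6)
  expect_gte(covering_radius(u), 60)
  e_rand <- vapply(1:100, function(i)
    electrostatic_energy(random_unit_dirs(6, seed = i + 300)), 0)
  expect_lt(electrostatic_energy(u), min(e_rand))
})

test_that("scheme generation is deterministic given the seed", {
  a <- generate_scheme(n_per_shell = 8, bvalues = 1000, n_b0 = 2,
                       seed = 5, n_restarts = 2, max_iter = 2000)
  b <- generate_scheme(n_per_shell = 8, bvalues = 1000, n_b0 = 2,
                       seed = 5, n_restarts = 2, max_iter = 2000)
  expect_identical(a, b)
})

test_that("incremental ordering keeps prefix shell proportions and volumes", {
  sch <- ref_scheme()
  raw <- generate_scheme(seed = 1, n_restarts = 4, max_iter = 1500)
  # permutation of the input volumes
  expect_equal(sort(do.call(paste, sch[, c("x", "y", "z", "bval")])),
               sort(do.call(paste, raw[, c("x", "y", "z", "bval")])))
  expect_identical(sch$order, 0:99)
  dw <- sch[sch$shell > 0, ]
  for (L in seq(5, 92, by = 1)) {
    n1 <- sum(dw$shell[1:L] == 1)
    expect_lte(abs(n1 - L * 32 / 92), 1)
  }
})

test_that("ordered prefixes have lower energy than random prefixes", {
  sch <- ref_scheme()
  dw <- sch[sch$shell > 0, ]
  u <- as.matrix(dw[, c("x", "y", "z")])
  for (k in c(23, 46, 69)) {
    e_prefix <- electrostatic_energy(u[1:k, ])
    e_rand <- vapply(1:100, function(i) {
      set.seed(1000 + i)
      electrostatic_energy(u[sample(92, k), ])
    }, 0)
    expect_lte(e_prefix, median(e_rand))
  }
})

test_that("truncation subsets are nested and keep the table counts", {
  sch <- ref_scheme()
  ch <- subsample_chain(sch, method = "eem")
  counts1 <- vapply(ch, function(s) sum(s$shell == 1), 0L)
  counts2 <- vapply(ch, function(s) sum(s$shell == 2), 0L)
  expect_identical(unname(counts1), c(30L, 29L, 26L, 22L, 19L, 16L))
  expect_identical(unname(counts2), c(57L, 54L, 48L, 42L, 36L, 30L))
  expect_true(all(vapply(ch, function(s) sum(s$shell == 0), 0L) == 8L))
  for (i in 2:length(ch))
    expect_true(all(ch[[i]]$order %in% ch[[i - 1]]$order))
})

test_that("spherical-code chain is nested with non-decreasing shell CR", {
  sch <- ref_scheme()
  ch <- subsample_chain(sch, fractions = c(0.8, 0.6, 0.5), method = "sc")
  for (i in 2:length(ch))
    expect_true(all(ch[[i]]$order %in% ch[[i - 1]]$order))
  cr_full <- covering_radius(scheme_directions(sch, 2))
  cr <- vapply(ch, function(s) covering_radius(scheme_directions(s, 2)), 0)
  expect_true(all(cr >= cr_full - 1e-12))
  expect_true(all(diff(cr) >= -1e-12))
})

test_that("greedy+exchange subset beats 1000 random subsets (8 of 16)", {
  u16 <- random_unit_dirs(16, seed = 8)
  sch16 <- gradient_scheme(u16, rep(1000, 16))
  sub <- subsample_scheme(sch16, 0.5, method = "sc")
  expect_equal(nrow(sub), 8L)
  obj <- function(idx) covering_radius(u16[idx, , drop = FALSE])
  got <- obj(match(sub$order, sch16$order))
  set.seed(99)
  rand_best <- max(replicate(1000, obj(sample(16, 8))))
  expect_gte(got, rand_best)
})

test_that("random truncation is seeded, nested and optionally balanced", {
  sch <- ref_scheme()
  a <- subsample_scheme(sch, 0.5, "random", seed = 7)
  b <- subsample_scheme(sch, 0.5, "random", seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 54L)             # 46 DW + 8 b0
  expect_equal(sum(a$shell == 0), 8L)
  # nesting across fractions under one seed
  a70 <- subsample_scheme(sch, 0.7, "random", seed = 7)
  expect_true(all(a$order %in% a70$order))
  # balanced variant reproduces the nominal per-shell counts
  bal <- subsample_scheme(sch, 0.5, "random", seed = 7, balance_shells = TRUE)
  expect_equal(sum(bal$shell == 1), 16L)
  expect_equal(sum(bal$shell == 2), 30L)
  # full-fraction subsampling returns all volumes
  expect_equal(nrow(subsample_scheme(sch, 1, "random", seed = 1)), 100L)
})

test_that("random subsets have lower angular resolution than optimized ones", {
  sch <- ref_scheme()
  sc50 <- subsample_chain(sch, method = "sc")[["0.50"]]
  cr_sc <- covering_radius(scheme_directions(sc50))
  cr_rand <- vapply(1:200, function(i) {
    s <- subsample_scheme(sch, 0.5, "random", seed = i)
    covering_radius(scheme_directions(s))
  }, 0)
  expect_lt(median(cr_rand), cr_sc)
})
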