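# Evaluation pipeline: bookkeeping, determinism, error tables, export.

small_experiment <- function() {
  .memo("small_experiment", {
    cfg <- experiment_config(methods = c("opt_eem", "random_trunc"),
                             fractions = c(1, 0.8), snr = 30,
                             n_orientations = 4, n_noise = 5, seed = 3,
                             sphere_n = 2562L,
                             scheme = ref_scheme())
    run_experiment(cfg)
  })
}

test_that("the default configuration enumerates the full-scale design", {
  cfg <- experiment_config()
  expect_equal(n_instances(cfg), 10000L)
  expect_equal(cfg$n_orientations, 100L)
  expect_equal(cfg$n_noise, 100L)
  expect_setequal(cfg$methods, c("opt_eem", "opt_sc", "random_trunc"))
  expect_equal(cfg$fractions, c(1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5))
  expect_equal(cfg$snr, c(10, 20, 30, 40, 50, 1000))
  expect_equal(cfg$fit_method, "constrained")
  # fraction 1 is forced into non-standard fraction sets
  expect_true(1 %in% experiment_config(fractions = 0.5)$fractions)
})

test_that("the experiment table has the factorial shape", {
  ex <- small_experiment()
  tab <- ex$table
  # cells: shared full + 2 methods x 1 sub-fraction; 7 params x 2 statistics
  expect_equal(nrow(tab), (1 + 2) * 7 * 2)
  expect_setequal(unique(tab$method), c("full", "opt_eem", "random_trunc"))
  expect_equal(ex$n_instances, 20L)
  expect_true(all(tab$value[tab$statistic == "iqr"] >= 0))
})

test_that("experiments are deterministic given the master seed", {
  ex1 <- small_experiment()
  cfg <- ex1$config
  ex2 <- run_experiment(cfg)
  expect_identical(ex1$table, ex2$table)
})

test_that("relative errors are zero at full fraction and correct by hand", {
  ex <- relative_error(small_experiment())
  tab <- ex$table
  rel <- tab[tab$statistic == "rel_error_pct", ]
  expect_equal(rel$value[rel$fraction == 1], rep(0, 7))
  # hand check one cell against the median rows
  med <- tab[tab$statistic == "median", ]
  pick <- function(d, m, p) d$value[d$method == m & d$parameter == p]
  hand <- 100 * abs(pick(med, "opt_eem", "MK") - pick(med, "full", "MK")) /
    pick(med, "full", "MK")
  expect_equal(pick(rel, "opt_eem", "MK"), hand)
  # synthetic case: 1.02 vs 1.00 is a 2% error
  toy <- data.frame(method = c("full", "m"), fraction = c(1, 0.5),
                    snr = 20, parameter = "MD", statistic = "median",
                    value = c(1.00, 1.02))
  out <- relative_error(toy)
  expect_equal(out$value[out$statistic == "rel_error_pct" &
                           out$method == "m"], 2)
  expect_equal(out$value[out$statistic == "rel_error_signed_pct" &
                           out$method == "m"], 2)
})

test_that("max_error_summary filters scopes correctly", {
  ex <- relative_error(small_experiment())
  tab <- ex$table
  one <- tab[tab$statistic == "rel_error_pct" & tab$method == "opt_eem" &
               tab$parameter == "FA", ]
  expect_equal(max_error_summary(ex, "FA", methods = "opt_eem",
                                 fractions = 0.8), max(one$value))
  expect_equal(max_error_summary(ex, "MD", fractions = 1), 0)
  expect_error(max_error_summary(ex, "FA", methods = "nope"), "empty scope")
})

test_that("exported CSVs are stable under re-export", {
  ex <- relative_error(small_experiment())
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_results(ex, d1)
  expect_true(all(file.exists(file.path(d1, c("medians.csv", "iqr.csv",
                                              "rel_error.csv",
                                              "manifest.txt")))))
  back <- utils::read.csv(file.path(d1, "medians.csv"))
  expect_equal(nrow(back), sum(ex$table$statistic == "median"))
  export_results(back, d2)
  expect_identical(readLines(file.path(d1, "medians.csv")),
                   readLines(file.path(d2, "medians.csv")))
  expect_error(export_results(ex$table[0, ], withr::local_tempdir()),
               "empty table")
})

test_that("configurations can be read from a key-value file", {
  skip_if_not_installed("yaml")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("methods: [opt_eem, random_trunc]",
               "fractions: [1, 0.7, 0.5]",
               "snr: [20, 30]",
               "n_orientations: 20",
               "n_noise: 10",
               "seed: 4"), f)
  cfg <- read_experiment_config(f)
  expect_s3_class(cfg, "experiment_config")
  expect_equal(cfg$methods, c("opt_eem", "random_trunc"))
  expect_equal(cfg$fractions, c(1, 0.7, 0.5))
  expect_equal(n_instances(cfg), 200L)
  writeLines("bogus_key: 1", f)
  expect_error(read_experiment_config(f), "unknown configuration keys")
})

test_that("per-instance metrics can be retained and exported", {
  cfg <- experiment_config(methods = "opt_eem", fractions = c(1, 0.5),
                           snr = 30, n_orientations = 2, n_noise = 3,
                           seed = 5, sphere_n = 2562L,
                           scheme = ref_scheme(), keep_instances = TRUE)
  ex <- run_experiment(cfg)
  expect_length(ex$instances, 2L)      # full + opt_eem 0.5
  f <- withr::local_tempfile(fileext = ".csv")
  export_instances(ex, f)
  d <- utils::read.csv(f)
  expect_equal(nrow(d), 2L * 6L * 7L)  # cells x instances x parameters
  expect_setequal(unique(d$parameter),
                  c("FA", "MD", "AD", "RD", "MK", "AK", "RK"))
  # per-instance medians reproduce the table medians
  md <- d$value[d$parameter == "MD" & d$fraction == 1]
  tab_md <- ex$table$value[ex$table$statistic == "median" &
                             ex$table$parameter == "MD" &
                             ex$table$method == "full"]
  expect_equal(median(md), tab_md)
  # without retention the export errors
  ex2 <- small_experiment()
  expect_error(export_instances(ex2, f), "keep_instances")
})

test_that("experiment plots render without error", {
  ex <- small_experiment()
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(ex, parameter = "MK", snr = 30))
  grDevices::dev.off()
  expect_true(file.size(f) > 0)
})
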