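# Factorial simulation pipeline: method x subset x SNR x orientation x noise.

#' Configuration of a subsampling simulation experiment
#'
#' Defines the full factorial design: subsampling methods, retained
#' fractions, SNR levels, number of substrate orientations and noise
#' instances per orientation, seeding and fitting options. The full
#' (fraction 1) dataset is always included as the paired reference.
#'
#' @param methods subsampling strategies, subset of
#'   `c("opt_eem", "opt_sc", "random_trunc")`.
#' @param fractions retained fractions per shell; 1.0 is added if missing.
#' @param snr SNR levels of the b = 0 volumes.
#' @param n_orientations number of random substrate orientations.
#' @param n_noise number of Rician noise instances per orientation.
#' @param seed master seed; the experiment's random elements
#'   (orientations, noise draws, random truncation) derive their own seeds
#'   from it, so results are reproducible and independent of execution
#'   order.
#' @param fit_method `"constrained"` (default, as appropriate for low-SNR
#'   simulation) or `"wls"`.
#' @param signal_model `"dki"` (signals from the ground-truth diffusion and
#'   kurtosis tensors; fits are unbiased in the noiseless limit) or
#'   `"mixture"` (raw multi-Gaussian signals; see [simulate_signal()]).
#' @param sphere_n sphere resolution for the MK average.
#' @param s0 baseline amplitude.
#' @param scheme optional pre-built full [gradient_scheme()] (ordered); by
#'   default an optimized 32 + 60 direction, 8 b = 0 scheme is generated
#'   from `scheme_seed`.
#' @param scheme_seed seed of the generated acquisition scheme. The scheme
#'   is the fixed protocol under study, so it is deliberately decoupled
#'   from `seed`: varying the master seed re-randomizes orientations,
#'   noise and the random-truncation draw while keeping the protocol
#'   fixed.
#' @param keep_instances retain the per-instance scalar metrics in the
#'   result (see [export_instances()]); intended for reduced designs, as
#'   the full design holds 10,000 instances per cell and SNR.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(methods = c("opt_eem", "opt_sc", "random_trunc"),
                              fractions = c(1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.5),
                              snr = c(10, 20, 30, 40, 50, 1000),
                              n_orientations = 100L, n_noise = 100L,
                              seed = 1L,
                              fit_method = c("constrained", "wls"),
                              signal_model = c("dki", "mixture"),
                              sphere_n = 10242L, s0 = 1, scheme = NULL,
                              scheme_seed = 1L, keep_instances = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  fit_method <- match.arg(fit_method)
  signal_model <- match.arg(signal_model)
  fractions <- sort(unique(c(1, fractions)), decreasing = TRUE)
  if (any(fractions <= 0 | fractions > 1)) stop("fractions must be in (0, 1]")
  if (any(snr <= 0)) stop("SNR levels must be positive")
  structure(list(methods = methods, fractions = fractions, snr = snr,
                 n_orientations = as.integer(n_orientations),
                 n_noise = as.integer(n_noise), seed = as.integer(seed),
                 fit_method = fit_method, signal_model = signal_model,
                 sphere_n = as.integer(sphere_n), s0 = s0, scheme = scheme,
                 scheme_seed = as.integer(scheme_seed),
                 keep_instances = isTRUE(keep_instances)),
            class = "experiment_config")
}

#' Read an experiment configuration from a key-value (YAML) file
#'
#' The file mirrors [experiment_config()]'s arguments, e.g.
#' \preformatted{
#' methods: [opt_eem, random_trunc]
#' fractions: [1, 0.7, 0.5]
#' snr: [20, 30]
#' n_orientations: 20
#' n_noise: 20
#' seed: 1
#' }
#' Unknown keys are an error. Requires the yaml package.
#'
#' @param path path to the configuration file.
#' @return An `experiment_config` object.
#' @export
read_experiment_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("read_experiment_config() requires the yaml package")
  vals <- yaml::read_yaml(path)
  # sequences of mixed integer/real entries parse as lists; flatten them
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, vals)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Subsampling experiment configuration\n")
  cat("  methods:   ", paste(x$methods, collapse = ", "), "\n")
  cat("  fractions: ", paste(x$fractions, collapse = ", "), "\n")
  cat("  SNR:       ", paste(x$snr, collapse = ", "), "\n")
  cat(sprintf("  instances:  %d orientations x %d noise = %d per SNR\n",
              x$n_orientations, x$n_noise, n_instances(x)))
  cat("  fit:", x$fit_method, "| signal model:", x$signal_model,
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Number of simulation instances enumerated per SNR level
#'
#' @param config an [experiment_config()].
#' @return `n_orientations * n_noise`.
#' @export
n_instances <- function(config) {
  config$n_orientations * config$n_noise
}

# map public method labels to subsample_scheme() methods
.method_key <- c(opt_eem = "eem", opt_sc = "sc", random_trunc = "random")

# Build the evaluation cells: the shared full-data reference plus one cell
# per method x fraction(<1). Each cell carries the row indices of its
# volumes in the full scheme.
.experiment_cells <- function(scheme, config) {
  cells <- list(list(method = "full", fraction = 1,
                     rows = seq_len(nrow(scheme))))
  sub_fracs <- config$fractions[config$fractions < 1]
  for (m in config$methods) {
    key <- .method_key[[m]]
    chain <- subsample_chain(scheme, sub_fracs, method = key,
                             seed = .derive_seed(config$seed, 5001L, 1L))
    for (i in seq_along(sub_fracs)) {
      sub <- chain[[i]]
      cells[[length(cells) + 1L]] <-
        list(method = m, fraction = sub_fracs[i],
             rows = match(sub$order, scheme$order))
    }
  }
  cells
}

#' Run the subsampling simulation experiment
#'
#' For every substrate orientation (seeded random rotation of the
#' crossing-fiber substrate) the noiseless 100-volume signal is generated
#' once; for every noise instance and SNR level one Rician realization of
#' the full dataset is drawn; every method x fraction cell then extracts
#' its volumes from that same realization (mirroring the truncation of a
#' real acquisition, so subset-versus-full comparisons are paired), fits
#' the DKI model and derives the seven scalar parameters. Cell summaries
#' are the median and interquartile range over all instances.
#'
#' @param config an [experiment_config()].
#' @param verbose print progress messages.
#' @return A `dki_experiment` object: list with `table` (tidy records:
#'   method, fraction, snr, parameter, statistic in `{median, iqr}`,
#'   value), `config`, `scheme`, `ground_truth`, `n_failed` (failed fits
#'   per cell), `n_instances`. Use [relative_error()] to add the paired
#'   subset-versus-full error rows.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  scheme <- config$scheme
  if (is.null(scheme)) {
    if (verbose) message("generating optimized full scheme ...")
    scheme <- order_scheme_eem(generate_scheme(seed = config$scheme_seed))
  }
  cells <- .experiment_cells(scheme, config)
  n_o <- config$n_orientations; n_n <- config$n_noise
  m_inst <- n_o * n_n
  n_vol <- nrow(scheme)
  params <- c("FA", "MD", "AD", "RD", "MK", "AK", "RK")

  # noiseless signals per orientation
  S0 <- matrix(NA_real_, n_vol, n_o)
  subs <- vector("list", n_o)
  for (o in seq_len(n_o)) {
    subs[[o]] <- fiber_substrate(seed = .derive_seed(config$seed, 4001L, o))
    S0[, o] <- simulate_signal(subs[[o]], scheme, s0 = config$s0,
                               model = config$signal_model)$signals
  }
  gt <- ground_truth_metrics(fiber_substrate(), sphere_n = config$sphere_n)

  # per-cell design matrices and constraint rows (shared across SNRs)
  designs <- lapply(cells, function(cl) {
    sub <- scheme[cl$rows, ]
    class(sub) <- c("gradient_scheme", "data.frame")
    list(X = dki_design_matrix(sub),
         A = if (config$fit_method == "constrained") .constraint_rows(sub))
  })

  rows <- list()
  instances <- if (config$keep_instances) list()
  n_failed <- matrix(0L, length(cells), length(config$snr))
  for (si in seq_along(config$snr)) {
    snr <- config$snr[si]
    sigma <- config$s0 / snr
    if (verbose) message("SNR ", snr, ": simulating ", m_inst, " instances ...")
    S <- matrix(NA_real_, n_vol, m_inst)
    for (o in seq_len(n_o)) for (ni in seq_len(n_n)) {
      sd <- .derive_seed(config$seed, o, (ni - 1L) * length(config$snr) + si)
      S[, (o - 1L) * n_n + ni] <- .with_seed(sd, .rician(S0[, o], sigma))
    }
    for (ci in seq_along(cells)) {
      cl <- cells[[ci]]
      fit <- .fit_batch(designs[[ci]]$X, S[cl$rows, , drop = FALSE],
                        designs[[ci]]$A, s0 = config$s0)
      ok <- fit$flag != 2L
      n_failed[ci, si] <- sum(!ok)
      met <- .metrics_batch(fit$coef[, ok, drop = FALSE], config$sphere_n)
      med <- apply(met, 1, stats::median)
      iqr <- apply(met, 1, stats::IQR)
      if (config$keep_instances) {
        m_all <- matrix(NA_real_, 7L, m_inst,
                        dimnames = list(rownames(met), NULL))
        m_all[, ok] <- met
        instances[[paste(cl$method, cl$fraction, snr, sep = "|")]] <- m_all
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = cl$method, fraction = cl$fraction, snr = snr,
        parameter = params,
        statistic = rep(c("median", "iqr"), each = 7L),
        value = c(med, iqr))
      if (verbose)
        message(sprintf("  %-12s fraction %.2f done (%d constrained, %d failed)",
                        cl$method, cl$fraction, sum(fit$flag == 1L),
                        sum(!ok)))
    }
  }
  if (any(n_failed > 0.01 * m_inst))
    warning("some cells had more than 1% failed fits; they are flagged in `n_failed`")
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, config = config, scheme = scheme,
                 ground_truth = gt, n_failed = n_failed,
                 n_instances = m_inst, cells = cells,
                 instances = instances),
            class = "dki_experiment")
}

#' @export
print.dki_experiment <- function(x, ...) {
  cat("DKI subsampling experiment:", length(x$cells), "cells x",
      length(x$config$snr), "SNR levels,", x$n_instances,
      "instances per SNR\n")
  cat("  statistics in $table:", paste(unique(x$table$statistic),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Paired subset-versus-full relative errors
#'
#' Adds, for every (method, fraction, snr, parameter), the relative
#' difference between the subset's median and the full dataset's median
#' over the same paired noise realizations:
#' `100 * |median_subset - median_full| / median_full`
#' (statistic `"rel_error_pct"`); the signed version is kept under
#' `"rel_error_signed_pct"`. Rows at fraction 1 are exactly 0.
#'
#' @param x a `dki_experiment` or its tidy `table` (which must contain the
#'   `method == "full"` median rows).
#' @return Object of the same type with the error rows appended.
#' @export
relative_error <- function(x) {
  tab <- if (inherits(x, "dki_experiment")) x$table else x
  med <- tab[tab$statistic == "median", ]
  ref <- med[med$method == "full", ]
  key <- function(d) paste(d$snr, d$parameter)
  full_med <- setNames(ref$value, key(ref))
  if (anyNA(full_med) || any(full_med == 0))
    warning("undefined relative error: full-data median is zero or NA")
  rel <- med
  denom <- full_med[key(med)]
  rel$value <- 100 * (med$value - denom) / denom
  signed <- rel
  signed$statistic <- "rel_error_signed_pct"
  rel$statistic <- "rel_error_pct"
  rel$value <- abs(rel$value)
  out <- rbind(tab[tab$statistic != "rel_error_pct" &
                     tab$statistic != "rel_error_signed_pct", ],
               rel, signed)
  rownames(out) <- NULL
  if (inherits(x, "dki_experiment")) { x$table <- out; x } else out
}

#' Maximum relative error over a scope of the experiment
#'
#' @param x a `dki_experiment` or tidy table (relative errors are computed
#'   on the fly if absent).
#' @param parameter scalar parameter name (`"FA"`, ..., `"RK"`).
#' @param methods,fractions,snr optional filters; `NULL` keeps all. The
#'   shared full-data reference rows (method `"full"`) are kept only when
#'   `fractions` includes 1.
#' @return Maximum `rel_error_pct` over the filtered cells (a scalar, %).
#' @export
max_error_summary <- function(x, parameter, methods = NULL, fractions = NULL,
                              snr = NULL) {
  tab <- if (inherits(x, "dki_experiment")) x$table else x
  if (!any(tab$statistic == "rel_error_pct"))
    tab <- relative_error(tab)
  sel <- tab$statistic == "rel_error_pct" & tab$parameter %in% parameter
  if (!is.null(methods)) sel <- sel & tab$method %in% methods
  if (!is.null(fractions)) sel <- sel & tab$fraction %in% fractions else
    sel <- sel & tab$fraction < 1
  if (!is.null(snr)) sel <- sel & tab$snr %in% snr
  if (!any(sel)) stop("empty scope: no matching cells")
  max(tab$value[sel])
}

#' Export experiment tables as tidy CSV files
#'
#' Writes one CSV per statistic (`medians.csv`, `iqr.csv`, `rel_error.csv`
#' when present) with values rounded to 6 significant digits for stable
#' diffs, plus a `manifest.txt` recording the configuration and seed.
#'
#' @param x a `dki_experiment` (or tidy table).
#' @param path output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(x, path) {
  tab <- if (inherits(x, "dki_experiment")) x$table else x
  if (nrow(tab) == 0L) stop("empty table: nothing to export")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) { d$value <- signif(d$value, 6); d }
  files <- c()
  groups <- list(medians = "median", iqr = "iqr",
                 rel_error = c("rel_error_pct", "rel_error_signed_pct"))
  for (nm in names(groups)) {
    d <- tab[tab$statistic %in% groups[[nm]], ]
    if (nrow(d) == 0L) next
    f <- file.path(path, paste0(nm, ".csv"))
    utils::write.csv(fmt(d), f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (inherits(x, "dki_experiment")) {
    f <- file.path(path, "manifest.txt")
    cfg <- x$config
    writeLines(c(
      paste0("dkisubsample version: ",
             as.character(utils::packageVersion("dkisubsample"))),
      paste0("seed: ", cfg$seed),
      paste0("methods: ", paste(cfg$methods, collapse = ",")),
      paste0("fractions: ", paste(cfg$fractions, collapse = ",")),
      paste0("snr: ", paste(cfg$snr, collapse = ",")),
      paste0("n_orientations: ", cfg$n_orientations),
      paste0("n_noise: ", cfg$n_noise),
      paste0("fit_method: ", cfg$fit_method),
      paste0("signal_model: ", cfg$signal_model)), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Export per-instance scalar metrics as a tidy CSV
#'
#' Writes one row per (orientation, noise instance, method, fraction, snr,
#' parameter) — the hand-off table for external statistical analysis
#' (e.g. repeated-measures ANOVA). Requires an experiment run with
#' `keep_instances = TRUE` in [experiment_config()].
#'
#' @param x a `dki_experiment` with retained instances.
#' @param file output CSV path.
#' @return Invisibly, the path written.
#' @export
export_instances <- function(x, file) {
  stopifnot(inherits(x, "dki_experiment"))
  if (is.null(x$instances) || !length(x$instances))
    stop("experiment was run without `keep_instances = TRUE`")
  n_n <- x$config$n_noise
  out <- do.call(rbind, lapply(names(x$instances), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- x$instances[[key]]
    idx <- seq_len(ncol(m))
    data.frame(orientation_id = rep((idx - 1L) %/% n_n + 1L, each = 7L),
               noise_id = rep((idx - 1L) %% n_n + 1L, each = 7L),
               method = parts[1], fraction = as.numeric(parts[2]),
               snr = as.numeric(parts[3]),
               parameter = rep(rownames(m), ncol(m)),
               value = as.vector(m))
  }))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Plot parameter medians or relative errors across subsampling levels
#'
#' @param x a `dki_experiment`.
#' @param parameter scalar parameter to plot.
#' @param snr single SNR level (defaults to the first configured).
#' @param statistic `"median"` (with the ground-truth value as a dashed
#'   reference line) or `"rel_error_pct"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dki_experiment <- function(x, parameter = "MK", snr = NULL,
                                statistic = c("median", "rel_error_pct"),
                                ...) {
  statistic <- match.arg(statistic)
  tab <- x$table
  if (statistic == "rel_error_pct" && !any(tab$statistic == "rel_error_pct"))
    tab <- relative_error(tab)
  if (is.null(snr)) snr <- x$config$snr[1]
  d <- tab[tab$parameter == parameter & tab$snr == snr &
             tab$statistic == statistic, ]
  if (nrow(d) == 0L) stop("no rows for requested parameter/snr")
  fr <- sort(unique(d$fraction))
  methods <- setdiff(unique(d$method), "full")
  ymat <- sapply(methods, function(m) {
    v <- rep(NA_real_, length(fr))
    for (i in seq_along(fr)) {
      row <- d[(d$method == m | d$fraction == 1) & d$fraction == fr[i], ]
      if (nrow(row)) v[i] <- row$value[1]
    }
    v
  })
  graphics::matplot(fr, ymat, type = "b", pch = 19, lty = 1,
                    xlab = "fraction of volumes retained",
                    ylab = paste(parameter, statistic),
                    main = sprintf("%s at SNR %g", parameter, snr), ...)
  if (statistic == "median" && parameter %in% names(x$ground_truth))
    graphics::abline(h = x$ground_truth[[parameter]], lty = 2, col = "blue")
  graphics::legend("topleft", legend = methods, col = seq_along(methods),
                   pch = 19, bty = "n")
  invisible(x)
}

#' @export
summary.dki_experiment <- function(object, snr = NULL, ...) {
  tab <- relative_error(object)$table
  if (is.null(snr)) snr <- object$config$snr[1]
  d <- tab[tab$statistic == "rel_error_pct" & tab$snr == snr &
             tab$method != "full", ]
  wide <- stats::reshape(
    d[, c("method", "fraction", "parameter", "value")],
    idvar = c("method", "fraction"), timevar = "parameter",
    direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[order(wide$method, -wide$fraction), ]
  rownames(wide) <- NULL
  structure(list(snr = snr, errors = wide), class = "summary.dki_experiment")
}

#' @export
print.summary.dki_experiment <- function(x, digits = 3, ...) {
  cat("Relative errors of parameter medians vs the full dataset (%), SNR",
      x$snr, "\n")
  d <- x$errors
  d[, -(1:2)] <- signif(d[, -(1:2)], digits)
  print(d, row.names = FALSE)
  invisible(x)
}
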