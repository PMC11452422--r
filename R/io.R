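# Readers/writers for the two standard gradient-table formats.

#' Read a gradient scheme from FSL bvals/bvecs files
#'
#' bvals: one row of N whitespace-separated b-values; bvecs: 3 rows of N
#' columns. Non-unit vectors are renormalized; volumes with b below
#' `b0_threshold` (default 50 s/mm^2) are treated as b = 0.
#'
#' @param bvals,bvecs file paths.
#' @param b0_threshold see [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_scheme_fsl <- function(bvals, bvecs, b0_threshold = 50) {
  bv <- scan(bvals, quiet = TRUE)
  vec <- matrix(scan(bvecs, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(vec) != length(bv))
    stop("bvals and bvecs disagree on the number of volumes")
  gradient_scheme(t(vec), bv, b0_threshold = b0_threshold)
}

#' Write a gradient scheme as FSL bvals/bvecs files
#'
#' @param scheme a [gradient_scheme()].
#' @param bvals,bvecs output file paths.
#' @return Invisibly, the paths written.
#' @export
write_scheme_fsl <- function(scheme, bvals, bvecs) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(sprintf("%.6f", scheme$bval), collapse = " "), bvals)
  writeLines(c(paste(sprintf("%.6f", scheme$x), collapse = " "),
               paste(sprintf("%.6f", scheme$y), collapse = " "),
               paste(sprintf("%.6f", scheme$z), collapse = " ")), bvecs)
  invisible(c(bvals, bvecs))
}

#' Read a gradient scheme from an MRtrix gradient table
#'
#' N rows of "x y z b".
#'
#' @param file path to the `.b` file.
#' @param b0_threshold see [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_scheme_mrtrix <- function(file, b0_threshold = 50) {
  m <- as.matrix(utils::read.table(file, col.names = c("x", "y", "z", "b")))
  gradient_scheme(m[, 1:3], m[, 4], b0_threshold = b0_threshold)
}

#' Write a gradient scheme as an MRtrix gradient table
#'
#' Fixed-point 6-decimal output, so write/read/write round-trips are
#' bit-identical.
#'
#' @param scheme a [gradient_scheme()].
#' @param file output path.
#' @return Invisibly, the path written.
#' @export
write_scheme_mrtrix <- function(scheme, file) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(sprintf("%.6f %.6f %.6f %.6f",
                     scheme$x, scheme$y, scheme$z, scheme$bval), file)
  invisible(file)
}
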