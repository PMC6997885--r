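# Natural-abundance correction of 13C mass-isotopomer distributions (MIDs)
# and labeled-fraction reporting.

#' Isotope correction configuration
#'
#' @param p_natural natural 13C abundance (fraction; default 0.0107).
#' @param derivatization_carbons carbons added by derivatization (e.g. the
#'   methyl of a FAME).  They contribute natural 13C but never tracer label.
#' @return a list of class `isotope_config`.
#' @export
isotope_config <- function(p_natural = 0.0107, derivatization_carbons = 0L) {
  stopifnot(p_natural > 0, p_natural < 1, derivatization_carbons >= 0)
  structure(list(p_natural = p_natural,
                 derivatization_carbons = as.integer(derivatization_carbons)),
            class = "isotope_config")
}

#' Natural-abundance correction matrix
#'
#' Entry `[i, j]` (0-based shifts) is the probability of observing mass shift
#' i given j tracer-labeled skeleton carbons: the remaining
#' `n_total - j` carbons (skeleton plus derivatization carbons) each carry a
#' natural 13C with probability `p_natural`, so the entry is
#' `dbinom(i - j, n_total - j, p_natural)` for `i >= j`, else 0.  The matrix
#' is truncated at shift `n_carbons`, so columns sum to at most 1.
#'
#' @param n_carbons skeleton carbons of the metabolite (tracer-labelable).
#' @param config an [isotope_config()].
#' @return an `(n_carbons + 1) x (n_carbons + 1)` matrix.
#' @examples
#' correction_matrix(1, isotope_config(0.0107))
#' @export
correction_matrix <- function(n_carbons, config = isotope_config()) {
  stopifnot(inherits(config, "isotope_config"), n_carbons >= 1)
  n <- as.integer(n_carbons)
  n_total <- n + config$derivatization_carbons
  M <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    i <- j:n
    M[i + 1L, j + 1L] <- stats::dbinom(i - j, n_total - j, config$p_natural)
  }
  dimnames(M) <- list(paste0("M+", 0:n), paste0("M+", 0:n))
  M
}

#' Correct a measured MID for natural abundance
#'
#' Solves `measured ~ matrix %*% corrected` by non-negative least squares and
#' renormalizes the corrected distribution to sum 1.
#'
#' @param measured numeric vector of M+0 ... M+n intensities (any scale).
#' @param matrix a [correction_matrix()].
#' @return corrected fractional MID (sums to 1).
#' @export
correct_mid <- function(measured, matrix) {
  stopifnot(length(measured) == nrow(matrix), all(measured >= 0))
  if (sum(measured) <= 0) stop("measured MID is all zero")
  if (rcond(matrix) < 1e-12) stop("correction matrix is ill-conditioned")
  m <- measured / sum(measured)
  fit <- pracma::lsqnonneg(matrix, m)
  x <- fit$x
  if (sum(x) <= 0) stop("non-negative least squares returned a zero solution")
  x / sum(x)
}

#' Percentage of a metabolite pool carrying one or more 13C atoms
#'
#' @param corrected corrected fractional MID (see [correct_mid()]).
#' @return percent labeled, `100 * (1 - corrected[M+0])`.
#' @examples
#' fraction_labeled(c(0.25, 0.25, 0.5))  # 75
#' @export
fraction_labeled <- function(corrected) {
  stopifnot(length(corrected) >= 1, all(corrected >= -1e-12))
  100 * (1 - corrected[1L] / sum(corrected))
}

#' Read / write isotopologue tables
#'
#' TSV with columns `metabolite`, `n_carbons`, then `M0 ... Mn` intensity
#' columns (ragged tails NA-padded).
#'
#' @param path file path.
#' @return a data frame.
#' @export
read_mid_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_mid_table
#' @param x data frame to write.
#' @export
write_mid_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
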