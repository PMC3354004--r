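#' Hartigan dip statistic of unimodality
#'
#' The dip is the smallest sup-norm distance between the empirical CDF of the
#' sample and the class of unimodal CDFs (convex below the mode, concave
#' above it, with at most one atom, at the mode).  Large values indicate
#' departure from unimodality.  The statistic is computed exactly on the
#' sorted sample by a convex-minorant / concave-majorant analysis of every
#' candidate mode placement (implemented in C); it is invariant under
#' strictly increasing affine transformations of the data and, for samples of
#' n distinct values, lies in [1/(2n), 1/4].
#'
#' @param x Numeric vector, at least 4 finite values. Ties are allowed.
#' @return The dip statistic (a single number).
#' @references Hartigan, J. A. and Hartigan, P. M. (1985) The dip test of
#'   unimodality. Annals of Statistics 13, 70-84.
#' @seealso [dip_test()]
#' @examples
#' dip_statistic(c(rnorm(50), rnorm(50, 8)))  # clearly bimodal: large dip
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("'x' must contain only finite values")
  if (length(x) < 4) stop("dip statistic needs at least 4 observations")
  dip_stat_cpp(x)
}

#' Dip test of unimodality with bootstrap calibration
#'
#' Computes the dip statistic and calibrates it against samples of the same
#' size drawn from the Uniform(0,1) distribution, the least favourable
#' unimodal null of Hartigan and Hartigan's test.  The p-value uses the
#' add-one convention p = (1 + #\{bootstrap dips >= observed\}) / (n_boot + 1).
#' For lighter-tailed unimodal data (e.g. Gaussian) the test is conservative.
#'
#' @param x Numeric vector, at least 4 finite values.
#' @param n_boot Number of bootstrap null samples (>= 100; default 2000).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return An object of class `"htest"` with the dip statistic and p-value.
#' @examples
#' dip_test(runif(200), n_boot = 500, seed = 1)
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL) {
  dn <- deparse(substitute(x))
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("'x' must contain only finite values")
  if (length(x) < 4) stop("dip test needs at least 4 observations")
  if (n_boot < 100) stop("'n_boot' must be at least 100")
  n <- length(x)
  dip <- dip_stat_cpp(x)
  count <- with_seed(seed, dip_boot_count_cpp(dip, n, as.integer(n_boot)))
  p <- (1 + count) / (n_boot + 1)
  structure(list(
    statistic = c(D = dip),
    p.value = p,
    parameter = c(n = n, n_boot = n_boot),
    alternative = "non-unimodal",
    method = "Hartigan dip test of unimodality (uniform bootstrap calibration)",
    data.name = dn
  ), class = "htest")
}
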