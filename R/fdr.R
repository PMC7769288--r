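#' Estimate the proportion of true nulls (pi0)
#'
#' Storey-Tibshirani estimator: for each lambda in the grid,
#' `pi0_hat(lambda) = #\{p_i > lambda\} / (m * (1 - lambda))`; a cubic
#' smoothing spline with 3 effective degrees of freedom is fitted to
#' `pi0_hat(lambda)` versus lambda and evaluated at the largest lambda; the
#' result is clamped into (0, 1].
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param lambda_grid Tuning grid (default `seq(0, 0.90, by = 0.05)`).
#' @return pi0 estimate, with attribute `flag` when a degenerate input forced
#'   a fallback.
#' @export
estimate_pi0 <- function(pvals, lambda_grid = seq(0, 0.90, by = 0.05)) {
  .check_pvals(pvals)
  m <- length(pvals)
  if (m < 2L || stats::sd(pvals) == 0) {
    return(structure(1, flag = "degenerate-pvalues"))
  }
  pi0_hat <- vapply(lambda_grid,
                    function(l) mean(pvals > l) / (1 - l), numeric(1))
  sp <- stats::smooth.spline(lambda_grid, pi0_hat, df = 3)
  pi0 <- stats::predict(sp, x = max(lambda_grid))$y
  flag <- NULL
  if (pi0 <= 0) {
    pi0 <- 1 / m   # keep pi0 strictly positive for degenerate, all-small p
    flag <- "pi0-clamped-low"
  }
  pi0 <- min(pi0, 1)
  structure(pi0, flag = flag)
}

#' Q-values from p-values at a given pi0
#'
#' Step-down construction over the order statistics: with p(1) <= ... <= p(m),
#' `q(p(m)) = min(1, pi0 * p(m))` and, for i = m-1, ..., 1,
#' `q(p(i)) = min(pi0 * m * p(i) / i, q(p(i+1)))`. Ties automatically share
#' the q of their rank block; results come back in input order. With
#' `pi0 = 1` this is exactly the Benjamini-Hochberg step-up adjustment.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param pi0 Proportion of true nulls, in (0, 1\].
#' @return Numeric vector of q-values, input order.
#' @export
qvalues <- function(pvals, pi0 = 1) {
  .check_pvals(pvals)
  if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
    stop("`pi0` must be a single value in (0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  ps <- pvals[o]
  # operation order (m/i) * p keeps the pi0 = 1 case bit-identical to the
  # Benjamini-Hochberg step-up adjustment
  qs <- pi0 * (m / seq_len(m)) * ps
  qs[m] <- min(qs[m], 1)
  if (m > 1L) for (i in (m - 1L):1L) qs[i] <- min(qs[i], qs[i + 1L])
  out <- numeric(m)
  out[o] <- qs
  out
}

.check_pvals <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric")
  if (length(pvals) && (anyNA(pvals) || any(pvals < 0 | pvals > 1)))
    stop("p-values must lie in [0, 1] with no missing values")
}

#' Q-values for one family of tests
#'
#' Dispatch layer used by the pipeline: for families of at least
#' `min_m_spline` tests, pi0 is estimated by the smoothing-spline method;
#' smaller families fall back to `pi0 = 1` (where q-values coincide with
#' Benjamini-Hochberg adjusted p-values) because the spline estimate is
#' unstable at small m.
#'
#' @param pvals Numeric vector of p-values.
#' @param lambda_grid Grid for [estimate_pi0()].
#' @param min_m_spline Smallest family size for which the spline estimator is
#'   used (default 20).
#' @param pi0 Optional fixed pi0 overriding estimation.
#' @return An object of class `qvalue_result` with fields `pvals`, `pi0`,
#'   `qvals`, `lambda_grid` and `method_note` (`"spline"` or
#'   `"fixed-pi0-1"` / `"fixed-pi0"`).
#' @export
qvalue_family <- function(pvals, lambda_grid = seq(0, 0.90, by = 0.05),
                          min_m_spline = 20L, pi0 = NULL) {
  .check_pvals(pvals)
  m <- length(pvals)
  if (m == 0L) {
    return(structure(list(pvals = numeric(0), pi0 = 1, qvals = numeric(0),
                          lambda_grid = lambda_grid,
                          method_note = "empty"),
                     class = "qvalue_result"))
  }
  if (!is.null(pi0)) {
    note <- if (pi0 == 1) "fixed-pi0-1" else "fixed-pi0"
  } else if (m < min_m_spline) {
    pi0 <- 1
    note <- "fixed-pi0-1"
  } else {
    pi0 <- as.numeric(estimate_pi0(pvals, lambda_grid))
    note <- "spline"
  }
  structure(list(pvals = pvals, pi0 = pi0,
                 qvals = qvalues(pvals, pi0),
                 lambda_grid = lambda_grid, method_note = note),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("<qvalue_result> m = %d, pi0 = %.3f (%s), %d q < 0.05\n",
              length(x$pvals), x$pi0, x$method_note, sum(x$qvals < 0.05)))
  invisible(x)
}
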