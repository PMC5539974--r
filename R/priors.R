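#' Gaussian prior for a regression coefficient
#'
#' @param mean Prior mean.
#' @param sd Prior standard deviation; floored at 0.01 so a degenerate
#'   posterior can never pin a downstream coefficient exactly.
#' @return An object of class `"gaussian_prior"`.
#' @export
gaussian_prior <- function(mean = 0, sd = sqrt(1000)) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0)
  structure(list(mean = mean, sd = max(sd, 0.01)), class = "gaussian_prior")
}

#' @export
print.gaussian_prior <- function(x, ...) {
  cat(sprintf("Gaussian prior: mean %.4g, sd %.4g\n", x$mean, x$sd))
  invisible(x)
}

#' Build an informed prior from posterior draws
#'
#' Moment-matches a Gaussian to the posterior marginal of a coefficient
#' from an upstream fit (here: the life-stage meta-analysis), so that a
#' downstream common-garden model starts from what the literature already
#' established.  The prior sd can be inflated to discount the upstream
#' evidence.
#'
#' @param coef_draws Numeric vector of at least two finite posterior draws.
#' @param inflation Multiplier (> 0) applied to the sample sd; default 1.
#' @return A [gaussian_prior()] with `mean = mean(coef_draws)` and
#'   `sd = inflation * sd(coef_draws)` (floored at 0.01).
#' @export
build_informed_prior <- function(coef_draws, inflation = 1) {
  coef_draws <- coef_draws[is.finite(coef_draws)]
  if (length(coef_draws) < 2) {
    stop("need at least 2 finite draws to build an informed prior",
         call. = FALSE)
  }
  stopifnot(inflation > 0)
  gaussian_prior(mean(coef_draws), inflation * stats::sd(coef_draws))
}

# Default diffuse prior: mean 0, precision 0.001 (variance 1000), the
# conventional flat Gaussian of BUGS-family samplers.
flat_prior <- function() gaussian_prior(0, sqrt(1000))

prior_precision <- function(p) 1 / p$sd^2
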