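#' Compress boundary proportions into the open unit interval
#'
#' The beta likelihood has support on (0, 1), but extracted survivorship
#' data contain exact 0s and 1s.  Applies the standard boundary compression
#' `(y * (n - 1) + 0.5) / n`, which is order-preserving, leaves 0.5 fixed,
#' and shrinks toward the midpoint by half an observation.
#'
#' @param y Proportions in [0, 1].
#' @param n Positive sample size(s) (recycled).
#' @return Proportions strictly inside (0, 1).
#' @export
compress_proportions <- function(y, n) {
  stopifnot(all(is.finite(y)), all(y >= 0), all(y <= 1))
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("sample size n must be >= 1", call. = FALSE)
  }
  (y * (n - 1) + 0.5) / n
}

#' Beta log-density in the mean-precision parameterization
#'
#' Log density of `Beta(mu * phi, (1 - mu) * phi)` at `y`: the natural
#' parameterization for regression on proportions, where `mu` is the mean
#' (linked to covariates via logit) and `phi` the precision.
#'
#' @param y Observation in the open interval (0, 1).
#' @param mu Mean in (0, 1).
#' @param phi Precision, > 0.
#' @return Log density (vectorized over arguments).
#' @export
beta_loglik <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) {
    stop("y must lie strictly inside (0, 1); compress boundary values first",
         call. = FALSE)
  }
  stopifnot(all(mu > 0 & mu < 1), all(phi > 0))
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Fit the Bayesian beta-regression meta-analysis for one life stage
#'
#' Models per-study survivorship proportions as
#' `y_ij ~ Beta(mu_ij * phi, (1 - mu_ij) * phi)` with
#' `logit(mu_ij) = beta0 + beta1 * salinity_ij + u_j`, where `u_j` is a
#' per-study random intercept, `u_j ~ Normal(0, sigma_u^2)`.  Survivorship
#' and salinity are fixed effects; studies are random effects.  Fixed
#' effects get diffuse Gaussian priors (mean 0, precision 0.001);
#' `sigma_u ~ Uniform(0, 10)` and `phi ~ Gamma(0.01, 0.01)`.  Proportions
#' of exactly 0 or 1 lie outside the beta support and are compressed via
#' [compress_proportions()] using the recorded sample size (imputed as 10
#' when missing, with a message); interior proportions are left untouched
#' so the likelihood is not attenuated.
#' Convergence is assessed with [gelman_rubin()]; the fit is flagged (with
#' a warning) if any parameter has R-hat >= 1.1.
#'
#' @param records Data frame of survivorship records as returned by
#'   [read_survival_csv()] or [simulate_meta_dataset()].
#' @param stage Life stage to fit: `"egg"`, `"tadpole"`, or `"adult"`.
#' @param config An [mcmc_config()].
#' @param prior_intercept,prior_slope Optional [gaussian_prior()]s
#'   replacing the diffuse defaults.
#' @param random_effects If `FALSE`, drop the study random intercepts —
#'   only sensible for degenerate designs (e.g. a single study, where `u`
#'   is confounded with the intercept) or for checking the fixed-effect
#'   kernel against a brute-force oracle.
#' @param fix_phi Optional positive value at which to pin the precision
#'   instead of sampling it.
#' @return An object of class `"beta_meta_fit"` with elements `draws`
#'   (a [posterior_draws()] over `beta0`, `beta1`, `sigma_u`, `phi`, and
#'   the `u[...]` study effects), `rhat`, `converged`, `stage`, `studies`,
#'   and `data`.
#' @seealso [lc50()], [predict.beta_meta_fit()], [survival_table()]
#' @export
fit_beta_meta <- function(records, stage, config = mcmc_config(),
                          prior_intercept = NULL, prior_slope = NULL,
                          random_effects = TRUE, fix_phi = NULL) {
  stage <- normalize_stage(stage)
  stopifnot(stage %in% .life_stages)
  rec <- records[records$stage == stage, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records for stage ", stage, call. = FALSE)
  if (nrow(rec) < 2) stop("need at least 2 records to fit", call. = FALSE)
  bad <- which(!is.finite(rec$survival) | rec$survival < 0 | rec$survival > 1 |
                 !is.finite(rec$salinity_ppt) | rec$salinity_ppt < 0)
  if (length(bad)) {
    stop("invalid survival/salinity in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  boundary <- rec$survival <= 0 | rec$survival >= 1
  n_imputed <- boundary & is.na(rec$n)
  if (any(n_imputed)) {
    message(sum(n_imputed),
            " boundary record(s) lack a sample size; using n = 10 for ",
            "boundary compression")
    rec$n[n_imputed] <- 10L
  }
  studies <- sort(unique(rec$study))
  if (length(studies) == 1 && random_effects) {
    warning("single study: the study effect is confounded with the ",
            "intercept", call. = FALSE)
  }
  y <- rec$survival
  y[boundary] <- compress_proportions(y[boundary], rec$n[boundary])
  p0 <- if (is.null(prior_intercept)) flat_prior() else prior_intercept
  p1 <- if (is.null(prior_slope)) flat_prior() else prior_slope
  model <- paste0("model {
    for (i in 1:N) {
      y[i] ~ dbeta(mu[i] * phi, (1 - mu[i]) * phi)
      logit(mu[i]) <- beta0 + beta1 * s[i]",
    if (random_effects) " + u[study[i]]" else "", "
    }",
    if (random_effects) "
    for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
    sigma_u ~ dunif(0, 10)
    tau_u <- pow(sigma_u, -2)" else "", "
    beta0 ~ dnorm(m0, t0)
    beta1 ~ dnorm(m1, t1)",
    if (is.null(fix_phi)) "
    phi ~ dgamma(0.01, 0.01)" else "", "
  }")
  data <- list(y = y, s = rec$salinity_ppt,
               N = nrow(rec),
               m0 = p0$mean, t0 = prior_precision(p0),
               m1 = p1$mean, t1 = prior_precision(p1))
  if (random_effects) {
    data$study <- match(rec$study, studies)
    data$J <- length(studies)
  }
  if (!is.null(fix_phi)) {
    stopifnot(fix_phi > 0)
    data$phi <- fix_phi
  }
  inits <- function(k) {
    ini <- list(beta0 = spread_init(0.5, k, config$n_chains),
                beta1 = -spread_init(0.05, k, config$n_chains))
    if (random_effects) ini$sigma_u <- 0.5
    if (is.null(fix_phi)) ini$phi <- 10
    ini
  }
  monitor <- c("beta0", "beta1",
               if (random_effects) c("sigma_u", "u"),
               if (is.null(fix_phi)) "phi")
  fit <- run_jags(model, data, monitor, config, inits)
  if (!fit$converged) {
    warning("meta-analysis fit for stage ", stage,
            " has not converged (max R-hat = ",
            round(max(fit$rhat), 3), ")", call. = FALSE)
  }
  structure(list(draws = fit$draws, rhat = fit$rhat,
                 converged = fit$converged, stage = stage,
                 studies = studies, n_imputed = sum(n_imputed),
                 config = config, data = rec),
            class = "beta_meta_fit")
}

#' @export
coef.beta_meta_fit <- function(object, ...) {
  keep <- intersect(c("beta0", "beta1", "sigma_u", "phi"),
                    object$draws$parameters)
  vapply(keep, function(p) mean(draws_of(object$draws, p)), 0)
}

#' @export
print.beta_meta_fit <- function(x, ...) {
  cat("Beta-regression meta-analysis (", x$stage, " stage)\n", sep = "")
  cat(nrow(x$data), "observations from", length(x$studies), "studies;",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(max R-hat %.3f)\n", max(x$rhat)))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.beta_meta_fit <- function(object, ...) {
  keep <- intersect(c("beta0", "beta1", "sigma_u", "phi"),
                    object$draws$parameters)
  tab <- fit_summary_table(object$draws, object$rhat)
  tab[match(keep, tab$parameter), , drop = FALSE]
}

#' Posterior LC50: the salinity imposing 50% mortality
#'
#' For each posterior draw with a negative salinity slope the survival
#' curve of a typical study (`u = 0`) crosses 0.5 at `-beta0 / beta1`;
#' draws with nonnegative slope are excluded (and counted), and negative
#' crossings are truncated to 0 ppt.  The point estimate is the posterior
#' median and the interval the central 95% of the transformed draws.  If
#' more than half the draws have a nonnegative slope, survival is not
#' credibly decreasing and the estimate is refused.
#'
#' @param fit A `beta_meta_fit`, or any [posterior_draws()] containing
#'   `beta0` and `beta1`.
#' @return Object of class `"lc50_estimate"`: `stage`, `point`, `lo`, `hi`,
#'   `truncated_at_zero`, `n_excluded`.
#' @export
lc50 <- function(fit) {
  draws <- if (inherits(fit, "beta_meta_fit")) fit$draws else fit
  stopifnot(inherits(draws, "posterior_draws"))
  b0 <- draws_of(draws, "beta0")
  b1 <- draws_of(draws, "beta1")
  ok <- b1 < 0
  if (mean(ok) <= 0.5) {
    stop("LC50 undefined: survival is not decreasing in salinity for most ",
         "posterior draws", call. = FALSE)
  }
  x <- -b0[ok] / b1[ok]
  truncated <- any(x < 0)
  x <- pmax(x, 0)
  q <- unname(stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE))
  structure(list(stage = if (inherits(fit, "beta_meta_fit")) fit$stage else NA,
                 point = q[2], lo = q[1], hi = q[3],
                 truncated_at_zero = truncated,
                 n_excluded = sum(!ok)),
            class = "lc50_estimate")
}

#' @export
print.lc50_estimate <- function(x, ...) {
  cat(sprintf("LC50%s: %.2f ppt (95%% BCI %.2f-%.2f)%s\n",
              if (is.na(x$stage)) "" else paste0(" [", x$stage, "]"),
              x$point, x$lo, x$hi,
              if (x$truncated_at_zero) " [interval truncated at 0]" else ""))
  invisible(x)
}

#' Predicted survival curve across salinities
#'
#' For each posterior draw, survival of a typical study (`u = 0`) at
#' salinity `s` is `plogis(beta0 + beta1 * s)`; the curve reports the
#' posterior mean and central 95% credible envelope at each requested
#' salinity.
#'
#' @param object A `beta_meta_fit`.
#' @param salinity Nonnegative salinities in ppt (default 1:40, the
#'   freshwater-to-beyond-seawater range).
#' @param ... Unused.
#' @return Data frame with columns `salinity`, `mean`, `lo`, `hi`.
#' @export
predict.beta_meta_fit <- function(object, salinity = 1:40, ...) {
  predict_survival(object$draws, salinity)
}

predict_survival <- function(draws, salinity) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (length(salinity) == 0) {
    return(data.frame(salinity = numeric(0), mean = numeric(0),
                      lo = numeric(0), hi = numeric(0)))
  }
  if (any(salinity < 0)) stop("salinity must be nonnegative", call. = FALSE)
  b0 <- draws_of(draws, "beta0")
  b1 <- draws_of(draws, "beta1")
  rows <- lapply(salinity, function(s) {
    p <- stats::plogis(b0 + b1 * s)
    q <- unname(stats::quantile(p, c(0.025, 0.975), names = FALSE))
    c(salinity = s, mean = mean(p), lo = q[1], hi = q[2])
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Stage-by-salinity predicted survivorship table
#'
#' Tabulates predicted survivorship (posterior mean with 95% credible
#' interval) for each fitted life stage at a set of field salinities, the
#' layout used to compare meta-analytic expectations with where frogs are
#' actually found.
#'
#' @param fits Named list of `beta_meta_fit` objects; names (or the fits'
#'   own stage labels) identify the stages.  A missing stage produces a
#'   warning and an omitted column.
#' @param salinities Salinities (ppt) at which to predict; rows are sorted
#'   ascending.  Defaults to the brackish-wetland salinities 3.9, 8.3, 11,
#'   16.8 and 23.4 ppt.
#' @return Data frame of class `"survival_table"` in long form:
#'   `salinity`, `stage`, `mean`, `lo`, `hi`.  Printing renders the wide
#'   stage-by-salinity layout with `mean (lo-hi)` cells.
#' @export
survival_table <- function(fits, salinities = c(3.9, 8.3, 11, 16.8, 23.4)) {
  stopifnot(is.list(fits), length(fits) >= 1)
  got <- vapply(fits, function(f) f$stage, "")
  missing_stages <- setdiff(.life_stages, got)
  if (length(missing_stages)) {
    warning("no fit supplied for stage(s): ",
            paste(missing_stages, collapse = ", "), "; column(s) omitted",
            call. = FALSE)
  }
  salinities <- sort(salinities)
  out <- do.call(rbind, lapply(fits, function(f) {
    cbind(stage = f$stage, predict(f, salinities))
  }))
  out <- out[order(out$salinity, match(out$stage, .life_stages)),
             c("salinity", "stage", "mean", "lo", "hi")]
  rownames(out) <- NULL
  class(out) <- c("survival_table", "data.frame")
  out
}

#' @export
print.survival_table <- function(x, digits = 2, ...) {
  cells <- sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                   x$mean, x$lo, x$hi)
  wide <- stats::reshape(
    data.frame(salinity = x$salinity, stage = x$stage, cell = cells,
               stringsAsFactors = FALSE),
    idvar = "salinity", timevar = "stage", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  print.data.frame(wide, row.names = FALSE)
  invisible(x)
}
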