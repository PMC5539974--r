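#' Daily tadpole survival under a salinity acclimation ramp
#'
#' Models the day-by-day survival of 50-tadpole groups ramped toward a
#' target salinity: conditional on the previous day's count,
#' `alive_t ~ Binomial(alive_{t-1}, p_t)` with
#' `logit(p_t) = d0 + ds * s_t + dL * coastal + dsL * s_t * coastal +
#' dd * day + c_clutch`, where `s_t` is the ramp salinity on day `t`, the
#' day covariate enters linearly, and `c_clutch ~ Normal(0, sigma_c^2)`
#' absorbs sibship.  Intercept and salinity slope accept informed priors
#' from the tadpole-stage meta-analysis.  Days starting from an empty
#' group contribute no information and are dropped, keeping the likelihood
#' defined when a clutch dies out.  The conventional chain settings for
#' this model are 4 chains of 50000 iterations with 25000 burn-in.
#'
#' @param series Data frame in the tadpole layout of [read_garden_csv()]:
#'   `clutch`, `location`, `target_ppt`, `day`, `ppt`, `alive`, with 6
#'   rows per clutch x target and nonincreasing counts from a start of 50.
#' @param priors Optional list with `intercept` and/or `salinity`
#'   [gaussian_prior()]s (typically built from the tadpole meta posterior).
#' @param config An [mcmc_config()], e.g.
#'   `mcmc_config(n_chains = 4, n_iter = 50000, n_burn = 25000)`.
#' @param start_n Group size at day 0 (50 in the ramp design).
#' @return An object of class `"tadpole_fit"`.
#' @export
fit_tadpole_survival <- function(series, priors = list(),
                                 config = mcmc_config(), start_n = 50L) {
  stopifnot(all(c("clutch", "location", "target_ppt", "day", "ppt", "alive")
                %in% names(series)))
  series <- series[order(series$clutch, series$target_ppt, series$day), ,
                   drop = FALSE]
  key <- paste(series$clutch, series$target_ppt)
  prev <- integer(nrow(series))
  for (k in unique(key)) {
    rows <- which(key == k)
    alive <- series$alive[rows]
    if (any(diff(alive) > 0)) {
      stop("alive counts increase within series ", k, call. = FALSE)
    }
    prev[rows] <- c(start_n, alive[-length(alive)])
  }
  if (any(series$alive > prev)) {
    stop("alive counts exceed the previous day's survivors", call. = FALSE)
  }
  informative <- prev > 0
  dat <- series[informative, , drop = FALSE]
  prev <- prev[informative]
  if (all(dat$alive == prev)) {
    warning("no deaths observed: daily survival estimates lie near the ",
            "boundary", call. = FALSE)
  }
  des <- garden_design(dat$ppt, dat$location, dat$clutch)
  # clutch effects centered on the clutch-constant intercept + location
  # part of the predictor (see .garden_model for why)
  model <- "model {
    for (i in 1:N) {
      y[i] ~ dbin(p[i], atrisk[i])
      logit(p[i]) <- eta[group[i]] + ds * s[i] +
                     dsL * s[i] * coastal[i] + dd * day[i]
    }
    for (j in 1:G) {
      mu_c[j] <- d0 + dL * cg[j]
      eta[j] ~ dnorm(mu_c[j], tau_c)
      b[j] <- eta[j] - mu_c[j]
    }
    d0 ~ dnorm(m0, t0)
    ds ~ dnorm(ms, ts)
    dL ~ dnorm(0, 0.16)
    dsL ~ dnorm(0, 0.16)
    dd ~ dnorm(0, 0.16)
    sigma_c ~ dunif(0, 10)
    tau_c <- pow(sigma_c, -2)
  }"
  data <- c(list(y = as.integer(dat$alive), atrisk = as.integer(prev),
                 s = des$s, day = as.numeric(dat$day),
                 coastal = des$coastal, group = des$group,
                 cg = group_coastal(des),
                 N = nrow(dat), G = length(des$groups)),
            garden_priors(priors))
  inits <- function(k) list(d0 = spread_init(0.5, k, config$n_chains),
                            ds = -spread_init(0.02, k, config$n_chains),
                            sigma_c = 0.3)
  fit <- run_jags(model, data, c("d0", "ds", "dL", "dsL", "dd", "sigma_c", "b"),
                  config, inits)
  if (!fit$converged) {
    warning("tadpole survival fit has not converged (max R-hat = ",
            round(max(fit$rhat), 3), ")", call. = FALSE)
  }
  structure(list(draws = fit$draws, rhat = fit$rhat,
                 converged = fit$converged, groups = des$groups,
                 config = config),
            class = "tadpole_fit")
}

#' Predicted end-of-ramp tadpole survival
#'
#' For each posterior draw, daily survival probabilities are evaluated on
#' the [ramp_schedule()] of the target salinity and multiplied across the
#' six acclimation days (`prod_t p_t`, at clutch effect 0); the result is
#' the probability a tadpole survives the whole ramp, summarized per
#' (location, target salinity) as posterior mean with 95% credible
#' interval.
#'
#' @param object A `tadpole_fit`.
#' @param target_ppt Ramp targets, each one of 0.5, 4, 6, 8, 12.
#' @param location `"coastal"` or `"inland"`.
#' @param ... Unused.
#' @return Data frame `target_ppt`, `location`, `mean`, `lo`, `hi`.
#' @export
predict.tadpole_fit <- function(object, target_ppt = c(0.5, 4, 6, 8, 12),
                                location = "inland", ...) {
  location <- match.arg(location, c("inland", "coastal"))
  cst <- as.integer(location == "coastal")
  d0 <- draws_of(object$draws, "d0")
  ds <- draws_of(object$draws, "ds")
  dL <- draws_of(object$draws, "dL")
  dsL <- draws_of(object$draws, "dsL")
  dd <- draws_of(object$draws, "dd")
  rows <- lapply(target_ppt, function(tp) {
    sched <- ramp_schedule(tp)
    surv <- rep(1, length(d0))
    for (t in sched$day) {
      s <- sched$ppt[t]
      surv <- surv * stats::plogis(d0 + ds * s + (dL + dsL * s) * cst + dd * t)
    }
    q <- unname(stats::quantile(surv, c(0.025, 0.975), names = FALSE))
    c(target_ppt = tp, mean = mean(surv), lo = q[1], hi = q[2])
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(out[1], location = location, out[-1])
  rownames(out) <- NULL
  out
}

#' @export
coef.tadpole_fit <- function(object, ...) {
  vapply(c("d0", "ds", "dL", "dsL", "dd", "sigma_c"),
         function(p) mean(draws_of(object$draws, p)), 0)
}

#' @export
print.tadpole_fit <- function(x, ...) {
  cat("Ramped tadpole survival fit (", length(x$groups), " clutches); ",
      if (x$converged) "converged" else "NOT converged",
      sprintf(" (max R-hat %.3f)\n", max(x$rhat)), sep = "")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.tadpole_fit <- function(object, ...) {
  keep <- c("d0", "ds", "dL", "dsL", "dd", "sigma_c")
  tab <- fit_summary_table(object$draws, object$rhat)
  tab[match(keep, tab$parameter), , drop = FALSE]
}
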