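#' MCMC sampler settings
#'
#' Chain settings for all model fits.  The defaults are three chains of
#' 5000 iterations with the first 2500 discarded as burn-in and starting
#' values that vary by an order of magnitude between chains; the ramped
#' tadpole model conventionally uses [mcmc_config(n_chains = 4,
#' n_iter = 50000, n_burn = 25000)][mcmc_config].
#'
#' @param n_chains Number of chains (>= 2 so convergence can be assessed).
#' @param n_iter Total iterations per chain, including burn-in.
#' @param n_burn Burn-in iterations discarded from each chain.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param n_adapt JAGS adaptation steps before burn-in.
#' @param thin Thinning interval for retained draws.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5000, n_burn = 2500,
                        seed = 1L, n_adapt = 1000, thin = 1) {
  stopifnot(n_chains >= 2, n_iter > n_burn, n_burn >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), seed = as.integer(seed),
                 n_adapt = as.integer(n_adapt), thin = as.integer(thin)),
            class = "mcmc_config")
}

#' Bundle per-chain draw matrices into a posterior object
#'
#' The currency passed between pipeline stages: a list of per-chain
#' iteration x parameter matrices with identical dimensions and finite
#' values.
#'
#' @param chains List of numeric matrices, one per chain, equal dimensions
#'   and identical column names.
#' @return An object of class `"posterior_draws"`.
#' @export
posterior_draws <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  cn <- colnames(chains[[1]])
  if (is.null(cn)) stop("draw matrices must have parameter column names")
  for (ch in chains) {
    if (!is.matrix(ch) || !identical(colnames(ch), cn) ||
        nrow(ch) != nrow(chains[[1]])) {
      stop("chains must be matrices of equal size with identical parameters")
    }
    if (any(!is.finite(ch))) stop("posterior draws must be finite")
  }
  structure(list(chains = chains, parameters = cn), class = "posterior_draws")
}

#' @export
as.matrix.posterior_draws <- function(x, ...) do.call(rbind, x$chains)

#' Extract the pooled draws of one parameter
#' @param x A `posterior_draws` object.
#' @param parameter Parameter name.
#' @return Numeric vector of draws pooled over chains.
#' @export
draws_of <- function(x, parameter) {
  stopifnot(inherits(x, "posterior_draws"))
  if (!parameter %in% x$parameters) {
    stop("no draws for parameter ", parameter, call. = FALSE)
  }
  as.vector(vapply(x$chains, function(ch) ch[, parameter],
                   numeric(nrow(x$chains[[1]]))))
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "iterations,", length(x$parameters),
      "parameters\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic between-/within-chain variance diagnostic
#' R-hat = sqrt(((n - 1)/n * W + B/n) / W), where `W` is the mean
#' within-chain variance and `B` is `n` times the variance of the chain
#' means.  Values near 1 indicate the chains have mixed; fits in this
#' package are gated at a maximum R-hat of 1.1 over all parameters.
#'
#' @param chains Draws of a single parameter: a list of numeric vectors
#'   (one per chain) or a matrix with one column per chain.
#' @return The scalar R-hat.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  chains <- lapply(chains, as.numeric)
  m <- length(chains)
  if (m < 2) stop("Gelman-Rubin diagnostic requires at least 2 chains",
                  call. = FALSE)
  n <- unique(lengths(chains))
  if (length(n) != 1 || n < 2) {
    stop("chains must have equal length of at least 2", call. = FALSE)
  }
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(vapply(chains, mean, 0))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' R-hat for every parameter of a posterior
#' @param x A `posterior_draws` object.
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  vapply(x$parameters, function(p) {
    gelman_rubin(lapply(x$chains, function(ch) ch[, p]))
  }, 0)
}

# Deterministic sub-seed derivation so independent model components can be
# simulated or fit independently from one global seed.  Result stays below
# 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1013 + index * 7919) %% 2147483647L
}

# Run a JAGS model and return posterior_draws plus convergence info.
# `inits` is a function(chain) returning a named list of starting values;
# per-chain RNG seeds are derived from cfg$seed.
run_jags <- function(model_string, data, monitor, cfg, inits = NULL) {
  init_list <- lapply(seq_len(cfg$n_chains), function(k) {
    ini <- if (is.null(inits)) list() else inits(k)
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- derive_seed(cfg$seed, k)
    ini
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = init_list, n.chains = cfg$n_chains,
                             n.adapt = cfg$n_adapt, quiet = TRUE)
  if (cfg$n_burn > 0) update(model, cfg$n_burn, progress.bar = "none")
  samples <- rjags::coda.samples(model, variable.names = monitor,
                                 n.iter = cfg$n_iter - cfg$n_burn,
                                 thin = cfg$thin, progress.bar = "none")
  draws <- posterior_draws(lapply(samples, function(ch) {
    m <- as.matrix(ch)
    m[, order(colnames(m)), drop = FALSE]
  }))
  rh <- rhat(draws)
  list(draws = draws, rhat = rh, converged = max(rh) < 1.1)
}

# Chain k starting value: base scaled by an order of magnitude per chain,
# so starting points span (at least) one order of magnitude.
spread_init <- function(base, k, n_chains) {
  base * 10^(k - 1 - (n_chains - 1) / 2)
}

# Summarize one parameter's pooled draws as mean/sd/95% interval.
draw_summary <- function(x) {
  q <- unname(stats::quantile(x, c(0.025, 0.975), names = FALSE))
  c(mean = mean(x), sd = stats::sd(x), lo = q[1], hi = q[2])
}

# Fit-summary table shared by all model classes.
fit_summary_table <- function(draws, rh) {
  stats <- t(vapply(draws$parameters, function(p) draw_summary(draws_of(draws, p)),
                    numeric(4)))
  data.frame(parameter = draws$parameters, mean = stats[, "mean"],
             sd = stats[, "sd"], lo = stats[, "lo"], hi = stats[, "hi"],
             rhat = unname(rh[draws$parameters]), row.names = NULL,
             stringsAsFactors = FALSE)
}
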