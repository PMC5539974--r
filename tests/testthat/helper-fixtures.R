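# Shared helpers: small MCMC settings for unit tests, fixture writers, and
# hand-rolled fit objects with known draws for closed-form checks.

quick_cfg <- function(seed = 1L, n_iter = 2500, n_burn = 1000) {
  mcmc_config(n_chains = 3, n_iter = n_iter, n_burn = n_burn, seed = seed,
              n_adapt = 500)
}

write_lines_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# A posterior_draws object holding constant (or supplied) values for beta0
# and beta1, split over two chains.
fake_meta_draws <- function(beta0, beta1) {
  n <- max(length(beta0), length(beta1), 4)
  b0 <- rep_len(beta0, n)
  b1 <- rep_len(beta1, n)
  half <- n / 2
  make <- function(i) cbind(beta0 = b0[i], beta1 = b1[i])
  posterior_draws(list(make(1:half), make((half + 1):n)))
}

fake_meta_fit <- function(beta0, beta1, stage = "egg", converged = TRUE) {
  draws <- fake_meta_draws(beta0, beta1)
  structure(list(draws = draws, rhat = rhat(draws), converged = converged,
                 stage = stage, studies = "fake", data = NULL),
            class = "beta_meta_fit")
}

fake_hurdle_fit <- function(g0, gs, gL = 0, gsL = 0) {
  n <- max(length(g0), length(gs), length(gL), length(gsL), 4)
  m <- cbind(g0 = rep_len(g0, n), gs = rep_len(gs, n),
             gL = rep_len(gL, n), gsL = rep_len(gsL, n))
  half <- n / 2
  structure(list(stage = "bernoulli",
                 draws = posterior_draws(list(m[1:half, , drop = FALSE],
                                              m[(half + 1):n, , drop = FALSE])),
                 converged = TRUE, groups = "fake"),
            class = "hurdle_fit")
}

fake_tadpole_fit <- function(d0, ds = 0, dL = 0, dsL = 0, dd = 0) {
  m <- cbind(d0 = rep_len(d0, 4), ds = rep_len(ds, 4), dL = rep_len(dL, 4),
             dsL = rep_len(dsL, 4), dd = rep_len(dd, 4))
  structure(list(draws = posterior_draws(list(m[1:2, , drop = FALSE],
                                              m[3:4, , drop = FALSE])),
                 converged = TRUE, groups = "fake"),
            class = "tadpole_fit")
}

# Brute-force oracle: maximum likelihood of the fixed-effect beta
# regression on compressed proportions, by dense 2-D grid search over
# (beta0, beta1) with the precision phi held fixed.  Independent of the
# package's sampling path (uses dbeta directly).
grid_mle_beta <- function(y, s, phi, b0_range, b1_range, n_grid = 121) {
  b0s <- seq(b0_range[1], b0_range[2], length.out = n_grid)
  b1s <- seq(b1_range[1], b1_range[2], length.out = n_grid)
  best <- c(-Inf, NA, NA)
  for (b0 in b0s) {
    for (b1 in b1s) {
      mu <- plogis(b0 + b1 * s)
      ll <- sum(dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
      if (ll > best[1]) best <- c(ll, b0, b1)
    }
  }
  c(beta0 = best[2], beta1 = best[3])
}
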