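test_that("boundary compression follows the Smithson-Verkuilen transform", {
  expect_equal(compress_proportions(1, 50), 0.99)
  expect_equal(compress_proportions(0, 50), 0.01)
  for (n in c(2, 10, 500)) expect_equal(compress_proportions(0.5, n), 0.5)
  # order-preserving and strictly interior
  y <- c(0, 0.2, 0.21, 0.7, 1)
  z <- compress_proportions(y, 25)
  expect_equal(order(z), order(y))
  expect_true(all(z > 0 & z < 1))
  expect_error(compress_proportions(0.5, 0), ">= 1")
})

test_that("beta log-likelihood matches closed forms and normalizes", {
  expect_equal(beta_loglik(0.5, 0.5, 2), 0)           # Beta(1,1) is uniform
  expect_equal(beta_loglik(0.25, 0.5, 4), log(1.125)) # 6 * y * (1-y) at 0.25
  # both beta shapes kept above 1 so the grid sum resolves the density
  set.seed(11)
  for (i in 1:5) {
    mu <- runif(1, 0.2, 0.8)
    phi <- runif(1, 8, 40)
    grid <- seq(1e-6, 1 - 1e-6, length.out = 20001)
    integral <- sum(exp(beta_loglik(grid, mu, phi))) * diff(grid[1:2])
    expect_lt(abs(integral - 1), 1e-3)
  }
  expect_error(beta_loglik(0, 0.5, 2), "compress")
  expect_error(beta_loglik(1, 0.5, 2), "compress")
})

test_that("LC50 matches the closed form on degenerate posteriors", {
  est <- lc50(fake_meta_fit(2, -0.4))
  expect_equal(est$point, 5)
  expect_equal(c(est$lo, est$hi), c(5, 5))
  expect_equal(lc50(fake_meta_fit(0, -1))$point, 0)
  # negative crossings truncate to zero and are flagged
  est <- lc50(fake_meta_fit(-1, -0.5))
  expect_equal(est$point, 0)
  expect_true(est$truncated_at_zero)
})

test_that("two-point posterior gives enumerable LC50 interval endpoints", {
  est <- lc50(fake_meta_draws(1.8, rep(c(-0.9, -0.3), each = 50)))
  expect_equal(est$lo, 2)
  expect_equal(est$hi, 6)
})

test_that("LC50 is refused when survival is not credibly decreasing", {
  b1 <- c(rep(0.1, 60), rep(-0.5, 40))
  expect_error(lc50(fake_meta_draws(2, b1)), "not decreasing")
  # draws with nonnegative slope are excluded but counted
  est <- lc50(fake_meta_draws(2, c(rep(-0.4, 80), rep(0.1, 20))))
  expect_equal(est$n_excluded, 20)
  expect_equal(est$point, 5)
})

test_that("per-draw LC50 equals the bisection root of the survival curve", {
  set.seed(5)
  b0 <- rnorm(50, 2, 0.5)
  b1 <- -runif(50, 0.1, 0.9)
  for (i in 1:50) {
    root <- uniroot(function(s) plogis(b0[i] + b1[i] * s) - 0.5,
                    c(0, 100), tol = 1e-12)$root
    expect_equal(-b0[i] / b1[i], root, tolerance = 1e-8)
  }
})

test_that("survival predictions match closed forms on degenerate draws", {
  fit <- fake_meta_fit(2, -0.4)
  pred <- predict(fit, c(0, 5))
  expect_equal(pred$mean, c(plogis(2), 0.5))
  expect_equal(pred$lo, pred$mean)
  expect_equal(pred$hi, pred$mean)
  expect_equal(nrow(predict(fit, numeric(0))), 0)
  expect_error(predict(fit, -1), "nonnegative")
})

test_that("mean survival declines in salinity when all slopes are negative", {
  set.seed(6)
  draws <- fake_meta_draws(rnorm(100, 2, 0.3), -runif(100, 0.2, 0.6))
  fit <- fake_meta_fit(2, -0.4)
  fit$draws <- draws
  pred <- predict(fit, seq(0, 30, by = 1.5))
  expect_true(all(diff(pred$mean) < 0))
  expect_true(all(pred$lo <= pred$mean & pred$mean <= pred$hi))
})

test_that("fixed-effect posterior agrees with a brute-force grid MLE", {
  truth <- meta_truth(beta0 = 1.5, beta1 = -0.3, sigma_u = 0, phi = 60,
                      n_studies = 1,
                      salinity_grid = seq(0, 11, by = 1),
                      n_per_record = 100)
  rec <- simulate_meta_dataset(truth, seed = 3)
  fit <- fit_beta_meta(rec, "tadpole", quick_cfg(seed = 3, n_iter = 6000,
                                                 n_burn = 2000),
                       random_effects = FALSE, fix_phi = 60)
  expect_true(fit$converged)
  # beta draws never hit the boundary, so the fit sees the raw proportions
  mle <- grid_mle_beta(rec$survival, rec$salinity_ppt, phi = 60,
                       b0_range = c(0.5, 2.5), b1_range = c(-0.6, -0.05),
                       n_grid = 161)
  est <- coef(fit)
  expect_lt(abs(est["beta0"] - mle["beta0"]), 0.05)
  expect_lt(abs(est["beta1"] - mle["beta1"]), 0.02)
})

test_that("single-study fits warn about confounded study effects", {
  truth <- meta_truth(n_studies = 1, salinity_grid = seq(0, 12, by = 2))
  rec <- simulate_meta_dataset(truth, seed = 2)
  expect_warning(
    fit_beta_meta(rec, "tadpole", quick_cfg(n_iter = 1500, n_burn = 600)),
    "confounded")
})

test_that("the meta-analysis recovers generating parameters", {
  truth <- meta_truth(beta0 = 2, beta1 = -0.45, sigma_u = 0.3, phi = 20,
                      n_studies = 30)
  rec <- simulate_meta_dataset(truth, seed = 8)
  fit <- fit_beta_meta(rec, "tadpole", quick_cfg(seed = 8, n_iter = 4000,
                                                 n_burn = 2000))
  expect_true(fit$converged)
  expect_lt(max(fit$rhat), 1.1)
  est <- coef(fit)
  expect_lt(abs(est["beta0"] - 2) / 2, 0.2)
  expect_lt(abs(est["beta1"] + 0.45) / 0.45, 0.2)
  sm <- summary(fit)
  b1 <- sm[sm$parameter == "beta1", ]
  expect_true(b1$lo <= -0.45 && -0.45 <= b1$hi)
})

test_that("fit rejects stages with no usable records", {
  rec <- simulate_meta_dataset(meta_truth("egg"), seed = 1)
  expect_error(fit_beta_meta(rec, "adult", quick_cfg()), "no records")
})

test_that("survival table mirrors closed forms, ordering, and warns on gaps", {
  fits <- list(egg = fake_meta_fit(2, -0.4, "egg"),
               tadpole = fake_meta_fit(1.5, -0.25, "tadpole"))
  expect_warning(tab <- survival_table(fits, c(11, 3.9)), "adult")
  expect_equal(tab$salinity, c(3.9, 3.9, 11, 11))  # sorted ascending
  egg_cells <- tab[tab$stage == "egg", ]
  expect_equal(egg_cells$mean, plogis(2 - 0.4 * c(3.9, 11)))
  expect_equal(egg_cells$lo, egg_cells$mean)
})
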