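test_that("generators are deterministic given a seed", {
  expect_identical(simulate_meta_dataset(meta_truth("egg"), seed = 4),
                   simulate_meta_dataset(meta_truth("egg"), seed = 4))
  expect_identical(simulate_oviposition(garden_truth(), 2, seed = 4),
                   simulate_oviposition(garden_truth(), 2, seed = 4))
  expect_identical(simulate_tadpoles(garden_truth(), 2, seed = 4),
                   simulate_tadpoles(garden_truth(), 2, seed = 4))
  # different seeds give different data
  expect_false(identical(simulate_meta_dataset(meta_truth("egg"), 4),
                         simulate_meta_dataset(meta_truth("egg"), 5)))
})

test_that("meta generator hits its own LC50 and intercept by construction", {
  # sigma_u = 0 and huge phi: survival at s = -beta0/beta1 is 0.5
  truth <- meta_truth(beta0 = 2, beta1 = -0.4, sigma_u = 0, phi = 1e6,
                      n_studies = 5, salinity_grid = 5)
  rec <- simulate_meta_dataset(truth, seed = 1)
  expect_true(all(abs(rec$survival - 0.5) < 0.01))
  # mean survival at s = 0 over many studies approaches plogis(beta0)
  truth <- meta_truth(beta0 = 1.2, beta1 = -0.3, sigma_u = 0.3, phi = 20,
                      n_studies = 200, salinity_grid = 0)
  rec <- simulate_meta_dataset(truth, seed = 2)
  # random intercepts make E[plogis(b0 + u)] slightly below plogis(b0)
  expect_lt(abs(mean(rec$survival) - plogis(1.2)), 0.03)
})

test_that("generated tables pass ingestion validation with zero rejections", {
  rec <- simulate_meta_dataset(meta_truth("tadpole"), seed = 6)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(study = rec$study, species = rec$species,
                       family = rec$family, stage = rec$stage,
                       salinity = rec$salinity_ppt, n = rec$n,
                       survival = rec$survival, sd = rec$sd,
                       hours = rec$hours, location = rec$location),
            path, row.names = FALSE)
  back <- read_survival_csv(path, quiet = TRUE)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(nrow(attr(back, "rejections")), 0)

  sim <- simulate_oviposition(garden_truth(), 3, seed = 6)
  tad <- simulate_tadpoles(garden_truth(), 3, seed = 6)
  for (case in list(list(sim$oviposition, "oviposition"),
                    list(sim$hatch, "hatch"), list(tad, "tadpole"))) {
    path <- tempfile(fileext = ".csv")
    write_garden_csv(case[[1]], path)
    back <- read_garden_csv(path, case[[2]], quiet = TRUE)
    expect_equal(nrow(back), nrow(case[[1]]))
    expect_length(attr(back, "rejections"), 0)
  }
})

test_that("oviposition output respects the binary-choice design invariants", {
  sim <- simulate_oviposition(garden_truth(), 4, seed = 10)
  ovi <- sim$oviposition
  expect_equal(nrow(ovi), 2 * 4 * 4 * 6)  # 2 locations x 4 reps x 4 bins x 6 cups
  for (b in unique(ovi$bin)) {
    cups <- ovi[ovi$bin == b, ]
    expect_equal(nrow(cups), 6)
    expect_equal(sum(cups$cup_ppt == 0), 3)
    expect_equal(sum(cups$cup_ppt == cups$treatment_ppt[1]), 3)
  }
  expect_true(all(sim$hatch$hatched <= sim$hatch$laid))
  expect_true(all(sim$hatch$laid >= 1))
})

test_that("clutch sizes match the overdispersed count model", {
  set.seed(77)
  tr <- garden_truth()
  draws <- round(rlnorm(1e4, tr$clutch_meanlog, tr$clutch_sdlog))
  expect_lt(abs(mean(draws) - 1363) / 1363, 0.05)
  expect_gt(min(draws), 300)   # range on the scale of observed clutches
  expect_lt(max(draws), 6000)
})

test_that("a positive interaction depresses coastal freshwater investment less", {
  # with gsL < 0 on the freshwater-share logit, coastal pairs put a larger
  # share into salt at 12 ppt than inland pairs
  sim <- simulate_oviposition(garden_truth(), 60, seed = 13)
  ovi <- sim$oviposition
  bins <- do.call(rbind, lapply(split(ovi, ovi$bin), function(b) {
    data.frame(location = b$location[1], trt = b$treatment_ppt[1],
               prop_fresh = sum(b$eggs[b$cup_ppt == 0]) / max(1, sum(b$eggs)))
  }))
  at12 <- bins[bins$trt == 12, ]
  expect_gt(mean(at12$prop_fresh[at12$location == "inland"]),
            mean(at12$prop_fresh[at12$location == "coastal"]))
})

test_that("hurdle decomposition reproduces the expected salt-side eggs", {
  # sigma = 0 truths make the marginal closed-form computable:
  # E[salt eggs] = P(any salt cup chosen) * E[clutch] * (1 - p_fresh)
  tr <- garden_truth(
    choice = c(g0 = 2, gs = -0.2, gL = 0, gsL = 0, sigma = 0),
    investment = c(g0 = 0.5, gs = 0.15, gL = 0, gsL = 0, sigma = 0))
  sim <- simulate_oviposition(tr, n_replicates = 300, seed = 21)
  ovi <- sim$oviposition
  salt6 <- ovi[ovi$treatment_ppt == 6 & ovi$cup_ppt > 0 &
                 ovi$location == "inland", ]
  per_bin <- tapply(salt6$eggs, salt6$bin, sum)
  p_cup <- plogis(2 - 0.2 * 6)
  p_any <- 1 - (1 - p_cup)^3
  e_clutch <- exp(tr$clutch_meanlog + tr$clutch_sdlog^2 / 2)
  expected <- p_any * e_clutch * (1 - plogis(0.5 + 0.15 * 6))
  expect_lt(abs(mean(per_bin) - expected) / expected, 0.1)
})

test_that("tadpole series obey the ramp and the death process", {
  tr <- garden_truth(tadpole = c(d0 = 30, ds = 0, dL = 0, dsL = 0, dd = 0,
                                 sigma = 0))
  series <- simulate_tadpoles(tr, 2, seed = 3)
  expect_true(all(series$alive == 50))  # daily p ~ 1 keeps everyone alive
  for (key in unique(paste(series$clutch, series$target_ppt))) {
    ser <- series[paste(series$clutch, series$target_ppt) == key, ]
    expect_equal(ser$ppt, ramp_schedule(ser$target_ppt[1])$ppt)
    expect_true(all(diff(ser$alive) <= 0))
  }
  # constant daily p = 0.9: day-6 survival concentrates near 0.9^6
  tr <- garden_truth(tadpole = c(d0 = qlogis(0.9), ds = 0, dL = 0, dsL = 0,
                                 dd = 0, sigma = 0))
  series <- simulate_tadpoles(tr, 100, seed = 19)
  day6 <- series$alive[series$day == 6] / 50
  expect_lt(abs(mean(day6) - 0.9^6), 0.02)
})
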