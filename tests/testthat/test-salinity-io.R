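test_that("salinity conversions hit the standard reference points", {
  expect_equal(convert_salinity(100, "percent_seawater"), 35)
  expect_equal(convert_salinity(12, "g_per_L"), 12)
  expect_equal(convert_salinity(4150, "mg_per_L"), 4.15)
  expect_equal(convert_salinity(10, "mS_per_cm"), 6.4)
  expect_equal(convert_salinity(1, "mol_NaCl_per_L"), 58.44)
  expect_equal(convert_salinity(7.5), 7.5)
})

test_that("conversion rejects unknown units and negative values", {
  expect_error(convert_salinity(5, "psu"), "supported units")
  expect_error(convert_salinity(5, "psu"), "mS_per_cm")
  expect_error(convert_salinity(-1, "ppt"), "nonnegative")
})

test_that("conversion is positively homogeneous in the measurement", {
  for (unit in c("ppt", "mg_per_L", "percent_seawater", "mS_per_cm",
                 "mol_NaCl_per_L")) {
    for (k in c(0.5, 2, 10)) {
      expect_equal(convert_salinity(k * 3, unit),
                   k * convert_salinity(3, unit))
    }
  }
})

test_that("well-formed survival CSV is read with normalized stages", {
  path <- write_lines_csv(c(
    "study,species,family,stage,salinity,n,survival,sd,hours,location",
    "s1,Hyla cinerea,Hylidae,Egg,4,20,0.6,0.1,96,lab",
    "s1,Hyla cinerea,Hylidae,LARVAE,8,20,0.4,0.1,96,lab",
    "s2,Bufo viridis,Bufonidae,adult,12,10,0.8,,48,field"))
  rec <- read_survival_csv(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$stage, c("egg", "tadpole", "adult"))
  expect_equal(rec$salinity_ppt, c(4, 8, 12))
  expect_equal(nrow(attr(rec, "rejections")), 0)
})

test_that("rows violating record invariants are rejected and logged", {
  path <- write_lines_csv(c(
    "study,stage,salinity,survival",
    "s1,egg,4,0.6",
    "s1,egg,8,1.2",
    "s2,tadpole,6,0.5"))
  expect_message(rec <- read_survival_csv(path), "row 2 rejected")
  expect_equal(nrow(rec), 2)
  rej <- attr(rec, "rejections")
  expect_equal(rej$row, 2L)
  expect_match(rej$reason, "survival")
})

test_that("a unit column triggers per-row conversion to ppt", {
  path <- write_lines_csv(c(
    "study,stage,salinity,unit,survival",
    "s1,egg,4000,mg_per_L,0.6",
    "s1,egg,8000,mg_per_L,0.4",
    "s2,egg,50,percent_seawater,0.3"))
  rec <- read_survival_csv(path)
  expect_equal(rec$salinity_ppt, c(4, 8, 17.5))
})

test_that("missing required columns are a hard failure naming the column", {
  path <- write_lines_csv(c("study,stage,salinity", "s1,egg,4"))
  expect_error(read_survival_csv(path), "survival")
})

test_that("ramp schedules match the published daily increments", {
  r12 <- ramp_schedule(12)
  expect_equal(r12$ppt, seq(2, 12, by = 2))
  expect_equal(ramp_schedule(0.5)$ppt, rep(0.5, 6))
  d6 <- ramp_schedule(4)$ppt[6]
  expect_gte(d6, 3.98 - 1e-9)
  expect_lte(d6, 4.02 + 1e-9)
  expect_true(abs(ramp_schedule(8)$ppt[6] - 8) <= 0.02 + 1e-9)
  expect_equal(ramp_schedule(6)$ppt[6], 6)
  for (tp in c(0.5, 4, 6, 8, 12)) {
    expect_true(all(diff(ramp_schedule(tp)$ppt) >= 0))
    expect_equal(nrow(ramp_schedule(tp)), 6)
  }
  expect_error(ramp_schedule(10), "one of")
})

test_that("garden tables round-trip through write and read", {
  sim <- simulate_oviposition(garden_truth(), n_replicates = 2, seed = 42)
  tad <- simulate_tadpoles(garden_truth(), n_clutches = 2, seed = 42)
  for (case in list(list(sim$oviposition, "oviposition"),
                    list(sim$hatch, "hatch"),
                    list(tad, "tadpole"))) {
    path <- tempfile(fileext = ".csv")
    write_garden_csv(case[[1]], path)
    back <- read_garden_csv(path, case[[2]], quiet = TRUE)
    attr(back, "rejections") <- NULL
    orig <- case[[1]]
    orig <- orig[do.call(order, orig), ]
    back <- back[do.call(order, back), ]
    rownames(orig) <- rownames(back) <- NULL
    num <- function(d) { d[] <- lapply(d, function(col) {
      if (is.numeric(col)) as.numeric(col) else col }); d }
    expect_equal(num(back), num(orig))
  }
})

test_that("malformed garden units are rejected", {
  sim <- simulate_oviposition(garden_truth(), n_replicates = 1, seed = 7)
  ovi <- sim$oviposition[-1, ]  # first bin now has 5 cups
  path <- tempfile(fileext = ".csv")
  write_garden_csv(ovi, path)
  expect_message(kept <- read_garden_csv(path, "oviposition"),
                 "3 freshwater \\+ 3 salt")
  expect_equal(nrow(kept), nrow(ovi) - 5)

  hatch <- sim$hatch
  hatch$hatched[1] <- hatch$laid[1] + 5
  path <- tempfile(fileext = ".csv")
  write_garden_csv(hatch, path)
  expect_message(kept <- read_garden_csv(path, "hatch"), "exceeds")
  expect_equal(nrow(kept), nrow(hatch) - 1)

  tad <- simulate_tadpoles(garden_truth(), n_clutches = 1, seed = 7)
  tad$alive[tad$day == 3][1] <- tad$alive[tad$day == 2][1] + 5
  path <- tempfile(fileext = ".csv")
  write_garden_csv(tad, path)
  expect_message(kept <- read_garden_csv(path, "tadpole"), "monotonicity")
  expect_equal(nrow(kept), nrow(tad) - 6)
})
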