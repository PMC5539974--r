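#' Ground truth for a synthetic meta-analysis layer
#'
#' Parameters of the generating beta regression for one life stage.  The
#' per-stage defaults are calibrated so the synthetic literature
#' qualitatively matches what is known about anuran salt tolerance: egg
#' survival crossing 50% near 4.2 ppt, tadpoles near 5.5 ppt, adults near
#' 9 ppt (the adult stage rests on only three studies with high
#' between-study heterogeneity, hence few studies and a large `sigma_u`).
#'
#' @param stage `"egg"`, `"tadpole"`, or `"adult"` (selects defaults), or
#'   `NULL` to use the explicit arguments.
#' @param beta0 Logit survival at 0 ppt for a typical study.
#' @param beta1 Logit change per ppt (negative: survival declines).
#' @param sigma_u Between-study sd of the random intercept.
#' @param phi Beta precision of the observed proportions.
#' @param n_studies Number of studies.
#' @param salinity_grid Salinities tested by every study (one record per
#'   study x salinity).
#' @param n_per_record Animals per extracted proportion.
#' @return Object of class `"meta_truth"`.
#' @export
meta_truth <- function(stage = NULL, beta0 = 2, beta1 = -0.45,
                       sigma_u = 0.3, phi = 20, n_studies = 30,
                       salinity_grid = c(0, 2, 4, 6, 8, 10, 12, 16),
                       n_per_record = 30) {
  if (!is.null(stage)) {
    stage <- normalize_stage(stage)
    defaults <- list(
      egg = list(beta0 = 1.0682, beta1 = -0.2574, sigma_u = 0.45, phi = 20,
                 n_studies = 18,
                 salinity_grid = c(0, 1, 2, 4, 6, 8, 12, 16)),
      tadpole = list(beta0 = 1.4976, beta1 = -0.2723, sigma_u = 0.3,
                     phi = 20, n_studies = 24,
                     salinity_grid = c(0, 1, 2, 4, 6, 8, 12, 16)),
      adult = list(beta0 = 0.7188, beta1 = -0.0799, sigma_u = 0.7, phi = 20,
                   n_studies = 3,
                   salinity_grid = c(0, 2, 4, 6, 9, 12, 16, 20, 24)))
    d <- defaults[[stage]]
    beta0 <- d$beta0; beta1 <- d$beta1; sigma_u <- d$sigma_u
    phi <- d$phi; n_studies <- d$n_studies; salinity_grid <- d$salinity_grid
  } else {
    stage <- "tadpole"
  }
  stopifnot(phi > 0, sigma_u >= 0, n_studies >= 1,
            all(salinity_grid >= 0), n_per_record >= 1)
  structure(list(stage = stage, beta0 = beta0, beta1 = beta1,
                 sigma_u = sigma_u, phi = phi, n_studies = n_studies,
                 salinity_grid = salinity_grid, n_per_record = n_per_record),
            class = "meta_truth")
}

#' Simulate a survivorship meta-analysis table
#'
#' For each study `j`, draws a random intercept `u_j ~ N(0, sigma_u^2)`,
#' then for every salinity `s` on the grid draws an observed survival
#' proportion from `Beta(mu * phi, (1 - mu) * phi)` with
#' `logit(mu) = beta0 + beta1 * s + u_j` — the exact generating process the
#' meta-analysis model assumes, so fits on this output are parameter-
#' recovery tests with known truth.  Deterministic given `seed`.
#'
#' @param truth A [meta_truth()].
#' @param seed Integer seed.
#' @return Data frame in the layout of [read_survival_csv()] output.
#' @export
simulate_meta_dataset <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "meta_truth"))
  old <- .Random.seed_guard(derive_seed(seed, 11L))
  on.exit(old())
  u <- stats::rnorm(truth$n_studies, 0, truth$sigma_u)
  rows <- expand.grid(study = seq_len(truth$n_studies),
                      salinity_ppt = truth$salinity_grid)
  mu <- stats::plogis(truth$beta0 + truth$beta1 * rows$salinity_ppt +
                        u[rows$study])
  surv <- stats::rbeta(nrow(rows), mu * truth$phi, (1 - mu) * truth$phi)
  data.frame(
    study = sprintf("synthetic_study_%02d", rows$study),
    species = sprintf("Synthetic species %02d", rows$study),
    family = "Synthetica",
    stage = truth$stage,
    salinity_ppt = rows$salinity_ppt,
    n = as.integer(truth$n_per_record),
    survival = surv,
    sd = NA_real_,
    hours = 96,
    location = "laboratory",
    stringsAsFactors = FALSE
  )
}

# Save/restore the global RNG state around a seeded simulation.
.Random.seed_guard <- function(seed) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Ground truth for a synthetic common-garden layer
#'
#' Coefficient sets for the four garden models on the shared linear
#' predictor (inland reference; `*_sL` terms are the coastal-by-salinity
#' interaction).  Defaults emulate a population pair in which coastal
#' (chronically salt-exposed) frogs avoid salt less, hatch better in salt,
#' and survive salt better as tadpoles than inland (salt-naive) frogs, on
#' the scales reported for green treefrog trials: clutch sizes around
#' 1363 eggs (713-3039), near-certain oviposition in freshwater, strong
#' hatching decline above ~4 ppt, and tadpole ramps surviving well to
#' 6-8 ppt but collapsing at 12 ppt.
#'
#' @param choice Named vector `g0, gs, gL, gsL, sigma` for cup-level
#'   "any eggs laid" (Bernoulli).
#' @param investment Named vector for the bin-level proportion of eggs
#'   laid in freshwater (binomial, logit of the freshwater share).
#' @param hatch Named vector for the cup-level proportion hatched
#'   (binomial).
#' @param tadpole Named vector `d0, ds, dL, dsL, dd, sigma` for daily
#'   tadpole survival on the ramp.
#' @param clutch_meanlog,clutch_sdlog Log-normal clutch-size parameters
#'   (rounded draws; defaults give mean ~1363 eggs).
#' @return Object of class `"garden_truth"`.
#' @export
garden_truth <- function(
    choice = c(g0 = 3, gs = -0.25, gL = -0.6, gsL = 0.22, sigma = 0.3),
    investment = c(g0 = 0.6, gs = 0.18, gL = 0, gsL = -0.09, sigma = 0.2),
    hatch = c(g0 = 2, gs = -0.9, gL = -1, gsL = 0.38, sigma = 0.3),
    tadpole = c(d0 = 6.7, ds = -0.58, dL = 0, dsL = 0.14, dd = -0.08,
                sigma = 0.25),
    clutch_meanlog = 7.1635, clutch_sdlog = 0.33) {
  stopifnot(choice["sigma"] >= 0, investment["sigma"] >= 0,
            hatch["sigma"] >= 0, tadpole["sigma"] >= 0, clutch_sdlog > 0)
  structure(list(choice = choice, investment = investment, hatch = hatch,
                 tadpole = tadpole, clutch_meanlog = clutch_meanlog,
                 clutch_sdlog = clutch_sdlog),
            class = "garden_truth")
}

garden_logit <- function(coefs, s, coastal, b = 0) {
  unname(coefs["g0"] + coefs["gs"] * s +
           (coefs["gL"] + coefs["gsL"] * s) * coastal + b)
}

#' Simulate oviposition-choice and hatch tables
#'
#' Emulates the binary-choice design: each replicate contributes one bin
#' per salt treatment in 4, 6, 8, 12 ppt per location, each bin holding
#' three freshwater and three salt cups.  Per bin, a clutch size is drawn
#' from the overdispersed (rounded log-normal) count model; the clutch is
#' split between the freshwater and salt sides by the investment model;
#' each cup independently receives eggs or not via the choice model (a
#' side's eggs are spread over its active cups, and are withheld entirely
#' when no cup on that side is chosen — the hurdle); hatches are drawn per
#' cup from the hatch model.  Deterministic given `seed`.
#'
#' @param truth A [garden_truth()].
#' @param n_replicates Replicates per location (4 bins each).
#' @param seed Integer seed.
#' @return List with data frames `oviposition` and `hatch` in the layouts
#'   of [read_garden_csv()].
#' @export
simulate_oviposition <- function(truth, n_replicates = 4, seed = 1L) {
  stopifnot(inherits(truth, "garden_truth"), n_replicates >= 1)
  old <- .Random.seed_guard(derive_seed(seed, 22L))
  on.exit(old())
  ovi <- list(); hat <- list()
  bin_no <- 0L
  for (loc in c("inland", "coastal")) {
    cst <- as.integer(loc == "coastal")
    for (rep_i in seq_len(n_replicates)) {
      for (trt in .bin_treatments) {
        bin_no <- bin_no + 1L
        bin_id <- sprintf("bin_%03d", bin_no)
        b_choice <- stats::rnorm(1, 0, truth$choice["sigma"])
        b_inv <- stats::rnorm(1, 0, truth$investment["sigma"])
        b_hatch <- stats::rnorm(1, 0, truth$hatch["sigma"])
        clutch <- max(1L, as.integer(round(
          stats::rlnorm(1, truth$clutch_meanlog, truth$clutch_sdlog))))
        p_fresh <- stats::plogis(garden_logit(truth$investment, trt, cst,
                                              b_inv))
        n_fresh <- stats::rbinom(1, clutch, p_fresh)
        n_salt <- clutch - n_fresh
        cup_ppt <- c(0, 0, 0, rep(trt, 3))
        active <- stats::rbinom(6, 1, stats::plogis(
          garden_logit(truth$choice, cup_ppt, cst, b_choice)))
        eggs <- integer(6)
        for (side in list(1:3, 4:6)) {
          n_side <- if (identical(side, 1:3)) n_fresh else n_salt
          on_cups <- side[active[side] == 1]
          if (length(on_cups) && n_side > 0) {
            eggs[on_cups] <- as.vector(stats::rmultinom(
              1, n_side, rep(1 / length(on_cups), length(on_cups))))
          }
        }
        ovi[[bin_no]] <- data.frame(
          bin = bin_id, location = loc,
          block = sprintf("%s_rep%d", loc, rep_i),
          treatment_ppt = trt, cup = sprintf("%s_cup%d", bin_id, 1:6),
          cup_ppt = cup_ppt, eggs = eggs, stringsAsFactors = FALSE)
        laid <- which(eggs > 0)
        if (length(laid)) {
          p_hatch <- stats::plogis(garden_logit(truth$hatch, cup_ppt[laid],
                                                cst, b_hatch))
          hat[[length(hat) + 1L]] <- data.frame(
            cup = sprintf("%s_cup%d", bin_id, laid), bin = bin_id,
            location = loc, cup_ppt = cup_ppt[laid], laid = eggs[laid],
            hatched = stats::rbinom(length(laid), eggs[laid], p_hatch),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(oviposition = do.call(rbind, ovi), hatch = do.call(rbind, hat))
}

#' Simulate ramped tadpole survival series
#'
#' Per location, each of `n_clutches` clutches contributes one 50-tadpole
#' group per target salinity in 0.5, 4, 6, 8, 12 ppt.  Counts follow the
#' conditional chain `alive_t ~ Binomial(alive_{t-1}, p_t)` with the daily
#' survival logit evaluated on the [ramp_schedule()] salinities — again the
#' exact process the fitting model assumes.  Deterministic given `seed`.
#'
#' @param truth A [garden_truth()].
#' @param n_clutches Clutches per location (the design used 8).
#' @param seed Integer seed.
#' @return Data frame in the tadpole layout of [read_garden_csv()].
#' @export
simulate_tadpoles <- function(truth, n_clutches = 8, seed = 1L) {
  stopifnot(inherits(truth, "garden_truth"), n_clutches >= 1)
  old <- .Random.seed_guard(derive_seed(seed, 33L))
  on.exit(old())
  tad <- truth$tadpole
  out <- list()
  for (loc in c("inland", "coastal")) {
    cst <- as.integer(loc == "coastal")
    for (cl in seq_len(n_clutches)) {
      clutch_id <- sprintf("%s_clutch%02d", loc, cl)
      b <- stats::rnorm(1, 0, tad["sigma"])
      for (tp in .ramp_targets) {
        sched <- ramp_schedule(tp)
        alive <- integer(6)
        prev <- 50L
        for (t in sched$day) {
          s <- sched$ppt[t]
          p <- stats::plogis(unname(
            tad["d0"] + tad["ds"] * s + (tad["dL"] + tad["dsL"] * s) * cst +
              tad["dd"] * t + b))
          alive[t] <- stats::rbinom(1, prev, p)
          prev <- alive[t]
        }
        out[[length(out) + 1L]] <- data.frame(
          clutch = clutch_id, location = loc, target_ppt = tp,
          day = 1:6, ppt = sched$ppt, alive = alive,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
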