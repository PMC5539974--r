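#' Configuration for a full analysis run
#'
#' Bundles inputs, stage selection, MCMC settings, prior mode, and output
#' location for [run_pipeline()].  Any input path left `NULL` is replaced
#' by a synthetic table from the generators (with the given seed), so a
#' complete run works out of the box.
#'
#' @param meta_csv Path to a survivorship meta-analysis CSV
#'   ([read_survival_csv()] layout), or `NULL` for synthetic data.
#' @param oviposition_csv,hatch_csv,tadpole_csv Paths to common-garden
#'   CSVs ([read_garden_csv()] layouts), or `NULL` for synthetic data.
#' @param stages Pipeline stages to run, a subset of
#'   `c("meta", "garden", "tadpole")`.  Garden and tadpole stages with
#'   informed priors require the meta stage (or cached meta fits).
#' @param life_stages Life stages to fit in the meta-analysis.
#' @param prior_mode `"informed"` (hatch and tadpole models receive
#'   moment-matched priors from the corresponding meta posterior) or
#'   `"flat"`.
#' @param inflation Informed-prior sd inflation factor.  The default of 10
#'   keeps the meta-analysis location while discounting its (typically
#'   very high) precision: the propagated posterior describes a different
#'   response scale (whole-exposure survival) than the garden models
#'   (e.g. daily survival), so an uninflated prior would override the
#'   trial data instead of informing them.
#' @param seed Global seed; all simulation and chain seeds derive from it.
#' @param meta_mcmc,garden_mcmc,tadpole_mcmc [mcmc_config()]s per model
#'   family (seeds are overridden from `seed`).
#' @param allow_nonconverged If `FALSE` (default), informed-prior stages
#'   refuse to run from a non-converged meta fit.
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(meta_csv = NULL, oviposition_csv = NULL,
                       hatch_csv = NULL, tadpole_csv = NULL,
                       stages = c("meta", "garden", "tadpole"),
                       life_stages = c("egg", "tadpole", "adult"),
                       prior_mode = c("informed", "flat"),
                       inflation = 10, seed = 1L,
                       meta_mcmc = mcmc_config(),
                       garden_mcmc = mcmc_config(),
                       tadpole_mcmc = mcmc_config(n_chains = 4,
                                                  n_iter = 50000,
                                                  n_burn = 25000),
                       allow_nonconverged = FALSE, out_dir = NULL) {
  stages <- match.arg(stages, c("meta", "garden", "tadpole"),
                      several.ok = TRUE)
  prior_mode <- match.arg(prior_mode)
  life_stages <- match.arg(life_stages, .life_stages, several.ok = TRUE)
  structure(list(meta_csv = meta_csv, oviposition_csv = oviposition_csv,
                 hatch_csv = hatch_csv, tadpole_csv = tadpole_csv,
                 stages = stages, life_stages = life_stages,
                 prior_mode = prior_mode, inflation = inflation,
                 seed = as.integer(seed), meta_mcmc = meta_mcmc,
                 garden_mcmc = garden_mcmc, tadpole_mcmc = tadpole_mcmc,
                 allow_nonconverged = allow_nonconverged,
                 out_dir = out_dir),
            class = "run_config")
}

# Stable short hash of the configuration, stamped into every output file
# so a table can be traced back to the settings that produced it.
config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_stamped_csv <- function(x, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Cup-level and bin-level analysis tables derived from the garden CSVs.
garden_units <- function(ovi, hatch) {
  choice <- data.frame(outcome = as.integer(ovi$eggs > 0),
                       salinity = ovi$cup_ppt, location = ovi$location,
                       group = ovi$bin, stringsAsFactors = FALSE)
  inv <- do.call(rbind, lapply(split(ovi, ovi$bin), function(b) {
    data.frame(successes = sum(b$eggs[b$cup_ppt == 0]),
               trials = sum(b$eggs), salinity = b$treatment_ppt[1],
               location = b$location[1], group = b$bin[1],
               stringsAsFactors = FALSE)
  }))
  inv <- inv[inv$trials > 0, , drop = FALSE]
  hatch_any <- data.frame(outcome = as.integer(hatch$hatched > 0),
                          salinity = hatch$cup_ppt,
                          location = hatch$location, group = hatch$bin,
                          stringsAsFactors = FALSE)
  hp <- hatch[hatch$hatched > 0, , drop = FALSE]
  hatch_prop <- data.frame(successes = hp$hatched, trials = hp$laid,
                           salinity = hp$cup_ppt, location = hp$location,
                           group = hp$bin, stringsAsFactors = FALSE)
  rownames(inv) <- NULL
  list(choice = choice, investment = inv, hatch_any = hatch_any,
       hatch_prop = hatch_prop)
}

meta_priors_for <- function(meta_fits, stage, config) {
  fit <- meta_fits[[stage]]
  if (is.null(fit)) return(list())
  if (!fit$converged && !config$allow_nonconverged) {
    stop("the ", stage, " meta-analysis fit has not converged; informed-",
         "prior stages refuse to run (set allow_nonconverged = TRUE to ",
         "override)", call. = FALSE)
  }
  list(intercept = build_informed_prior(draws_of(fit$draws, "beta0"),
                                        config$inflation),
       salinity = build_informed_prior(draws_of(fit$draws, "beta1"),
                                       config$inflation))
}

#' Run the full inference chain
#'
#' Executes the pipeline in the analysis order: per-stage meta-analysis
#' fits, LC50 and survival-curve derivation, informed-prior construction,
#' then the common-garden hurdle models and the ramped tadpole survival
#' model.  When `config$out_dir` is set, writes `lc50.csv`,
#' `survival_table.csv`, `survival_curves.csv`, per-model
#' `summary_*.csv` files, prediction curves, and `run_log.txt` (seeds,
#' chain settings, convergence flags); every file is stamped with the
#' configuration hash, so identical configurations reproduce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param meta_fits Optional named list of cached `beta_meta_fit`s (from a
#'   previous run) so garden/tadpole stages can run without refitting the
#'   meta-analysis.
#' @return List with elements `meta` (fits, lc50 table, survival table),
#'   `garden` (hurdle fits and prediction curves), `tadpole` (fit and
#'   end-of-ramp predictions), `config`, and `hash`; unrun stages are
#'   `NULL`.
#' @export
run_pipeline <- function(config = run_config(), meta_fits = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  log_lines <- c(paste0("config_hash: ", hash),
                 paste0("seed: ", config$seed),
                 paste0("prior_mode: ", config$prior_mode))
  out <- list(meta = NULL, garden = NULL, tadpole = NULL,
              config = config, hash = hash)
  odir <- config$out_dir
  if (!is.null(odir) && !dir.exists(odir)) {
    dir.create(odir, recursive = TRUE)
  }

  if ("meta" %in% config$stages) {
    records <- if (is.null(config$meta_csv)) {
      do.call(rbind, lapply(config$life_stages, function(st) {
        simulate_meta_dataset(meta_truth(st), seed = config$seed)
      }))
    } else {
      read_survival_csv(config$meta_csv, quiet = TRUE)
    }
    meta_fits <- list()
    for (st in config$life_stages) {
      cfg <- config$meta_mcmc
      cfg$seed <- derive_seed(config$seed, 100L + match(st, .life_stages))
      meta_fits[[st]] <- fit_beta_meta(records, st, cfg)
      log_lines <- c(log_lines, sprintf(
        "meta[%s]: %d chains x %d iter (burn %d), seed %d, max R-hat %.3f%s",
        st, cfg$n_chains, cfg$n_iter, cfg$n_burn, cfg$seed,
        max(meta_fits[[st]]$rhat),
        if (meta_fits[[st]]$converged) "" else " NOT CONVERGED"))
    }
    lc50s <- lapply(meta_fits, lc50)
    lc50_tab <- data.frame(
      stage = vapply(lc50s, function(x) x$stage, ""),
      point = vapply(lc50s, function(x) x$point, 0),
      lo = vapply(lc50s, function(x) x$lo, 0),
      hi = vapply(lc50s, function(x) x$hi, 0), row.names = NULL)
    surv_tab <- survival_table(meta_fits)
    curves <- do.call(rbind, lapply(meta_fits, function(f) {
      cbind(stage = f$stage, predict(f, 1:40))
    }))
    out$meta <- list(fits = meta_fits, lc50 = lc50_tab,
                     survival_table = surv_tab, curves = curves)
    if (!is.null(odir)) {
      write_stamped_csv(lc50_tab, file.path(odir, "lc50.csv"), hash)
      write_stamped_csv(as.data.frame(surv_tab),
                        file.path(odir, "survival_table.csv"), hash)
      write_stamped_csv(curves, file.path(odir, "survival_curves.csv"), hash)
      for (st in names(meta_fits)) {
        write_stamped_csv(summary(meta_fits[[st]]),
                          file.path(odir, paste0("summary_meta_", st, ".csv")),
                          hash)
      }
    }
  }

  informed <- config$prior_mode == "informed"
  if ("garden" %in% config$stages) {
    if (is.null(config$oviposition_csv) != is.null(config$hatch_csv)) {
      stop("supply both oviposition and hatch CSVs, or neither",
           call. = FALSE)
    }
    if (is.null(config$oviposition_csv)) {
      sim <- simulate_oviposition(garden_truth(), seed = config$seed)
      ovi <- sim$oviposition; hatch <- sim$hatch
    } else {
      ovi <- read_garden_csv(config$oviposition_csv, "oviposition",
                             quiet = TRUE)
      hatch <- read_garden_csv(config$hatch_csv, "hatch", quiet = TRUE)
    }
    units <- garden_units(ovi, hatch)
    hatch_priors <- if (informed) {
      meta_priors_for(meta_fits, "egg", config)
    } else list()
    fits <- list()
    specs <- list(choice = list(units$choice, list(), fit_bernoulli_stage),
                  investment = list(units$investment, list(),
                                    fit_binomial_stage),
                  hatch_any = list(units$hatch_any, hatch_priors,
                                   fit_bernoulli_stage),
                  hatch_prop = list(units$hatch_prop, hatch_priors,
                                    fit_binomial_stage))
    preds <- list()
    for (nm in names(specs)) {
      cfg <- config$garden_mcmc
      cfg$seed <- derive_seed(config$seed, 200L + match(nm, names(specs)))
      fits[[nm]] <- specs[[nm]][[3]](specs[[nm]][[1]],
                                     priors = specs[[nm]][[2]], config = cfg)
      log_lines <- c(log_lines, sprintf(
        "garden[%s]: %d chains x %d iter (burn %d), seed %d, max R-hat %.3f%s",
        nm, cfg$n_chains, cfg$n_iter, cfg$n_burn, cfg$seed,
        max(fits[[nm]]$rhat),
        if (fits[[nm]]$converged) "" else " NOT CONVERGED"))
      grid <- seq(0, 12, by = 0.5)
      preds[[nm]] <- cbind(model = nm, rbind(
        predict(fits[[nm]], grid, "inland"),
        predict(fits[[nm]], grid, "coastal")))
    }
    pred_tab <- do.call(rbind, preds)
    out$garden <- list(fits = fits, predictions = pred_tab)
    if (!is.null(odir)) {
      write_stamped_csv(pred_tab, file.path(odir, "garden_predictions.csv"),
                        hash)
      for (nm in names(fits)) {
        write_stamped_csv(summary(fits[[nm]]),
                          file.path(odir, paste0("summary_garden_", nm,
                                                 ".csv")), hash)
      }
    }
  }

  if ("tadpole" %in% config$stages) {
    series <- if (is.null(config$tadpole_csv)) {
      simulate_tadpoles(garden_truth(), seed = config$seed)
    } else {
      read_garden_csv(config$tadpole_csv, "tadpole", quiet = TRUE)
    }
    tad_priors <- if (informed) {
      meta_priors_for(meta_fits, "tadpole", config)
    } else list()
    cfg <- config$tadpole_mcmc
    cfg$seed <- derive_seed(config$seed, 300L)
    tad_fit <- fit_tadpole_survival(series, priors = tad_priors,
                                    config = cfg)
    log_lines <- c(log_lines, sprintf(
      "tadpole: %d chains x %d iter (burn %d), seed %d, max R-hat %.3f%s",
      cfg$n_chains, cfg$n_iter, cfg$n_burn, cfg$seed, max(tad_fit$rhat),
      if (tad_fit$converged) "" else " NOT CONVERGED"))
    tad_pred <- rbind(predict(tad_fit, location = "inland"),
                      predict(tad_fit, location = "coastal"))
    out$tadpole <- list(fit = tad_fit, predictions = tad_pred)
    if (!is.null(odir)) {
      write_stamped_csv(tad_pred, file.path(odir, "tadpole_predictions.csv"),
                        hash)
      write_stamped_csv(summary(tad_fit),
                        file.path(odir, "summary_tadpole.csv"), hash)
    }
  }

  if (!is.null(odir)) {
    writeLines(log_lines, file.path(odir, "run_log.txt"))
  }
  out
}
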