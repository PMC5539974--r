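#' Convert a salinity measurement to parts per thousand
#'
#' Published exposure experiments report salinity in a mix of units.  All
#' downstream models work on parts per thousand (ppt; approximately grams of
#' dissolved NaCl per litre, with natural seawater at 35 ppt), so every
#' measurement is converted on ingestion.
#'
#' Conversions: ppt and g/L are treated as identical; mg/L divides by 1000;
#' percent seawater scales by 0.35 ppt per percent (100% seawater = 35 ppt);
#' molar NaCl multiplies by the molecular weight 58.44 g/mol; specific
#' conductance uses a fixed linear factor of 0.64 g/L per mS/cm, a
#' freshwater-range approximation chosen for reproducibility over the
#' nonlinear PSS-78 curve.
#'
#' @param value Numeric vector of nonnegative measurements.
#' @param unit Single string naming the unit of `value`; one of
#'   `"ppt"`, `"g_per_L"`, `"mg_per_L"`, `"percent_seawater"`,
#'   `"mS_per_cm"`, `"mol_NaCl_per_L"`.
#' @return Numeric vector of salinities in ppt.
#' @examples
#' convert_salinity(100, "percent_seawater")  # 35 ppt
#' convert_salinity(4150, "mg_per_L")         # 4.15 ppt
#' @export
convert_salinity <- function(value, unit = "ppt") {
  if (!is.character(unit) || length(unit) != 1L || !unit %in% names(.ppt_factors)) {
    stop("unknown salinity unit ", deparse(unit), "; supported units: ",
         paste(names(.ppt_factors), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("salinity values must be finite and nonnegative", call. = FALSE)
  }
  value * .ppt_factors[[unit]]
}

# linear factors to ppt, keyed by unit label
.ppt_factors <- c(
  ppt = 1, g_per_L = 1, mg_per_L = 1 / 1000,
  percent_seawater = 0.35, mS_per_cm = 0.64, mol_NaCl_per_L = 58.44
)

.life_stages <- c("egg", "tadpole", "adult")

# Stage synonyms are case-insensitive; "larva"/"larvae"/"larval" map to
# tadpole since the literature uses the terms interchangeably.
normalize_stage <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[x %in% c("larva", "larvae", "larval", "tadpoles")] <- "tadpole"
  x[x %in% c("eggs", "embryo", "embryos", "embryonic")] <- "egg"
  x[x %in% c("adults", "frog", "juvenile/adult")] <- "adult"
  x
}

#' Read a survivorship meta-analysis table
#'
#' Ingests one row per study x salinity observation of anuran survivorship.
#' Expected columns: `study`, `stage`, `salinity`, `survival` (required) and
#' `species`, `family`, `unit`, `n`, `sd`, `hours`, `location` (optional).
#' Salinity is converted to ppt via [convert_salinity()] when a `unit`
#' column is present.  Rows violating the record invariants (survival
#' outside [0, 1], negative salinity, unknown stage, empty study label) are
#' dropped, and each rejection is reported with its row number and reason;
#' a missing required column is an error.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param quiet If `TRUE`, suppress the per-row rejection messages.
#' @return A data frame of validated records with columns `study`,
#'   `species`, `family`, `stage`, `salinity_ppt`, `n`, `survival`, `sd`,
#'   `hours`, `location`, carrying a `"rejections"` attribute
#'   (data frame of `row`, `reason`).
#' @export
read_survival_csv <- function(path, quiet = FALSE) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study", "stage", "salinity", "survival")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  opt <- function(col, default = NA) {
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  out <- data.frame(
    study = as.character(raw$study),
    species = as.character(opt("species", NA_character_)),
    family = as.character(opt("family", NA_character_)),
    stage = normalize_stage(raw$stage),
    salinity_ppt = suppressWarnings(as.numeric(raw$salinity)),
    n = suppressWarnings(as.integer(opt("n"))),
    survival = suppressWarnings(as.numeric(raw$survival)),
    sd = suppressWarnings(as.numeric(opt("sd"))),
    hours = suppressWarnings(as.numeric(opt("hours"))),
    location = as.character(opt("location", NA_character_)),
    stringsAsFactors = FALSE
  )
  if ("unit" %in% names(raw)) {
    for (i in seq_len(nrow(out))) {
      u <- trimws(raw$unit[i])
      if (!is.na(u) && nzchar(u) && is.finite(out$salinity_ppt[i]) &&
          out$salinity_ppt[i] >= 0) {
        if (!u %in% names(.ppt_factors)) {
          out$salinity_ppt[i] <- NA_real_  # flagged for rejection below
        } else {
          out$salinity_ppt[i] <- convert_salinity(out$salinity_ppt[i], u)
        }
      }
    }
  }
  reason <- rep(NA_character_, nrow(out))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  bad(is.na(out$study) | !nzchar(trimws(out$study)), "empty study label")
  bad(!out$stage %in% .life_stages, "unrecognized life stage")
  bad(!is.finite(out$salinity_ppt) | out$salinity_ppt < 0,
      "salinity missing, negative, or in an unknown unit")
  bad(!is.finite(out$survival) | out$survival < 0 | out$survival > 1,
      "survival proportion outside [0, 1]")
  bad(!is.na(out$n) & out$n < 1, "nonpositive sample size")
  bad(!is.na(out$sd) & out$sd < 0, "negative survival SD")
  bad(!is.na(out$hours) & out$hours <= 0, "nonpositive exposure hours")
  rejections <- data.frame(row = which(!is.na(reason)),
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  if (!quiet && nrow(rejections)) {
    for (i in seq_len(nrow(rejections))) {
      message("row ", rejections$row[i], " rejected: ", rejections$reason[i])
    }
  }
  out <- out[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Daily acclimation schedule for a ramped tadpole treatment
#'
#' Tadpole groups are acclimated to a target salinity over six days: the
#' 4 ppt treatment rises 0.67 ppt/day, 6 ppt rises 1 ppt/day, 8 ppt rises
#' 1.33 ppt/day, and 12 ppt rises 2 ppt/day, reaching the target on day 6
#' (within 0.02 ppt for the rounded 0.67/1.33 increments).  The freshwater
#' control (0.5 ppt) is held constant.  Day `t` salinity is `t` times the
#' daily increment, i.e. the first raise happens on day 1 after an
#' overnight acclimation in freshwater.
#'
#' @param target_ppt One of 0.5, 4, 6, 8, 12.
#' @return Data frame with columns `day` (1:6) and `ppt`.
#' @export
ramp_schedule <- function(target_ppt) {
  inc <- c(`0.5` = 0, `4` = 0.67, `6` = 1, `8` = 1.33, `12` = 2)
  key <- as.character(target_ppt)
  if (length(target_ppt) != 1L || !key %in% names(inc)) {
    stop("target salinity must be one of 0.5, 4, 6, 8, 12 ppt", call. = FALSE)
  }
  ppt <- if (inc[[key]] == 0) rep(0.5, 6) else inc[[key]] * (1:6)
  data.frame(day = 1:6, ppt = ppt)
}

.ramp_targets <- c(0.5, 4, 6, 8, 12)
.bin_treatments <- c(4, 6, 8, 12)

#' Read a common-garden trial table
#'
#' Three trial layouts are supported, matching the generator's writers:
#' \describe{
#'   \item{oviposition}{columns `bin`, `location`, `block`, `treatment_ppt`,
#'     `cup`, `cup_ppt`, `eggs`; each bin must have exactly 6 cups, 3 of
#'     them freshwater (0 ppt) and 3 at the bin's salt treatment.}
#'   \item{hatch}{columns `cup`, `bin`, `location`, `cup_ppt`, `laid`,
#'     `hatched`; requires `hatched <= laid` and `laid >= 1`.}
#'   \item{tadpole}{columns `clutch`, `location`, `target_ppt`, `day`,
#'     `ppt`, `alive`; per clutch x target series must have nonincreasing
#'     alive counts, at most 50 alive, and a salinity schedule matching
#'     [ramp_schedule()].}
#' }
#' Invalid units (bins, rows, or series) are dropped with a message; the
#' returned data frame carries a `"rejections"` attribute.
#'
#' @param path CSV path.
#' @param kind `"oviposition"`, `"hatch"`, or `"tadpole"`.
#' @param quiet Suppress rejection messages.
#' @return Validated data frame for the requested layout.
#' @export
read_garden_csv <- function(path, kind = c("oviposition", "hatch", "tadpole"),
                            quiet = FALSE) {
  kind <- match.arg(kind)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- switch(kind,
    oviposition = c("bin", "location", "block", "treatment_ppt", "cup",
                    "cup_ppt", "eggs"),
    hatch = c("cup", "bin", "location", "cup_ppt", "laid", "hatched"),
    tadpole = c("clutch", "location", "target_ppt", "day", "ppt", "alive"))
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw$location <- tolower(trimws(raw$location))
  drop <- character(0)
  keep <- rep(TRUE, nrow(raw))
  reject <- function(rows, why) {
    keep[rows] <<- FALSE
    drop <<- c(drop, paste0(why, " (rows ", paste(rows, collapse = ","), ")"))
  }
  if (any(!raw$location %in% c("coastal", "inland"))) {
    reject(which(!raw$location %in% c("coastal", "inland")),
           "location not coastal/inland")
  }
  if (kind == "oviposition") {
    bad <- which(!is.finite(raw$eggs) | raw$eggs < 0 |
                   raw$eggs != round(raw$eggs))
    if (length(bad)) reject(bad, "eggs_laid not a nonnegative integer")
    for (b in unique(raw$bin)) {
      rows <- which(raw$bin == b & keep)
      if (!length(rows)) next
      cups <- raw[rows, ]
      ok <- nrow(cups) == 6L &&
        sum(cups$cup_ppt == 0) == 3L &&
        sum(abs(cups$cup_ppt - cups$treatment_ppt[1]) < 1e-8) == 3L &&
        length(unique(cups$treatment_ppt)) == 1L &&
        cups$treatment_ppt[1] %in% .bin_treatments
      if (!ok) reject(rows, paste0("bin ", b, " is not 3 freshwater + 3 salt cups"))
    }
  } else if (kind == "hatch") {
    bad <- which(!is.finite(raw$laid) | raw$laid < 1 |
                   !is.finite(raw$hatched) | raw$hatched < 0 |
                   raw$hatched > raw$laid)
    if (length(bad)) reject(bad, "hatched exceeds laid or counts invalid")
  } else {
    raw <- raw[order(raw$clutch, raw$target_ppt, raw$day), , drop = FALSE]
    keep <- rep(TRUE, nrow(raw))
    key <- paste(raw$clutch, raw$target_ppt)
    for (k in unique(key)) {
      rows <- which(key == k)
      ser <- raw[rows, ]
      sched <- if (ser$target_ppt[1] %in% .ramp_targets) {
        ramp_schedule(ser$target_ppt[1])
      } else NULL
      ok <- !is.null(sched) &&
        identical(as.integer(ser$day), 1:6) &&
        all(ser$alive >= 0 & ser$alive <= 50) &&
        all(diff(ser$alive) <= 0) &&
        all(abs(ser$ppt - sched$ppt) < 0.02 + 1e-9)
      if (!ok) reject(rows, paste0("series ", k,
                                   " violates ramp/monotonicity invariants"))
    }
  }
  if (!quiet) for (why in drop) message("rejected: ", why)
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- drop
  out
}

#' Write a common-garden trial table
#'
#' Inverse of [read_garden_csv()]: writes the exact CSV dialect the reader
#' expects, so generated fixtures and real data files are interchangeable.
#'
#' @param x Data frame in one of the three garden layouts.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_garden_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
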