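## Synthetic linked-health-data generator.
##
## Emulates the structure of linked primary-care / hospital / death registry
## data for people intensifying from metformin monotherapy to a second-line
## oral antidiabetic drug: patients nested in prescriber groups (CCGs) nested
## in regions, with three-arm assignment driven by the group's prescribing
## preference, observed covariates and a latent confounder.

rdirichlet_ <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

## draw one category per row from a matrix of row-stochastic probabilities
sample_categorical <- function(p) {
  u <- runif(nrow(p))
  cum <- t(apply(p, 1L, cumsum))
  1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
}

END_OF_DATA_CONT <- as.Date("2021-12-31")
END_OF_DATA_TTE <- as.Date("2021-03-31")

#' Generate synthetic linked health tables with a known truth
#'
#' Simulates the five linked source tables (patients, prescriptions,
#' measurements, hospital episodes, deaths) together with a `TruthRecord`
#' holding everything the generator knows and downstream estimators do not:
#' the realised per-CCG preference triples, the latent confounder values, the
#' individual frailties and the true treatment effects.
#'
#' Assignment is a three-arm multinomial logit whose linear predictor for arm
#' a is `instrument_strength * log(preference_a)` plus observed-covariate
#' terms plus `confounding_unobserved * loading_a * U`, with U standard
#' normal. Continuous follow-up values are baseline + drift + arm effect +
#' covariate effects + U loading + Gaussian noise. Event times are
#' exponential given covariates, with a mean-1 gamma frailty of variance
#' `frailty_variance` multiplying each patient's hazards, generated by
#' inverse transform; dropout (deregistration) is exponential and
#' independent. Identical configs and seeds give identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `tables` (named list of five data frames) and
#'   `truth` (class `prefiv_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "prefiv_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  cf <- config

  ## ---- prescriber groups -------------------------------------------------
  ccg_region <- rep_len(seq_len(cf$n_regions), cf$n_ccgs)
  pref <- rdirichlet_(cf$n_ccgs, cf$tendency_concentration)
  colnames(pref) <- ARMS

  ## ---- patients ----------------------------------------------------------
  ccg <- rep_len(seq_len(cf$n_ccgs), n)
  n_days <- as.integer(cf$study_end - cf$study_start)
  index_date <- cf$study_start + sample.int(n_days + 1L, n, replace = TRUE) - 1L
  age <- pmin(pmax(round(rnorm(n, 60, 12)), 20), 90)
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.39, 0.61))
  ethnicity <- sample(c("White", "SouthAsian", "Black", "MixedOther"), n,
                      replace = TRUE, prob = c(0.785, 0.133, 0.047, 0.035))
  deprivation <- sample.int(5L, n, replace = TRUE,
                            prob = c(0.15, 0.18, 0.19, 0.23, 0.25))
  practice_size <- round(rlnorm(n, log(10000), 0.5))
  smoking <- sample(c("non", "former", "current"), n, replace = TRUE,
                    prob = c(0.22, 0.51, 0.27))
  alcohol <- sample(c("non", "former", "current"), n, replace = TRUE,
                    prob = c(0.11, 0.28, 0.61))
  U <- rnorm(n)

  ## baseline clinical values (always measured pre-index)
  hba1c0 <- pmin(pmax(rnorm(n, 75, 15), 40), 130)
  sbp0 <- rnorm(n, 132, 14)
  dbp0 <- rnorm(n, 78, 9)
  bmi0 <- pmin(pmax(rnorm(n, 32, 6), 16), 60)
  egfr0 <- pmin(pmax(rnorm(n, 91, 16), 10), 140)
  base_vals <- cbind(HbA1c = hba1c0, SBP = sbp0, DBP = dbp0,
                     BMI = bmi0, eGFR = egfr0)
  x_age <- (age - 60) / 10
  x_hba1c <- (hba1c0 - 75) / 15

  ## ---- three-arm assignment ----------------------------------------------
  pref_i <- pref[ccg, , drop = FALSE]
  if (cf$sglt2_year_trend != 0) {
    yr <- as.numeric(index_date - cf$study_start) / 365.25
    pref_i[, "SGLT2"] <- pmax(pref_i[, "SGLT2"] + cf$sglt2_year_trend * yr, 1e-6)
    pref_i <- pref_i / rowSums(pref_i)
  }
  ## observed-covariate pattern: older -> DPP4, younger/heavier -> SGLT2,
  ## higher baseline HbA1c -> SU (the sulfonylurea-for-poor-control pattern)
  obs_pat <- rbind(age = c(DPP4 = 0.5, SGLT2 = -1.0),
                   hba1c = c(DPP4 = -0.5, SGLT2 = 0.5))
  co <- cf$confounding_observed
  g <- cf$confounding_unobserved
  eta <- cf$instrument_strength * log(pref_i)
  for (a in c("DPP4", "SGLT2")) {
    eta[, a] <- eta[, a] + cf$arm_offsets[[a]] +
      co["age"] * obs_pat["age", a] * x_age +
      co["hba1c"] * obs_pat["hba1c", a] * x_hba1c +
      g * U_TREAT_LOADING[a] * U
  }
  expeta <- exp(eta - apply(eta, 1L, max))
  p_arm <- expeta / rowSums(expeta)
  arm <- ARMS[sample_categorical(p_arm)]

  ## ---- prescriptions -----------------------------------------------------
  met_start <- index_date - round(runif(n, 183, 8 * 365))
  met_before <- index_date - sample.int(60L, n, replace = TRUE)
  met_after <- index_date + sample.int(61L, n, replace = TRUE) - 1L
  regist_date <- met_start - sample.int(3650L, n, replace = TRUE)
  linked <- rep(TRUE, n)
  last_pregnancy_date <- as.Date(rep(NA_integer_, n),
                                 origin = "1970-01-01")
  drop_met_after <- rep(FALSE, n)

  ## inject eligibility violations for a configured fraction of patients
  if (cf$ineligible_fraction > 0) {
    k <- ceiling(cf$ineligible_fraction * n)
    bad <- sample.int(n, k)
    kind <- sample(c("pregnancy", "met_before", "met_after",
                     "low_egfr", "linkage"), k, replace = TRUE)
    i <- bad[kind == "pregnancy"]
    sex[i] <- "F"
    last_pregnancy_date[i] <- index_date[i] - sample(30:300, length(i), replace = TRUE)
    i <- bad[kind == "met_before"]
    met_before[i] <- index_date[i] - sample(61:180, length(i), replace = TRUE)
    drop_met_after[bad[kind == "met_after"]] <- TRUE
    i <- bad[kind == "low_egfr"]
    egfr0[i] <- runif(length(i), 12, 29)
    base_vals[i, "eGFR"] <- egfr0[i]
    linked[bad[kind == "linkage"]] <- FALSE
  }

  prescriptions <- data.frame(
    patient_id = rep(seq_len(n), 4L),
    drug_class = rep(c("metformin", "metformin", "metformin", NA), each = n),
    date = c(met_start, met_before, met_after, index_date),
    duration_days = 28L,
    stringsAsFactors = FALSE
  )
  prescriptions$drug_class[3L * n + seq_len(n)] <- arm
  keep <- rep(TRUE, 4L * n)
  keep[2L * n + which(drop_met_after)] <- FALSE
  prescriptions <- prescriptions[keep, , drop = FALSE]

  ## ---- event times (proportional hazards, gamma frailty) ------------------
  frailty <- if (cf$frailty_variance > 0)
    rgamma(n, shape = 1 / cf$frailty_variance, scale = cf$frailty_variance)
  else rep(1, n)
  lhr <- cf$true_log_hazard_ratios
  arm_col <- match(arm, c("DPP4", "SGLT2"))   # NA for SU
  event_t <- matrix(NA_real_, n, length(HAZARD_ENDPOINTS),
                    dimnames = list(NULL, HAZARD_ENDPOINTS))
  for (e in HAZARD_ENDPOINTS) {
    arm_lhr <- ifelse(is.na(arm_col), 0, lhr[e, ][arm_col])
    lp <- arm_lhr + cf$covariate_log_hazard[["age"]] * x_age +
      g * U_TTE_LOADING * U
    rate_day <- cf$baseline_event_rate[[e]] / 365.25
    event_t[, e] <- if (rate_day > 0)
      rexp(n) / (rate_day * frailty * exp(lp)) else Inf
  }
  death_t <- pmin(event_t[, "death_cvd"], event_t[, "death_other"])
  death_cause <- ifelse(event_t[, "death_cvd"] <= event_t[, "death_other"],
                        "CVD", "other")
  dropout_t <- if (cf$censoring_rate > 0)
    rexp(n) / (cf$censoring_rate / 365.25) else rep(Inf, n)

  death_date <- index_date + ceiling(death_t)
  has_death <- is.finite(death_t) & death_date <= END_OF_DATA_CONT
  deaths <- data.frame(patient_id = which(has_death),
                       date = death_date[has_death],
                       cause = death_cause[has_death],
                       stringsAsFactors = FALSE)

  dereg_date <- index_date + ceiling(dropout_t)
  has_dereg <- is.finite(dropout_t) & dereg_date <= END_OF_DATA_CONT &
    (!is.finite(death_t) | dropout_t < death_t)
  dereg_out <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  dereg_out[has_dereg] <- dereg_date[has_dereg]

  ep_rows <- lapply(c("hf", "mi", "stroke"), function(e) {
    t_e <- event_t[, e]
    ok <- is.finite(t_e) & t_e < death_t &
      index_date + ceiling(t_e) <= END_OF_DATA_CONT
    data.frame(patient_id = which(ok),
               admission_date = index_date[ok] + ceiling(t_e[ok]),
               diagnosis = rep(if (e == "hf") "heart_failure" else
                 if (e == "mi") "MI" else "stroke", sum(ok)),
               stringsAsFactors = FALSE)
  })
  hospital_episodes <- do.call(rbind, ep_rows)
  hospital_episodes <- hospital_episodes[order(hospital_episodes$patient_id,
                                               hospital_episodes$admission_date), ]
  rownames(hospital_episodes) <- NULL

  ## ---- measurements ------------------------------------------------------
  base_lag <- cbind(
    HbA1c = sample(7:170, n, replace = TRUE),
    SBP = sample(7:500, n, replace = TRUE),
    DBP = integer(n),   # measured with SBP
    BMI = pmin(round(rexp(n, 1 / 60)), 2000),
    eGFR = sample(7:500, n, replace = TRUE)
  )
  base_lag[, "DBP"] <- base_lag[, "SBP"]
  meas <- vector("list", 3L * length(CONT_MEASURES))
  k <- 0L
  tau <- cf$true_mean_differences
  progressor <- runif(n) < PROG_PROB[arm]
  fup_end <- pmin(death_t, dropout_t,
                  as.numeric(END_OF_DATA_CONT - index_date))
  for (m in CONT_MEASURES) {
    k <- k + 1L
    meas[[k]] <- data.frame(patient_id = seq_len(n), test = m,
                            date = index_date - base_lag[, m],
                            value = round(base_vals[, m], 1),
                            stringsAsFactors = FALSE)
    for (tp in c("y1", "y2")) {
      t_days <- if (tp == "y1") 365L else 730L
      arm_eff <- ifelse(is.na(arm_col), 0, tau[m, ][arm_col])
      change <- CONT_DRIFT[m, tp] +
        CONT_RTM[m] * (base_vals[, m] - mean(base_vals[, m])) +
        CONT_AGE[m] * x_age +
        arm_eff +
        g * U_CONT_LOADING[m] * U +
        rnorm(n, 0, CONT_NOISE_SD[m])
      val <- base_vals[, m] + change
      if (m == "eGFR") {
        ## CKD progressors follow a steep decline trajectory instead
        val[progressor] <- base_vals[progressor, m] *
          (1 - PROG_DECLINE[[tp]]) +
          rnorm(sum(progressor), 0, PROG_NOISE_SD)
        val <- pmax(val, 3)
      }
      if (m == "BMI") val <- pmax(val, 12)
      ok <- fup_end >= t_days
      k <- k + 1L
      meas[[k]] <- data.frame(patient_id = which(ok), test = m,
                              date = index_date[ok] + t_days,
                              value = round(val[ok], 1),
                              stringsAsFactors = FALSE)
    }
  }
  measurements <- do.call(rbind, meas)
  measurements <- measurements[order(measurements$patient_id,
                                     measurements$test, measurements$date), ]
  rownames(measurements) <- NULL

  patients <- data.frame(
    patient_id = seq_len(n),
    ccg = ccg,
    region = ccg_region[ccg],
    practice_size = practice_size,
    birth_year = as.integer(format(index_date, "%Y")) - age,
    sex = sex,
    ethnicity = ethnicity,
    deprivation = deprivation,
    smoking = smoking,
    alcohol = alcohol,
    regist_date = regist_date,
    dereg_date = dereg_out,
    linked = linked,
    last_pregnancy_date = last_pregnancy_date,
    stringsAsFactors = FALSE
  )

  tables <- list(patients = patients,
                 prescriptions = prescriptions,
                 measurements = measurements,
                 hospital_episodes = hospital_episodes,
                 deaths = deaths)

  truth <- structure(list(
    preferences = pref,
    ccg_region = ccg_region,
    patient = data.frame(patient_id = seq_len(n), ccg = ccg, arm = arm,
                         index_date = index_date, U = U, frailty = frailty,
                         stringsAsFactors = FALSE),
    true_mean_differences = cf$true_mean_differences,
    true_log_hazard_ratios = cf$true_log_hazard_ratios,
    config = cf
  ), class = "prefiv_truth")

  list(tables = tables, truth = truth)
}

#' True effect of one contrast from a truth record
#'
#' Contrasts not stored directly (e.g. SGLT2 vs DPP4) are derived by
#' differencing on the linear-predictor scale, so stored and derived
#' contrasts are always transitive.
#'
#' @param truth a `prefiv_truth`.
#' @param outcome a continuous measure (`"HbA1c"`, ...) or hazard endpoint
#'   (`"hf"`, ...).
#' @param contrast e.g. `"SGLT2 vs SU"`.
#' @return the true mean difference or log hazard ratio.
#' @export
true_effect <- function(truth, outcome, contrast) {
  stopifnot(inherits(truth, "prefiv_truth"))
  parts <- strsplit(contrast, " vs ", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 2L, all(parts %in% ARMS))
  tab <- if (outcome %in% CONT_MEASURES) truth$true_mean_differences
         else truth$true_log_hazard_ratios
  eff <- function(a) if (a == "SU") 0 else tab[outcome, a]
  eff(parts[1]) - eff(parts[2])
}

#' Delete follow-up measurements under a configured missingness mechanism
#'
#' Removes rows of the measurements table at the one- and two-year follow-up
#' timepoints at the configured per-measure per-timepoint rates. Under
#' `"MCAR"` deletion is uniform; under `"MAR"` the deletion log-odds depend
#' linearly on the patient's (always observed) baseline value of the same
#' measure, with the intercept calibrated so the marginal deletion rate
#' equals the configured rate. Treatment assignment, dates, hospital
#' episodes and deaths are never touched: the time-to-event record is
#' treated as fully observed.
#'
#' @param tables raw table list from [generate_cohort()].
#' @param config the [sim_config()] whose `missingness` element applies.
#' @param seed RNG seed for the deletion draws (default derived from the
#'   config seed).
#' @return a new table list with thinned measurements.
#' @export
impose_missingness <- function(tables, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "prefiv_sim_config"))
  spec <- config$missingness
  if (all(spec$rates == 0)) return(tables)
  set.seed(seed)

  meas <- data.table::as.data.table(tables$measurements)
  rx <- data.table::as.data.table(tables$prescriptions)
  idx <- rx[drug_class %in% ARMS, .(index_date = min(date)), by = patient_id]
  meas <- idx[meas, on = "patient_id"]
  dt <- as.numeric(meas$date - meas$index_date)
  timepoint <- rep(NA_character_, nrow(meas))
  timepoint[!is.na(dt) & dt > 0 & abs(dt - 365) <= 182] <- "y1"
  timepoint[!is.na(dt) & dt > 0 & dt - 365 > 182] <- "y2"

  ## baseline value of the same measure (most recent pre-index), for MAR
  base <- meas[dt <= 0 | is.na(dt),
               .SD[which.max(as.numeric(date))],
               by = .(patient_id, test)][, .(patient_id, test, base = value)]
  meas <- base[meas, on = c("patient_id", "test")]

  drop <- rep(FALSE, nrow(meas))
  for (m in CONT_MEASURES) {
    for (tp in c("y1", "y2")) {
      rate <- spec$rates[m, tp]
      if (rate <= 0) next
      sel <- which(meas$test == m & !is.na(timepoint) & timepoint == tp)
      if (!length(sel)) next
      if (spec$mechanism == "MCAR") {
        p <- rep(rate, length(sel))
      } else {
        b <- meas$base[sel]
        z <- (b - mean(b, na.rm = TRUE)) / max(sd(b, na.rm = TRUE), 1e-8)
        z[is.na(z)] <- 0
        ## calibrate the intercept so the marginal rate matches `rate`
        a <- stats::uniroot(function(a) mean(stats::plogis(a + spec$mar_slope * z)) - rate,
                            interval = c(-20, 20))$root
        p <- stats::plogis(a + spec$mar_slope * z)
      }
      drop[sel] <- runif(length(sel)) < p
    }
  }
  out <- tables
  kept <- as.data.frame(meas[!drop, .(patient_id, test, date, value)])
  kept <- kept[order(kept$patient_id, kept$test, kept$date), ]
  rownames(kept) <- NULL
  out$measurements <- kept
  out
}

#' Write / read the five raw tables as delimited text
#'
#' One tab-separated file per table with a header row and ISO-8601 dates.
#'
#' @param tables raw table list.
#' @param dir directory to write to (created if needed).
#' @return `write_raw_tables` returns `dir` invisibly; `read_raw_tables`
#'   returns the table list.
#' @export
write_raw_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(tables)) {
    write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_raw_tables
#' @export
read_raw_tables <- function(dir) {
  date_cols <- list(
    patients = c("regist_date", "dereg_date", "last_pregnancy_date"),
    prescriptions = "date", measurements = "date",
    hospital_episodes = "admission_date", deaths = "date"
  )
  out <- lapply(names(date_cols), function(nm) {
    df <- read.delim(file.path(dir, paste0(nm, ".tsv")),
                     stringsAsFactors = FALSE)
    for (dc in date_cols[[nm]])
      if (dc %in% names(df)) df[[dc]] <- as.Date(df[[dc]])
    df
  })
  names(out) <- names(date_cols)
  out
}
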