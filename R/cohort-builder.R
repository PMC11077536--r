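## Cohort construction: eligibility rules, baseline and outcome
## ascertainment under the trial-emulation measurement windows.

#' Eligibility and measurement-window rules
#'
#' Encodes the target-trial protocol: time zero is the first-ever
#' prescription of one of the three second-line classes inside the index
#' window; eligibility requires adulthood, continuous metformin use around
#' time zero, no recent pregnancy, no severe renal impairment on the last
#' recorded eGFR, and hospital-data linkage. Baseline lookback windows are
#' 180 days for HbA1c, 540 days for blood pressure and eGFR, and any time
#' before (or on) time zero for BMI; follow-up continuous outcomes accept
#' the measurement closest to the nominal timepoint within +/-90 days.
#'
#' @param min_age minimum age in years at time zero.
#' @param metformin_lookback days before time zero within which a metformin
#'   prescription is required.
#' @param metformin_continuation days after time zero within which metformin
#'   must be re-prescribed (the index day itself qualifies).
#' @param pregnancy_lookback exclusion window in days for a pregnancy record.
#' @param egfr_exclusion_threshold exclude if the last recorded eGFR before
#'   time zero is below this (patients with no eGFR on record are retained).
#' @param index_start,index_end the index-date window (Date).
#' @param hba1c_baseline_window,bp_egfr_baseline_window baseline lookback
#'   windows in days.
#' @param outcome_tolerance half-width in days of the follow-up measurement
#'   window around each nominal timepoint.
#' @param followup_years follow-up cap for time-to-event endpoints: 2 (base
#'   case) or 5.
#' @return list with class `prefiv_rules`.
#' @export
eligibility_rules <- function(min_age = 18,
                              metformin_lookback = 60,
                              metformin_continuation = 60,
                              pregnancy_lookback = 365,
                              egfr_exclusion_threshold = 30,
                              index_start = as.Date("2015-01-01"),
                              index_end = as.Date("2020-12-31"),
                              hba1c_baseline_window = 180,
                              bp_egfr_baseline_window = 540,
                              outcome_tolerance = 90,
                              followup_years = 2) {
  stopifnot(min_age > 0, metformin_lookback > 0, metformin_continuation > 0,
            pregnancy_lookback > 0, hba1c_baseline_window > 0,
            bp_egfr_baseline_window > 0, outcome_tolerance > 0,
            followup_years %in% c(2, 5))
  structure(as.list(environment()), class = "prefiv_rules")
}

## column-name prefix for each clinical measure
measure_prefix <- function(m) c(HbA1c = "hba1c", SBP = "sbp", DBP = "dbp",
                                BMI = "bmi", eGFR = "egfr")[[m]]

#' Apply the eligibility rules and define time zero
#'
#' Candidates are patients whose first-ever prescription of any of the three
#' second-line classes falls inside the index window; that date is time zero
#' and the class prescribed is the assigned arm (intention to treat). The
#' exclusion rules are then applied in protocol order, each removal counted
#' once against the first rule the patient fails:
#'
#' 1. `single_class_at_index`: more than one second-line class prescribed on
#'    the index date (assignment ambiguous);
#' 2. `age_under_min`: under `min_age` at time zero;
#' 3. `no_metformin_before`: no metformin prescription within
#'    `metformin_lookback` days before time zero;
#' 4. `no_metformin_after`: no metformin on the index day or within
#'    `metformin_continuation` days after;
#' 5. `recent_pregnancy`: pregnancy recorded within `pregnancy_lookback`
#'    days before time zero;
#' 6. `low_egfr`: last recorded eGFR before time zero below the threshold
#'    (no record on file does not exclude);
#' 7. `not_linked`: hospital-data linkage flag not set.
#'
#' @param tables raw table list (see [generate_cohort()]).
#' @param rules an [eligibility_rules()] object.
#' @return list with `cohort` (one row per eligible patient: ids, index
#'   date, arm, demographics) and `attrition` (data frame of per-rule
#'   removal counts, with candidate and survivor totals as attributes).
#' @export
apply_eligibility <- function(tables, rules) {
  stopifnot(inherits(rules, "prefiv_rules"))
  if (!nrow(tables$patients)) stop("empty patients table")
  rx <- data.table::as.data.table(tables$prescriptions)
  pat <- data.table::as.data.table(tables$patients)

  second <- rx[drug_class %in% ARMS]
  if (!nrow(second)) stop("no second-line prescriptions in input")
  idx <- second[, .(index_date = min(date)), by = patient_id]
  idx <- second[idx, on = c("patient_id", "date" = "index_date")]
  idx <- idx[, .(index_date = date[1L],
                 n_classes = data.table::uniqueN(drug_class),
                 arm = drug_class[1L]), by = patient_id]
  idx <- idx[index_date >= rules$index_start & index_date <= rules$index_end]

  d <- merge(idx, pat, by = "patient_id")
  data.table::setkey(d, patient_id)
  n_candidates <- nrow(d)

  d[, age := as.integer(format(index_date, "%Y")) - birth_year]

  met <- rx[drug_class == "metformin", .(patient_id, met_date = date)]
  d[, met_before := FALSE]
  d[, met_after := FALSE]
  if (nrow(met)) {
    mb <- merge(met, d[, .(patient_id, index_date)], by = "patient_id")
    gap <- as.numeric(mb$index_date - mb$met_date)
    before_ok <- unique(mb$patient_id[gap >= 1 & gap <= rules$metformin_lookback])
    after_ok <- unique(mb$patient_id[gap <= 0 & -gap <= rules$metformin_continuation])
    d[patient_id %in% before_ok, met_before := TRUE]
    d[patient_id %in% after_ok, met_after := TRUE]
  }

  meas <- data.table::as.data.table(tables$measurements)
  eg <- meas[test == "eGFR"]
  d[, last_egfr := NA_real_]
  if (nrow(eg)) {
    eg <- merge(eg, d[, .(patient_id, index_date)], by = "patient_id")
    eg <- eg[date <= index_date]
    if (nrow(eg)) {
      last <- eg[order(date), .(last_egfr = value[.N]), by = patient_id]
      d[last, last_egfr := i.last_egfr, on = "patient_id"]
    }
  }

  preg_gap <- as.numeric(d$index_date - d$last_pregnancy_date)
  fails <- list(
    single_class_at_index = d$n_classes > 1L,
    age_under_min = d$age < rules$min_age,
    no_metformin_before = !d$met_before,
    no_metformin_after = !d$met_after,
    recent_pregnancy = !is.na(preg_gap) & preg_gap >= 0 &
      preg_gap <= rules$pregnancy_lookback,
    low_egfr = !is.na(d$last_egfr) & d$last_egfr < rules$egfr_exclusion_threshold,
    not_linked = !d$linked
  )
  removed_by <- rep(NA_character_, nrow(d))
  for (rule in names(fails)) {
    hit <- is.na(removed_by) & fails[[rule]]
    removed_by[hit] <- rule
  }
  attrition <- data.frame(rule = names(fails),
                          n_removed = vapply(names(fails), function(r)
                            sum(removed_by == r, na.rm = TRUE), integer(1)),
                          row.names = NULL, stringsAsFactors = FALSE)

  keep <- d[is.na(removed_by)]
  met_first <- if (nrow(met)) met[, .(met_start = min(met_date)), by = patient_id]
               else data.table::data.table(patient_id = integer(), met_start = as.Date(integer()))
  keep <- merge(keep, met_first, by = "patient_id", all.x = TRUE)
  cohort <- data.frame(
    patient_id = keep$patient_id,
    ccg = keep$ccg,
    region = factor(keep$region),
    index_date = keep$index_date,
    arm = factor(keep$arm, levels = ARMS),
    age = keep$age,
    sex = factor(keep$sex),
    ethnicity = factor(keep$ethnicity),
    deprivation = factor(keep$deprivation),
    smoking = factor(keep$smoking),
    alcohol = factor(keep$alcohol),
    year_index = factor(format(keep$index_date, "%Y")),
    years_metformin = as.numeric(keep$index_date - keep$met_start) / 365.25,
    practice_size = keep$practice_size,
    practice_size_log = log(keep$practice_size),
    regist_date = keep$regist_date,
    dereg_date = keep$dereg_date,
    stringsAsFactors = FALSE
  )
  attr(attrition, "n_candidates") <- n_candidates
  attr(attrition, "n_eligible") <- nrow(cohort)
  list(cohort = cohort, attrition = attrition)
}

## most recent value of `measure` in [index - window, index] per patient
latest_in_window <- function(cohort, meas, measure, window) {
  m <- meas[test == measure]
  m <- merge(m, data.table::as.data.table(cohort[, c("patient_id", "index_date")]),
             by = "patient_id")
  gap <- as.numeric(m$index_date - m$date)
  m <- m[gap >= 0 & (is.infinite(window) | gap <= window)]
  if (!nrow(m)) return(data.frame(patient_id = integer(), value = numeric()))
  out <- m[order(date), .(value = value[.N]), by = patient_id]
  as.data.frame(out)
}

#' Ascertain baseline covariate measurements
#'
#' Per measure, the most recent pre-index value inside its lookback window
#' (HbA1c 180 days; blood pressure and eGFR 540 days; BMI the latest value
#' at any time up to the index day). Same-day measurements count as
#' baseline; older values are treated as out-dated and left absent.
#'
#' @param cohort eligibility output.
#' @param measurements measurements table.
#' @param rules an [eligibility_rules()].
#' @return cohort with columns `hba1c_base`, `sbp_base`, `dbp_base`,
#'   `bmi_base`, `egfr_base` (NA where no in-window value exists).
#' @export
ascertain_baseline <- function(cohort, measurements, rules) {
  meas <- data.table::as.data.table(measurements)
  windows <- c(HbA1c = rules$hba1c_baseline_window,
               SBP = rules$bp_egfr_baseline_window,
               DBP = rules$bp_egfr_baseline_window,
               BMI = Inf,
               eGFR = rules$bp_egfr_baseline_window)
  for (m in CONT_MEASURES) {
    v <- latest_in_window(cohort, meas, m, windows[[m]])
    col <- paste0(measure_prefix(m), "_base")
    cohort[[col]] <- v$value[match(cohort$patient_id, v$patient_id)]
  }
  cohort
}

#' Ascertain follow-up continuous outcomes at one and two years
#'
#' Per measure and nominal timepoint t (365 and 730 days), takes the
#' post-index measurement minimising |date - (index + t)| within the +/-90
#' day tolerance, with ties broken toward the earlier measurement; otherwise
#' the value is missing. Patients whose continuous follow-up (earliest of
#' deregistration, death, end of data) ends before t are flagged
#' censored-by-t and their value is missing.
#'
#' @inheritParams ascertain_baseline
#' @param deaths deaths table (for censoring continuous follow-up).
#' @return cohort with `<measure>_y1`, `<measure>_y2` columns and
#'   `censored_by_y1`, `censored_by_y2` flags.
#' @export
ascertain_continuous_outcomes <- function(cohort, measurements, rules,
                                          deaths = NULL) {
  meas <- data.table::as.data.table(measurements)
  idx <- data.table::as.data.table(cohort[, c("patient_id", "index_date")])

  death_date <- rep(as.Date(NA), nrow(cohort))
  if (!is.null(deaths) && nrow(deaths)) {
    dd <- deaths[match(cohort$patient_id, deaths$patient_id), "date"]
    death_date <- as.Date(dd, origin = "1970-01-01")
  }
  fup_end <- pmin(
    ifelse(is.na(cohort$dereg_date), Inf, as.numeric(cohort$dereg_date - cohort$index_date)),
    ifelse(is.na(death_date), Inf, as.numeric(death_date - cohort$index_date)),
    as.numeric(END_OF_DATA_CONT - cohort$index_date)
  )

  for (tp in c("y1", "y2")) {
    t_days <- if (tp == "y1") 365 else 730
    cohort[[paste0("censored_by_", tp)]] <- fup_end < t_days
    for (m in CONT_MEASURES) {
      mm <- merge(meas[test == m], idx, by = "patient_id")
      off <- as.numeric(mm$date - mm$index_date) - t_days
      mm <- mm[abs(off) <= rules$outcome_tolerance & off + t_days > 0]
      col <- paste0(measure_prefix(m), "_", tp)
      if (!nrow(mm)) { cohort[[col]] <- NA_real_; next }
      ## nearest to the target; tie -> earlier measurement
      mm[, dist := abs(as.numeric(date - index_date) - t_days)]
      pick <- mm[order(dist, date), .(value = value[1L]), by = patient_id]
      val <- pick$value[match(cohort$patient_id, pick$patient_id)]
      val[fup_end < t_days] <- NA_real_
      cohort[[col]] <- val
    }
  }
  cohort
}

#' Ascertain time-to-event endpoints
#'
#' Builds, per endpoint, the first qualifying event time in days from the
#' index date, censored at the earliest of deregistration, end of
#' time-to-event data, death (for endpoints in which death is not a
#' component) and the follow-up cap. Endpoints:
#'
#' * `egfr40`: first post-index eGFR at or below 60\% of the baseline eGFR
#'   (undefined, and flagged, for patients with no baseline eGFR);
#' * `make`: major adverse kidney event, earliest of the 40\% eGFR decline
#'   or all-cause death;
#' * `hf`: first hospital admission for heart failure;
#' * `mace`: earliest of myocardial infarction, stroke, or CVD death
#'   (non-CVD death censors);
#' * `mi`, `stroke`: the individual components;
#' * `mortality`: all-cause death.
#'
#' Patients with a death recorded on or before their index date are a data
#' fault: they are removed and counted in the `faults` attribute.
#'
#' @inheritParams ascertain_baseline
#' @param hospital_episodes,deaths raw event tables.
#' @param measurements measurements table (for the eGFR-decline endpoint).
#' @return cohort with `<endpoint>_time` / `<endpoint>_event` columns, a
#'   `death_date` column and a `strata_status` factor
#'   (complete/censored/died before the follow-up cap), with attributes
#'   `faults` and `n_no_baseline_egfr`.
#' @export
ascertain_events <- function(cohort, hospital_episodes, deaths, measurements,
                             rules) {
  cap_days <- round(rules$followup_years * 365.25)
  n <- nrow(cohort)
  idx_num <- as.numeric(cohort$index_date)

  death_date <- rep(NA_real_, n)
  death_cause <- rep(NA_character_, n)
  if (!is.null(deaths) && nrow(deaths)) {
    j <- match(cohort$patient_id, deaths$patient_id)
    death_date <- as.numeric(as.Date(deaths$date[j], origin = "1970-01-01"))
    death_cause <- deaths$cause[j]
  }
  fault <- !is.na(death_date) & death_date <= idx_num
  n_fault <- sum(fault)
  if (n_fault) {
    cohort <- cohort[!fault, , drop = FALSE]
    death_date <- death_date[!fault]
    death_cause <- death_cause[!fault]
    idx_num <- idx_num[!fault]
    n <- nrow(cohort)
  }

  dereg_t <- ifelse(is.na(cohort$dereg_date), Inf,
                    as.numeric(cohort$dereg_date) - idx_num)
  data_end_t <- as.numeric(END_OF_DATA_TTE) - idx_num
  admin_end <- pmin(dereg_t, data_end_t, cap_days)
  death_t <- ifelse(is.na(death_date), Inf, death_date - idx_num)

  first_event_time <- function(tab, date_col, diag, diag_col) {
    out <- rep(Inf, n)
    if (is.null(tab) || !nrow(tab)) return(out)
    keep <- tab[tab[[diag_col]] %in% diag, , drop = FALSE]
    if (!nrow(keep)) return(out)
    j <- match(keep$patient_id, cohort$patient_id)
    ok <- !is.na(j)
    t_ev <- as.numeric(as.Date(keep[[date_col]][ok], origin = "1970-01-01")) -
      idx_num[j[ok]]
    t_ev[t_ev <= 0] <- Inf        # pre-index admissions are history, not outcomes
    tapply_min <- tapply(t_ev, j[ok], min)
    out[as.integer(names(tapply_min))] <- pmin(out[as.integer(names(tapply_min))],
                                               tapply_min)
    out
  }

  hf_t <- first_event_time(hospital_episodes, "admission_date", "heart_failure", "diagnosis")
  mi_t <- first_event_time(hospital_episodes, "admission_date", "MI", "diagnosis")
  stroke_t <- first_event_time(hospital_episodes, "admission_date", "stroke", "diagnosis")
  death_cvd_t <- ifelse(!is.na(death_cause) & death_cause == "CVD", death_t, Inf)

  ## 40% eGFR decline from the measurement trajectory
  egfr40_t <- rep(Inf, n)
  has_base <- !is.na(cohort$egfr_base)
  meas <- data.table::as.data.table(measurements)
  eg <- meas[test == "eGFR"]
  if (nrow(eg)) {
    eg <- merge(eg,
                data.table::data.table(patient_id = cohort$patient_id,
                                       index_num = idx_num,
                                       egfr_base = cohort$egfr_base),
                by = "patient_id")
    eg <- eg[!is.na(egfr_base)]
    eg[, t_ev := as.numeric(date) - index_num]
    eg <- eg[t_ev > 0 & value <= 0.6 * egfr_base]
    if (nrow(eg)) {
      first <- eg[, .(t_ev = min(t_ev)), by = patient_id]
      j <- match(first$patient_id, cohort$patient_id)
      egfr40_t[j] <- first$t_ev
    }
  }

  score <- function(event_t, censor_at) {
    tt <- pmin(event_t, censor_at)
    ev <- as.integer(event_t <= censor_at & is.finite(event_t))
    tt[tt < 0] <- 0
    list(time = tt, event = ev)
  }

  nonfatal_censor <- pmin(admin_end, death_t)
  eps <- list(
    hf = score(hf_t, nonfatal_censor),
    mi = score(mi_t, nonfatal_censor),
    stroke = score(stroke_t, nonfatal_censor),
    egfr40 = score(egfr40_t, nonfatal_censor),
    make = score(pmin(egfr40_t, death_t), admin_end),
    mace = score(pmin(mi_t, stroke_t, death_cvd_t),
                 pmin(admin_end,
                      ifelse(!is.na(death_cause) & death_cause != "CVD",
                             death_t, Inf))),
    mortality = score(death_t, admin_end)
  )
  for (e in names(eps)) {
    cohort[[paste0(e, "_time")]] <- eps[[e]]$time
    cohort[[paste0(e, "_event")]] <- eps[[e]]$event
  }
  ## eGFR-decline endpoints undefined without a baseline eGFR
  cohort$egfr40_time[!has_base] <- NA_real_
  cohort$egfr40_event[!has_base] <- NA_integer_
  cohort$make_time[!has_base] <- NA_real_
  cohort$make_event[!has_base] <- NA_integer_

  cohort$death_date <- as.Date(death_date, origin = "1970-01-01")
  died <- is.finite(death_t) & death_t <= admin_end
  censored <- !died & admin_end < cap_days
  cohort$strata_status <- factor(ifelse(died, "died",
                                 ifelse(censored, "censored", "complete")),
                                 levels = c("complete", "censored", "died"))
  attr(cohort, "faults") <- n_fault
  attr(cohort, "n_no_baseline_egfr") <- sum(!has_base)
  cohort
}

#' Build the analysis cohort from raw tables
#'
#' Runs eligibility, baseline ascertainment, follow-up continuous outcome
#' ascertainment and event ascertainment in sequence.
#'
#' @param tables raw table list.
#' @param rules an [eligibility_rules()].
#' @return list with `cohort` and `attrition`.
#' @export
build_cohort <- function(tables, rules = eligibility_rules()) {
  el <- apply_eligibility(tables, rules)
  ch <- ascertain_baseline(el$cohort, tables$measurements, rules)
  ch <- ascertain_continuous_outcomes(ch, tables$measurements, rules,
                                      deaths = tables$deaths)
  ch <- ascertain_events(ch, tables$hospital_episodes, tables$deaths,
                         tables$measurements, rules)
  list(cohort = ch, attrition = el$attrition)
}
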