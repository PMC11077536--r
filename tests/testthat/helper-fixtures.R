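# shared fixtures and scaled-down study configurations

no_missing <- function() missingness_spec(rates = default_missing_rates() * 0)

no_events <- c(hf = 0, mi = 0, stroke = 0, death_cvd = 0, death_other = 0)

# the parameter-recovery study conditions: strong instrument, unmeasured
# confounding on treatment and outcomes, no missingness, and no deaths so
# the 1-year outcome sample is not selected on survival
recovery_config <- function(seed, n = 20000) {
  sim_config(n_patients = n, n_ccgs = 100,
             missingness = no_missing(),
             baseline_event_rate = no_events,
             censoring_rate = 0.05, seed = seed)
}

small_config <- function(seed = 1, n = 1500, n_ccgs = 15, ...) {
  sim_config(n_patients = n, n_ccgs = n_ccgs, seed = seed, ...)
}

# ---- hand-written eligibility fixture -------------------------------------
# eight patients, one violating each of the seven exclusion rules, one
# (patient 1) eligible
toy_raw_tables <- function() {
  idx <- as.Date("2018-06-01")
  n <- 8L
  na_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  patients <- data.frame(
    patient_id = 1:8,
    ccg = 1L, region = 1L, practice_size = 9000,
    birth_year = c(1960, 1960, 2001, 1960, 1960, 1985, 1960, 1960),
    sex = c("M", "M", "M", "M", "M", "F", "M", "M"),
    ethnicity = "White", deprivation = 3L,
    smoking = "non", alcohol = "current",
    regist_date = as.Date("2005-01-01"),
    dereg_date = na_date,
    linked = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    last_pregnancy_date = na_date,
    stringsAsFactors = FALSE
  )
  patients$last_pregnancy_date[6] <- idx - 100    # rule 5: recent pregnancy

  rx <- list()
  for (i in 1:8) {
    before_gap <- if (i == 4) 61L else 30L        # rule 3: outside 60-day lookback
    rx[[length(rx) + 1L]] <- data.frame(patient_id = i, drug_class = "metformin",
                                        date = idx - before_gap,
                                        duration_days = 28L)
    if (i != 5)                                   # rule 4: no continuation for P5
      rx[[length(rx) + 1L]] <- data.frame(patient_id = i, drug_class = "metformin",
                                          date = idx + 10L, duration_days = 28L)
    rx[[length(rx) + 1L]] <- data.frame(patient_id = i, drug_class = "SU",
                                        date = idx, duration_days = 28L)
  }
  # rule 1: a second class on the index date for P2
  rx[[length(rx) + 1L]] <- data.frame(patient_id = 2L, drug_class = "DPP4",
                                      date = idx, duration_days = 28L)
  prescriptions <- do.call(rbind, rx)

  measurements <- data.frame(
    patient_id = 1:8, test = "eGFR", date = idx - 50,
    value = c(90, 90, 90, 90, 90, 90, 25, 90),   # rule 6: last eGFR 25 for P7
    stringsAsFactors = FALSE
  )

  list(patients = patients, prescriptions = prescriptions,
       measurements = measurements,
       hospital_episodes = data.frame(patient_id = integer(),
                                      admission_date = as.Date(integer()),
                                      diagnosis = character()),
       deaths = data.frame(patient_id = integer(),
                           date = as.Date(integer()),
                           cause = character()))
}

# minimal always-eligible raw tables for one or more hand-specified patients;
# `extra` rows are appended to the named tables
plain_eligible_tables <- function(ids, index = as.Date("2016-03-01"),
                                  extra = list()) {
  n <- length(ids)
  na_date <- as.Date(rep(NA_integer_, n), origin = "1970-01-01")
  patients <- data.frame(
    patient_id = ids, ccg = 1L, region = 1L, practice_size = 9000,
    birth_year = 1960L, sex = "M", ethnicity = "White", deprivation = 3L,
    smoking = "non", alcohol = "current",
    regist_date = as.Date("2005-01-01"), dereg_date = na_date,
    linked = TRUE, last_pregnancy_date = na_date,
    stringsAsFactors = FALSE
  )
  prescriptions <- rbind(
    data.frame(patient_id = ids, drug_class = "metformin",
               date = index - 30, duration_days = 28L),
    data.frame(patient_id = ids, drug_class = "metformin",
               date = index + 10, duration_days = 28L),
    data.frame(patient_id = ids, drug_class = "SU",
               date = index, duration_days = 28L)
  )
  tabs <- list(patients = patients, prescriptions = prescriptions,
               measurements = data.frame(patient_id = integer(),
                                         test = character(),
                                         date = as.Date(integer()),
                                         value = numeric()),
               hospital_episodes = data.frame(patient_id = integer(),
                                              admission_date = as.Date(integer()),
                                              diagnosis = character()),
               deaths = data.frame(patient_id = integer(),
                                   date = as.Date(integer()),
                                   cause = character()))
  for (nm in names(extra)) tabs[[nm]] <- rbind(tabs[[nm]], extra[[nm]])
  tabs
}

# ---- hand-counted tendency fixture ----------------------------------------
# target patient 100 in CCG 1 with prior-window initiators 4 SU, 3 DPP4,
# 2 SGLT2; a second CCG provides an all-SGLT2 window and an empty window
tendency_fixture_cohort <- function() {
  idx <- as.Date("2018-06-01")
  prior <- data.frame(
    patient_id = 1:9, ccg = 1L,
    index_date = idx - seq(30, 350, length.out = 9),
    arm = factor(rep(c("SU", "DPP4", "SGLT2"), times = c(4, 3, 2)),
                 levels = c("SU", "DPP4", "SGLT2")),
    stringsAsFactors = FALSE
  )
  target <- data.frame(patient_id = 100L, ccg = 1L, index_date = idx,
                       arm = factor("SU", levels = levels(prior$arm)))
  ccg2_prior <- data.frame(patient_id = 201:210, ccg = 2L,
                           index_date = idx - seq(20, 340, length.out = 10),
                           arm = factor("SGLT2", levels = levels(prior$arm)))
  ccg2_target <- data.frame(patient_id = 300L, ccg = 2L, index_date = idx,
                            arm = factor("DPP4", levels = levels(prior$arm)))
  ccg2_empty <- data.frame(patient_id = 301L, ccg = 2L,
                           index_date = idx - 400,  # nobody initiated before
                           arm = factor("SU", levels = levels(prior$arm)))
  rbind(prior, target, ccg2_prior, ccg2_target, ccg2_empty)
}

# simulate, build and instrument a small cohort once per session
cached_small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- generate_cohort(small_config(seed = 42, n = 2500, n_ccgs = 20,
                                        missingness = no_missing()))
      bc <- build_cohort(g$tables)
      inst <- compute_tendency(bc$cohort)
      cache <<- list(g = g, cohort = bc$cohort, attrition = bc$attrition,
                     instrument = inst)
    }
    cache
  }
})
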