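test_that("toy fixture: exactly one removal per rule and one survivor", {
  res <- apply_eligibility(toy_raw_tables(), eligibility_rules())
  expect_equal(res$attrition$n_removed, rep(1L, 7))
  expect_equal(res$cohort$patient_id, 1L)
  expect_equal(as.character(res$cohort$arm), "SU")
  # attrition sums: candidates - eligible = total removed
  expect_equal(attr(res$attrition, "n_candidates") -
                 attr(res$attrition, "n_eligible"),
               sum(res$attrition$n_removed))
})

test_that("metformin window boundaries behave as closed 60-day intervals", {
  idx <- as.Date("2016-03-01")
  # prescription exactly 60 days before qualifies; 61 does not
  t60 <- plain_eligible_tables(1L, idx)
  t60$prescriptions$date[t60$prescriptions$drug_class == "metformin" &
                           t60$prescriptions$date < idx] <- idx - 60
  expect_equal(nrow(apply_eligibility(t60, eligibility_rules())$cohort), 1L)

  t61 <- plain_eligible_tables(1L, idx)
  t61$prescriptions$date[t61$prescriptions$drug_class == "metformin" &
                           t61$prescriptions$date < idx] <- idx - 61
  r61 <- apply_eligibility(t61, eligibility_rules())
  expect_equal(nrow(r61$cohort), 0L)
  expect_equal(r61$attrition$n_removed[r61$attrition$rule == "no_metformin_before"], 1L)

  # metformin on the index day itself satisfies the continuation rule
  tix <- plain_eligible_tables(1L, idx)
  tix$prescriptions$date[tix$prescriptions$drug_class == "metformin" &
                           tix$prescriptions$date > idx] <- idx
  expect_equal(nrow(apply_eligibility(tix, eligibility_rules())$cohort), 1L)
})

test_that("baseline ascertainment respects lookback windows and recency", {
  idx <- as.Date("2016-03-01")
  meas <- rbind(
    data.frame(patient_id = 1L, test = "HbA1c", date = idx - 179, value = 70),
    data.frame(patient_id = 1L, test = "HbA1c", date = idx - 200, value = 99),
    data.frame(patient_id = 1L, test = "SBP", date = idx - 541, value = 140),
    data.frame(patient_id = 1L, test = "eGFR", date = idx - 30, value = 88),
    data.frame(patient_id = 1L, test = "eGFR", date = idx - 100, value = 95),
    data.frame(patient_id = 1L, test = "BMI", date = idx - 900, value = 31)
  )
  tabs <- plain_eligible_tables(1L, idx, extra = list(measurements = meas))
  ch <- build_cohort(tabs)$cohort
  expect_equal(ch$hba1c_base, 70)     # in-window value, not the out-dated one
  expect_true(is.na(ch$sbp_base))     # 541 days is just outside 540
  expect_equal(ch$egfr_base, 88)      # most recent of the two in-window values
  expect_equal(ch$bmi_base, 31)       # BMI takes the latest value at any time
})

test_that("follow-up window selection: tolerance boundary and tie-break", {
  idx <- as.Date("2016-03-01")
  meas <- rbind(
    data.frame(patient_id = 1L, test = "HbA1c", date = idx + 450, value = 60),
    data.frame(patient_id = 2L, test = "HbA1c", date = idx + 456, value = 61),
    data.frame(patient_id = 3L, test = "HbA1c", date = idx + 300, value = 55),
    data.frame(patient_id = 3L, test = "HbA1c", date = idx + 430, value = 65)
  )
  tabs <- plain_eligible_tables(1:3, idx, extra = list(measurements = meas))
  ch <- build_cohort(tabs)$cohort
  ch <- ch[order(ch$patient_id), ]
  expect_equal(ch$hba1c_y1[1], 60)    # 85 days out: inside +/-90
  expect_true(is.na(ch$hba1c_y1[2]))  # 91 days out: just outside
  expect_equal(ch$hba1c_y1[3], 55)    # symmetric 65-day tie: earlier wins
})

test_that("event ascertainment: composites, censoring, and data faults", {
  idx <- as.Date("2016-03-01")
  meas <- rbind(
    data.frame(patient_id = 1L, test = "eGFR", date = idx - 50, value = 90),
    data.frame(patient_id = 1L, test = "eGFR", date = idx + 200, value = 80),
    data.frame(patient_id = 1L, test = "eGFR", date = idx + 400, value = 50),
    data.frame(patient_id = 2L, test = "eGFR", date = idx - 50, value = 90),
    data.frame(patient_id = 3L, test = "eGFR", date = idx - 50, value = 90)
  )
  eps <- rbind(
    data.frame(patient_id = 2L, admission_date = idx + 100, diagnosis = "MI"),
    data.frame(patient_id = 2L, admission_date = idx + 50, diagnosis = "stroke")
  )
  dth <- rbind(
    data.frame(patient_id = 3L, date = idx + 300, cause = "other"),
    data.frame(patient_id = 4L, date = idx - 10, cause = "other")  # fault
  )
  tabs <- plain_eligible_tables(1:4, idx,
                                extra = list(measurements = meas,
                                             hospital_episodes = eps,
                                             deaths = dth))
  ch <- build_cohort(tabs)$cohort
  expect_equal(attr(ch, "faults"), 1L)          # death before index rejected
  expect_false(4L %in% ch$patient_id)
  ch <- ch[order(ch$patient_id), ]

  # 0.6 x 90 = 54: the value 80 does not trigger, 50 at day 400 does
  expect_equal(ch$egfr40_time[1], 400)
  expect_equal(ch$egfr40_event[1], 1L)
  # MACE takes the earliest component (stroke at day 50, before the MI)
  expect_equal(ch$mace_time[2], 50)
  expect_equal(ch$mace_event[2], 1L)
  # non-CVD death: MAKE event at day 300, MACE censored there
  expect_equal(ch$make_time[3], 300)
  expect_equal(ch$make_event[3], 1L)
  expect_equal(ch$mace_time[3], 300)
  expect_equal(ch$mace_event[3], 0L)
  expect_equal(as.character(ch$strata_status[3]), "died")
})

test_that("patients without a baseline eGFR are excluded from decline endpoints only", {
  idx <- as.Date("2016-03-01")
  tabs <- plain_eligible_tables(1L, idx)   # no measurements at all
  ch <- build_cohort(tabs)$cohort
  expect_true(is.na(ch$egfr40_time))
  expect_true(is.na(ch$make_time))
  expect_false(is.na(ch$mortality_time))
  expect_equal(attr(ch, "n_no_baseline_egfr"), 1L)
})

test_that("attrition counts sum and ascertainment is idempotent on simulated data", {
  p <- cached_small_pipeline()
  att <- p$attrition
  expect_equal(attr(att, "n_candidates") - attr(att, "n_eligible"),
               sum(att$n_removed))
  g <- p$g
  rules <- eligibility_rules()
  again <- ascertain_baseline(
    ascertain_baseline(apply_eligibility(g$tables, rules)$cohort,
                       g$tables$measurements, rules),
    g$tables$measurements, rules)
  once <- ascertain_baseline(apply_eligibility(g$tables, rules)$cohort,
                             g$tables$measurements, rules)
  expect_identical(once, again)
})

test_that("no censoring, no events, no missingness: complete follow-up values", {
  cfg <- sim_config(n_patients = 400, n_ccgs = 5,
                    study_end = as.Date("2019-06-30"),
                    missingness = no_missing(),
                    baseline_event_rate = no_events,
                    censoring_rate = 0, seed = 21)
  ch <- build_cohort(generate_cohort(cfg)$tables)$cohort
  for (col in c("hba1c_y1", "hba1c_y2", "bmi_y1", "bmi_y2", "sbp_y1",
                "egfr_y1", "egfr_y2"))
    expect_false(anyNA(ch[[col]]))
  expect_false(any(ch$censored_by_y1))
  expect_false(any(ch$censored_by_y2))
})
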