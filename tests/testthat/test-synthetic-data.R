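test_that("generation is deterministic and tables are internally consistent", {
  cfg <- small_config(seed = 7, n = 800, n_ccgs = 8)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$tables, g2$tables)

  tabs <- g1$tables
  ids <- tabs$patients$patient_id
  for (nm in c("prescriptions", "measurements", "hospital_episodes", "deaths"))
    expect_true(all(tabs[[nm]]$patient_id %in% ids))
  expect_true(all(tabs$measurements$value[tabs$measurements$test == "eGFR"] > 0))
  expect_equal(rowSums(g1$truth$preferences), rep(1, cfg$n_ccgs))
  expect_true(all(g1$truth$preferences > 0))
})

test_that("preference triples match the configured Dirichlet mean", {
  cfg <- sim_config(n_patients = 400, n_ccgs = 400, seed = 3)
  g <- generate_cohort(cfg)
  alpha <- cfg$tendency_concentration
  mu <- alpha / sum(alpha)
  m <- colMeans(g$truth$preferences)
  se <- apply(g$truth$preferences, 2, sd) / sqrt(nrow(g$truth$preferences))
  expect_true(all(abs(m - mu) < 4 * se))
})

test_that("true effects are transitive on the linear predictor scale", {
  tr <- generate_cohort(small_config(seed = 2, n = 200, n_ccgs = 4))$truth
  for (o in c("HbA1c", "BMI", "hf")) {
    expect_equal(true_effect(tr, o, "SGLT2 vs DPP4"),
                 true_effect(tr, o, "SGLT2 vs SU") -
                   true_effect(tr, o, "DPP4 vs SU"))
    expect_equal(true_effect(tr, o, "SU vs SGLT2"),
                 -true_effect(tr, o, "SGLT2 vs SU"))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_ccgs = 1), "at least 2")
  expect_error(sim_config(frailty_variance = -0.1), "nonnegative")
  expect_error(sim_config(tendency_concentration = c(1, -1, 1)), "positive")
  expect_error(missingness_spec(rates = default_missing_rates() + 1))
  expect_error(sim_config(instrument_strength = -2), "nonnegative")
})

test_that("zero frailty variance and no covariate hazard effects give exponential event times", {
  # conditional Kolmogorov-Smirnov against the truncated exponential, over
  # repeated seeds; the discretisation to whole days is negligible at this
  # rate
  lam <- 0.8 / 365.25
  horizon <- 400
  pass <- vapply(1:40, function(s) {
    cfg <- sim_config(n_patients = 600, n_ccgs = 6,
                      frailty_variance = 0, confounding_unobserved = 0,
                      covariate_log_hazard = c(age = 0),
                      baseline_event_rate = c(hf = 0, mi = 0, stroke = 0,
                                              death_cvd = 0, death_other = 0.8),
                      censoring_rate = 0, missingness = no_missing(),
                      seed = 1200 + s)
    g <- generate_cohort(cfg)
    tr <- g$truth$patient
    de <- g$tables$deaths
    window_ok <- tr$patient_id[as.numeric(as.Date("2021-12-31") -
                                            tr$index_date) >= horizon]
    t_obs <- as.numeric(de$date - tr$index_date[match(de$patient_id,
                                                      tr$patient_id)])
    sub <- t_obs[de$patient_id %in% window_ok & t_obs <= horizon]
    cdf <- function(q) (1 - exp(-lam * q)) / (1 - exp(-lam * horizon))
    p <- suppressWarnings(stats::ks.test(sub, cdf)$p.value)
    p > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("zero deletion rates leave the tables untouched", {
  cfg <- small_config(seed = 5, n = 500, n_ccgs = 5,
                      missingness = no_missing())
  g <- generate_cohort(cfg)
  expect_identical(impose_missingness(g$tables, cfg), g$tables)
})

test_that("MCAR deletion hits the configured rate within binomial bounds", {
  rates <- default_missing_rates() * 0
  rates["HbA1c", "y1"] <- 0.337
  cfg <- sim_config(n_patients = 10000, n_ccgs = 50,
                    missingness = missingness_spec("MCAR", rates = rates),
                    seed = 9)
  g <- generate_cohort(cfg)
  idx <- g$truth$patient
  is_y1_hba1c <- function(tab) {
    j <- match(tab$patient_id, idx$patient_id)
    tab$test == "HbA1c" & as.numeric(tab$date - idx$index_date[j]) == 365
  }
  n_before <- sum(is_y1_hba1c(g$tables$measurements))
  out <- impose_missingness(g$tables, cfg)
  n_after <- sum(is_y1_hba1c(out$measurements))
  frac <- 1 - n_after / n_before
  half <- qnorm(0.995) * sqrt(0.337 * 0.663 / n_before)
  expect_lt(abs(frac - 0.337), half)
  # other measures and timepoints untouched
  expect_equal(sum(out$measurements$test == "BMI"),
               sum(g$tables$measurements$test == "BMI"))
  # treatment and event records never deleted
  expect_identical(out$prescriptions, g$tables$prescriptions)
  expect_identical(out$deaths, g$tables$deaths)
})

test_that("MAR deletion depends on the baseline value with the configured sign", {
  rates <- default_missing_rates() * 0
  rates["HbA1c", "y1"] <- 0.3
  cfg <- sim_config(n_patients = 8000, n_ccgs = 40,
                    missingness = missingness_spec("MAR", rates = rates,
                                                   mar_slope = 0.8),
                    seed = 10)
  g <- generate_cohort(cfg)
  out <- impose_missingness(g$tables, cfg)
  idx <- g$truth$patient
  meas <- g$tables$measurements
  j <- match(meas$patient_id, idx$patient_id)
  cand <- meas[meas$test == "HbA1c" &
                 as.numeric(meas$date - idx$index_date[j]) == 365, ]
  kept_key <- paste(out$measurements$patient_id, out$measurements$test,
                    out$measurements$date)
  deleted <- !(paste(cand$patient_id, cand$test, cand$date) %in% kept_key)
  base <- meas[meas$test == "HbA1c", ]
  jb <- match(base$patient_id, idx$patient_id)
  base <- base[as.numeric(base$date - idx$index_date[jb]) < 0, ]
  b <- base$value[match(cand$patient_id, base$patient_id)]
  fit <- glm(deleted ~ b, family = binomial)
  z <- summary(fit)$coefficients["b", ]
  expect_gt(z["Estimate"], 0)         # deletion log-odds rise with baseline
  expect_lt(z["Pr(>|z|)"], 0.001)
  # marginal rate still calibrated
  expect_lt(abs(mean(deleted) - 0.3), 0.03)
})

test_that("raw tables round-trip through delimited text files", {
  g <- generate_cohort(small_config(seed = 4, n = 200, n_ccgs = 4))
  dir <- tempfile("rawtabs")
  write_raw_tables(g$tables, dir)
  back <- read_raw_tables(dir)
  for (nm in names(g$tables)) {
    expect_equal(nrow(back[[nm]]), nrow(g$tables[[nm]]))
  }
  expect_equal(back$patients$regist_date, g$tables$patients$regist_date)
  expect_equal(back$measurements$value, g$tables$measurements$value)
  unlink(dir, recursive = TRUE)
})
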