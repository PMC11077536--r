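test_that("first-stage probabilities sum to one and residual columns sum to zero", {
  p <- cached_small_pipeline()
  fs <- fit_first_stage(p$cohort, p$instrument)
  d <- fs$data
  expect_true(all(abs(d$p_SU + d$p_DPP4 + d$p_SGLT2 - 1) < 1e-10))
  expect_true(all(d$p_SU > 0 & d$p_SU < 1))
  # score identities of the multinomial logit MLE
  expect_lt(abs(sum(d$r_DPP4)), 1e-5)
  expect_lt(abs(sum(d$r_SGLT2)), 1e-5)
})

test_that("fitted first-stage probabilities track the realised CCG preferences", {
  cfg <- recovery_config(seed = 61, n = 6000)
  g <- generate_cohort(cfg)
  ch <- build_cohort(g$tables)$cohort
  inst <- compute_tendency(ch)
  fs <- fit_first_stage(ch, inst)
  p_ccg <- tapply(fs$data$p_SGLT2, fs$data$ccg, mean)
  pref <- g$truth$preferences[as.integer(names(p_ccg)), "SGLT2"]
  expect_gt(cor(p_ccg, pref, method = "spearman"), 0.8)
})

test_that("residual-inclusion and naive estimators agree without unmeasured confounding", {
  diffs <- vapply(1:6, function(r) {
    cfg <- sim_config(n_patients = 4000, n_ccgs = 50,
                      confounding_unobserved = 0,
                      missingness = no_missing(),
                      baseline_event_rate = no_events,
                      censoring_rate = 0, seed = 550 + r)
    ch <- build_cohort(generate_cohort(cfg)$tables)$cohort
    fs <- fit_first_stage(ch, compute_tendency(ch))
    e2 <- estimate_continuous_2sri(fs, "HbA1c", "y1")
    en <- estimate_naive(ch, "HbA1c", "continuous")
    e2$estimate[e2$contrast == "SGLT2 vs SU"] -
      en$estimate[en$contrast == "SGLT2 vs SU"]
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.5)
})

test_that("naive regression bias has the sign of the confounding product", {
  # latent health raises SGLT2 uptake and improves (lowers) the HbA1c
  # change, so the naive estimate overstates the benefit (negative bias)
  ests <- vapply(1:4, function(r) {
    ch <- build_cohort(generate_cohort(recovery_config(570 + r, n = 8000))$tables)$cohort
    en <- estimate_naive(ch, "HbA1c", "continuous")
    en$estimate[en$contrast == "SGLT2 vs SU"]
  }, numeric(1))
  expect_lt(mean(ests), -3)
})

test_that("zero events in an arm returns a flagged record, not numbers", {
  p <- cached_small_pipeline()
  ch <- p$cohort
  ch$hf_event[ch$arm == "SGLT2"] <- 0L
  fs <- fit_first_stage(ch, p$instrument)
  out <- estimate_tte_2sri_cox(fs, "hf")
  expect_true(all(is.na(out$estimate)))
  expect_match(attr(out, "flag"), "zero events")
})

test_that("post-double selection keeps genuine expansions, bounds noise, and never drops the base", {
  ch <- cached_small_pipeline()$cohort
  covs <- c("age", "sex", "hba1c_base", "bmi_base", "sbp_base", "egfr_base")
  # plant a strong genuine age^2 signal in the outcome
  set.seed(12)
  ch$hba1c_y1 <- ch$hba1c_base - 12 + 0.08 * (ch$age - 60)^2 + rnorm(nrow(ch), 0, 5)
  sel <- select_covariates_pds(ch, "HbA1c", "continuous",
                               covariates = covs, seed = 3)
  expect_true("I(age^2)" %in% sel$selected)
  expect_identical(sel$base, covs)
  expect_false(anyDuplicated(sel$selected) > 0)
  expect_true(all(sel$selected %in% sel$candidates))

  # pure-noise outcome: few false selections from the outcome fit
  set.seed(13)
  ch$hba1c_y1 <- ch$hba1c_base + rnorm(nrow(ch), 0, 10)
  sel0 <- select_covariates_pds(ch, "HbA1c", "continuous",
                                covariates = covs, seed = 3)
  expect_lte(length(sel0$selected), 6)
})

test_that("stabilised weights average one per arm; IPTW matches the randomised limit", {
  cfg <- sim_config(n_patients = 6000, n_ccgs = 50,
                    confounding_unobserved = 0,
                    confounding_observed = c(age = 0, hba1c = 0),
                    missingness = no_missing(),
                    baseline_event_rate = no_events,
                    censoring_rate = 0, seed = 77)
  ch <- build_cohort(generate_cohort(cfg)$tables)$cohort
  w <- compute_iptw_weights(ch, stabilize = TRUE)
  for (a in levels(w$arm))
    expect_lt(abs(mean(w$.weight[w$arm == a]) - 1), 0.02)
  # with assignment independent of covariates, IPTW equals the unadjusted
  # contrast up to Monte Carlo error
  ei <- estimate_iptw(ch, "HbA1c", "continuous")
  chg <- ch$hba1c_y1 - ch$hba1c_base
  unadj <- mean(chg[ch$arm == "SGLT2"]) - mean(chg[ch$arm == "SU"])
  expect_lt(abs(ei$estimate[ei$contrast == "SGLT2 vs SU"] - unadj), 0.3)
})

test_that("IPTW recovers under measured confounding and breaks when the confounder is withheld", {
  res <- t(vapply(1:4, function(r) {
    cfg <- sim_config(n_patients = 8000, n_ccgs = 50,
                      confounding_unobserved = 0,
                      confounding_observed = c(age = 0.8, hba1c = 0.6),
                      missingness = no_missing(),
                      baseline_event_rate = no_events,
                      censoring_rate = 0, seed = 660 + r)
    ch <- build_cohort(generate_cohort(cfg)$tables)$cohort
    full <- estimate_iptw(ch, "HbA1c", "continuous")
    # withhold the true confounders from the propensity model
    bad <- estimate_iptw(ch, "HbA1c", "continuous",
                         covariates = c("sex", "deprivation"))
    c(full = full$estimate[full$contrast == "SGLT2 vs SU"],
      bad = bad$estimate[bad$contrast == "SGLT2 vs SU"])
  }, numeric(2)))
  expect_lt(abs(mean(res[, "full"]) + 3), 0.5)
  expect_gt(abs(mean(res[, "bad"]) + 3), abs(mean(res[, "full"]) + 3))
})

test_that("weighted regression is doubly robust", {
  res <- t(vapply(1:4, function(r) {
    cfg <- sim_config(n_patients = 8000, n_ccgs = 50,
                      confounding_unobserved = 0,
                      confounding_observed = c(age = 0.8, hba1c = 0.6),
                      missingness = no_missing(),
                      baseline_event_rate = no_events,
                      censoring_rate = 0, seed = 680 + r)
    ch <- build_cohort(generate_cohort(cfg)$tables)$cohort
    good_w <- compute_iptw_weights(ch)   # correct propensity model
    # (a) correct propensity, outcome model missing the confounders
    a <- estimate_weighted_regression(ch, "HbA1c", "continuous",
                                      covariates = c("sex", "deprivation"),
                                      weights = good_w)
    # (b) wrong propensity, correct outcome model
    bad_w <- compute_iptw_weights(ch, covariates = c("sex", "deprivation"))
    b <- estimate_weighted_regression(ch, "HbA1c", "continuous",
                                      weights = bad_w)
    c(a = a$estimate[a$contrast == "SGLT2 vs SU"],
      b = b$estimate[b$contrast == "SGLT2 vs SU"])
  }, numeric(2)))
  expect_lt(abs(mean(res[, "a"]) + 3), 0.5)
  expect_lt(abs(mean(res[, "b"]) + 3), 0.5)
})

test_that("contrasts from one joint model are exactly transitive", {
  p <- cached_small_pipeline()
  fs <- fit_first_stage(p$cohort, p$instrument)
  for (est in list(estimate_continuous_2sri(fs, "HbA1c", "y1"),
                   estimate_naive(p$cohort, "HbA1c", "continuous"))) {
    e <- setNames(est$estimate, est$contrast)
    expect_equal(e[["SGLT2 vs DPP4"]],
                 e[["SGLT2 vs SU"]] - e[["DPP4 vs SU"]])
  }
})
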