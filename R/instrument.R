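## Tendency-to-prescribe instrument: construction and diagnostics.

#' Compute the CCG tendency-to-prescribe instrument
#'
#' For each patient, the shares of the three second-line classes among
#' eligible initiators in the same CCG whose index dates fall in the
#' `window_days` days preceding that patient's own index date (the window
#' `[index - window_days, index - 1]`, which never contains the patient's
#' own initiation: the instrument is leave-one-out by construction).
#' Patients with fewer than `min_count` contributing initiators are flagged
#' instrument-undefined and carry NA shares.
#'
#' @param cohort analysis cohort (needs `patient_id`, `ccg`, `index_date`,
#'   `arm`).
#' @param window_days length of the rolling window (default 365, i.e. the
#'   12 preceding months).
#' @param min_count minimum number of contributing initiators for the
#'   instrument to be considered defined.
#' @return data frame with `patient_id`, `ccg`, `index_date`, shares
#'   `z_SU`, `z_DPP4`, `z_SGLT2`, `n_window` and a `defined` flag.
#' @export
compute_tendency <- function(cohort, window_days = 365, min_count = 5) {
  stopifnot(all(c("patient_id", "ccg", "index_date", "arm") %in% names(cohort)))
  n <- nrow(cohort)
  z <- matrix(NA_real_, n, 3L, dimnames = list(NULL, ARMS))
  n_window <- integer(n)
  d_num <- as.numeric(cohort$index_date)
  arm_chr <- as.character(cohort$arm)

  for (c_id in unique(cohort$ccg)) {
    rows <- which(cohort$ccg == c_id)
    dd <- d_num[rows]
    ord <- order(dd)
    ds <- dd[ord]
    counts <- vapply(ARMS, function(a) {
      da <- ds[arm_chr[rows][ord] == a]
      ## initiators of arm a with index date in [d - window, d - 1]
      findInterval(dd - 1, da) - findInterval(dd - window_days - 1, da)
    }, numeric(length(rows)))
    if (length(rows) == 1L) counts <- matrix(counts, nrow = 1L,
                                             dimnames = list(NULL, ARMS))
    tot <- rowSums(counts)
    n_window[rows] <- as.integer(tot)
    ok <- tot > 0
    z[rows[ok], ] <- counts[ok, , drop = FALSE] / tot[ok]
  }

  defined <- n_window >= min_count
  z[!defined, ] <- NA_real_
  data.frame(patient_id = cohort$patient_id,
             ccg = cohort$ccg,
             index_date = cohort$index_date,
             z_SU = z[, "SU"], z_DPP4 = z[, "DPP4"], z_SGLT2 = z[, "SGLT2"],
             n_window = n_window,
             defined = defined,
             stringsAsFactors = FALSE)
}

## merge instrument shares onto the cohort, keeping defined rows only
merge_instrument <- function(cohort, instrument) {
  j <- match(cohort$patient_id, instrument$patient_id)
  cohort$z_SU <- instrument$z_SU[j]
  cohort$z_DPP4 <- instrument$z_DPP4[j]
  cohort$z_SGLT2 <- instrument$z_SGLT2[j]
  def <- !is.na(j) & instrument$defined[j]
  cohort[def, , drop = FALSE]
}

#' Default baseline-covariate adjustment set
#'
#' Column names of the analysis cohort entered additively in first-stage,
#' second-stage and propensity models: demographics, context (region,
#' deprivation, calendar year, practice size) and baseline clinical values.
#'
#' @return character vector of covariate column names.
#' @export
default_covariates <- function() {
  c("age", "sex", "hba1c_base", "bmi_base", "sbp_base", "egfr_base",
    "deprivation", "year_index", "practice_size_log", "region")
}

#' Cluster-robust weak-instrument F test
#'
#' For each non-reference arm, fits the linear first-stage regression of the
#' arm indicator on the two identifying tendency shares (`z_DPP4`,
#' `z_SGLT2`; the SU share is dropped as the triple sums to one) plus the
#' baseline covariates, and computes the joint Wald F statistic on the
#' tendency coefficients using a heteroscedasticity-consistent covariance
#' clustered on region. The conventional relevance rule requires F > 100.
#'
#' @param cohort analysis cohort.
#' @param instrument output of [compute_tendency()].
#' @param covariates covariate column names (default
#'   [default_covariates()]).
#' @return data frame with one row per non-reference arm: `F`, `df`,
#'   `n_clusters` and `pass` (`F > 100`).
#' @export
weak_instrument_test <- function(cohort, instrument,
                                 covariates = default_covariates()) {
  d <- merge_instrument(cohort, instrument)
  d <- droplevels(d[complete.cases(d[, c("z_DPP4", "z_SGLT2", covariates)]), ])
  if (length(unique(d$region)) < 2L)
    stop("cluster-robust F requires at least 2 region clusters")
  out <- lapply(c("DPP4", "SGLT2"), function(a) {
    d$.y <- as.numeric(d$arm == a)
    f <- reformulate(c("z_DPP4", "z_SGLT2", covariates), response = ".y")
    fit <- lm(f, data = d)
    V <- sandwich::vcovCL(fit, cluster = d$region)
    k <- c("z_DPP4", "z_SGLT2")
    b <- coef(fit)[k]
    W <- drop(t(b) %*% solve(V[k, k]) %*% b)
    data.frame(arm = a, F = W / length(k), df = length(k),
               n_clusters = length(unique(d$region)),
               pass = (W / length(k)) > 100,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Covariate balance across levels of the instrument
#'
#' Groups patients into tertiles of each arm's tendency share and reports
#' the absolute standardised mean difference of every baseline covariate
#' between the top and bottom tertile. Factor covariates are expanded into
#' level indicators. Differences above the conventional 0.1 threshold are
#' flagged.
#'
#' @inheritParams weak_instrument_test
#' @return data frame with `tendency`, `covariate`, `smd`, `flag`.
#' @export
balance_diagnostics <- function(cohort, instrument,
                                covariates = default_covariates()) {
  d <- merge_instrument(cohort, instrument)
  d <- d[complete.cases(d[, covariates]), ]
  X <- model.matrix(reformulate(covariates, intercept = FALSE), data = d)
  out <- list()
  for (a in ARMS) {
    zc <- d[[paste0("z_", a)]]
    br <- quantile(zc, c(1 / 3, 2 / 3))
    if (br[1] == br[2]) stop("degenerate tertiles for tendency ", a,
                             ": shares are all equal")
    g <- cut(zc, c(-Inf, br, Inf), labels = c("low", "mid", "high"))
    lo <- X[g == "low", , drop = FALSE]
    hi <- X[g == "high", , drop = FALSE]
    sp <- sqrt((apply(hi, 2, var) + apply(lo, 2, var)) / 2)
    smd <- abs(colMeans(hi) - colMeans(lo)) / ifelse(sp > 0, sp, 1)
    smd[sp == 0] <- 0
    out[[a]] <- data.frame(tendency = a, covariate = colnames(X),
                           smd = unname(smd), flag = unname(smd) > 0.1,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}
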