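## Nested bootstrap-then-impute inference: stratified resampling, multiple
## imputation within each replicate, Rubin pooling per replicate, t-based
## confidence intervals across replicates.

#' Bootstrap specification
#'
#' @param B number of bootstrap replicates.
#' @param m_per_replicate imputations per replicate when missing data are
#'   present.
#' @param strata cohort columns whose interaction defines the resampling
#'   strata (default CCG x arm x death/censoring status, which preserves
#'   the structure of the original sample across replicates).
#' @param seed master seed; replicate b derives its own streams from
#'   `seed` and `b` so any replicate is independently reproducible.
#' @return list with class `prefiv_bootstrap_spec`.
#' @export
bootstrap_spec <- function(B = 500, m_per_replicate = 5,
                           strata = c("ccg", "arm", "strata_status"),
                           seed = 1L) {
  stopifnot(B >= 2, m_per_replicate >= 1)
  structure(list(B = as.integer(B),
                 m_per_replicate = as.integer(m_per_replicate),
                 strata = strata, seed = as.integer(seed)),
            class = "prefiv_bootstrap_spec")
}

#' Stratified resampling with replacement
#'
#' Draws, within each stratum, a sample with replacement of the stratum's
#' original size, so every replicate preserves the stratum sizes exactly.
#'
#' @param cohort data frame.
#' @param strata columns defining the strata.
#' @param seed optional RNG seed.
#' @return the resampled data frame.
#' @export
stratified_resample <- function(cohort, strata = c("ccg", "arm",
                                                   "strata_status"),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- interaction(cohort[, strata, drop = FALSE], drop = TRUE)
  idx <- unlist(lapply(split(seq_len(nrow(cohort)), g), function(i)
    if (length(i) == 1L) i else i[sample.int(length(i), length(i),
                                             replace = TRUE)]),
    use.names = FALSE)
  cohort[idx, , drop = FALSE]
}

#' Rubin's first rule
#'
#' Pools per-imputation point estimates by their arithmetic mean (log
#' hazard ratios must be supplied, and are pooled, on the log scale). Any
#' non-finite input marks the whole set as failed and returns `NA`.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @return pooled estimate, or `NA_real_` if any input is non-finite.
#' @export
pool_rubin <- function(estimates) {
  if (!length(estimates) || any(!is.finite(estimates))) return(NA_real_)
  mean(estimates)
}

#' Build a pipeline estimator closure for bootstrap inference
#'
#' Returns a function of a (possibly resampled, possibly imputed) cohort
#' that re-runs the first-stage treatment model and the requested second
#' stage, and returns the three contrasts as a named numeric vector. The
#' tendency shares are looked up from the supplied instrument table by
#' patient id (the instrument is a fixed patient attribute; the first-stage
#' and second-stage models are re-estimated inside every replicate).
#'
#' @param instrument output of [compute_tendency()] on the original cohort.
#' @param outcome outcome or endpoint name.
#' @param type `"continuous"` or `"tte"`.
#' @param timepoint for continuous outcomes.
#' @param covariates covariate columns.
#' @param frailty for time-to-event second stages.
#' @param selection optional [select_covariates_pds()] result (treated as
#'   fixed across replicates unless the caller rebuilds it).
#' @return function `cohort -> named numeric length 3`.
#' @export
make_2sri_estimator <- function(instrument, outcome = "HbA1c",
                                type = c("continuous", "tte"),
                                timepoint = "y1",
                                covariates = default_covariates(),
                                frailty = TRUE, selection = NULL) {
  type <- match.arg(type)
  force(instrument)
  function(ch) {
    fs <- fit_first_stage(ch, instrument, covariates = covariates,
                          selection = selection)
    est <- if (type == "continuous")
      estimate_continuous_2sri(fs, outcome, timepoint)
    else
      estimate_tte_2sri_cox(fs, outcome, frailty = frailty)
    setNames(est$estimate, est$contrast)
  }
}

#' Nested bootstrap-then-impute confidence intervals
#'
#' For each replicate b = 1..B: resample the cohort stratified on
#' `spec$strata`; impute `m_per_replicate` times (skipped automatically if
#' the estimator's inputs are complete); apply the estimator to each
#' completion; Rubin-pool to one vector per replicate. The reported point
#' estimate is the Rubin-pooled estimate on the original data; the
#' bootstrap SD is the sample SD of the replicate estimates; the default
#' interval is point +/- t(B_eff - 1, 0.975) x SD, with a percentile
#' option. Replicates in which estimation fails are logged and excluded
#' from B_eff.
#'
#' @param cohort analysis cohort.
#' @param estimator function `cohort -> named numeric` (see
#'   [make_2sri_estimator()]).
#' @param spec a [bootstrap_spec()].
#' @param imputation `NULL` for complete-data estimation, or an
#'   [imputation_spec()] applied inside every replicate (and to the
#'   original data for the point estimate).
#' @param interval `"t"` or `"percentile"`.
#' @return data frame of class `prefiv_pooled`: one row per estimated term
#'   with `estimate`, `boot_sd`, `t_mult`, `ci_low`, `ci_high`, `B_eff`;
#'   the replicate matrix is attached as attribute `replicates`.
#' @export
run_nested_bootstrap <- function(cohort, estimator, spec = bootstrap_spec(),
                                 imputation = NULL,
                                 interval = c("t", "percentile")) {
  stopifnot(inherits(spec, "prefiv_bootstrap_spec"))
  interval <- match.arg(interval)

  impute_and_estimate <- function(ch, seed) {
    if (is.null(imputation)) return(estimator(ch))
    imp <- imputation
    imp$seed <- as.integer(seed)
    completions <- mice_pmm(ch, imp)
    ests <- do.call(cbind, lapply(completions, estimator))
    apply(ests, 1L, pool_rubin)
  }

  point <- impute_and_estimate(cohort, spec$seed)
  p <- length(point)
  theta <- matrix(NA_real_, spec$B, p,
                  dimnames = list(NULL, names(point)))
  status <- character(spec$B)
  for (b in seq_len(spec$B)) {
    rs <- stratified_resample(cohort, spec$strata,
                              seed = spec$seed + 7L * b)
    th <- tryCatch(impute_and_estimate(rs, spec$seed + 7L * b + 3L),
                   error = function(e) {
                     status[b] <<- conditionMessage(e)
                     rep(NA_real_, p)
                   })
    theta[b, ] <- th
  }
  ok <- rowSums(!is.finite(theta)) == 0
  B_eff <- sum(ok)
  if (B_eff < 0.9 * spec$B)
    warning("only ", B_eff, " of ", spec$B,
            " bootstrap replicates produced estimates")
  sd_b <- apply(theta[ok, , drop = FALSE], 2L, sd)
  t_mult <- if (B_eff >= 2) qt(0.975, df = B_eff - 1) else NA_real_
  if (interval == "t") {
    lo <- point - t_mult * sd_b
    hi <- point + t_mult * sd_b
  } else {
    qs <- apply(theta[ok, , drop = FALSE], 2L, quantile,
                probs = c(0.025, 0.975))
    lo <- qs[1L, ]; hi <- qs[2L, ]
  }
  out <- data.frame(term = names(point), estimate = unname(point),
                    boot_sd = unname(sd_b), t_mult = t_mult,
                    ci_low = unname(lo), ci_high = unname(hi),
                    B_eff = B_eff, stringsAsFactors = FALSE)
  class(out) <- c("prefiv_pooled", class(out))
  attr(out, "replicates") <- theta
  attr(out, "failures") <- status[nzchar(status)]
  out
}

#' Assemble a tidy results table
#'
#' Binds effect-estimate frames into one long table (outcome x contrast x
#' estimator), exponentiates log-hazard-ratio rows into `hr`, `hr_low`,
#' `hr_high` display columns (a monotone transform of the interval), and,
#' when a truth record is supplied, appends the true value and the bias.
#'
#' @param estimates one effect-estimate data frame or a list of them.
#' @param truth optional `prefiv_truth`.
#' @return tidy data frame.
#' @export
assemble_results <- function(estimates, truth = NULL) {
  if (is.data.frame(estimates)) estimates <- list(estimates)
  cols <- c("contrast", "outcome", "scale", "estimate", "se",
            "ci_low", "ci_high", "estimator", "n")
  if (!length(estimates) || !sum(vapply(estimates, nrow, integer(1)))) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  tab <- do.call(rbind, lapply(estimates, function(e) e[, cols]))
  rownames(tab) <- NULL
  is_hr <- tab$scale == "log hazard ratio"
  tab$hr <- ifelse(is_hr, exp(tab$estimate), NA_real_)
  tab$hr_low <- ifelse(is_hr, exp(tab$ci_low), NA_real_)
  tab$hr_high <- ifelse(is_hr, exp(tab$ci_high), NA_real_)
  if (!is.null(truth)) {
    tab$true_value <- mapply(function(o, ct) {
      ok <- o %in% CONT_MEASURES ||
        o %in% rownames(truth$true_log_hazard_ratios)
      if (ok) true_effect(truth, o, ct) else NA_real_
    }, tab$outcome, tab$contrast)
    tab$bias <- tab$estimate - tab$true_value
  }
  tab
}
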