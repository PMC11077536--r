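## Effect estimation: two-stage residual inclusion (continuous and
## time-to-event second stages) and the comparator estimators.

CONTRASTS <- c("DPP4 vs SU", "SGLT2 vs SU", "SGLT2 vs DPP4")

## assemble the three transitive contrasts from one joint model's two
## non-reference arm coefficients and their covariance; arms absent from
## the data yield NA contrasts
contrasts_from_joint <- function(b, V, outcome, scale, estimator, n) {
  pick <- function(k) if (k %in% names(b)) unname(b[k]) else NA_real_
  vv <- function(i, j) {
    if (all(c(i, j) %in% rownames(V))) V[i, j] else NA_real_
  }
  est <- c(pick("a_DPP4"), pick("a_SGLT2"), pick("a_SGLT2") - pick("a_DPP4"))
  se <- c(sqrt(vv("a_DPP4", "a_DPP4")),
          sqrt(vv("a_SGLT2", "a_SGLT2")),
          sqrt(vv("a_DPP4", "a_DPP4") + vv("a_SGLT2", "a_SGLT2") -
                 2 * vv("a_DPP4", "a_SGLT2")))
  data.frame(contrast = CONTRASTS, outcome = outcome, scale = scale,
             estimate = est, se = se,
             ci_low = est - qnorm(0.975) * se,
             ci_high = est + qnorm(0.975) * se,
             estimator = estimator, n = n,
             stringsAsFactors = FALSE)
}

## a_*/r_* model terms for the non-reference arms actually present
present_arm_terms <- function(d, prefixes = c("a_", "r_")) {
  arms <- c("DPP4", "SGLT2")[c("DPP4", "SGLT2") %in% unique(as.character(d$arm))]
  unlist(lapply(prefixes, paste0, arms))
}

## change-from-baseline score for a continuous outcome
outcome_change <- function(d, outcome, timepoint) {
  p <- measure_prefix(outcome)
  d[[paste0(p, "_", timepoint)]] - d[[paste0(p, "_base")]]
}

add_arm_indicators <- function(d) {
  d$a_DPP4 <- as.numeric(d$arm == "DPP4")
  d$a_SGLT2 <- as.numeric(d$arm == "SGLT2")
  d
}

model_terms <- function(covariates, selection = NULL) {
  unique(c(covariates, if (!is.null(selection)) selection$selected))
}

#' Fit the first-stage treatment model
#'
#' Models the probability that each patient received each of the three
#' classes given the two identifying tendency shares (`z_DPP4`, `z_SGLT2`)
#' and the baseline covariates, and returns the generalised residuals
#' (arm indicator minus fitted probability) used by the second-stage
#' residual-inclusion models. The default first stage is a multinomial
#' logit; `method = "linear"` fits per-arm linear probability models, the
#' variant under which residual inclusion reproduces two-stage least
#' squares exactly.
#'
#' @param cohort analysis cohort.
#' @param instrument output of [compute_tendency()]; rows with undefined
#'   instrument are excluded.
#' @param covariates covariate columns (default [default_covariates()]).
#' @param selection optional [select_covariates_pds()] result; its selected
#'   expansion terms are added to the model.
#' @param method `"multinomial"` or `"linear"`.
#' @return object of class `prefiv_first_stage`: the estimation sample with
#'   fitted probabilities `p_SU`, `p_DPP4`, `p_SGLT2` and residuals
#'   `r_DPP4`, `r_SGLT2`, plus the fitted model and metadata.
#' @export
fit_first_stage <- function(cohort, instrument,
                            covariates = default_covariates(),
                            selection = NULL,
                            method = c("multinomial", "linear")) {
  method <- match.arg(method)
  d <- merge_instrument(cohort, instrument)
  terms <- model_terms(covariates, selection)
  d <- droplevels(d[complete.cases(d[, intersect(c("z_DPP4", "z_SGLT2", covariates),
                                                 names(d))]), ])
  rhs <- c("z_DPP4", "z_SGLT2", terms)
  if (method == "multinomial") {
    fit <- nnet::multinom(reformulate(rhs, response = "arm"), data = d,
                          trace = FALSE, maxit = 500, reltol = 1e-14)
    if (fit$convergence != 0)
      stop("first-stage multinomial logit did not converge")
    if (max(abs(coef(fit))) > 100)
      stop("first-stage coefficients diverged: separation in the ",
           "treatment model")
    p <- fitted(fit)
    if (is.null(dim(p)) || ncol(p) == 1L)   # two observed arms: P(2nd level)
      p <- cbind(1 - as.numeric(p), as.numeric(p))
    colnames(p) <- fit$lev
    full <- matrix(0, nrow(d), length(ARMS), dimnames = list(NULL, ARMS))
    full[, colnames(p)] <- p
    p <- full
  } else {
    fit <- lapply(ARMS, function(a) {
      d$.y <- as.numeric(d$arm == a)
      lm(reformulate(rhs, response = ".y"), data = d)
    })
    names(fit) <- ARMS
    p <- vapply(fit, fitted, numeric(nrow(d)))
  }
  d$p_SU <- p[, "SU"]; d$p_DPP4 <- p[, "DPP4"]; d$p_SGLT2 <- p[, "SGLT2"]
  d$r_DPP4 <- as.numeric(d$arm == "DPP4") - d$p_DPP4
  d$r_SGLT2 <- as.numeric(d$arm == "SGLT2") - d$p_SGLT2
  d <- add_arm_indicators(d)
  structure(list(data = d, model = fit, method = method,
                 covariates = covariates, selection = selection),
            class = "prefiv_first_stage")
}

#' Two-stage residual inclusion for a continuous outcome
#'
#' Second stage: ordinary least squares of the baseline-to-follow-up change
#' score on the two arm indicators, the two first-stage generalised
#' residuals and the baseline covariates. The residual terms absorb the
#' association between treatment choice and unmeasured prognosis, so the
#' arm coefficients estimate average treatment effects under the instrument
#' assumptions. All three pairwise contrasts are read from the one joint
#' fit and are exactly transitive. Per-fit standard errors are reported as
#' diagnostics only; headline inference should come from
#' [run_nested_bootstrap()], since two-step plug-in standard errors are
#' inconsistent.
#'
#' @param firststage a [fit_first_stage()] result.
#' @param outcome continuous measure name (`"HbA1c"`, `"SBP"`, `"DBP"`,
#'   `"BMI"`, `"eGFR"`).
#' @param timepoint `"y1"` or `"y2"`.
#' @return an effect-estimate data frame (three contrasts).
#' @export
estimate_continuous_2sri <- function(firststage, outcome = "HbA1c",
                                     timepoint = "y1") {
  stopifnot(inherits(firststage, "prefiv_first_stage"))
  d <- firststage$data
  d$.chg <- outcome_change(d, outcome, timepoint)
  d <- d[!is.na(d$.chg), , drop = FALSE]
  terms <- model_terms(firststage$covariates, firststage$selection)
  at <- present_arm_terms(d)
  f <- reformulate(c(at, terms), response = ".chg")
  fit <- lm(f, data = d)
  b <- coef(fit)
  if (any(is.na(b[at])))
    stop("arm indicators and first-stage residuals are collinear: ",
         "the instrument is degenerate (check weak_instrument_test)")
  contrasts_from_joint(b, vcov(fit), outcome,
                       scale = "mean difference", estimator = "2SRI",
                       n = nrow(d))
}

#' Two-stage residual inclusion for a time-to-event endpoint
#'
#' Second stage: Cox proportional hazards partial-likelihood fit of the
#' endpoint on the arm indicators, the first-stage generalised residuals
#' and the baseline covariates, with an individual gamma frailty (Efron tie
#' handling where available). If the frailty variance is estimated at the
#' boundary (0), the model reduces to a plain Cox fit, which is also what
#' `frailty = FALSE` requests directly.
#'
#' @inheritParams estimate_continuous_2sri
#' @param endpoint endpoint name (`"hf"`, `"mi"`, `"stroke"`, `"egfr40"`,
#'   `"make"`, `"mace"`, `"mortality"`).
#' @param frailty logical: include the individual gamma frailty term.
#' @param theta optional fixed frailty variance; `theta = 0` constrains the
#'   frailty to be degenerate, which reduces the model to a plain Cox fit.
#' @return an effect-estimate data frame on the log hazard ratio scale; if
#'   an arm has zero events the estimates are returned as NA with a
#'   `flag` attribute rather than numbers.
#' @export
estimate_tte_2sri_cox <- function(firststage, endpoint = "hf",
                                  frailty = TRUE, theta = NULL) {
  stopifnot(inherits(firststage, "prefiv_first_stage"))
  d <- firststage$data
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  d <- d[!is.na(d[[tcol]]) & !is.na(d[[ecol]]) & d[[tcol]] > 0, , drop = FALSE]
  terms <- model_terms(firststage$covariates, firststage$selection)
  ev_by_arm <- tapply(d[[ecol]], droplevels(d$arm), sum)
  if (any(is.na(ev_by_arm)) || any(ev_by_arm == 0)) {
    out <- data.frame(contrast = CONTRASTS, outcome = endpoint,
                      scale = "log hazard ratio", estimate = NA_real_,
                      se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      estimator = "2SRI-Cox", n = nrow(d),
                      stringsAsFactors = FALSE)
    attr(out, "flag") <- "zero events in at least one arm"
    return(out)
  }
  at <- present_arm_terms(d)
  base_rhs <- c(at, terms)
  surv <- paste0("survival::Surv(", tcol, ", ", ecol, ")")
  fit_plain <- function() {
    survival::coxph(as.formula(paste(surv, "~",
                                     paste(base_rhs, collapse = " + "))),
                    data = d, ties = "efron")
  }
  note <- NULL
  if (frailty) {
    fr <- if (is.null(theta))
      "survival::frailty(patient_id, distribution = 'gamma')"
    else
      sprintf("survival::frailty(patient_id, distribution = 'gamma', theta = %.10g)",
              theta)
    f <- as.formula(paste(surv, "~", paste(base_rhs, collapse = " + "),
                          "+", fr))
    fit <- survival::coxph(f, data = d)
    theta_hat <- fit$history[[1]]$theta
    if (is.null(theta)) {
      if (is.null(theta_hat) || theta_hat < 1e-8) {
        fit <- fit_plain()
        note <- "frailty variance estimated at boundary 0; plain Cox fit used"
      }
    }
  } else {
    fit <- fit_plain()
  }
  ak <- intersect(c("a_DPP4", "a_SGLT2"), names(coef(fit)))
  b <- coef(fit)[ak]
  V <- vcov(fit)[ak, ak, drop = FALSE]
  rownames(V) <- colnames(V) <- ak
  out <- contrasts_from_joint(b, V, endpoint, scale = "log hazard ratio",
                              estimator = "2SRI-Cox", n = nrow(d))
  if (!is.null(note)) attr(out, "note") <- note
  out
}

#' Two-stage least squares for a continuous outcome
#'
#' The linear instrumental-variables benchmark: the two arm indicators are
#' instrumented by the two tendency shares, with the baseline covariates
#' exogenous. Point estimates are computed by the standard projection
#' (regress each endogenous indicator on instruments plus exogenous
#' covariates, then regress the outcome on the fitted indicators plus the
#' exogenous covariates); standard errors use the classical IV covariance
#' with residuals evaluated at the structural coefficients.
#'
#' @param cohort analysis cohort.
#' @param instrument output of [compute_tendency()].
#' @param outcome,timepoint as in [estimate_continuous_2sri()].
#' @param covariates covariate columns.
#' @return an effect-estimate data frame (three contrasts).
#' @export
estimate_2sls <- function(cohort, instrument, outcome = "HbA1c",
                          timepoint = "y1",
                          covariates = default_covariates()) {
  d <- merge_instrument(cohort, instrument)
  d <- add_arm_indicators(d)
  d$.chg <- outcome_change(d, outcome, timepoint)
  use <- complete.cases(d[, c(".chg", "z_DPP4", "z_SGLT2", covariates)])
  d <- droplevels(d[use, , drop = FALSE])
  X <- model.matrix(reformulate(covariates), data = d)       # exogenous incl. intercept
  Z <- cbind(X, z_DPP4 = d$z_DPP4, z_SGLT2 = d$z_SGLT2)      # full instrument set
  W <- cbind(a_DPP4 = d$a_DPP4, a_SGLT2 = d$a_SGLT2, X)      # structural regressors
  y <- d$.chg
  PZW <- Z %*% solve(crossprod(Z), crossprod(Z, W))
  bhat <- solve(crossprod(PZW, W), crossprod(PZW, y))
  res <- y - W %*% bhat
  s2 <- sum(res^2) / (nrow(W) - ncol(W))
  Vb <- s2 * solve(crossprod(PZW))
  rownames(Vb) <- colnames(Vb) <- colnames(W)
  b <- setNames(drop(bhat), colnames(W))
  contrasts_from_joint(b, Vb, outcome, scale = "mean difference",
                       estimator = "2SLS", n = nrow(d))
}

#' Multivariable regression assuming no unmeasured confounding
#'
#' The naive comparator: least squares of the change score (continuous) or
#' a Cox model (time to event) on the arm indicators and all measured
#' baseline covariates, with no instrument and no residual terms.
#'
#' @param cohort analysis cohort.
#' @param outcome continuous measure or endpoint name, per `type`.
#' @param type `"continuous"` or `"tte"`.
#' @param timepoint for continuous outcomes.
#' @param covariates covariate columns.
#' @param selection optional [select_covariates_pds()] result.
#' @return an effect-estimate data frame (three contrasts).
#' @export
estimate_naive <- function(cohort, outcome = "HbA1c",
                           type = c("continuous", "tte"),
                           timepoint = "y1",
                           covariates = default_covariates(),
                           selection = NULL) {
  type <- match.arg(type)
  d <- add_arm_indicators(cohort)
  terms <- model_terms(covariates, selection)
  if (type == "continuous") {
    d$.chg <- outcome_change(d, outcome, timepoint)
    use <- complete.cases(d[, c(".chg", covariates)])
    d <- droplevels(d[use, , drop = FALSE])
    fit <- lm(reformulate(c(present_arm_terms(d, "a_"), terms),
                          response = ".chg"), data = d)
    contrasts_from_joint(coef(fit), vcov(fit), outcome,
                         scale = "mean difference", estimator = "naive",
                         n = nrow(d))
  } else {
    tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
    use <- !is.na(d[[tcol]]) & d[[tcol]] > 0 &
      complete.cases(d[, covariates])
    d <- droplevels(d[use, , drop = FALSE])
    f <- as.formula(paste0("survival::Surv(", tcol, ", ", ecol, ") ~ ",
                           paste(c(present_arm_terms(d, "a_"), terms),
                                 collapse = " + ")))
    fit <- survival::coxph(f, data = d, ties = "efron")
    k <- c("a_DPP4", "a_SGLT2")
    contrasts_from_joint(coef(fit)[k], vcov(fit)[k, k], outcome,
                         scale = "log hazard ratio", estimator = "naive",
                         n = nrow(d))
  }
}

#' Inverse-probability-of-treatment weights
#'
#' Propensities from a multinomial logit of arm on the baseline covariates
#' (no instrument terms). Non-stabilised weights are `1 / p(assigned arm)`;
#' stabilised weights multiply by the marginal arm share. Optional
#' asymmetric trimming truncates the weights at the given lower/upper
#' quantiles within each arm.
#'
#' @param cohort analysis cohort (complete cases on the covariates).
#' @param covariates covariate columns.
#' @param stabilize logical.
#' @param trim `NULL` or a length-2 quantile pair, e.g. `c(0.01, 0.99)`.
#' @return the cohort restricted to the estimation sample, with a
#'   `.weight` column.
#' @export
compute_iptw_weights <- function(cohort, covariates = default_covariates(),
                                 stabilize = TRUE, trim = NULL) {
  d <- droplevels(cohort[complete.cases(cohort[, covariates]), , drop = FALSE])
  fit <- nnet::multinom(reformulate(covariates, response = "arm"), data = d,
                        trace = FALSE, maxit = 500, reltol = 1e-12)
  p <- fitted(fit)[, ARMS, drop = FALSE]
  p_assigned <- p[cbind(seq_len(nrow(d)), match(as.character(d$arm), ARMS))]
  if (any(p_assigned < 1e-12))
    stop("propensity of the assigned arm numerically 0; ",
         "trim the sample or revise the propensity model")
  w <- 1 / p_assigned
  if (stabilize) {
    share <- prop.table(table(factor(d$arm, levels = ARMS)))
    w <- w * as.numeric(share[as.character(d$arm)])
  }
  if (!is.null(trim)) {
    stopifnot(length(trim) == 2L, trim[1] < trim[2])
    for (a in ARMS) {
      i <- d$arm == a
      q <- quantile(w[i], trim)
      w[i] <- pmin(pmax(w[i], q[1]), q[2])
    }
  }
  d$.weight <- w
  d
}

#' Inverse probability of treatment weighting
#'
#' Weighted arm contrasts with no further covariate adjustment: weighted
#' least squares of the change score (continuous) or a weighted Cox model
#' (time to event) on the arm indicators alone, with robust (sandwich)
#' variances.
#'
#' @inheritParams estimate_naive
#' @inheritParams compute_iptw_weights
#' @return an effect-estimate data frame (three contrasts).
#' @export
estimate_iptw <- function(cohort, outcome = "HbA1c",
                          type = c("continuous", "tte"),
                          timepoint = "y1",
                          covariates = default_covariates(),
                          stabilize = TRUE, trim = NULL) {
  type <- match.arg(type)
  d <- compute_iptw_weights(cohort, covariates, stabilize, trim)
  d <- add_arm_indicators(d)
  iptw_fit(d, outcome, type, timepoint, terms = NULL, estimator = "IPTW")
}

#' Doubly robust weighted regression
#'
#' The IPT-weighted outcome regression: the weighted model additionally
#' adjusts for the baseline covariates, giving the double-robustness
#' property (consistent if either the propensity model or the outcome
#' model is correctly specified, under no unmeasured confounding).
#'
#' @inheritParams estimate_iptw
#' @param selection optional [select_covariates_pds()] result.
#' @param weights optional data frame from [compute_iptw_weights()]; if
#'   `NULL`, weights are computed with the same covariates.
#' @return an effect-estimate data frame (three contrasts).
#' @export
estimate_weighted_regression <- function(cohort, outcome = "HbA1c",
                                         type = c("continuous", "tte"),
                                         timepoint = "y1",
                                         covariates = default_covariates(),
                                         stabilize = TRUE, trim = NULL,
                                         selection = NULL, weights = NULL) {
  type <- match.arg(type)
  d <- if (is.null(weights))
    compute_iptw_weights(cohort, covariates, stabilize, trim) else weights
  d <- add_arm_indicators(d)
  iptw_fit(d, outcome, type, timepoint,
           terms = model_terms(covariates, selection), estimator = "WR")
}

iptw_fit <- function(d, outcome, type, timepoint, terms, estimator) {
  if (type == "continuous") {
    d$.chg <- outcome_change(d, outcome, timepoint)
    d <- d[!is.na(d$.chg), , drop = FALSE]
    fit <- lm(reformulate(c(present_arm_terms(d, "a_"), terms),
                          response = ".chg"), data = d, weights = d$.weight)
    V <- sandwich::vcovHC(fit, type = "HC0")
    contrasts_from_joint(coef(fit), V, outcome, scale = "mean difference",
                         estimator = estimator, n = nrow(d))
  } else {
    tcol <- paste0(outcome, "_time"); ecol <- paste0(outcome, "_event")
    d <- d[!is.na(d[[tcol]]) & d[[tcol]] > 0, , drop = FALSE]
    f <- as.formula(paste0("survival::Surv(", tcol, ", ", ecol, ") ~ ",
                           paste(c(present_arm_terms(d, "a_"), terms),
                                 collapse = " + ")))
    fit <- survival::coxph(f, data = d, weights = d$.weight, robust = TRUE,
                           ties = "efron")
    k <- c("a_DPP4", "a_SGLT2")
    contrasts_from_joint(coef(fit)[k], vcov(fit)[k, k], outcome,
                         scale = "log hazard ratio", estimator = estimator,
                         n = nrow(d))
  }
}

#' Post-double-selection of covariate expansions by LASSO
#'
#' Builds a candidate dictionary (squares of the numeric base covariates
#' and their pairwise interactions, plus any extra candidates supplied),
#' then runs two cross-validated LASSO fits: the outcome on base +
#' candidates and the treatment (multinomial) on base + candidates, with
#' the base covariates unpenalised so they are never dropped. The selected
#' set is the union of candidate terms active in either fit at the
#' one-standard-error penalty.
#'
#' @param cohort analysis cohort.
#' @param outcome continuous measure name or endpoint, per `type`.
#' @param type `"continuous"` or `"tte"` (for `"tte"` the LASSO outcome is
#'   the event indicator at the capped follow-up, a congenial linearisation).
#' @param timepoint for continuous outcomes.
#' @param covariates base covariate columns (always retained).
#' @param extra_candidates optional character vector of extra formula terms.
#' @param seed fold seed for cross-validation.
#' @return list of class `prefiv_selection` with `base`, `candidates`,
#'   `selected`.
#' @export
select_covariates_pds <- function(cohort, outcome = "HbA1c",
                                  type = c("continuous", "tte"),
                                  timepoint = "y1",
                                  covariates = default_covariates(),
                                  extra_candidates = NULL,
                                  seed = 1L) {
  type <- match.arg(type)
  d <- cohort
  d$.y <- if (type == "continuous") outcome_change(d, outcome, timepoint)
          else d[[paste0(outcome, "_event")]]
  use <- complete.cases(d[, c(".y", covariates)])
  d <- droplevels(d[use, , drop = FALSE])

  num <- covariates[vapply(covariates, function(v) is.numeric(d[[v]]), logical(1))]
  cand <- c(paste0("I(", num, "^2)"),
            if (length(num) > 1)
              utils::combn(num, 2, FUN = function(p) paste(p, collapse = ":")),
            extra_candidates)
  cand <- unique(cand)
  if (!length(cand))
    return(structure(list(base = covariates, candidates = character(),
                          selected = character()),
                     class = "prefiv_selection"))

  f <- reformulate(c(covariates, cand))
  X <- model.matrix(f, data = d)[, -1, drop = FALSE]
  assign <- attr(model.matrix(f, data = d), "assign")[-1]
  labels <- attr(terms(f), "term.labels")
  col_term <- labels[assign]
  pen <- as.numeric(col_term %in% cand)

  set.seed(seed)
  foldid <- sample(rep_len(1:10, nrow(X)))
  active_terms <- function(cvfit) {
    cf <- coef(cvfit, s = "lambda.1se")
    if (is.list(cf)) {
      nz <- Reduce(`|`, lapply(cf, function(m) as.matrix(m)[-1, 1] != 0))
    } else nz <- as.matrix(cf)[-1, 1] != 0
    unique(col_term[nz])
  }
  cv_out <- glmnet::cv.glmnet(X, d$.y, penalty.factor = pen, foldid = foldid)
  sel_out <- intersect(active_terms(cv_out), cand)
  cv_trt <- glmnet::cv.glmnet(X, d$arm, family = "multinomial",
                              penalty.factor = pen, foldid = foldid,
                              type.measure = "deviance")
  sel_trt <- intersect(active_terms(cv_trt), cand)

  structure(list(base = covariates, candidates = cand,
                 selected = union(sel_out, sel_trt)),
            class = "prefiv_selection")
}
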