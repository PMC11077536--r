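## Multiple imputation by chained equations with predictive mean matching,
## stratified by treatment arm and death/censoring status.

#' Imputation specification
#'
#' @param m number of imputed datasets.
#' @param donors donor-pool size for predictive mean matching.
#' @param cycles chained-equation sweeps per imputed dataset.
#' @param strata cohort columns whose interaction defines the imputation
#'   strata; imputation runs fully separately within each stratum.
#' @param targets columns to impute; `NULL` means every clinical-measure
#'   column (`*_base`, `*_y1`, `*_y2`) with at least one missing value.
#' @param predictors named list mapping each target to its predictor
#'   columns; `NULL` builds default sets (see [default_predictor_sets()]).
#'   A target never appears in its own predictor set.
#' @param seed base RNG seed; imputation k uses `seed + k`.
#' @return list with class `prefiv_imputation_spec`.
#' @export
imputation_spec <- function(m = 5, donors = 10, cycles = 10,
                            strata = c("arm", "strata_status"),
                            targets = NULL, predictors = NULL, seed = 1L) {
  stopifnot(m >= 1, donors >= 1, cycles >= 1)
  structure(list(m = as.integer(m), donors = as.integer(donors),
                 cycles = as.integer(cycles), strata = strata,
                 targets = targets, predictors = predictors,
                 seed = as.integer(seed)),
            class = "prefiv_imputation_spec")
}

measure_columns <- function() {
  as.vector(outer(vapply(CONT_MEASURES, measure_prefix, character(1)),
                  c("_base", "_y1", "_y2"), paste0))
}

#' Default predictor sets for the clinical-measure targets
#'
#' Each target is predicted from the same measure at the other timepoints
#' (baseline, one year, two years), the baselines of the other measures,
#' and age and sex. The target itself is always excluded.
#'
#' @param targets character vector of target columns.
#' @param data the cohort (used to keep only available columns).
#' @return named list of predictor character vectors.
#' @export
default_predictor_sets <- function(targets, data) {
  bases <- paste0(vapply(CONT_MEASURES, measure_prefix, character(1)), "_base")
  out <- lapply(targets, function(v) {
    pre <- sub("_(base|y1|y2)$", "", v)
    same <- paste0(pre, c("_base", "_y1", "_y2"))
    preds <- unique(c(setdiff(same, v), bases, "age", "sex"))
    setdiff(intersect(preds, names(data)), v)
  })
  names(out) <- targets
  out
}

#' Make imputation models congenial with the analysis model
#'
#' For a time-to-event analysis, augments every predictor set with the
#' endpoint's event indicator and the Nelson-Aalen cumulative-hazard
#' transform of the follow-up time (added to the data as
#' `cumhaz_<endpoint>`); for a continuous analysis the default sets already
#' carry the same measure at the other timepoints.
#'
#' @param cohort analysis cohort.
#' @param outcome_kind `"continuous"` or `"time-to-event"`.
#' @param endpoint endpoint name (required for time-to-event).
#' @param spec an [imputation_spec()] to augment.
#' @return list with `data` (possibly augmented cohort) and `spec` (with
#'   explicit predictor sets).
#' @export
congeniality_features <- function(cohort, outcome_kind = c("continuous",
                                                           "time-to-event"),
                                  endpoint = NULL,
                                  spec = imputation_spec()) {
  outcome_kind <- match.arg(outcome_kind)
  targets <- spec$targets
  if (is.null(targets)) {
    cand <- intersect(measure_columns(), names(cohort))
    targets <- cand[vapply(cand, function(v) anyNA(cohort[[v]]), logical(1))]
  }
  preds <- spec$predictors
  if (is.null(preds)) preds <- default_predictor_sets(targets, cohort)
  if (outcome_kind == "time-to-event") {
    stopifnot(!is.null(endpoint))
    tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
    sf <- survival::survfit(survival::Surv(cohort[[tcol]],
                                           cohort[[ecol]]) ~ 1,
                            ctype = 1)
    ch <- c(0, sf$cumhaz)[1L + findInterval(cohort[[tcol]], sf$time)]
    hz <- paste0("cumhaz_", endpoint)
    cohort[[hz]] <- ch
    preds <- lapply(preds, function(p) unique(c(p, ecol, hz)))
  }
  spec$targets <- targets
  spec$predictors <- preds
  list(data = cohort, spec = spec)
}

## least-squares coefficients with aliased columns zeroed
ls_coef <- function(X, y) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  b[is.na(b)] <- 0
  b
}

## nearest-`donors` predictive-mean match: for each element of yhat_mis,
## draw one observed y among the `donors` observed rows with closest
## predicted mean (compiled kernel; uniform draws taken from R's RNG so the
## chain stays reproducible from the seed)
pmm_draw <- function(yhat_obs, y_obs, yhat_mis, donors) {
  ord <- order(yhat_obs)
  pmm_match(yhat_obs[ord], y_obs[ord], yhat_mis,
            as.integer(min(donors, length(ord))),
            runif(length(yhat_mis)))
}

impute_stratum <- function(d, targets, preds, donors, cycles, masks) {
  mis <- lapply(targets, function(v) is.na(d[[v]]))
  names(mis) <- targets
  unfillable <- character()
  for (v in targets[vapply(mis, any, logical(1))]) {
    if (all(mis[[v]])) {
      ## a stratum may legitimately have no observed values when every
      ## member is structurally censored at that timepoint; a genuinely
      ## imputable value with an empty donor base is an error
      if (any(mis[[v]] & masks[[v]]))
        stop("stratum has zero observed values for '", v,
             "': cannot impute within this stratum")
      unfillable <- c(unfillable, v)
      next
    }
    ## initial fill: random draw from the stratum's observed marginal
    d[[v]][mis[[v]]] <- sample(d[[v]][!mis[[v]]], sum(mis[[v]]),
                               replace = TRUE)
  }
  active <- setdiff(targets[vapply(mis, any, logical(1))], unfillable)
  dropped <- character()
  for (cy in seq_len(cycles)) {
    for (v in active) {
      p <- setdiff(preds[[v]], unfillable)
      ## drop predictors constant (or still missing) within this stratum
      keep <- vapply(p, function(q) {
        x <- d[[q]]
        if (anyNA(x)) return(FALSE)
        if (is.factor(x) || is.character(x)) length(unique(x)) > 1L
        else sd(x) > 0
      }, logical(1))
      if (any(!keep)) dropped <- union(dropped, p[!keep])
      p <- p[keep]
      X <- if (length(p))
        model.matrix(reformulate(p), data = d) else
        matrix(1, nrow(d), 1L)
      m_v <- mis[[v]]
      if (is.numeric(d[[v]])) {
        b <- ls_coef(X[!m_v, , drop = FALSE], d[[v]][!m_v])
        yhat <- drop(X %*% b)
        d[[v]][m_v] <- pmm_draw(yhat[!m_v], d[[v]][!m_v], yhat[m_v], donors)
      } else {
        ## per-category score matching on predicted class probabilities
        df_fit <- data.frame(.y = d[[v]][!m_v],
                             X[!m_v, -1, drop = FALSE])
        fit <- nnet::multinom(.y ~ ., data = df_fit, trace = FALSE,
                              maxit = 200)
        P_obs <- predict(fit, newdata = data.frame(X[!m_v, -1, drop = FALSE]),
                         type = "probs")
        P_mis <- predict(fit, newdata = data.frame(X[m_v, -1, drop = FALSE]),
                         type = "probs")
        if (is.null(dim(P_obs))) { P_obs <- cbind(1 - P_obs, P_obs) }
        if (is.null(dim(P_mis))) P_mis <- matrix(P_mis, ncol = ncol(P_obs))
        y_obs <- d[[v]][!m_v]
        k <- min(donors, length(y_obs))
        pick <- apply(P_mis, 1L, function(pr) {
          dist <- colSums((t(P_obs) - pr)^2)
          pool <- order(dist)[seq_len(k)]
          pool[sample.int(k, 1L)]
        })
        d[[v]][m_v] <- y_obs[pick]
      }
    }
  }
  ## working fills of structurally censored entries are reverted: those
  ## values are undefined, not missing
  for (v in targets) d[[v]][mis[[v]] & !masks[[v]]] <- NA
  attr(d, "dropped_predictors") <- dropped
  d
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Within each stratum (by default treatment arm crossed with
#' death/censoring status), missing values of the target columns are filled
#' by chained equations: each sweep regresses a target on its predictor set
#' over the observed rows, predicts the mean for every row, and replaces
#' each missing entry with the observed value of one of the `donors`
#' nearest-predicted-mean rows, drawn uniformly. Categorical targets are
#' matched on predicted class-probability scores. The initial fill draws
#' from the stratum's observed marginal. Event times and indicators are
#' never imputed, and follow-up values flagged structurally censored
#' (`censored_by_y1` / `censored_by_y2`) are undefined rather than missing:
#' they are given only a temporary working fill during the sweeps and
#' returned as NA. Every imputed value is by construction a member of the
#' observed within-stratum support. The `m` completions are independent
#' chains seeded `seed + 1 ... seed + m`.
#'
#' @param cohort analysis cohort (or any data frame with the target,
#'   predictor and strata columns).
#' @param spec an [imputation_spec()].
#' @return list of `m` completed data frames; the imputation log (dropped
#'   zero-variance predictors, per-stratum imputation counts) is attached
#'   as attribute `log`.
#' @export
mice_pmm <- function(cohort, spec = imputation_spec()) {
  stopifnot(inherits(spec, "prefiv_imputation_spec"))
  targets <- spec$targets
  if (is.null(targets)) {
    cand <- intersect(measure_columns(), names(cohort))
    targets <- cand[vapply(cand, function(v) anyNA(cohort[[v]]), logical(1))]
  }
  if (!length(targets)) {
    out <- replicate(spec$m, cohort, simplify = FALSE)
    attr(out, "log") <- data.frame(stratum = character(),
                                   target = character(),
                                   n_imputed = integer())
    return(out)
  }
  preds <- spec$predictors
  if (is.null(preds)) preds <- default_predictor_sets(targets, cohort)
  for (v in targets)
    if (v %in% preds[[v]])
      stop("predictor set of '", v, "' contains itself")

  ## follow-up values flagged censored-by-t are structurally undefined and
  ## are never imputation targets (they stay NA); they may still receive a
  ## temporary working fill so chained sweeps have complete predictors
  masks <- lapply(targets, function(v) {
    tp <- sub("^.*_", "", v)
    flag <- paste0("censored_by_", tp)
    if (tp %in% c("y1", "y2") && flag %in% names(cohort))
      !cohort[[flag]] else rep(TRUE, nrow(cohort))
  })
  names(masks) <- targets

  strata <- interaction(cohort[, spec$strata, drop = FALSE], drop = TRUE)
  idx_by_stratum <- split(seq_len(nrow(cohort)), strata)
  logs <- list()
  for (s in names(idx_by_stratum)) {
    rows <- idx_by_stratum[[s]]
    n_imp <- vapply(targets, function(v)
      sum(is.na(cohort[[v]][rows]) & masks[[v]][rows]), integer(1))
    logs[[s]] <- data.frame(stratum = s, target = targets,
                            n_imputed = unname(n_imp),
                            stringsAsFactors = FALSE)
  }

  out <- vector("list", spec$m)
  for (k in seq_len(spec$m)) {
    set.seed(spec$seed + k)
    comp <- cohort
    for (s in names(idx_by_stratum)) {
      rows <- idx_by_stratum[[s]]
      comp[rows, ] <- impute_stratum(cohort[rows, , drop = FALSE],
                                     targets, preds,
                                     spec$donors, spec$cycles,
                                     lapply(masks, `[`, rows))
    }
    out[[k]] <- comp
  }
  attr(out, "log") <- do.call(rbind, c(logs, list(make.row.names = FALSE)))
  out
}
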