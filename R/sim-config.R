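## Simulation configuration for the synthetic linked-data generator.

#' Drug classes compared (reference arm first)
#' @keywords internal
ARMS <- c("SU", "DPP4", "SGLT2")

#' Continuous clinical measures carried through the pipeline
#' @keywords internal
CONT_MEASURES <- c("HbA1c", "SBP", "DBP", "BMI", "eGFR")

## hazard-generated endpoints in the raw tables; composite endpoints
## (MACE, MAKE, 40% eGFR decline) are derived by the cohort builder
HAZARD_ENDPOINTS <- c("hf", "mi", "stroke", "death_cvd", "death_other")

#' Default true mean differences for continuous outcomes (vs sulfonylureas)
#'
#' Change-from-baseline differences, per non-reference arm, on each measure's
#' clinical scale (HbA1c mmol/mol, SBP/DBP mm Hg, BMI kg/m2, eGFR
#' mL/min/1.73m2). Magnitudes are in the range reported for these drug
#' classes in routine care.
#'
#' @return matrix with rows `CONT_MEASURES`, columns `DPP4`, `SGLT2`.
#' @export
default_mean_differences <- function() {
  m <- rbind(
    HbA1c = c(DPP4 = -1.0, SGLT2 = -3.0),
    SBP   = c(DPP4 = -0.3, SGLT2 = -2.1),
    DBP   = c(DPP4 =  0.0, SGLT2 = -1.0),
    BMI   = c(DPP4 = -0.8, SGLT2 = -1.6),
    eGFR  = c(DPP4 =  0.0, SGLT2 =  1.4)
  )
  m
}

#' Default true log hazard ratios for event endpoints (vs sulfonylureas)
#'
#' @return matrix with rows `hf`, `mi`, `stroke`, `death_cvd`, `death_other`
#'   and columns `DPP4`, `SGLT2`.
#' @export
default_log_hazard_ratios <- function() {
  rbind(
    hf          = c(DPP4 = 0, SGLT2 = log(0.46)),
    mi          = c(DPP4 = 0, SGLT2 = 0),
    stroke      = c(DPP4 = 0, SGLT2 = 0),
    death_cvd   = c(DPP4 = 0, SGLT2 = log(0.8)),
    death_other = c(DPP4 = 0, SGLT2 = 0)
  )
}

#' Missingness specification for follow-up continuous measures
#'
#' Rates are the fractions of follow-up values deleted per measure and
#' timepoint. Defaults reproduce the missingness levels typical of routine
#' primary-care follow-up of these measures at one and two years (roughly a
#' third to a half of values absent). Mechanism `"MAR"` makes deletion
#' probability depend, on the log-odds scale, on the (always observed)
#' baseline value of the same measure; `"MCAR"` deletes uniformly.
#'
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param rates matrix of deletion rates, rows `CONT_MEASURES`, columns
#'   `y1`, `y2`.
#' @param mar_slope log-odds change in deletion probability per standard
#'   deviation of the baseline value (only used for `"MAR"`).
#' @return list with class `prefiv_missingness`.
#' @export
missingness_spec <- function(mechanism = c("MAR", "MCAR"),
                             rates = default_missing_rates(),
                             mar_slope = 0.5) {
  mechanism <- match.arg(mechanism)
  stopifnot(is.matrix(rates),
            all(rownames(rates) == CONT_MEASURES),
            all(colnames(rates) == c("y1", "y2")),
            all(rates >= 0 & rates <= 1))
  structure(list(mechanism = mechanism, rates = rates,
                 mar_slope = mar_slope),
            class = "prefiv_missingness")
}

#' @rdname missingness_spec
#' @export
default_missing_rates <- function() {
  rbind(
    HbA1c = c(y1 = 0.337, y2 = 0.364),
    SBP   = c(y1 = 0.336, y2 = 0.372),
    DBP   = c(y1 = 0.336, y2 = 0.372),
    BMI   = c(y1 = 0.447, y2 = 0.478),
    eGFR  = c(y1 = 0.374, y2 = 0.400)
  )
}

#' Simulation configuration
#'
#' Defines the full data-generating process for the synthetic linked tables:
#' prescriber groups (CCGs) nested in regions with Dirichlet-distributed
#' prescribing preferences over the three drug classes, three-arm treatment
#' assignment by multinomial logit driven by the group preference, observed
#' covariates, and a latent standard-normal confounder U; continuous
#' outcomes as baseline + drift + arm effect + covariate effects + loading*U
#' + noise; event times from proportional hazards with an individual gamma
#' frailty; independent exponential dropout.
#'
#' @param n_patients number of patients to simulate.
#' @param n_ccgs number of prescriber groups (clinical commissioning groups);
#'   must be at least 2 for the instrument to be defined.
#' @param n_regions number of regions the CCGs are nested in.
#' @param study_start,study_end index-date window (Date).
#' @param tendency_concentration positive length-3 Dirichlet concentration
#'   (SU, DPP4, SGLT2) for the cross-CCG distribution of prescribing
#'   preference triples; the mean preference is the normalised vector.
#' @param instrument_strength nonnegative scale on `log(preference)` in the
#'   assignment logit; 0 disconnects assignment from the CCG preference, 1
#'   makes assignment probabilities proportional to the preference triple
#'   (absent covariates), larger values sharpen the dependence.
#' @param confounding_observed named vector `c(age=, hba1c=)`: strength with
#'   which standardised age and baseline HbA1c shift treatment choice (they
#'   also enter all outcome models, making them observed confounders).
#' @param confounding_unobserved nonnegative scale of the latent confounder
#'   U on both the treatment log-odds and every outcome (0 switches
#'   unmeasured confounding off).
#' @param true_mean_differences matrix as [default_mean_differences()].
#' @param true_log_hazard_ratios matrix as [default_log_hazard_ratios()].
#' @param frailty_variance variance of the individual gamma frailty (mean 1)
#'   shared across a patient's event hazards; 0 gives conditionally
#'   independent exponential event times.
#' @param baseline_event_rate named events-per-person-year rates for the five
#'   hazard-generated endpoints.
#' @param covariate_log_hazard named vector of log-hazard-ratio effects of
#'   observed covariates on every event hazard (currently `age`, per decade
#'   over 60); set to 0 for covariate-free exponential event times.
#' @param missingness a [missingness_spec()].
#' @param censoring_rate per-year rate of the exponential dropout
#'   (deregistration) process.
#' @param ineligible_fraction fraction of patients given a randomly chosen
#'   eligibility violation (pregnancy record, broken metformin continuity,
#'   missing hospital linkage) so cohort attrition is exercised; low-eGFR
#'   exclusions arise naturally from the eGFR distribution.
#' @param arm_offsets named intercepts `c(DPP4=, SGLT2=)` added to the
#'   assignment log-odds; the defaults centre the marginal arm shares at
#'   roughly 34/45/21 percent (SU/DPP4/SGLT2) under the default
#'   configuration.
#' @param sglt2_year_trend optional linear per-year additive drift in the
#'   SGLT2 preference share (uptake trend); 0 (off) by default.
#' @param seed integer seed; the generator is deterministic given the config.
#' @return list with class `prefiv_sim_config`.
#' @export
sim_config <- function(n_patients = 5000L,
                       n_ccgs = 100L,
                       n_regions = 7L,
                       study_start = as.Date("2015-01-01"),
                       study_end = as.Date("2020-12-31"),
                       tendency_concentration = c(SU = 6.8, DPP4 = 9.1, SGLT2 = 4.1),
                       instrument_strength = 3,
                       confounding_observed = c(age = 0.3, hba1c = 0.15),
                       confounding_unobserved = 0.5,
                       true_mean_differences = default_mean_differences(),
                       true_log_hazard_ratios = default_log_hazard_ratios(),
                       frailty_variance = 0.5,
                       baseline_event_rate = c(hf = 0.010, mi = 0.008,
                                               stroke = 0.007,
                                               death_cvd = 0.004,
                                               death_other = 0.012),
                       covariate_log_hazard = c(age = 0.3),
                       missingness = missingness_spec(),
                       censoring_rate = 0.08,
                       ineligible_fraction = 0,
                       arm_offsets = c(DPP4 = -0.1485, SGLT2 = 0.7472),
                       sglt2_year_trend = 0,
                       seed = 1L) {
  if (n_ccgs < 2L)
    stop("n_ccgs must be at least 2: the prescribing-preference instrument ",
         "is undefined with a single prescriber group")
  if (any(tendency_concentration <= 0))
    stop("tendency_concentration entries must be strictly positive")
  if (frailty_variance < 0) stop("frailty_variance must be nonnegative")
  if (instrument_strength < 0) stop("instrument_strength must be nonnegative")
  if (censoring_rate < 0) stop("censoring_rate must be nonnegative")
  if (ineligible_fraction < 0 || ineligible_fraction > 1)
    stop("ineligible_fraction must be in [0, 1]")
  stopifnot(inherits(missingness, "prefiv_missingness"),
            all(rownames(true_mean_differences) == CONT_MEASURES),
            all(rownames(true_log_hazard_ratios) == HAZARD_ENDPOINTS),
            all(baseline_event_rate >= 0),
            study_end > study_start)
  structure(list(
    n_patients = as.integer(n_patients),
    n_ccgs = as.integer(n_ccgs),
    n_regions = as.integer(n_regions),
    study_start = study_start, study_end = study_end,
    tendency_concentration = tendency_concentration,
    instrument_strength = instrument_strength,
    confounding_observed = confounding_observed,
    confounding_unobserved = confounding_unobserved,
    true_mean_differences = true_mean_differences,
    true_log_hazard_ratios = true_log_hazard_ratios,
    frailty_variance = frailty_variance,
    baseline_event_rate = baseline_event_rate,
    covariate_log_hazard = covariate_log_hazard,
    missingness = missingness,
    censoring_rate = censoring_rate,
    ineligible_fraction = ineligible_fraction,
    arm_offsets = arm_offsets,
    sglt2_year_trend = sglt2_year_trend,
    seed = as.integer(seed)
  ), class = "prefiv_sim_config")
}

## Outcome loadings of the latent confounder U, per unit of
## `confounding_unobserved`. U is oriented as latent "health" (diet,
## exercise, engagement with care): it raises the odds of being prescribed
## the newer classes and independently improves every outcome. Values are
## fixed design constants of the generator, not tuning knobs.
U_TREAT_LOADING <- c(DPP4 = 1.0, SGLT2 = 2.0)   # log-odds shift per U, per unit conf_u
U_CONT_LOADING <- c(HbA1c = -5.0, SBP = -3.0, DBP = -1.5,
                    BMI = -1.0, eGFR = 2.0)      # change-score shift per U, per unit conf_u
U_TTE_LOADING <- -1.6                            # log-hazard shift per U, per unit conf_u

## chronic-kidney-disease progressor subpopulation: probability of a steep
## eGFR decline trajectory (roughly -35% of baseline by one year, -55% by
## two years), by arm; the lower SGLT2 probability encodes the
## kidney-protective pattern of that class
PROG_PROB <- c(SU = 0.05, DPP4 = 0.05, SGLT2 = 0.03)
PROG_DECLINE <- c(y1 = 0.35, y2 = 0.55)
PROG_NOISE_SD <- 6

## baseline-to-follow-up drifts (change-score intercepts) and noise SDs
CONT_DRIFT <- rbind(
  HbA1c = c(y1 = -12, y2 = -10),
  SBP   = c(y1 = -1,  y2 = -1),
  DBP   = c(y1 = -0.5, y2 = -0.5),
  BMI   = c(y1 = -0.3, y2 = -0.2),
  eGFR  = c(y1 = -2,  y2 = -3)
)
CONT_NOISE_SD <- c(HbA1c = 10, SBP = 12, DBP = 8, BMI = 2, eGFR = 8)
## regression-to-the-mean pull of the change score toward the cohort-mean baseline
CONT_RTM <- c(HbA1c = -0.30, SBP = -0.25, DBP = -0.25, BMI = -0.02, eGFR = -0.10)
## age effect (per decade over 60) on each change score
CONT_AGE <- c(HbA1c = 0.5, SBP = 0.5, DBP = -0.3, BMI = -0.1, eGFR = -1.0)
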