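#' @importFrom stats approx pnorm qnorm qpois runif rbinom setNames rgamma rbeta rnorm
#' @importFrom utils read.csv write.csv modifyList
NULL

STAGES <- 1:4
STAGE_LABELS <- c("stage1", "stage2", "stage3", "stage4")
SEXES <- c("male", "female")
AGE_BANDS <- c("35-39", "40-49", "50-59", "60-69", "70-80")
UTILITY_BANDS <- c("35-39", "40-49", "50-59", "60-69", "70-79", "80+")
COST_CATEGORIES <- c("screening", "diagnosis", "maintenance", "treatment",
                     "exacerbation", "complication")

#' Default model parameters
#'
#' Builds the full parameter registry of the microsimulation: COPD
#' epidemiology (prevalence, incidence, FEV1 percent-predicted
#' distributions), natural history (stage-specific FEV1 decline,
#' exacerbation rates, mortality hazard ratios), the care cascade
#' (screening-test accuracy, follow-up and treatment-uptake
#' probabilities, per-cycle symptom-diagnosis probabilities, treatment
#' archetypes), utilities, unit costs, and simulation controls.
#'
#' All probabilities are proportions in `[0, 1]`, rates are annual events
#' per person-year, costs are 2022 US dollars, and FEV1 decline is in
#' ml/year.  Every field can be overridden through [load_parameters()].
#'
#' @return A named list of class `copd_params`.
#' @export
default_parameters <- function() {
  life_table <- read.csv(
    system.file("extdata", "life_table_synthetic.csv", package = "copdsim"),
    stringsAsFactors = FALSE)

  p <- list(
    ## epidemiology -----------------------------------------------------
    # proportion with COPD by sex and age band
    prevalence = list(
      male   = c(0.0186, 0.0745, 0.1557, 0.2708, 0.4296),
      female = c(0.0179, 0.0314, 0.0596, 0.1158, 0.2027)),
    # annual incidence rate per person-year (printed per 100,000)
    incidence = list(
      male   = c(50.42, 165.64, 442.46, 1053.21, 5056.24) / 1e5,
      female = c(48.50,  69.84, 169.44,  450.33, 2385.55) / 1e5),
    fev1pct_initial = list(
      male   = c(mean = 0.797, sd = 0.206),
      female = c(mean = 0.835, sd = 0.206)),
    # male sd is 0.0906, not the printed 0.906 (a sd of 0.906 would make
    # most incident draws non-physiologic); see package vignette
    fev1pct_incident = list(
      male   = c(mean = 1.014, sd = 0.0906),
      female = c(mean = 1.034, sd = 0.107)),
    fev1pct_bounds = c(0.05, 1.30),
    # the oldest-band incidence estimate covers ages 70-85; no new
    # incidence is generated beyond this age
    incidence_max_age = 85,
    initial_diagnosed = c(0.0063, 0.0200, 0.1287, 0.2104),

    ## natural history --------------------------------------------------
    decline_mean = c(40, 60, 56, 34),   # ml/yr by GOLD stage
    decline_sd   = c(5, 5, 5, 5),
    exac_rate_nonsevere = c(0.71, 1.01, 1.39, 1.82),
    exac_rate_severe    = c(0.11, 0.16, 0.22, 0.28),
    exac_decline_multiplier = 1.957,    # +95.7% decline after an exacerbation
    exac_effect_months  = 12,
    treat_effect_months = 12,
    mortality_hr = c(1.2, 1.6, 2.7, 2.7),
    life_table = life_table,

    ## predicted FEV1 reference (liters at age 35, slope liters/yr)
    pred_fev1 = list(
      male   = c(at35 = 4.0, slope = -0.025),
      female = c(at35 = 2.9, slope = -0.020)),

    ## care cascade -----------------------------------------------------
    sq_sens = 0.57, sq_spec = 0.82,
    spiro_sens = 0.85, spiro_spec = 0.85,
    p_followup_dx  = 0.40,
    p_treat_uptake = 0.30,
    # per-cycle symptom-diagnosis probabilities by stage: output of
    # calibrate_symptom_diagnosis() against the awareness targets in
    # initial_diagnosed (200k cohort, 40 cycles, seed 20; see vignette).
    # Stage 4 needs little symptom-diagnosis pressure because most aware
    # stage-4 patients arrive already diagnosed from stage 3.
    p_symptom_dx = c(0.000128, 0.000434, 0.009512, 0.001068),
    treatments = data.frame(
      id = 1:5,
      decline_reduction = c(73, 105, 137, 169, 201),
      rr_exac = c(0.92, 0.845, 0.77, 0.695, 0.62),
      rr_mort = c(0.99, 0.92, 0.85, 0.78, 0.71),
      monthly_cost = c(20.21, 41.30, 62.40, 83.49, 104.58)),
    # distribution over treatment archetypes by stage (rows = stage)
    treat_mix = rbind(
      c(0.30, 0.30, 0.20, 0.15, 0.05),
      c(0.20, 0.25, 0.25, 0.20, 0.10),
      c(0.10, 0.20, 0.25, 0.25, 0.20),
      c(0.05, 0.15, 0.20, 0.30, 0.30)),

    ## utilities ----------------------------------------------------------
    utility_baseline = c(0.962, 0.955, 0.944, 0.925, 0.895, 0.855),
    utility_stage = c(0.806, 0.767, 0.704, 0.616),
    # "multiplier": stage utility acts multiplicatively on the age-band
    # baseline, normalised so the printed stage values are reproduced at
    # the reference band; "absolute": stage utility used as-is
    utility_stage_mode = "multiplier",
    utility_ref_band = "60-69",
    disutility_exac_nonsevere = 0.010,
    disutility_exac_severe    = 0.040,

    ## costs (2022 USD) ---------------------------------------------------
    cost_sq = 0.72, cost_spiro = 2.90, cost_setup = 4.00,
    cost_dx_spirometry = 26.93,
    cost_maint_monthly = c(7.66, 24.25, 34.56, 54.04),
    cost_exac_nonsevere = 68.24,
    cost_exac_severe = 2987.06,
    cost_complication_monthly = c(0, 0, 0, 0),
    # routine maintenance accrues for every COPD patient (undiagnosed
    # respiratory care included); set TRUE to restrict to the diagnosed
    maint_diagnosed_only = FALSE,
    # program setup is a one-time per-person charge at the first round;
    # set TRUE to charge it at every screening round
    setup_per_round = FALSE,

    ## economics / simulation controls ------------------------------------
    discount_rate = 0.03,
    cycle_years = 0.25,
    wtp = 38441,
    cohort_size = 1e6,
    age_range = c(35, 80),
    max_age = 110,
    p_male = 0.511,
    band_weights = c(0.130, 0.271, 0.292, 0.193, 0.114),
    seed_policy = "common_random_numbers")

  class(p) <- "copd_params"
  p
}

#' Load and validate a parameter configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills every
#' unspecified field with its default, and validates the result.  The
#' token `"defaults"` returns the default set.
#'
#' @param source `"defaults"`, a file path to a YAML/JSON document, or a
#'   named list of overrides.
#' @return A validated `copd_params` object.
#' @export
load_parameters <- function(source = "defaults") {
  base <- default_parameters()
  if (identical(source, "defaults")) return(validate_parameters(base))
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) stop("configuration file not found: ", source)
    overrides <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::fromJSON(source, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    overrides <- source
  } else {
    stop("source must be \"defaults\", a file path, or a named list")
  }
  validate_parameters(merge_parameters(base, overrides))
}

# deep-merge overrides into the defaults; unknown field names are errors
merge_parameters <- function(base, overrides) {
  if (length(overrides) == 0) return(base)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (is.null(ov)) stop("field '", nm, "' set to null; every field needs a value")
    if (nm == "life_table") {
      base[[nm]] <- as.data.frame(ov, stringsAsFactors = FALSE)
    } else if (nm == "treatments") {
      base[[nm]] <- as.data.frame(ov, stringsAsFactors = FALSE)
    } else if (nm == "treat_mix") {
      base[[nm]] <- if (is.matrix(ov)) ov else
        do.call(rbind, lapply(ov, function(r) as.numeric(unlist(r))))
    } else if (is.list(base[[nm]]) && is.list(ov) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- modifyList(base[[nm]], ov)
    } else {
      base[[nm]] <- if (is.list(ov)) unlist(ov) else ov
    }
  }
  class(base) <- "copd_params"
  base
}

#' Validate a parameter set
#'
#' Checks the structural invariants: probabilities in `[0, 1]`, rates and
#' costs non-negative, utilities in `[0, 1]`, treatment mixes summing to
#' one per stage, and mortality hazard ratios at least 1.  Prevalence or
#' incidence that is not non-decreasing with age raises a warning only.
#'
#' @param params a `copd_params` list.
#' @return The validated object (invisibly the same list).
#' @export
validate_parameters <- function(params) {
  chk_prob <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop("validation error: ", what, " must lie in [0, 1]")
  }
  chk_nonneg <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0))
      stop("validation error: ", what, " must be non-negative")
  }
  for (sx in SEXES) {
    chk_prob(params$prevalence[[sx]], paste("prevalence", sx))
    chk_nonneg(params$incidence[[sx]], paste("incidence", sx))
    if (is.unsorted(params$prevalence[[sx]]))
      warning("prevalence not non-decreasing with age for ", sx)
    if (is.unsorted(params$incidence[[sx]]))
      warning("incidence not non-decreasing with age for ", sx)
  }
  chk_prob(c(params$sq_sens, params$sq_spec, params$spiro_sens,
             params$spiro_spec, params$p_followup_dx, params$p_treat_uptake,
             params$p_symptom_dx, params$initial_diagnosed),
           "test accuracies and cascade probabilities")
  chk_prob(params$life_table$annual_mortality_probability, "life-table entries")
  chk_prob(c(params$utility_baseline, params$utility_stage,
             params$disutility_exac_nonsevere, params$disutility_exac_severe),
           "utilities")
  chk_nonneg(c(params$cost_sq, params$cost_spiro, params$cost_setup,
               params$cost_dx_spirometry, params$cost_maint_monthly,
               params$cost_exac_nonsevere, params$cost_exac_severe,
               params$cost_complication_monthly,
               params$treatments$monthly_cost), "costs")
  chk_nonneg(c(params$exac_rate_nonsevere, params$exac_rate_severe,
               params$decline_mean, params$decline_sd,
               params$discount_rate), "rates")
  if (any(params$mortality_hr < 1))
    stop("validation error: mortality_hr must be >= 1 for every stage")
  mix <- params$treat_mix
  if (!is.matrix(mix) || nrow(mix) != 4 ||
      any(abs(rowSums(mix) - 1) > 1e-8) || any(mix < 0))
    stop("validation error: treat_mix rows must be distributions summing to 1")
  if (!params$utility_stage_mode %in% c("multiplier", "absolute"))
    stop("validation error: utility_stage_mode must be 'multiplier' or 'absolute'")
  if (params$cycle_years <= 0) stop("validation error: cycle_years must be > 0")
  if (params$age_range[1] < 35 || params$age_range[2] > params$max_age)
    stop("validation error: age_range must lie within [35, max_age]")
  params
}

#' Serialize a parameter set to YAML or JSON
#'
#' @param params a `copd_params` object.
#' @param path output file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  x$treat_mix <- lapply(seq_len(nrow(params$treat_mix)),
                        function(i) params$treat_mix[i, ])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  } else {
    yaml::write_yaml(x, path, precision = 12)
  }
  invisible(path)
}

#' Convert an annual event rate to a per-cycle probability
#'
#' Uses the constant-hazard (exponential) transform
#' `1 - exp(-rate * cycle_years)`, the standard conversion in
#' discrete-time state-transition models; it is monotone in the rate and
#' always yields a probability in `[0, 1)`.
#'
#' @param rate annual events per person-year (non-negative).
#' @param cycle_years cycle length in years (positive).
#' @return Per-cycle probability.
#' @export
annual_rate_to_cycle_prob <- function(rate, cycle_years = 0.25) {
  if (any(rate < 0)) stop("domain error: rate must be non-negative")
  if (any(cycle_years <= 0)) stop("domain error: cycle_years must be positive")
  1 - exp(-rate * cycle_years)
}

#' Discount factor at time t
#'
#' `(1 + rate)^(-t)` for outcomes accruing `t` years after simulation
#' start, with a 3% annual rate by default.
#'
#' @param t years since simulation start (non-negative).
#' @param rate annual discount rate (non-negative proportion).
#' @return Discount factor in `(0, 1]`.
#' @export
discount_factor <- function(t, rate = 0.03) {
  if (any(t < 0)) stop("domain error: t must be non-negative")
  if (any(rate < 0)) stop("domain error: rate must be non-negative")
  (1 + rate)^(-t)
}

# age band index (prevalence/incidence bands); ages past 80 reuse the
# 70-80 band
age_band <- function(age) {
  findInterval(age, c(35, 40, 50, 60, 70))
}

# utility age band index (six bands incl. 70-79 and 80+)
utility_band <- function(age) {
  findInterval(age, c(35, 40, 50, 60, 70, 80))
}

# short stable digest of a full parameter set
params_hash <- function(params) {
  rlang::hash(unclass(params))
}

# digest of only the cohort-generating fields, so care-cascade overrides
# (e.g. linkage-to-care scenarios) can reuse a generated cohort
cohort_params_hash <- function(params) {
  rlang::hash(params[c("prevalence", "fev1pct_initial", "fev1pct_bounds",
                       "initial_diagnosed", "p_male", "band_weights",
                       "age_range")])
}

#' @export
print.copd_params <- function(x, ...) {
  cat("<copd_params>\n")
  cat(sprintf("  cohort_size %g, ages %d-%d, cycle %.2f y, discount %.1f%%, WTP $%g/QALY\n",
              x$cohort_size, x$age_range[1], x$age_range[2], x$cycle_years,
              100 * x$discount_rate, x$wtp))
  cat(sprintf("  COPD-SQ sens/spec %.2f/%.2f, spirometer %.2f/%.2f, follow-up %.0f%%, uptake %.0f%%\n",
              x$sq_sens, x$sq_spec, x$spiro_sens, x$spiro_spec,
              100 * x$p_followup_dx, 100 * x$p_treat_uptake))
  invisible(x)
}
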