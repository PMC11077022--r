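#' Per-cycle utility weight
#'
#' Persons without COPD carry the age-band baseline utility of the
#' general population.  Persons with COPD carry the stage-adjusted value:
#' in `"multiplier"` mode (default) the stage utilities act as
#' multipliers on the age-band baseline, normalised so the printed stage
#' values are reproduced exactly at the reference age band; in
#' `"absolute"` mode the stage values are used as-is.  Exacerbations this
#' cycle subtract an absolute per-event decrement.  The result is clamped
#' to `[0, 1]`.
#'
#' @param stage 0 for no COPD, else GOLD stage 1-4 (vectorized).
#' @param age years.
#' @param n_nonsevere,n_severe exacerbation counts this cycle.
#' @param params parameter set.
#' @return Utility weight (QALY per year of occupancy).
#' @export
cycle_utility <- function(stage, age, n_nonsevere = 0, n_severe = 0,
                          params = default_parameters()) {
  w <- params$utility_baseline[utility_band(age)]
  ci <- which(stage > 0)
  if (length(ci)) {
    if (params$utility_stage_mode == "multiplier") {
      ref <- params$utility_baseline[match(params$utility_ref_band, UTILITY_BANDS)]
      w[ci] <- w[ci] * (params$utility_stage / ref)[stage[ci]]
    } else {
      w[ci] <- params$utility_stage[stage[ci]]
    }
  }
  w <- w - n_nonsevere * params$disutility_exac_nonsevere -
    n_severe * params$disutility_exac_severe
  pmax(pmin(w, 1), 0)
}

#' Per-cycle costs by category
#'
#' Monthly-rated categories (maintenance, treatment, complication)
#' accrue `monthly * 3 * frac` where `frac` is 1 for a full cycle and
#' 0.5 for persons dying within the cycle; maintenance accrues for
#' diagnosed COPD persons only by default (payer-perspective COPD-coded
#' claims; set `maint_diagnosed_only = FALSE` to charge all COPD
#' persons).  Exacerbation costs are per event and charge in full.
#' Screening/diagnosis charges are passed through from the care cascade.
#'
#' @param stage 0 for no COPD, else GOLD stage 1-4 (vectorized).
#' @param diagnosed logical.
#' @param treat_id treatment archetype id (0 untreated).
#' @param n_nonsevere,n_severe exacerbation counts this cycle.
#' @param frac cycle-occupancy fraction (0.5 for deaths in cycle).
#' @param params parameter set.
#' @param screening_charge,diagnosis_charge pass-through charges (USD,
#'   non-negative).
#' @return Named list of per-person cost vectors, one per category.
#' @export
cycle_cost <- function(stage, diagnosed, treat_id, n_nonsevere = 0,
                       n_severe = 0, frac = 1,
                       params = default_parameters(),
                       screening_charge = 0, diagnosis_charge = 0) {
  if (any(screening_charge < 0) || any(diagnosis_charge < 0))
    stop("domain error: charges must be non-negative")
  m <- length(stage)
  maint <- trt <- comp <- numeric(m)
  ci <- which(stage > 0)
  if (length(ci)) {
    pays <- if (params$maint_diagnosed_only) ci[diagnosed[ci]] else ci
    maint[pays] <- params$cost_maint_monthly[stage[pays]] * 3
    comp[ci] <- params$cost_complication_monthly[stage[ci]] * 3
  }
  ti <- which(treat_id > 0)
  if (length(ti)) trt[ti] <- params$treatments$monthly_cost[treat_id[ti]] * 3
  list(screening = rep_len(screening_charge, m),
       diagnosis = rep_len(diagnosis_charge, m),
       maintenance = maint * frac,
       treatment = trt * frac,
       exacerbation = n_nonsevere * params$cost_exac_nonsevere +
         n_severe * params$cost_exac_severe,
       complication = comp * frac)
}

#' Discounted sum of a payment/QALY stream
#'
#' `sum(amount * (1 + rate)^(-time))`; linear in the amounts.
#'
#' @param time years since simulation start (non-negative, vectorized).
#' @param amount amounts accruing at those times.
#' @param rate annual discount rate.
#' @return Discounted total.
#' @export
accumulate_discounted <- function(time, amount, rate = 0.03) {
  if (any(time < 0)) stop("domain error: time must be non-negative")
  sum(amount * discount_factor(time, rate))
}
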