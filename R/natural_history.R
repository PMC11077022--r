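#' GOLD stage from FEV1 percent-predicted
#'
#' Standard GOLD severity bands on FEV1 percent of predicted:
#' `>= 0.80` stage 1, `[0.50, 0.80)` stage 2, `[0.30, 0.50)` stage 3,
#' `< 0.30` stage 4.  Applies only to persons with COPD.
#'
#' @param fev1_pct proportion of predicted FEV1 (non-negative).
#' @return Integer stage 1-4 (vectorized).
#' @export
gold_stage <- function(fev1_pct) {
  if (any(fev1_pct < 0, na.rm = TRUE))
    stop("domain error: fev1_pct must be non-negative")
  4L - findInterval(fev1_pct, c(0.30, 0.50, 0.80))
}

#' FEV1 loss over one cycle
#'
#' Draws the annual decline from the stage-specific normal (negative
#' draws floored at 0 ml/yr), multiplies by the exacerbation factor when
#' an exacerbation occurred within the effect window, subtracts the
#' treatment reduction (ml/yr), floors the net annual decline at 0, and
#' scales to the cycle length.
#'
#' @param stage GOLD stage 1-4 (vectorized).
#' @param recent_exac logical: exacerbation within the effect window.
#' @param treatment_reduction ml/yr reduction (0 when untreated).
#' @param params parameter set.
#' @param u optional uniforms (CRN stream) of the same length as `stage`.
#' @return ml of FEV1 lost this cycle (non-negative).
#' @export
sample_cycle_decline <- function(stage, recent_exac = FALSE,
                                 treatment_reduction = 0,
                                 params = default_parameters(), u = NULL) {
  if (is.null(u)) u <- runif(length(stage))
  annual <- qnorm(u, params$decline_mean[stage], params$decline_sd[stage])
  annual <- pmax(annual, 0)
  annual <- annual * ifelse(recent_exac, params$exac_decline_multiplier, 1)
  annual <- pmax(annual - treatment_reduction, 0)
  annual * params$cycle_years
}

#' Exacerbation events over one cycle
#'
#' Non-severe and severe counts are drawn independently as Poisson with
#' mean `rate[stage] * rr_exac * cycle_years`.
#'
#' @param stage GOLD stage 1-4 (vectorized).
#' @param rr_exac treatment relative risk on exacerbation (1 untreated).
#' @param params parameter set.
#' @param u_nonsevere,u_severe optional uniforms (CRN streams).
#' @return list with integer vectors `nonsevere` and `severe`.
#' @export
sample_exacerbations <- function(stage, rr_exac = 1,
                                 params = default_parameters(),
                                 u_nonsevere = NULL, u_severe = NULL) {
  m <- length(stage)
  if (is.null(u_nonsevere)) u_nonsevere <- runif(m)
  if (is.null(u_severe)) u_severe <- runif(m)
  cy <- params$cycle_years
  list(
    nonsevere = qpois(u_nonsevere, params$exac_rate_nonsevere[stage] * rr_exac * cy),
    severe    = qpois(u_severe,    params$exac_rate_severe[stage]    * rr_exac * cy))
}

# annual background mortality probability lookup, extended beyond the
# last table row by 15%/yr growth and forced to 1 at max_age
mortality_q_table <- function(params) {
  lt <- params$life_table
  ages <- sort(unique(lt$age))
  amin <- min(ages); amax_tab <- max(ages); amax <- params$max_age
  out <- matrix(NA_real_, nrow = 2, ncol = amax - amin + 1)
  for (sx in 1:2) {
    sub <- lt[lt$sex == SEXES[sx], ]
    q <- approx(sub$age, sub$annual_mortality_probability,
                xout = amin:amax_tab, rule = 2)$y
    if (amax > amax_tab) {
      tail_q <- pmin(1, q[length(q)] * 1.15^(seq_len(amax - amax_tab)))
      q <- c(q, tail_q)
    }
    q[length(q)] <- 1
    out[sx, ] <- q
  }
  attr(out, "age_min") <- amin
  out
}

mortality_q <- function(params, sex, age) {
  tab <- mortality_q_table(params)
  amin <- attr(tab, "age_min")
  ai <- pmin(pmax(floor(age), amin), amin + ncol(tab) - 1) - amin + 1
  tab[cbind(sex, ai)]
}

#' Death sampling over one cycle
#'
#' Background annual probability `q` from the life table becomes a hazard
#' `h = -log(1 - q)`.  Persons with COPD die over the cycle with
#' probability `1 - exp(-h * HR[stage] * rr_mort * cycle_years)`, others
#' with `1 - exp(-h * cycle_years)`.  A death of a COPD person is
#' labelled COPD-attributed with the excess-hazard fraction
#' `(HR * rr - 1) / (HR * rr)` (clamped at 0), else background.
#'
#' @param sex 1/2, `age` years, `stage` 0 for no COPD else 1-4,
#'   `rr_mort` treatment relative risk (1 untreated) — all vectorized.
#' @param age,stage,rr_mort see above.
#' @param params parameter set.
#' @param u,u_cause optional uniforms (CRN streams).
#' @param q_annual optional precomputed annual background probabilities
#'   (engine fast path).
#' @return list of logical `died` and integer `cause`
#'   (0 alive, 1 background, 2 COPD-attributed).
#' @export
sample_death <- function(sex, age, stage, rr_mort = 1,
                         params = default_parameters(),
                         u = NULL, u_cause = NULL, q_annual = NULL) {
  m <- length(age)
  if (is.null(u)) u <- runif(m)
  if (is.null(u_cause)) u_cause <- runif(m)
  if (is.null(q_annual)) q_annual <- mortality_q(params, sex, age)
  h <- -log(pmax(1 - q_annual, 1e-12))
  mult <- ifelse(stage > 0, params$mortality_hr[pmax(stage, 1)] * rr_mort, 1)
  p <- 1 - exp(-h * mult * params$cycle_years)
  died <- u < p
  frac_excess <- pmax((mult - 1) / mult, 0)
  cause <- integer(m)
  cause[died] <- ifelse(u_cause[died] < frac_excess[died], 2L, 1L)
  list(died = died, cause = cause)
}
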