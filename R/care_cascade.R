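POLICY_METHODS <- c("none", "one_step", "two_step")
POLICY_FREQUENCIES <- c("one_time", "every_1y", "every_2y", "every_5y", "every_10y")

#' Define a screening policy
#'
#' A policy is a screening method crossed with a frequency.  One-step
#' screening administers the COPD screening questionnaire (COPD-SQ) to
#' everyone not already diagnosed; two-step screening adds a portable
#' spirometer test for questionnaire-positives.  Screen-positives proceed
#' to confirmatory diagnostic spirometry with the follow-up probability.
#'
#' @param method `"none"`, `"one_step"`, or `"two_step"`.
#' @param frequency `"one_time"`, `"every_1y"`, `"every_2y"`,
#'   `"every_5y"`, or `"every_10y"` (ignored for `"none"`).
#' @return A `copd_policy` object.
#' @export
screening_policy <- function(method = "none", frequency = "one_time") {
  method <- match.arg(method, POLICY_METHODS)
  frequency <- match.arg(frequency, POLICY_FREQUENCIES)
  structure(list(method = method,
                 frequency = if (method == "none") "one_time" else frequency),
            class = "copd_policy")
}

#' Parse a policy string such as `"two_step:1y"`
#'
#' Grammar: `none`, or `<method>:<freq>` with method `one_step`/`two_step`
#' and freq `once`, `1y`, `2y`, `5y`, `10y`.
#' @param x policy string.
#' @return A `copd_policy`.
#' @export
parse_policy <- function(x) {
  if (identical(x, "none")) return(screening_policy("none"))
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  freq_map <- c(once = "one_time", "1y" = "every_1y", "2y" = "every_2y",
                "5y" = "every_5y", "10y" = "every_10y")
  if (length(parts) != 2 || !parts[1] %in% c("one_step", "two_step") ||
      !parts[2] %in% names(freq_map))
    stop("bad policy string '", x, "'; use none, or one_step|two_step:",
         "once|1y|2y|5y|10y")
  screening_policy(parts[1], freq_map[[parts[2]]])
}

#' @export
format.copd_policy <- function(x, ...) {
  if (x$method == "none") return("none")
  freq <- c(one_time = "once", every_1y = "1y", every_2y = "2y",
            every_5y = "5y", every_10y = "10y")[x$frequency]
  paste0(x$method, ":", freq)
}

#' @export
print.copd_policy <- function(x, ...) {
  cat("<copd_policy>", format(x), "\n"); invisible(x)
}

#' The 11-policy evaluation set
#'
#' Status quo (no screening) plus one-step and two-step screening at the
#' five frequencies.
#' @return Named list of `copd_policy` objects.
#' @export
all_policies <- function() {
  out <- list(screening_policy("none"))
  for (m in c("two_step", "one_step"))
    for (f in POLICY_FREQUENCIES)
      out <- c(out, list(screening_policy(m, f)))
  names(out) <- vapply(out, format, "")
  out
}

#' Is this cycle a screening cycle?
#'
#' One-time screening happens only at cycle 0; `every_ky` screening at
#' cycles where the elapsed years are a multiple of k, starting at year 0.
#'
#' @param cycle_index 0-based cycle counter.
#' @param frequency a policy frequency string.
#' @param cycle_years cycle length (years).
#' @return logical.
#' @export
is_screening_cycle <- function(cycle_index, frequency, cycle_years = 0.25) {
  if (any(cycle_index < 0)) stop("domain error: cycle_index must be >= 0")
  k <- c(one_time = Inf, every_1y = 1, every_2y = 2, every_5y = 5,
         every_10y = 10)[[frequency]]
  if (is.infinite(k)) return(cycle_index == 0)
  cpk <- round(k / cycle_years)
  cycle_index %% cpk == 0
}

#' Screen a set of not-yet-diagnosed persons
#'
#' Vectorized over persons.  One-step: COPD-SQ positive with probability
#' `sq_sens` (COPD) or `1 - sq_spec` (no COPD).  Two-step: SQ-positives
#' take the portable spirometer (`spiro_sens` / `1 - spiro_spec`).
#' Screen-positives take confirmatory diagnostic spirometry with
#' probability `p_followup_dx`; confirmation is a perfect gold standard,
#' so true cases become diagnosed and false positives are cleared back to
#' the unlabelled pool.  Costs: SQ + per-round setup for every screened
#' person (screening category), spirometer for SQ-positives under
#' two-step (screening), diagnostic spirometry for followers-up
#' (diagnosis category).
#'
#' @param has_copd logical vector over the screened persons.
#' @param method `"one_step"` or `"two_step"`.
#' @param params parameter set.
#' @param u_sq,u_spiro,u_follow optional uniforms (CRN streams).
#' @return list: `outcome` (factor `negative` / `positive_no_followup` /
#'   `newly_diagnosed` / `cleared_false_positive`), `newly_diagnosed`
#'   logical, counts `n_screened`, `n_spiro`, `n_confirm`, and costs
#'   `cost_screening`, `cost_diagnosis`.
#' @export
screen_persons <- function(has_copd, method, params = default_parameters(),
                           u_sq = NULL, u_spiro = NULL, u_follow = NULL) {
  m <- length(has_copd)
  if (is.null(u_sq)) u_sq <- runif(m)
  if (is.null(u_spiro)) u_spiro <- runif(m)
  if (is.null(u_follow)) u_follow <- runif(m)
  sq_pos <- ifelse(has_copd, u_sq < params$sq_sens, u_sq < 1 - params$sq_spec)
  if (method == "two_step") {
    spiro_pos <- sq_pos & ifelse(has_copd, u_spiro < params$spiro_sens,
                                 u_spiro < 1 - params$spiro_spec)
    screen_pos <- spiro_pos
    n_spiro <- sum(sq_pos)
  } else {
    screen_pos <- sq_pos
    n_spiro <- 0L
  }
  followup <- screen_pos & (u_follow < params$p_followup_dx)
  newly_dx <- followup & has_copd
  outcome <- rep("negative", m)
  outcome[screen_pos & !followup] <- "positive_no_followup"
  outcome[followup & has_copd] <- "newly_diagnosed"
  outcome[followup & !has_copd] <- "cleared_false_positive"
  cost_screening <- m * (params$cost_sq +
                           if (params$setup_per_round) params$cost_setup else 0) +
    n_spiro * params$cost_spiro
  list(outcome = factor(outcome, levels = c("negative", "positive_no_followup",
                                            "newly_diagnosed",
                                            "cleared_false_positive")),
       newly_diagnosed = newly_dx,
       n_screened = m, n_spiro = n_spiro, n_confirm = sum(followup),
       cost_screening = cost_screening,
       cost_diagnosis = sum(followup) * params$cost_dx_spirometry)
}

#' Composite accuracy of the two-step screen
#'
#' Sensitivity multiplies along the chain (both tests must flag a true
#' case); specificity is `1 - (1 - sq_spec) * (1 - spiro_spec)` (a false
#' positive must slip through both).
#' @param params parameter set.
#' @return c(sensitivity, specificity).
#' @export
two_step_accuracy <- function(params = default_parameters()) {
  c(sensitivity = params$sq_sens * params$spiro_sens,
    specificity = 1 - (1 - params$sq_spec) * (1 - params$spiro_spec))
}

#' Symptom-driven diagnosis over one cycle
#'
#' Undiagnosed COPD patients present and get diagnosed with the small
#' per-cycle stage-specific probability `p_symptom_dx[stage]` (itself the
#' output of [calibrate_symptom_diagnosis()] against observed awareness
#' rates by stage).
#'
#' @param stage GOLD stage 1-4 (vectorized over eligible persons).
#' @param params parameter set.
#' @param u optional uniforms (CRN stream).
#' @return logical: diagnosed this cycle.
#' @export
sample_symptom_diagnosis <- function(stage, params = default_parameters(),
                                     u = NULL) {
  if (is.null(u)) u <- runif(length(stage))
  u < params$p_symptom_dx[stage]
}

# archetype draw from the stage-specific mix via one uniform per person
draw_archetype <- function(stage, params, u) {
  if (!length(stage)) return(integer(0))
  cum <- t(apply(params$treat_mix, 1, cumsum))
  out <- integer(length(stage))
  for (s in 1:4) {
    sel <- stage == s
    if (any(sel)) out[sel] <- findInterval(u[sel], cum[s, ],
                                           left.open = TRUE) + 1L
  }
  pmin(out, nrow(params$treatments))
}

#' Treatment (re)assignment
#'
#' Newly diagnosed persons take up treatment with probability
#' `p_treat_uptake`; those who do draw an archetype from the
#' stage-specific mix.  On a GOLD-stage change, treated persons redraw
#' the archetype from the new stage's mix (a switch, resetting the
#' time-on-treatment clock); previously untreated diagnosed persons get
#' a fresh uptake draw.
#'
#' @param stage GOLD stage of each person considered.
#' @param currently_treated logical; `TRUE` means re-assignment after a
#'   stage change (no fresh uptake draw, always switches).
#' @param params parameter set.
#' @param u_uptake,u_choice optional uniforms (CRN streams).
#' @return integer archetype id per person (0 = untreated).
#' @export
assign_treatment <- function(stage, currently_treated = FALSE,
                             params = default_parameters(),
                             u_uptake = NULL, u_choice = NULL) {
  m <- length(stage)
  currently_treated <- rep_len(currently_treated, m)
  if (is.null(u_uptake)) u_uptake <- runif(m)
  if (is.null(u_choice)) u_choice <- runif(m)
  takes <- currently_treated | (u_uptake < params$p_treat_uptake)
  out <- integer(m)
  out[takes] <- draw_archetype(stage[takes], params, u_choice[takes])
  out
}

#' Calibrate per-cycle symptom-diagnosis probabilities
#'
#' Finds stage-specific per-cycle probabilities such that, under a
#' status-quo simulation started at the target awareness profile, the
#' cross-sectional awareness fraction among living COPD patients per
#' stage stays at the targets (stationarity calibration).  Uses
#' coordinate-wise bisection with the full simulator as the forward
#' model; deterministic given the seed.
#'
#' @param targets awareness proportions by stage (length 4, in `[0, 1)`).
#' @param params parameter set (its `initial_diagnosed` is set to the
#'   targets for the forward runs).
#' @param cohort_size,n_cycles,seed simulation budget for each forward run.
#' @param tol relative tolerance on achieved awareness (default 10%).
#' @param max_iter fixed-point iterations (each is one forward run
#'   adjusting all four stages jointly).
#' @param initial_diagnosed initial awareness profile of the forward
#'   cohort; defaults to the targets themselves (the observed awareness
#'   is both the initial condition and the stationarity target).
#' @return list: `p_symptom_dx`, `achieved` awareness, `targets`, and
#'   `converged` per stage.  Unattainable targets (below the awareness
#'   retained from the initial cohort even with zero symptom diagnosis)
#'   raise an error reporting the bracketing values.
#' @export
calibrate_symptom_diagnosis <- function(targets,
                                        params = default_parameters(),
                                        cohort_size = 200000, n_cycles = 40,
                                        seed = 1L, tol = 0.10,
                                        max_iter = 10,
                                        initial_diagnosed = targets) {
  stopifnot(length(targets) == 4)
  if (any(targets < 0 | targets >= 1))
    stop("targets must lie in [0, 1)")
  params$initial_diagnosed <- initial_diagnosed
  if (all(targets == 0))
    return(list(p_symptom_dx = rep(0, 4), achieved = rep(0, 4),
                targets = targets, converged = rep(TRUE, 4)))

  forward <- function(p) {
    par2 <- params
    par2$p_symptom_dx <- p
    measure_awareness(par2, cohort_size = cohort_size, n_cycles = n_cycles,
                      seed = seed)
  }

  # awareness floor: what persists from the initial cohort with no
  # symptom-driven diagnosis at all
  a0 <- forward(rep(0, 4))
  short <- targets > 0 & a0 > targets * (1 + tol)
  if (any(short))
    stop("calibration failure for stage(s) ",
         paste(which(short), collapse = ", "), ": target(s) ",
         paste(signif(targets[short], 3), collapse = ", "),
         " below the zero-diagnosis floor(s) ",
         paste(signif(a0[short], 3), collapse = ", "),
         " (bracket [0, floor])")

  # proportional fixed point on the diagnosis-driven excess over the
  # floor; awareness is monotone in each stage's probability
  p <- pmin(pmax((targets - a0) / (2 * n_cycles), 0), 0.5)
  converged <- targets == 0
  a <- a0
  for (it in seq_len(max_iter)) {
    a <- forward(p)
    converged <- targets == 0 | abs(a - targets) <= tol * pmax(targets, 1e-12)
    if (all(converged)) break
    gain <- pmax(targets - a0, 0) / pmax(a - a0, 1e-9)
    p <- pmin(pmax(p * pmin(pmax(gain, 0.2), 5), 0), 0.5)
    p[targets == 0] <- 0
  }
  list(p_symptom_dx = p, achieved = a, targets = targets,
       converged = converged)
}

# cross-sectional awareness among living COPD patients by stage under the
# status quo, averaged over the second half of the simulated cycles
measure_awareness <- function(params, cohort_size = 20000, n_cycles = 40,
                              seed = 1L) {
  cohort <- generate_cohort(cohort_size, params, seed = seed)
  res <- run_policy(cohort, screening_policy("none"), params, seed = seed,
                    max_cycles = n_cycles, track_awareness = TRUE)
  aw <- res$awareness
  keep <- seq(ceiling(nrow(aw) / 2) + 1, nrow(aw))
  colMeans(aw[keep, , drop = FALSE], na.rm = TRUE)
}
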