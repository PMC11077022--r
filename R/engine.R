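# CRN stream ids: each (process, cycle) pair owns an independently seeded
# uniform stream, drawn full-cohort-length in person order so that the
# uniform consumed by (person, process, cycle) is identical across
# policies run from the same master seed.
PROC <- c(sq = 1L, spiro = 2L, followup = 3L, symptom = 4L, uptake = 5L,
          choice = 6L, incidence = 8L, incident_fev = 9L, exac_ns = 10L,
          exac_sev = 11L, decline = 12L, death = 13L, cause = 14L)

crn_uniforms <- function(seed, pid, cycle, n) {
  derived <- ((seed %% 100000) * 20011 + pid * 7919 + cycle * 104729) %% 2147483647
  set.seed(as.integer(derived))
  runif(n)
}

#' Run one policy over a cohort
#'
#' Iterates 3-month cycles until everyone has died or the absorbing
#' maximum age is reached.  Per cycle and per living person, in order:
#' screening (on screening cycles) -> symptom diagnosis -> treatment
#' (re)assignment -> incidence (for persons without COPD) ->
#' exacerbations -> FEV1 decline and restaging -> death -> discounted
#' QALY/cost accrual.  Reproducible given `(cohort, policy, params,
#' seed)`; identical seeds give identical per-person random streams
#' across policies (common random numbers).
#'
#' Accrual conventions: outcomes discount at the cycle midpoint;
#' persons dying within a cycle accrue half a cycle of utility and of
#' the monthly-rated cost categories; incident cases accrue at their
#' pre-conversion state for the conversion cycle and at the new state
#' from the next cycle on.
#'
#' @param cohort a `copd_cohort` generated from the same epidemiological
#'   parameters.
#' @param policy a `copd_policy` (or policy string).
#' @param params parameter set.
#' @param seed master seed for all per-cycle random streams.
#' @param max_cycles optional cap on the number of cycles (default: run
#'   to extinction / maximum age).
#' @param track_awareness record per-cycle diagnosed fractions among
#'   living COPD patients by stage (used by the calibration).
#' @param return_state also return the final person-level state vectors
#'   (for diagnostics and invariant checks).
#' @return A `copd_policy_result` list: discounted QALYs (total and for
#'   COPD patients), discounted cost by category, exacerbation and death
#'   counts, screening-cascade counts, and run metadata.
#' @export
run_policy <- function(cohort, policy, params = default_parameters(),
                       seed = 1L, max_cycles = Inf, track_awareness = FALSE,
                       return_state = FALSE) {
  if (is.character(policy)) policy <- parse_policy(policy)
  if (!inherits(cohort, "copd_cohort")) stop("cohort must be a copd_cohort")
  if (!is.na(cohort$parameters_hash) &&
      !identical(cohort$parameters_hash, cohort_params_hash(params)))
    stop("consistency error: cohort was generated from different parameters")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  n <- cohort$n
  cy <- params$cycle_years
  alive <- cohort$alive; sex <- cohort$sex; age <- cohort$age
  has_copd <- cohort$has_copd; fev1_pct <- cohort$fev1_pct
  fev1 <- if (!is.null(cohort$fev1)) cohort$fev1 else {
    f <- rep(NA_real_, n)
    ci <- which(has_copd)
    f[ci] <- fev1_pct[ci] * predicted_fev1(sex[ci], age[ci], params)
    f
  }
  stage <- cohort$stage; diagnosed <- cohort$diagnosed
  treat_id <- cohort$treat_id
  mse <- cohort$months_since_exac; mot <- cohort$months_on_treat
  death_cause <- cohort$death_cause
  pending <- logical(n)

  qtab <- mortality_q_table(params)
  amin <- attr(qtab, "age_min"); amax_i <- ncol(qtab)
  tr_red <- c(0, params$treatments$decline_reduction)
  tr_rre <- c(1, params$treatments$rr_exac)
  tr_rrm <- c(1, params$treatments$rr_mort)

  tq <- tq_undisc <- tq_copd <- 0
  cost <- setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  nx_ns <- nx_sev <- 0
  n_deaths_copd <- n_deaths_bg <- 0
  n_screens <- n_spiro <- n_confirm <- ndx_screen <- ndx_sympt <- 0

  cycles_cap <- ceiling((params$max_age - min(c(age, params$max_age))) / cy) + 1
  max_cycles <- min(max_cycles, cycles_cap)
  aw <- if (track_awareness) matrix(NA_real_, nrow = max_cycles, ncol = 4)

  method <- policy$method
  cycle <- 0L
  while (cycle < max_cycles) {
    aidx <- which(alive)
    if (!length(aidx)) break
    df <- (1 + params$discount_rate)^(-(cycle * cy + cy / 2))
    crn <- function(pid) crn_uniforms(seed, pid, cycle, n)
    new_dx <- integer(0)

    ## --- screening -------------------------------------------------
    if (method != "none" && is_screening_cycle(cycle, policy$frequency, cy)) {
      elig <- aidx[!diagnosed[aidx]]
      if (length(elig)) {
        u_sq <- crn(PROC["sq"]); u_sp <- crn(PROC["spiro"])
        u_fo <- crn(PROC["followup"])
        scr <- screen_persons(has_copd[elig], method, params,
                              u_sq[elig], u_sp[elig], u_fo[elig])
        ndx <- elig[scr$newly_diagnosed]
        diagnosed[ndx] <- TRUE
        new_dx <- ndx
        if (!params$setup_per_round && n_screens == 0)  # one-time setup variant
          cost["screening"] <- cost["screening"] +
            scr$n_screened * params$cost_setup * df
        cost["screening"] <- cost["screening"] + scr$cost_screening * df
        cost["diagnosis"] <- cost["diagnosis"] + scr$cost_diagnosis * df
        n_screens <- n_screens + scr$n_screened
        n_spiro <- n_spiro + scr$n_spiro
        n_confirm <- n_confirm + scr$n_confirm
        ndx_screen <- ndx_screen + length(ndx)
      }
    }

    ## --- symptom-based diagnosis ------------------------------------
    elig <- aidx[has_copd[aidx] & !diagnosed[aidx]]
    if (length(elig)) {
      u <- crn(PROC["symptom"])
      sdx <- elig[sample_symptom_diagnosis(stage[elig], params, u[elig])]
      if (length(sdx)) {
        diagnosed[sdx] <- TRUE
        cost["diagnosis"] <- cost["diagnosis"] +
          length(sdx) * params$cost_dx_spirometry * df
        ndx_sympt <- ndx_sympt + length(sdx)
        new_dx <- c(new_dx, sdx)
      }
    }

    ## --- treatment (re)assignment ------------------------------------
    # a treatment is a 12-month course: effects and cost run for
    # treat_effect_months, after which the patient reverts to untreated
    # until a stage change triggers a fresh uptake draw
    expired <- aidx[treat_id[aidx] > 0L &
                      mot[aidx] >= params$treat_effect_months]
    treat_id[expired] <- 0L
    re <- aidx[pending[aidx]]
    if (length(new_dx) || length(re)) {
      u_up <- crn(PROC["uptake"]); u_ch <- crn(PROC["choice"])
      if (length(new_dx)) {
        treat_id[new_dx] <- assign_treatment(stage[new_dx], FALSE, params,
                                             u_up[new_dx], u_ch[new_dx])
        mot[new_dx] <- 0
        pending[new_dx] <- FALSE
      }
      if (length(re)) {
        treat_id[re] <- assign_treatment(stage[re], treat_id[re] > 0, params,
                                         u_up[re], u_ch[re])
        mot[re] <- 0
        pending[re] <- FALSE
      }
    }

    ## --- incidence ----------------------------------------------------
    inc <- sample_incident_cases(
      list(n = n, alive = alive, has_copd = has_copd, age = age, sex = sex),
      params, crn(PROC["incidence"]), crn(PROC["incident_fev"]))
    new_mask <- logical(n)
    if (length(inc$idx)) {
      new_mask[inc$idx] <- TRUE
      has_copd[inc$idx] <- TRUE
      fev1_pct[inc$idx] <- inc$fev1_pct
      fev1[inc$idx] <- inc$fev1_pct *
        predicted_fev1(sex[inc$idx], pmin(age[inc$idx], params$max_age), params)
      stage[inc$idx] <- inc$stage
      mse[inc$idx] <- Inf
    }

    ## --- exacerbations & FEV1 decline ---------------------------------
    cidx <- aidx[has_copd[aidx] & !new_mask[aidx]]
    ev_ns <- integer(n); ev_sv <- integer(n)
    if (length(cidx)) {
      u_ns <- crn(PROC["exac_ns"]); u_sv <- crn(PROC["exac_sev"])
      ex <- sample_exacerbations(stage[cidx], tr_rre[treat_id[cidx] + 1L],
                                 params, u_ns[cidx], u_sv[cidx])
      ev_ns[cidx] <- ex$nonsevere; ev_sv[cidx] <- ex$severe
      mse[cidx] <- mse[cidx] + 3
      mse[cidx[ex$nonsevere + ex$severe > 0]] <- 0
      nx_ns <- nx_ns + sum(ex$nonsevere); nx_sev <- nx_sev + sum(ex$severe)

      u_dc <- crn(PROC["decline"])
      # treatment reduces the decline rate only for the first
      # treat_effect_months on the current treatment; switching resets
      red <- tr_red[treat_id[cidx] + 1L] *
        (mot[cidx] < params$treat_effect_months)
      ml <- sample_cycle_decline(stage[cidx],
                                 mse[cidx] < params$exac_effect_months,
                                 red, params, u_dc[cidx])
      # FEV1 is tracked in liters; percent-predicted follows against the
      # age-declining reference, ratcheted so it never increases (the
      # reference falls with age, so a slow decliner would otherwise gain)
      fev1[cidx] <- pmax(fev1[cidx] - ml / 1000, 0)
      pred <- predicted_fev1(sex[cidx], pmin(age[cidx], params$max_age), params)
      fev1_pct[cidx] <- pmax(pmin(fev1_pct[cidx], fev1[cidx] / pred), 0)
      ns <- gold_stage(fev1_pct[cidx])
      chg <- ns != stage[cidx]
      stage[cidx] <- ns
      pending[cidx[chg & diagnosed[cidx]]] <- TRUE
      mot[cidx] <- mot[cidx] + 3
    }

    ## --- death --------------------------------------------------------
    ai <- pmin(pmax(floor(age[aidx]), amin), amin + amax_i - 1) - amin + 1
    q_bg <- qtab[cbind(sex[aidx], ai)]
    stg_eff <- stage[aidx]
    stg_eff[new_mask[aidx]] <- 0L
    u_de <- crn(PROC["death"]); u_ca <- crn(PROC["cause"])
    d <- sample_death(sex[aidx], age[aidx], stg_eff,
                      tr_rrm[treat_id[aidx] + 1L], params,
                      u_de[aidx], u_ca[aidx], q_annual = q_bg)
    died_idx <- aidx[d$died]
    alive[died_idx] <- FALSE
    death_cause[died_idx] <- d$cause[d$died]
    n_deaths_copd <- n_deaths_copd + sum(d$cause == 2L)
    n_deaths_bg <- n_deaths_bg + sum(d$cause == 1L)

    ## --- accrual ------------------------------------------------------
    frac <- rep(1, length(aidx)); frac[d$died] <- 0.5
    util <- cycle_utility(stg_eff, age[aidx], ev_ns[aidx], ev_sv[aidx], params)
    q_this <- util * cy * frac
    tq <- tq + sum(q_this) * df
    tq_undisc <- tq_undisc + sum(q_this)
    tq_copd <- tq_copd + sum(q_this[stg_eff > 0]) * df
    cc <- cycle_cost(stg_eff, diagnosed[aidx], treat_id[aidx],
                     ev_ns[aidx], ev_sv[aidx], frac, params)
    cost["maintenance"] <- cost["maintenance"] + sum(cc$maintenance) * df
    cost["treatment"] <- cost["treatment"] + sum(cc$treatment) * df
    cost["exacerbation"] <- cost["exacerbation"] + sum(cc$exacerbation) * df
    cost["complication"] <- cost["complication"] + sum(cc$complication) * df

    ## --- aging & bookkeeping ------------------------------------------
    surv <- aidx[!d$died]
    age[surv] <- age[surv] + cy
    if (track_awareness) {
      li <- which(alive & has_copd)
      ncs <- tabulate(stage[li], 4)
      nds <- tabulate(stage[li[diagnosed[li]]], 4)
      aw[cycle + 1L, ] <- ifelse(ncs > 0, nds / ncs, NA_real_)
    }
    cycle <- cycle + 1L
  }

  structure(list(
    policy = format(policy),
    total_qaly_discounted = tq,
    total_qaly_undiscounted = tq_undisc,
    qaly_copd_patients_discounted = tq_copd,
    total_cost_discounted = sum(cost),
    cost_by_category = cost,
    n_exac_nonsevere = nx_ns, n_exac_severe = nx_sev,
    n_copd_deaths = n_deaths_copd, n_background_deaths = n_deaths_bg,
    n_screens = n_screens, n_spiro_tests = n_spiro,
    n_confirm_tests = n_confirm,
    n_new_dx_by_screen = ndx_screen, n_new_dx_by_symptom = ndx_sympt,
    n_alive_end = sum(alive),
    cohort_size = n, seed = seed, n_cycles = cycle,
    awareness = if (track_awareness) aw[seq_len(cycle), , drop = FALSE],
    state = if (return_state)
      list(alive = alive, age = age, has_copd = has_copd,
           fev1_pct = fev1_pct, fev1 = fev1, stage = stage,
           diagnosed = diagnosed, treat_id = treat_id,
           death_cause = death_cause)),
    class = "copd_policy_result")
}

#' @export
print.copd_policy_result <- function(x, ...) {
  cat(sprintf("<copd_policy_result> %s: n = %d, %.0f QALYs, $%.0f, %d COPD deaths\n",
              x$policy, x$cohort_size, x$total_qaly_discounted,
              x$total_cost_discounted, x$n_copd_deaths))
  invisible(x)
}

#' Run a set of policies on one cohort
#'
#' Under `"common_random_numbers"` (default) every policy reuses the same
#' per-(person, process, cycle) uniform streams, so differences between
#' arms are attributable to the policy alone; under `"independent"` each
#' policy gets fresh streams derived from the master seed.
#'
#' @param cohort a `copd_cohort`.
#' @param policies list of `copd_policy` objects or policy strings; must
#'   include the status quo (`"none"`) and contain no duplicates.
#' @param params parameter set.
#' @param seed master seed.
#' @param seed_mode `"common_random_numbers"` or `"independent"`.
#' @return Named list of `copd_policy_result`s (class
#'   `copd_policy_set`).
#' @export
run_policy_set <- function(cohort, policies = all_policies(),
                           params = default_parameters(), seed = 1L,
                           seed_mode = c("common_random_numbers",
                                         "independent")) {
  seed_mode <- match.arg(seed_mode)
  policies <- lapply(policies, function(p)
    if (is.character(p)) parse_policy(p) else p)
  labs <- vapply(policies, format, "")
  if (anyDuplicated(labs)) stop("duplicate policies: ",
                                paste(labs[duplicated(labs)], collapse = ", "))
  if (!"none" %in% labs) stop("the policy set must include the status quo ('none')")
  out <- vector("list", length(policies))
  for (i in seq_along(policies)) {
    s <- if (seed_mode == "independent") seed + (i - 1L) * 7777L else seed
    out[[i]] <- run_policy(cohort, policies[[i]], params, seed = s)
  }
  names(out) <- labs
  class(out) <- "copd_policy_set"
  out
}

#' Tabulate policy results
#'
#' @param results a `copd_policy_set` or list of `copd_policy_result`s.
#' @return A tibble with one row per policy (QALYs, costs by category,
#'   event and cascade counts).
#' @export
policy_results_table <- function(results) {
  rows <- lapply(results, function(r) {
    cc <- as.list(r$cost_by_category)
    names(cc) <- paste0("cost_", names(cc))
    tibble::as_tibble(c(list(
      policy = r$policy,
      total_qaly = r$total_qaly_discounted,
      qaly_copd_patients = r$qaly_copd_patients_discounted,
      total_cost = r$total_cost_discounted),
      cc,
      list(n_exac_nonsevere = r$n_exac_nonsevere,
           n_exac_severe = r$n_exac_severe,
           n_copd_deaths = r$n_copd_deaths,
           n_screens = r$n_screens,
           n_spiro_tests = r$n_spiro_tests,
           n_confirm_tests = r$n_confirm_tests,
           n_new_dx_by_screen = r$n_new_dx_by_screen,
           n_new_dx_by_symptom = r$n_new_dx_by_symptom,
           cohort_size = r$cohort_size, seed = r$seed)))
  })
  do.call(rbind, rows)
}
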