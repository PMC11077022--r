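# pull (qaly, cost) out of a policy result or a plain list
qc <- function(x) {
  if (inherits(x, "copd_policy_result"))
    c(x$total_qaly_discounted, x$total_cost_discounted)
  else c(x$qaly, x$cost)
}

#' Incremental cost-effectiveness ratio of a vs b
#'
#' `(cost_a - cost_b) / (qaly_a - qaly_b)` when a yields more QALYs.
#' When a has at least as many QALYs at no greater cost (strict
#' somewhere) the verdict is `"dominates"`; the mirror case is
#' `"dominated"`; equal QALYs give an `"undefined"` verdict rather than
#' a division.
#'
#' @param result_a,result_b `copd_policy_result`s or lists with `qaly`
#'   and `cost`.
#' @return list with `icer` (USD/QALY or `NA`) and `verdict` (`"icer"`,
#'   `"dominates"`, `"dominated"`, `"undefined"`).
#' @export
icer <- function(result_a, result_b) {
  a <- qc(result_a); b <- qc(result_b)
  dq <- a[1] - b[1]; dc <- a[2] - b[2]
  if (dq >= 0 && dc <= 0 && (dq > 0 || dc < 0))
    return(list(icer = NA_real_, verdict = "dominates"))
  if (dq <= 0 && dc >= 0 && (dq < 0 || dc > 0))
    return(list(icer = NA_real_, verdict = "dominated"))
  if (dq == 0) return(list(icer = NA_real_, verdict = "undefined"))
  list(icer = dc / dq, verdict = "icer")
}

# frontier member labels for (qaly, cost) pairs: start from the cheapest
# policy, repeatedly step to the policy with the smallest ICER among
# those with more QALYs.  Equivalent to the lower-right convex hull;
# strictly and extended-dominated policies never enter.
frontier_members <- function(qaly, cost) {
  n <- length(qaly)
  member <- logical(n)
  cur <- which(cost == min(cost))
  cur <- cur[which.max(qaly[cur])]
  member[cur] <- TRUE
  repeat {
    cand <- which(qaly > qaly[cur])
    if (!length(cand)) break
    ic <- (cost[cand] - cost[cur]) / (qaly[cand] - qaly[cur])
    nxt <- cand[order(ic, -qaly[cand])][1]
    member[nxt] <- TRUE
    cur <- nxt
  }
  member
}

#' Averted events relative to the status quo
#'
#' @param result,statusquo `copd_policy_result`s from the same cohort,
#'   or scalar counts.
#' @return list with `count` (status quo minus policy) and `percent`
#'   (`count / statusquo * 100`, `NA` when the status-quo count is 0).
#' @export
averted <- function(result, statusquo) {
  count <- statusquo - result
  pct <- count / statusquo * 100
  pct[rep_len(statusquo == 0, length(count))] <- NA_real_
  list(count = count, percent = pct)
}

#' Cost-effectiveness table for a policy set
#'
#' Builds the decision-analytic summary: per-policy discounted QALYs and
#' costs, ICER versus the status quo (with dominance verdicts), frontier
#' membership (strict plus extended dominance), incremental ICERs along
#' the frontier, exacerbations and COPD-attributed deaths averted (count
#' and percent), and cost per event averted.
#'
#' @param results a `copd_policy_set`, or a data frame / tibble with
#'   columns `policy`, `qaly`, `cost` (and optionally `exac`, `deaths`).
#' @return A `copd_cea_table` tibble, sorted by increasing QALYs.
#' @export
cea_table <- function(results) {
  if (inherits(results, "copd_policy_set") ||
      (is.list(results) && !is.data.frame(results) &&
       all(vapply(results, inherits, TRUE, "copd_policy_result")))) {
    df <- tibble::tibble(
      policy = vapply(results, `[[`, "", "policy"),
      qaly = vapply(results, `[[`, 0, "total_qaly_discounted"),
      cost = vapply(results, `[[`, 0, "total_cost_discounted"),
      exac = vapply(results, function(r) r$n_exac_nonsevere + r$n_exac_severe, 0),
      deaths = vapply(results, `[[`, 0, "n_copd_deaths"))
  } else {
    df <- tibble::as_tibble(results)
    if (!all(c("policy", "qaly", "cost") %in% names(df)))
      stop("need columns policy, qaly, cost")
    if (!"exac" %in% names(df)) df$exac <- NA_real_
    if (!"deaths" %in% names(df)) df$deaths <- NA_real_
  }
  if (nrow(df) == 0) stop("empty result set")
  if (!"none" %in% df$policy) stop("the policy set must include 'none'")

  sq <- df[df$policy == "none", ]
  vs <- lapply(seq_len(nrow(df)), function(i)
    icer(list(qaly = df$qaly[i], cost = df$cost[i]),
         list(qaly = sq$qaly, cost = sq$cost)))
  df$icer_vs_statusquo <- vapply(vs, `[[`, 0, "icer")
  df$verdict_vs_statusquo <- vapply(vs, `[[`, "", "verdict")
  df$verdict_vs_statusquo[df$policy == "none"] <- ""
  df$icer_vs_statusquo[df$policy == "none"] <- NA_real_

  df$frontier_member <- frontier_members(df$qaly, df$cost)
  ord <- order(df$qaly, df$cost)
  df <- df[ord, ]
  fr <- which(df$frontier_member)
  df$icer_on_frontier <- NA_real_
  if (length(fr) > 1)
    for (k in 2:length(fr))
      df$icer_on_frontier[fr[k]] <-
        (df$cost[fr[k]] - df$cost[fr[k - 1]]) /
        (df$qaly[fr[k]] - df$qaly[fr[k - 1]])

  av_e <- averted(df$exac, sq$exac)
  av_d <- averted(df$deaths, sq$deaths)
  df$exac_averted <- av_e$count; df$exac_averted_pct <- av_e$percent
  df$deaths_averted <- av_d$count; df$deaths_averted_pct <- av_d$percent
  dcost <- df$cost - sq$cost
  df$cost_per_exac_averted <- ifelse(df$exac_averted > 0, dcost / df$exac_averted,
                                     NA_real_)
  df$cost_per_death_averted <- ifelse(df$deaths_averted > 0,
                                      dcost / df$deaths_averted, NA_real_)
  class(df) <- c("copd_cea_table", class(df))
  df
}

#' Most cost-effective policy at a willingness-to-pay threshold
#'
#' The frontier policy with the largest QALYs whose incremental frontier
#' ICER is at or below the threshold (the status quo anchors the
#' frontier and is always affordable).
#'
#' @param tab a `copd_cea_table`.
#' @param wtp willingness-to-pay (USD/QALY).
#' @return The policy label.
#' @export
most_cost_effective <- function(tab, wtp) {
  fr <- tab[tab$frontier_member, ]
  ok <- is.na(fr$icer_on_frontier) | fr$icer_on_frontier <= wtp
  # walk up the frontier while affordable
  last <- max(which(cumprod(ok) == 1))
  fr$policy[last]
}

#' Linkage-to-care scenario grid
#'
#' Re-evaluates the policy set over a grid of follow-up diagnosis and
#' treatment-uptake probabilities and reports the most cost-effective
#' policy at the willingness-to-pay threshold in each cell.
#'
#' @param cohort a `copd_cohort`.
#' @param params parameter set.
#' @param dx_probs,treat_probs probability grids in `[0, 1]`.
#' @param policies policy list (must include `"none"`).
#' @param seed master seed (common random numbers within each cell).
#' @return Tibble with columns `p_followup_dx`, `p_treat_uptake`,
#'   `best_policy`, and that policy's ICER versus the status quo.
#' @export
linkage_scenario_grid <- function(cohort, params = default_parameters(),
                                  dx_probs = c(0.4, 0.7, 1.0),
                                  treat_probs = c(0.3, 0.5, 0.8),
                                  policies = all_policies(), seed = 1L) {
  stopifnot(all(dx_probs >= 0 & dx_probs <= 1),
            all(treat_probs >= 0 & treat_probs <= 1))
  out <- list()
  for (dx in dx_probs) for (tp in treat_probs) {
    par2 <- params
    par2$p_followup_dx <- dx
    par2$p_treat_uptake <- tp
    res <- run_policy_set(cohort, policies, par2, seed = seed)
    tab <- cea_table(res)
    best <- most_cost_effective(tab, params$wtp)
    out[[length(out) + 1]] <- tibble::tibble(
      p_followup_dx = dx, p_treat_uptake = tp, best_policy = best,
      icer_vs_statusquo = tab$icer_vs_statusquo[tab$policy == best])
  }
  do.call(rbind, out)
}

# set / read a scalar parameter by path, e.g. "cost_exac_severe",
# "mortality_hr.3", "prevalence.male.2"
set_param <- function(params, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (!parts[1] %in% names(params))
    stop("unknown parameter path '", path, "'; top-level fields: ",
         paste(names(params)[vapply(params, is.numeric, TRUE)], collapse = ", "))
  node <- params[[parts[1]]]
  if (length(parts) == 1) {
    if (length(node) != 1) stop("path '", path, "' is not scalar; give an index")
    params[[parts[1]]] <- value
  } else if (length(parts) == 2) {
    i <- suppressWarnings(as.integer(parts[2]))
    if (is.na(i)) params[[parts[1]]][[parts[2]]] <- value
    else params[[parts[1]]][i] <- value
  } else {
    i <- suppressWarnings(as.integer(parts[3]))
    params[[parts[1]]][[parts[2]]][i] <- value
  }
  params
}

get_param <- function(params, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- params[[parts[1]]]
  for (p in parts[-1]) {
    i <- suppressWarnings(as.integer(p))
    node <- if (is.na(i)) node[[p]] else node[[i]]
  }
  node
}

#' One-way sensitivity sweep
#'
#' Runs the policy set with one parameter at its low and high value and
#' reports the designated policy's ICER versus the status quo at each
#' end (tornado-diagram input).
#'
#' @param param_path dotted path to a scalar field (e.g.
#'   `"cost_exac_severe"`, `"mortality_hr.3"`).
#' @param low,high the two values to evaluate.
#' @param cohort a `copd_cohort`.
#' @param policies policy list incl. `"none"` and the designated policy.
#' @param params base parameter set.
#' @param designated_policy the policy whose ICER is tracked.
#' @param seed master seed.
#' @return One-row tibble: `param`, `low`, `high`, `icer_low`,
#'   `icer_high`, `span`.
#' @export
one_way_sweep <- function(param_path, low, high, cohort,
                          policies = list("none", "two_step:every_1y"),
                          params = default_parameters(),
                          designated_policy = "two_step:1y", seed = 1L) {
  run_at <- function(v) {
    par2 <- validate_parameters(set_param(params, param_path, v))
    res <- run_policy_set(cohort, policies, par2, seed = seed)
    tab <- cea_table(res)
    tab$icer_vs_statusquo[tab$policy == designated_policy]
  }
  il <- run_at(low); ih <- run_at(high)
  tibble::tibble(param = param_path, low = low, high = high,
                 icer_low = il, icer_high = ih, span = abs(ih - il))
}

#' Default PSA distribution specification
#'
#' Beta for probabilities and utilities, gamma for costs and rates,
#' normal for effect sizes; dispersion such that the 95% interval spans
#' roughly +/-20% of the base-case mean.
#'
#' @param params base parameter set.
#' @return List of entries `(path, family)`.
#' @export
default_psa_spec <- function(params = default_parameters()) {
  spec <- list(
    list(path = "sq_sens", family = "beta"),
    list(path = "sq_spec", family = "beta"),
    list(path = "spiro_sens", family = "beta"),
    list(path = "spiro_spec", family = "beta"),
    list(path = "p_followup_dx", family = "beta"),
    list(path = "p_treat_uptake", family = "beta"),
    list(path = "cost_exac_nonsevere", family = "gamma"),
    list(path = "cost_exac_severe", family = "gamma"),
    list(path = "cost_dx_spirometry", family = "gamma"),
    list(path = "exac_decline_multiplier", family = "normal"))
  for (s in 1:4) {
    spec <- c(spec,
              list(list(path = paste0("exac_rate_nonsevere.", s), family = "gamma"),
                   list(path = paste0("exac_rate_severe.", s), family = "gamma"),
                   list(path = paste0("cost_maint_monthly.", s), family = "gamma"),
                   list(path = paste0("utility_stage.", s), family = "beta"),
                   list(path = paste0("decline_mean.", s), family = "normal"),
                   list(path = paste0("mortality_hr.", s), family = "normal")))
  }
  spec
}

# one PSA parameter draw; sd chosen so 1.96*sd = 20% of the mean
draw_psa_params <- function(params, spec) {
  for (e in spec) {
    m <- get_param(params, e$path)
    sd <- 0.20 * m / 1.96
    if (sd == 0) next
    v <- switch(e$family,
      beta = {
        s2 <- sd^2
        if (m <= 0 || m >= 1) m else {
          k <- m * (1 - m) / s2 - 1
          if (k <= 0) m else rbeta(1, m * k, (1 - m) * k)
        }
      },
      gamma = rgamma(1, shape = (m / sd)^2, rate = m / sd^2),
      normal = rnorm(1, m, sd),
      stop("invalid distribution family '", e$family, "'"))
    if (grepl("mortality_hr", e$path)) v <- max(v, 1)
    params <- set_param(params, e$path, v)
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Per replicate, draws a parameter set from the PSA distributions,
#' generates a (reduced-size) cohort, simulates all policies under
#' common random numbers, and records each policy's discounted QALYs and
#' cost.  Reproducible given the seed.
#'
#' @param cohort_size persons per replicate (reduced sizes trade Monte
#'   Carlo error for runtime).
#' @param n_reps Monte Carlo replications (1000 in the full analysis).
#' @param spec distribution specification ([default_psa_spec()]).
#' @param policies policy list incl. `"none"`.
#' @param params base parameter set.
#' @param seed master seed.
#' @return A `copd_psa` tibble: `rep`, `policy`, `qaly`, `cost`.
#' @export
run_psa <- function(cohort_size = 2000, n_reps = 1000,
                    spec = default_psa_spec(), policies = all_policies(),
                    params = default_parameters(), seed = 1L) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + 104729L * r)
    par_r <- draw_psa_params(params, spec)
    cohort <- generate_cohort(cohort_size, par_r, seed = seed + r)
    res <- run_policy_set(cohort, policies, par_r, seed = seed + r)
    out[[r]] <- tibble::tibble(
      rep = r,
      policy = vapply(res, `[[`, "", "policy"),
      qaly = vapply(res, `[[`, 0, "total_qaly_discounted"),
      cost = vapply(res, `[[`, 0, "total_cost_discounted"))
  }
  out <- do.call(rbind, out)
  class(out) <- c("copd_psa", class(out))
  out
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, each replicate's winner maximises
#' net monetary benefit `wtp * qaly - cost`; the curve value is the
#' fraction of replicates won (ties split equally), so probabilities sum
#' to 1 across policies at every threshold.
#'
#' @param samples a `copd_psa` tibble (or any tibble with `rep`,
#'   `policy`, `qaly`, `cost`).
#' @param wtp_grid willingness-to-pay values (USD/QALY), non-empty.
#' @return Tibble: `wtp`, `policy`, `probability`.
#' @export
ceac <- function(samples, wtp_grid) {
  if (length(wtp_grid) == 0) stop("empty WTP grid")
  if (nrow(samples) == 0) stop("need at least one PSA sample")
  reps <- split(samples, samples$rep)
  pols <- unique(samples$policy)
  out <- list()
  for (w in wtp_grid) {
    wins <- setNames(numeric(length(pols)), pols)
    for (rr in reps) {
      nmb <- w * rr$qaly - rr$cost
      top <- which(nmb == max(nmb))
      wins[rr$policy[top]] <- wins[rr$policy[top]] + 1 / length(top)
    }
    out[[length(out) + 1]] <- tibble::tibble(
      wtp = w, policy = pols, probability = as.numeric(wins[pols]) / length(reps))
  }
  do.call(rbind, out)
}
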