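# truncated-normal draw via inverse CDF from uniforms (keeps a single code
# path whether uniforms come from the CRN streams or runif)
rtrunc_norm <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate the initial simulation cohort
#'
#' Draws `n` individuals aged 35-80 with the configured sex and age-band
#' structure; assigns prevalent COPD by the age- and sex-specific
#' prevalence, FEV1 percent-predicted for cases from the sex-specific
#' truncated normal, GOLD stage from the staging map, diagnosis status
#' from the stage-specific initial awareness, and (for the diagnosed)
#' treatment via the usual uptake rule.
#'
#' @param n cohort size (non-negative integer).
#' @param params a validated [default_parameters()] set.
#' @param seed integer RNG seed; identical `(n, params, seed)` reproduce
#'   the cohort exactly.
#' @return A `copd_cohort` list of parallel person-level vectors.
#' @export
generate_cohort <- function(n, params = default_parameters(), seed = 1L) {
  if (n < 0) stop("domain error: n must be non-negative")
  n <- as.integer(n)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  sex <- 1L + (runif(n) >= params$p_male)          # 1 male, 2 female
  band <- sample.int(5L, n, replace = TRUE, prob = params$band_weights)
  lo <- c(35, 40, 50, 60, 70)[band]
  hi <- c(40, 50, 60, 70, min(80, params$age_range[2]) + 1)[band]
  hi <- pmin(hi, params$age_range[2])
  age <- lo + runif(n) * (hi - lo)

  prev <- cbind(params$prevalence$male, params$prevalence$female)
  has_copd <- runif(n) < prev[cbind(band, sex)]

  fev1_pct <- rep(NA_real_, n)
  stage <- integer(n)
  for (sx in 1:2) {
    idx <- which(has_copd & sex == sx)
    if (!length(idx)) next
    par <- params$fev1pct_initial[[SEXES[sx]]]
    fev1_pct[idx] <- rtrunc_norm(runif(length(idx)), par["mean"], par["sd"],
                                 params$fev1pct_bounds[1], params$fev1pct_bounds[2])
  }
  stage[has_copd] <- gold_stage(fev1_pct[has_copd])

  diagnosed <- rep(FALSE, n)
  idx <- which(has_copd)
  diagnosed[idx] <- runif(length(idx)) < params$initial_diagnosed[stage[idx]]

  treat_id <- integer(n)
  dxi <- which(diagnosed)
  if (length(dxi)) {
    up <- runif(length(dxi)) < params$p_treat_uptake
    treat_id[dxi[up]] <- draw_archetype(stage[dxi[up]], params, runif(sum(up)))
  }

  fev1 <- rep(NA_real_, n)
  ci <- which(has_copd)
  fev1[ci] <- fev1_pct[ci] * predicted_fev1(sex[ci], age[ci], params)

  structure(list(
    n = n, id = seq_len(n), sex = sex, age = age,
    has_copd = has_copd, fev1_pct = fev1_pct, fev1 = fev1, stage = stage,
    diagnosed = diagnosed, treat_id = treat_id,
    months_since_exac = rep(Inf, n),
    months_on_treat = numeric(n),
    alive = rep(TRUE, n), death_cause = integer(n),
    creation_seed = as.integer(seed),
    parameters_hash = cohort_params_hash(params)),
    class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("<copd_cohort> n = %d, %.1f%% male, %.2f%% COPD, seed %d\n",
              x$n, 100 * mean(x$sex == 1), 100 * mean(x$has_copd),
              x$creation_seed))
  invisible(x)
}

#' Sample this cycle's incident COPD cases
#'
#' Each living person without COPD converts with probability
#' `annual_rate_to_cycle_prob(incidence[sex, band], cycle_years)`.
#' Converters receive an FEV1 percent-predicted drawn from the incident
#' truncated normal, a stage from the staging map, and are undiagnosed.
#'
#' @param cohort a `copd_cohort` (or the engine's live state).
#' @param params parameter set.
#' @param u,u_fev optional uniforms of length `cohort$n` (CRN streams);
#'   drawn internally when `NULL`.
#' @return list with `idx` (converting person indices), `fev1_pct` and
#'   `stage` for those persons.
#' @export
sample_incident_cases <- function(cohort, params, u = NULL, u_fev = NULL) {
  n <- cohort$n
  if (is.null(u)) u <- runif(n)
  if (is.null(u_fev)) u_fev <- runif(n)
  elig <- which(cohort$alive & !cohort$has_copd)
  if (!length(elig)) return(list(idx = integer(0), fev1_pct = numeric(0),
                                 stage = integer(0)))
  band <- age_band(cohort$age[elig])
  inc <- cbind(params$incidence$male, params$incidence$female)
  p <- annual_rate_to_cycle_prob(inc[cbind(band, cohort$sex[elig])],
                                 params$cycle_years)
  p[cohort$age[elig] > params$incidence_max_age] <- 0
  idx <- elig[u[elig] < p]
  if (!length(idx)) return(list(idx = integer(0), fev1_pct = numeric(0),
                                stage = integer(0)))
  fp <- numeric(length(idx))
  for (sx in 1:2) {
    sel <- cohort$sex[idx] == sx
    if (!any(sel)) next
    par <- params$fev1pct_incident[[SEXES[sx]]]
    fp[sel] <- rtrunc_norm(u_fev[idx[sel]], par["mean"], par["sd"],
                           params$fev1pct_bounds[1], params$fev1pct_bounds[2])
  }
  list(idx = idx, fev1_pct = fp, stage = gold_stage(fp))
}

#' Reference (predicted) FEV1 in liters
#'
#' A configurable linear-in-age reference: sex-specific value at age 35
#' declining by a fixed slope per year.  A person's absolute FEV1 is
#' `fev1_pct * predicted_fev1(sex, age)` everywhere in the model; GOLD
#' staging depends only on `fev1_pct` and is invariant to this fixture.
#'
#' @param sex `"male"`/`"female"` or 1/2.
#' @param age years, within `[35, max_age]`.
#' @param params parameter set.
#' @return Predicted FEV1 (liters), positive and non-increasing in age.
#' @export
predicted_fev1 <- function(sex, age, params = default_parameters()) {
  if (is.character(sex)) sex <- match(sex, SEXES)
  if (any(age < 35 | age > params$max_age))
    stop("domain error: age outside [35, max_age]")
  ref <- rbind(params$pred_fev1$male, params$pred_fev1$female)
  pmax(ref[sex, 1] + ref[sex, 2] * (age - 35), 0.3)
}

#' Write / read a cohort snapshot as CSV
#'
#' One row per person with the documented column dictionary (id, sex,
#' age, has_copd, fev1_pct, stage, diagnosed, treat_id,
#' months_since_exac, months_on_treat, alive, death_cause).
#' @param cohort a `copd_cohort`.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort[c("id", "sex", "age", "has_copd", "fev1_pct",
                               "fev1", "stage", "diagnosed", "treat_id",
                               "months_since_exac", "months_on_treat",
                               "alive", "death_cause")])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  out <- as.list(df)
  out$n <- nrow(df)
  out$months_since_exac <- as.numeric(out$months_since_exac)
  out$creation_seed <- NA_integer_
  out$parameters_hash <- NA_character_
  class(out) <- "copd_cohort"
  out
}
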