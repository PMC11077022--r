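test_that("a deterministic single person matches the hand-computed trace", {
  p <- params_deterministic()
  co <- manual_cohort(p, sex = 1L, age = 60, has_copd = TRUE,
                      fev1_pct = 0.70, diagnosed = TRUE)
  r <- run_policy(co, "none", p, seed = 1, max_cycles = 4,
                  return_state = TRUE)
  # spreadsheet trace: stage 2, utility 0.767 (multiplier mode at the
  # reference band), maintenance 24.25 * 3 per cycle, decline 60 ml/yr
  dfs <- 1.03^-(c(0.125, 0.375, 0.625, 0.875))
  expect_equal(r$total_qaly_discounted, 0.767 * 0.25 * sum(dfs))
  expect_equal(r$qaly_copd_patients_discounted, r$total_qaly_discounted)
  expect_equal(unname(r$cost_by_category["maintenance"]), 72.75 * sum(dfs))
  expect_equal(r$total_cost_discounted,
               unname(r$cost_by_category["maintenance"]))
  # 4 cycles x 15 ml off an initial 0.70 x 3.375 L
  expect_equal(r$state$fev1, 0.70 * 3.375 - 4 * 0.015)
  expect_equal(r$state$stage, 2L)
  expect_true(r$state$alive)
})

test_that("treatment acts as a 12-month course: effect and cost then stop", {
  p <- params_deterministic()
  co <- manual_cohort(p, sex = 1L, age = 60, has_copd = TRUE,
                      fev1_pct = 0.70, diagnosed = TRUE, treat_id = 1L)
  r <- run_policy(co, "none", p, seed = 1, max_cycles = 8,
                  return_state = TRUE)
  dfs4 <- 1.03^-(c(0.125, 0.375, 0.625, 0.875))
  # archetype 1 wipes out stage-2 decline (73 > 60) for four cycles,
  # and bills 20.21/month over exactly those four cycles
  expect_equal(unname(r$cost_by_category["treatment"]),
               20.21 * 3 * sum(dfs4))
  expect_equal(r$state$fev1, 0.70 * 3.375 - 4 * 0.015)  # only cycles 5-8
  expect_equal(r$state$treat_id, 0L)                    # course over
})

test_that("a zero-cycle horizon yields empty outcomes", {
  p <- default_parameters()
  co <- generate_cohort(100, p, seed = 1)
  r <- run_policy(co, "two_step:1y", p, seed = 1, max_cycles = 0)
  expect_equal(r$total_qaly_discounted, 0)
  expect_equal(r$total_cost_discounted, 0)
  expect_equal(r$n_exac_nonsevere + r$n_exac_severe, 0)
  expect_equal(r$n_screens, 0)
})

test_that("runs are reproducible and seeds matter", {
  p <- default_parameters()
  co <- generate_cohort(1500, p, seed = 2)
  a <- run_policy(co, "one_step:2y", p, seed = 5, max_cycles = 60)
  b <- run_policy(co, "one_step:2y", p, seed = 5, max_cycles = 60)
  c <- run_policy(co, "one_step:2y", p, seed = 6, max_cycles = 60)
  expect_equal(a$total_qaly_discounted, b$total_qaly_discounted)
  expect_equal(a$cost_by_category, b$cost_by_category)
  expect_false(a$total_qaly_discounted == c$total_qaly_discounted)
  # the engine does not disturb the caller's RNG stream
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(run_policy(co, "none", p, seed = 1, max_cycles = 4))
  x2 <- runif(1)
  expect_equal(x1, x2)
})

test_that("common random numbers couple policies exactly", {
  p <- default_parameters()
  co <- generate_cohort(1500, p, seed = 3)
  pair <- run_policy_set(co, list("none", "two_step:5y"), p, seed = 9)
  # rerunning the status quo alone reproduces its arm bit-for-bit
  solo <- run_policy(co, "none", p, seed = 9)
  expect_equal(pair[["none"]]$total_qaly_discounted,
               solo$total_qaly_discounted)
  expect_equal(pair[["none"]]$n_copd_deaths, solo$n_copd_deaths)
  # duplicate policies and a missing status quo are rejected
  expect_error(run_policy_set(co, list("none", "none"), p), "duplicate")
  expect_error(run_policy_set(co, list("two_step:1y"), p), "status quo")
  # independent mode is still seed-deterministic
  i1 <- run_policy_set(co, list("none", "one_step:1y"), p, seed = 4,
                       seed_mode = "independent")
  i2 <- run_policy_set(co, list("none", "one_step:1y"), p, seed = 4,
                       seed_mode = "independent")
  expect_equal(policy_results_table(i1), policy_results_table(i2))
})

test_that("screening can only act through diagnoses", {
  # with both test sensitivities zero, a screening arm's health outcomes
  # collapse onto the status quo under common random numbers
  p <- default_parameters()
  p$sq_sens <- 0; p$spiro_sens <- 0
  co <- generate_cohort(2000, p, seed = 8)
  res <- run_policy_set(co, list("none", "two_step:1y"), p, seed = 8)
  expect_equal(res[["two_step:1y"]]$total_qaly_discounted,
               res[["none"]]$total_qaly_discounted)
  expect_equal(res[["two_step:1y"]]$n_copd_deaths, res[["none"]]$n_copd_deaths)
  expect_equal(res[["two_step:1y"]]$n_exac_severe, res[["none"]]$n_exac_severe)
  # ... while still paying for the tests
  expect_gt(res[["two_step:1y"]]$total_cost_discounted,
            res[["none"]]$total_cost_discounted)
})

test_that("conservation and accounting invariants hold on a full run", {
  p <- default_parameters()
  co <- generate_cohort(3000, p, seed = 12)
  r <- run_policy(co, "two_step:2y", p, seed = 12, return_state = TRUE)
  st <- r$state
  expect_equal(sum(st$alive) + sum(!st$alive), 3000)
  expect_true(all(st$death_cause[!st$alive] %in% 1:2))
  expect_true(all(st$death_cause[st$alive] == 0))
  expect_equal(r$n_copd_deaths, sum(st$death_cause == 2))
  expect_equal(r$total_cost_discounted, sum(r$cost_by_category))
  expect_lte(r$qaly_copd_patients_discounted, r$total_qaly_discounted)
  expect_lte(r$total_qaly_discounted, r$total_qaly_undiscounted)
  expect_true(all(unlist(r[c("n_exac_nonsevere", "n_exac_severe",
                             "n_copd_deaths", "n_screens", "n_spiro_tests",
                             "n_confirm_tests")]) >= 0))
  expect_lte(r$n_confirm_tests, r$n_spiro_tests)
  expect_lte(r$n_spiro_tests, r$n_screens)
})

test_that("screening volume is monotone in frequency under CRN", {
  p <- default_parameters()
  co <- generate_cohort(4000, p, seed = 15)
  pols <- list("none", "two_step:once", "two_step:10y", "two_step:5y",
               "two_step:2y", "two_step:1y")
  res <- run_policy_set(co, pols, p, seed = 15)
  screens <- vapply(res[-1], `[[`, 0, "n_screens")
  expect_true(all(diff(screens) >= 0))
  scost <- vapply(res[-1], function(r) r$cost_by_category[["screening"]], 0)
  expect_true(all(diff(scost) > 0))
  # diagnosed head counts never fall behind the status quo
  dx <- vapply(res, function(r) r$n_new_dx_by_screen + r$n_new_dx_by_symptom, 0)
  expect_true(all(dx[-1] >= dx[1]))
})

test_that("cohort/parameter consistency is enforced", {
  p <- default_parameters()
  co <- generate_cohort(100, p, seed = 1)
  p2 <- p
  p2$prevalence$male <- rep(0.5, 5)
  expect_error(run_policy(co, "none", p2, seed = 1), "consistency error")
  # cascade overrides (linkage scenarios) do not invalidate the cohort
  p3 <- p
  p3$p_followup_dx <- 1
  expect_s3_class(run_policy(co, "none", p3, seed = 1, max_cycles = 2),
                  "copd_policy_result")
})
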