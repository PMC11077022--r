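test_that("ICERs and dominance verdicts follow the definitions", {
  ic <- icer(list(qaly = 7000, cost = 56e6), list(qaly = 0, cost = 0))
  expect_equal(ic$icer, 8000)
  expect_equal(ic$verdict, "icer")
  expect_equal(icer(list(qaly = 10, cost = 5), list(qaly = 8, cost = 9))$verdict,
               "dominates")
  expect_equal(icer(list(qaly = 8, cost = 9), list(qaly = 10, cost = 5))$verdict,
               "dominated")
  expect_equal(icer(list(qaly = 8, cost = 9), list(qaly = 8, cost = 9))$verdict,
               "undefined")
  # equal QALYs at higher cost is dominated, not a division
  expect_equal(icer(list(qaly = 8, cost = 10), list(qaly = 8, cost = 9))$verdict,
               "dominated")
})

# brute-force oracle: a policy is off the frontier iff some other policy
# (strict dominance) or convex blend of two policies (extended dominance)
# achieves at least its QALYs at strictly lower cost, or more QALYs at no
# greater cost
frontier_oracle <- function(qaly, cost) {
  n <- length(qaly)
  member <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      if (qaly[j] >= qaly[i] && cost[j] <= cost[i] &&
          (qaly[j] > qaly[i] || cost[j] < cost[i])) member[i] <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (qaly[j] <= qaly[i] && qaly[i] <= qaly[k] && qaly[k] > qaly[j]) {
          lam <- (qaly[k] - qaly[i]) / (qaly[k] - qaly[j])
          blend_cost <- lam * cost[j] + (1 - lam) * cost[k]
          if (blend_cost < cost[i]) member[i] <- FALSE
        }
      }
    }
  }
  member
}

test_that("the frontier agrees with a convex-hull oracle on random instances", {
  set.seed(123)
  for (trial in 1:60) {
    n <- sample(2:8, 1)
    qaly <- runif(n, 100, 200)
    cost <- runif(n, 0, 100)
    mine <- copdsim:::frontier_members(qaly, cost)
    oracle <- frontier_oracle(qaly, cost)
    expect_equal(mine, oracle,
                 label = paste("trial", trial, ":", toString(round(qaly, 2)),
                               "/", toString(round(cost, 2))))
  }
})

test_that("frontier membership is invariant to ordering and cost scaling", {
  set.seed(7)
  qaly <- runif(7, 10, 20); cost <- runif(7, 5, 50)
  base <- copdsim:::frontier_members(qaly, cost)
  perm <- sample(7)
  expect_equal(copdsim:::frontier_members(qaly[perm], cost[perm])[order(perm)],
               base[order(seq_len(7))])
  expect_equal(copdsim:::frontier_members(qaly, cost * 1e4), base)
})

test_that("the published table reproduces its dominance annotations", {
  tab <- cea_table(published_policy_table())
  frontier <- tab$policy[tab$frontier_member]
  expect_setequal(frontier, c("none", "two_step:10y", "two_step:2y",
                              "two_step:1y", "one_step:1y"))
  dominated <- tab$policy[!tab$frontier_member]
  expect_setequal(dominated, c("two_step:once", "one_step:once",
                               "one_step:10y", "two_step:5y", "one_step:5y",
                               "one_step:2y", "two_step:2y", "two_step:1y",
                               "one_step:1y")[1:6])
  # frontier ICERs strictly increase and match the printed ladder
  fr <- tab[tab$frontier_member & tab$policy != "none", ]
  fr <- fr[order(fr$qaly), ]
  expect_true(all(diff(fr$icer_on_frontier) > 0))
  expect_equal(fr$icer_on_frontier[fr$policy == "two_step:10y"], 8034,
               tolerance = 0.001)
  expect_equal(fr$icer_on_frontier[fr$policy == "two_step:2y"], 8526,
               tolerance = 0.01)
  expect_equal(fr$icer_on_frontier[fr$policy == "two_step:1y"], 13671,
               tolerance = 0.01)
  # the status-quo row carries no ICER
  expect_true(is.na(tab$icer_vs_statusquo[tab$policy == "none"]))
})

test_that("averted-event arithmetic matches the published cells", {
  tab <- published_policy_table()
  sq <- tab[tab$policy == "none", ]
  ann1 <- tab[tab$policy == "one_step:1y", ]
  expect_equal(averted(ann1$deaths, sq$deaths)$count, 4811)
  expect_equal(averted(ann1$deaths, sq$deaths)$percent, 8.10, tolerance = 0.001)
  once2 <- tab[tab$policy == "two_step:once", ]
  av <- averted(once2$exac, sq$exac)
  expect_equal(av$count, 14002)
  expect_equal(av$percent, 0.58, tolerance = 0.01)
  expect_equal(averted(once2$deaths, sq$deaths)$percent, 0.39,
               tolerance = 0.01)
  expect_equal(averted(ann1$exac, sq$exac)$percent, 2.70, tolerance = 0.001)
  expect_equal(averted(5, 5)$count, 0)
  expect_true(is.na(averted(3, 0)$percent))
})

test_that("the most cost-effective policy walks up the frontier to the WTP", {
  tab <- cea_table(published_policy_table())
  expect_equal(most_cost_effective(tab, 38441), "two_step:1y")
  expect_equal(most_cost_effective(tab, 12813), "two_step:2y")
  expect_equal(most_cost_effective(tab, 100), "none")
  expect_equal(most_cost_effective(tab, 1e9), "one_step:1y")
})

test_that("CEAC probabilities partition and match a Gaussian oracle", {
  # single replicate: the winner takes probability one everywhere
  s1 <- tibble::tibble(rep = 1, policy = c("a", "b"),
                       qaly = c(10, 11), cost = c(0, 5))
  cc <- ceac(s1, c(0, 3, 1000))
  expect_equal(cc$probability[cc$policy == "a"], c(1, 1, 0))
  expect_equal(cc$probability[cc$policy == "b"], c(0, 0, 1))
  expect_error(ceac(s1, numeric(0)), "empty")

  # Gaussian oracle: B's incremental (dQ, dC) ~ independent normals
  set.seed(42)
  nrep <- 4000
  muQ <- 1; sdQ <- 0.8; muC <- 20000; sdC <- 15000
  dQ <- rnorm(nrep, muQ, sdQ); dC <- rnorm(nrep, muC, sdC)
  samples <- tibble::tibble(
    rep = rep(seq_len(nrep), each = 2),
    policy = rep(c("sq", "new"), nrep),
    qaly = as.vector(rbind(0, dQ)),
    cost = as.vector(rbind(0, dC)))
  for (lam in c(10000, 25000, 60000)) {
    cc <- ceac(samples, lam)
    p_hat <- cc$probability[cc$policy == "new"]
    p_true <- pnorm((lam * muQ - muC) / sqrt(lam^2 * sdQ^2 + sdC^2))
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / nrep))
    expect_equal(sum(cc$probability), 1)
  }
  # ties split equally
  s3 <- tibble::tibble(rep = 1, policy = c("a", "b"),
                       qaly = c(10, 10), cost = c(5, 5))
  cc3 <- ceac(s3, 500)
  expect_equal(cc3$probability, c(0.5, 0.5))
})

test_that("PSA draws stay in-support and reduce to the base case", {
  p <- default_parameters()
  set.seed(11)
  for (k in 1:20) {
    pr <- copdsim:::draw_psa_params(p, default_psa_spec(p))
    expect_true(all(c(pr$sq_sens, pr$sq_spec, pr$p_followup_dx,
                      pr$p_treat_uptake, pr$utility_stage) >= 0))
    expect_true(all(c(pr$sq_sens, pr$sq_spec, pr$utility_stage) <= 1))
    expect_true(all(c(pr$cost_exac_severe, pr$exac_rate_nonsevere) >= 0))
    expect_true(all(pr$mortality_hr >= 1))
  }
  samples <- run_psa(cohort_size = 400, n_reps = 3,
                     policies = list("none", "two_step:1y"),
                     params = p, seed = 5)
  expect_equal(nrow(samples), 6)
  expect_true(all(samples$cost >= 0))
  samples2 <- run_psa(cohort_size = 400, n_reps = 3,
                      policies = list("none", "two_step:1y"),
                      params = p, seed = 5)
  expect_equal(samples$qaly, samples2$qaly)
  # CEAC at zero willingness-to-pay backs the cheapest policy
  cc <- ceac(samples, 0)
  cheapest <- vapply(split(samples, samples$rep),
                     function(d) d$policy[which.min(d$cost)], "")
  expect_equal(cc$probability[cc$policy == "none"],
               mean(cheapest == "none"))
})

test_that("one-way sweeps and the linkage grid run end to end", {
  p <- default_parameters()
  co <- generate_cohort(800, p, seed = 19)
  sw <- one_way_sweep("cost_exac_severe", 2987.06, 2987.06, co,
                      policies = list("none", "two_step:1y"),
                      params = p, seed = 19)
  expect_equal(sw$icer_low, sw$icer_high)
  expect_equal(sw$span, 0)
  sw2 <- one_way_sweep("mortality_hr.3", 1.5, 4.0, co,
                       policies = list("none", "two_step:1y"),
                       params = p, seed = 19)
  expect_gt(sw2$span, 0)
  expect_error(one_way_sweep("no_such_thing", 0, 1, co, params = p),
               "unknown parameter path")
  grid <- linkage_scenario_grid(co, p, dx_probs = 0.4, treat_probs = 0.3,
                                policies = list("none", "two_step:1y"),
                                seed = 19)
  expect_equal(nrow(grid), 1)
  expect_true(grid$best_policy %in% c("none", "two_step:1y"))
})
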