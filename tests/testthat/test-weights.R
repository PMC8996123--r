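test_that("multinomial logit recovers known coefficients", {
  set.seed(31)
  n <- 6000
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  B <- cbind(c(-0.5, 0.8, -0.6), c(0.3, -0.4, 0.9))
  P <- longsig:::softmax_probs(x, B)
  y <- apply(P, 1, function(p) sample(c("NONE", "FIRST_GEN", "SECOND_GEN"),
                                      1, prob = p))
  fit <- longsig:::fit_multinom(x, y,
                                levels_ = c("NONE", "FIRST_GEN", "SECOND_GEN"))
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients - B)), 0.15)
  ## predicted probabilities are proper
  pr <- predict(fit, x)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  ## a never-observed class is an error, not a silent omission
  expect_error(longsig:::fit_multinom(x, rep("NONE", n),
                                      levels_ = c("NONE", "FIRST_GEN",
                                                  "SECOND_GEN")),
               "never observed")
})

test_that("stabilized weights are 1 when numerator equals denominator", {
  sim <- simulate_cohort(scenario_presets("confounded", n_patients = 400,
                                          horizon_months = 36, seed = 12))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  ip <- interval_panel(pan)
  den <- fit_treatment_model(ip, c("edss", "relapses_6m"))
  w_same <- stabilized_iptw(ip, den, numerator = den, truncate = NULL)
  expect_lt(max(abs(w_same$weight - 1)), 1e-10)
})

test_that("stabilized weights are positive with mean near 1, and truncate", {
  sim <- simulate_cohort(scenario_presets("confounded", n_patients = 1200,
                                          horizon_months = 48, seed = 13))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  ip <- interval_panel(pan)
  den <- fit_treatment_model(ip, c("edss", "relapses_6m"))
  w <- stabilized_iptw(ip, den)
  expect_true(all(is.finite(w$weight) & w$weight > 0))
  expect_lt(abs(mean(w$weight) - 1), 0.1)
  di <- attr(w, "diagnostics")
  expect_lte(max(w$weight), di$truncation_bounds[2] + 1e-12)
  raw <- stabilized_iptw(ip, den, truncate = NULL)
  expect_gte(max(raw$weight), max(w$weight))
})

test_that("fitted assignment probabilities track the simulator's truth", {
  sim <- simulate_cohort(scenario_presets("confounded", n_patients = 2000,
                                          horizon_months = 48, seed = 14))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  ip <- interval_panel(pan)
  den <- fit_treatment_model(ip, c("edss", "relapses_6m"))
  des <- longsig:::treatment_design(ip, den$covariates, TRUE)
  fitted_p <- predict(den, des$X)[, "SECOND_GEN"]
  tr <- sim$truth$assignments[, .(participant_id, month, p_second)]
  key <- data.table(participant_id = ip$participant_id[des$ok],
                    month = ip$month0[des$ok], fitted = fitted_p)
  m <- merge(key, tr, by = c("participant_id", "month"))
  expect_gt(nrow(m), 1000)
  expect_gt(cor(m$fitted, m$p_second, method = "spearman"), 0.9)
})

test_that("weighting balances covariates on the confounded preset", {
  sim <- simulate_cohort(scenario_presets("confounded", n_patients = 1500,
                                          horizon_months = 48, seed = 15))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  ip <- interval_panel(pan)
  den <- fit_treatment_model(ip, c("edss", "relapses_6m"))
  w <- stabilized_iptw(ip, den)
  pre <- balance_table(ip, NULL)
  post <- balance_table(ip, w)
  expect_lt(max(post$max_smd), max(pre$max_smd))
  expect_lt(max(post$max_smd), 0.1)
})

test_that("episode propensity weights invert the fitted propensity", {
  ## two identical episodes, one exposed, one not: fitted propensity 0.5,
  ## both weights 2
  et <- data.table(participant_id = c("A", "B"),
                   stratum = "NO_PRIOR_FIRST_GEN",
                   exposed = c(TRUE, FALSE), edss = 2, relapses_6m = 0)
  out <- episode_propensity_weights(et, truncate = NULL)
  expect_equal(out$propensity, c(0.5, 0.5))
  expect_equal(out$weight, c(2, 2))
})

test_that("weighted cells reduce to tabulate with unit weights", {
  sim <- simulate_cohort(scenario_presets("null", n_patients = 300,
                                          horizon_months = 24, seed = 16))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  cp <- apply_incident_censoring(pan, "INFECTION")
  ip <- interval_panel(pan)
  ones <- data.table(participant_id = ip$participant_id,
                     interval = ip$interval, weight = 1)
  tab_w <- weighted_cells(cp, ones, "CLASS:SECOND_GEN")
  tab_u <- tabulate_panel(cp, "CLASS:SECOND_GEN")
  expect_equal(unlist(tab_w[1:4]), unlist(tab_u[1:4]))
  ## doubling all weights leaves ratio measures unchanged
  twos <- copy(ones)[, weight := 2]
  tab_2 <- weighted_cells(cp, twos, "CLASS:SECOND_GEN")
  expect_close(prr(tab_2)$point, prr(tab_u)$point)
})
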