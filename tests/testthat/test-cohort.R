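make_cohort <- function(episodes, events = NULL, n_months = 40L) {
  d0 <- as.Date("2020-01-01")
  ids <- unique(c(episodes$participant_id, events$participant_id, "N1"))
  pt <- data.table(id = ids, sex = "F", birth_date = d0 - 13000,
                   enrolment_date = d0, exit_date = d0 + n_months * 30,
                   baseline_edss = 2)
  if (is.null(events)) {
    events <- data.table(participant_id = character(), category = character(),
                         subtype = character(),
                         event_date = as.Date(character()))
  }
  list(participants = pt, episodes = episodes, events = events, d0 = d0)
}

test_that("new-user cohort excludes pre-enrolment second-generation use", {
  d0 <- as.Date("2020-01-01")
  pt <- data.table(id = c("A", "B", "C"), sex = "F", birth_date = d0 - 13000,
                   enrolment_date = d0)
  eps <- data.table(
    participant_id = c("A", "B"),
    drug = c("NATALIZUMAB", "IFN_BETA_1B"),
    start_date = d0 - c(400, 400), end_date = d0 - c(100, 100))
  out <- select_new_user_cohort(pt, eps)
  expect_setequal(out$id, c("B", "C"))
})

test_that("primary episodes split follow-up at initiation and cessation", {
  d0 <- as.Date("2020-01-01")
  eps <- data.table(
    participant_id = c("S1", "S2", "S2"),
    drug = c("OCRELIZUMAB", "IFN_BETA_1A_SC", "OCRELIZUMAB"),
    start_date = d0 + c(12, 0, 12) * 30,
    end_date = d0 + c(30, 12, 30) * 30)
  cc <- make_cohort(eps)
  pan <- build_panel(cc$participants, cc$episodes, cc$events,
                     exposure_def = "E1")
  et <- build_primary_episodes(pan, "INFECTION")
  ## S1: unexposed [0,12), exposed [12,30); months 30-40 excluded
  s1 <- et[participant_id == "S1"][order(start_month)]
  expect_equal(s1$start_month, c(0L, 12L))
  expect_equal(s1$end_month, c(12L, 30L))
  expect_equal(s1$exposed, c(FALSE, TRUE))
  expect_equal(unique(s1$stratum), "NO_PRIOR_FIRST_GEN")
  ## S2: first-gen before 2G -> PRIOR_FIRST_GEN stratum
  expect_equal(unique(et[participant_id == "S2", stratum]),
               "PRIOR_FIRST_GEN")
  ## never-treated participant: single unexposed episode spanning follow-up
  n1 <- et[participant_id == "N1"]
  expect_equal(nrow(n1), 1L)
  expect_false(n1$exposed)
  expect_equal(n1$end_month - n1$start_month, 40L)
  ## person-time conservation: episodes partition follow-up to 2G cessation
  tot <- et[, .(pt = sum(end_month - start_month)), by = participant_id]
  expect_equal(tot[participant_id == "S1", pt], 30L)
  expect_equal(tot[participant_id == "N1", pt], 40L)
})

test_that("outcome events censor primary episodes", {
  d0 <- as.Date("2020-01-01")
  eps <- data.table(participant_id = "S1", drug = "OCRELIZUMAB",
                    start_date = d0 + 12 * 30, end_date = d0 + 30 * 30)
  ev <- data.table(participant_id = "S1", category = "INFECTION",
                   subtype = NA_character_, event_date = d0 + 20 * 30 + 5)
  cc <- make_cohort(eps, ev)
  pan <- build_panel(cc$participants, cc$episodes, cc$events,
                     exposure_def = "E1")
  et <- build_primary_episodes(pan, "INFECTION")
  s1 <- et[participant_id == "S1"][order(start_month)]
  expect_equal(s1$end_month, c(12L, 21L))     # censored after event month
  expect_equal(s1$outcome, c(0L, 1L))
})

test_that("exposure models A-D build the documented covariates", {
  d0 <- as.Date("2020-01-01")
  ## 18 months continuous 2G from enrolment, then nothing
  eps <- data.table(participant_id = "S1", drug = "FINGOLIMOD",
                    start_date = d0, end_date = d0 + 18 * 30)
  cc <- make_cohort(eps, n_months = 36L)
  pan <- build_panel(cc$participants, cc$episodes, cc$events,
                     exposure_def = "E1")
  ip <- interval_panel(pan)
  s1 <- function(x) x[x$participant_id == "S1"]

  ia <- build_exposure_covariates(pan, ip, "A_CURRENT")
  expect_equal(s1(ia)$cur_second, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  ic <- build_exposure_covariates(pan, ip, "C_CUMULATIVE")
  ## cumulative months through the end of each interval
  expect_equal(s1(ic)$cum_second, c(6L, 12L, 18L, 18L, 18L, 18L))
  expect_equal(s1(ic)$cum_first, rep(0L, 6))

  idec <- build_exposure_covariates(pan, ip, "D_DECAYED", decay_half_life = 6)
  ## interval starting at month 24: months 18..23 unexposed, exposed months
  ## at lags 7..24 relative to month 24
  lag_contrib <- sum(2^(-(7:24) / 6))
  expect_close(s1(idec)$dec_second[5], lag_contrib, 1e-10)
  ## single exposed month 6 months before an interval start contributes 0.5:
  ## month 12 exposure seen from interval starting at 18 has lag 6
  eps2 <- data.table(participant_id = "S1", drug = "FINGOLIMOD",
                     start_date = d0 + 12 * 30, end_date = d0 + 13 * 30)
  cc2 <- make_cohort(eps2, n_months = 36L)
  pan2 <- build_panel(cc2$participants, cc2$episodes, cc2$events,
                      exposure_def = "E1")
  ip2 <- interval_panel(pan2)
  id2 <- build_exposure_covariates(pan2, ip2, "D_DECAYED",
                                   decay_half_life = 6)
  expect_close(s1(id2)$dec_second[4], 0.5, 1e-10)   # interval month0 = 18

  ## model B: switched 1G -> 2G three months before an interval start
  eps3 <- data.table(participant_id = c("S1", "S1"),
                     drug = c("IFN_BETA_1B", "FINGOLIMOD"),
                     start_date = d0 + c(0, 9) * 30,
                     end_date = d0 + c(9, 36) * 30)
  cc3 <- make_cohort(eps3, n_months = 36L)
  pan3 <- build_panel(cc3$participants, cc3$episodes, cc3$events,
                      exposure_def = "E1")
  ip3 <- interval_panel(pan3)
  ib3 <- build_exposure_covariates(pan3, ip3, "B_CARRYOVER")
  r2 <- s1(ib3)[3]   # interval months 12-17: current 2G, 1G 3 months back
  expect_true(r2$cur_second)
  expect_true(r2$carry_first)
  expect_false(r2$carry_second)
  ## never-treated participant: all exposure covariates zero
  nt <- ib3[ib3$participant_id == "N1"]
  expect_false(any(nt$cur_first | nt$cur_second | nt$carry_first |
                     nt$carry_second))
  expect_error(build_exposure_covariates(pan3, ip3, "E_NOPE"))
})

test_that("outcome models: null calibration of the primary analysis", {
  covered <- 0L
  for (s in 1:6) {
    sim <- simulate_cohort(scenario_presets("null", n_patients = 500,
                                            horizon_months = 36,
                                            seed = 300 + s))
    pan <- build_panel(sim$participants, sim$episodes, sim$events,
                       edss = sim$edss, exposure_def = "E1")
    et <- build_primary_episodes(pan, "INFECTION")
    m_cox <- fit_outcome_model(et, "exposed", method = "cox",
                               strata_col = "stratum")
    if (m_cox$ci_low[1] <= 1 && m_cox$ci_high[1] >= 1) covered <- covered + 1L
  }
  expect_gte(covered, 4L)      # nominal 95%, Monte-Carlo margin
  expect_error(fit_outcome_model(
    data.table(participant_id = "A", tstart = 0, tstop = 5, outcome = 0L,
               exposed = TRUE), "exposed"), "no events")
})

test_that("pooled discrete-time fit agrees with the partial likelihood", {
  ## agreement is asymptotic; checked at a scale with ~700 events
  sim <- simulate_cohort(scenario_presets("confounded", n_patients = 2500,
                                          horizon_months = 48, seed = 311))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  et <- build_primary_episodes(pan, "INFECTION")
  etw <- suppressWarnings(episode_propensity_weights(et))
  m_cox <- fit_outcome_model(etw, "exposed", weights = etw$weight,
                             method = "cox", strata_col = "stratum")
  m_pois <- fit_outcome_model(etw, "exposed", weights = etw$weight,
                              method = "pooled")
  expect_lt(abs(m_pois$estimate[1] - m_cox$estimate[1]),
            max(0.05 * abs(m_cox$estimate[1]), 0.03))
})

test_that("planted carryover-by-current-class interaction is recovered", {
  sim <- simulate_cohort(scenario_presets("switching_carryover",
                                          n_patients = 3000,
                                          horizon_months = 60, seed = 17))
  pan <- build_panel(sim$participants, sim$episodes, sim$events,
                     edss = sim$edss, exposure_def = "E1")
  ip <- interval_panel(pan)
  io <- interval_outcomes(pan, ip, "INFECTION")
  m <- tertiary_interaction(pan, io, weights = NULL)
  ## hazard doubled in post-1G months only while on 2G: positive interaction
  expect_gt(m[term == "int_2g_carry1gTRUE", estimate], 0)
})
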