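test_that("exposure window arithmetic follows the active definition", {
  ## episode spans months 3-5 (days 90..179, end exclusive)
  p1 <- tiny_panel("E1")
  fA <- p1[p1$participant_id == "A"]
  expect_equal(fA$exp_NATALIZUMAB, c(rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 5)))

  p3 <- tiny_panel("E3")
  fA3 <- p3[p3$participant_id == "A"]
  expect_equal(fA3$exp_NATALIZUMAB, c(rep(FALSE, 3), rep(TRUE, 9)))

  ## untreated participant: never exposed, class NONE throughout
  fB <- p1[p1$participant_id == "B"]
  expect_false(any(fB$exp_NATALIZUMAB))
  expect_true(all(fB$cur_class == "NONE"))
})

test_that("window nesting E1 => E2 => E3 holds over random episode sets", {
  set.seed(41)
  d0 <- as.Date("2021-06-01")
  for (rep_i in 1:5) {
    n <- 5L
    pt <- data.table(id = sprintf("P%d", 1:n), sex = "F",
                     birth_date = d0 - 12000, enrolment_date = d0,
                     exit_date = d0 + 24 * 30)
    eps <- rbindlist(lapply(1:n, function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      st <- sort(sample(0:600, k))
      data.table(participant_id = sprintf("P%d", i),
                 drug = sample(c("FINGOLIMOD", "RITUXIMAB"), k, TRUE),
                 start_date = d0 + st,
                 end_date = d0 + st + sample(20:200, k, TRUE))
    }))
    if (is.null(eps) || nrow(eps) == 0) next
    ev <- data.table(participant_id = "P1", category = "OTHER_SAE",
                     subtype = NA, event_date = d0 + 100)
    pans <- lapply(c("E1", "E2", "E3"), function(d)
      suppressWarnings(build_panel(pt, eps, ev, exposure_def = d)))
    for (dcol in grep("^exp_", names(pans[[1]]), value = TRUE)) {
      expect_true(all(!pans[[1]][[dcol]] | pans[[2]][[dcol]]), label = dcol)
      expect_true(all(!pans[[2]][[dcol]] | pans[[3]][[dcol]]), label = dcol)
    }
    ## brute-force oracle on the E-definitions, day-by-day membership
    epsn <- suppressWarnings(normalize_episodes(eps))
    for (def_i in 1:3) {
      pan <- pans[[def_i]]
      for (i in 1:n) {
        pid <- sprintf("P%d", i)
        for (dg in unique(epsn[participant_id == pid, drug])) {
          days <- epsn[participant_id == pid & drug == dg, {
            unlist(Map(seq.int, as.integer(start_date - d0),
                       as.integer(end_date - d0) - 1L))
          }]
          got <- pan[participant_id == pid][[paste0("exp_", dg)]]
          want <- vapply(seq_along(got) - 1L, function(m)
            naive_flag(days, m, c("E1", "E2", "E3")[def_i]), logical(1))
          expect_equal(got, want,
                       label = paste("oracle", pid, dg, def_i))
        }
      }
    }
  }
})

test_that("incident censoring keeps only the first event month", {
  pan <- tiny_panel("E1")
  cp <- apply_incident_censoring(pan, "INFECTION")
  a <- cp[cp$participant_id == "A"]
  ## events at months 4 and 9: keep months 0..4, event at 4 only
  expect_equal(max(a$month), 4L)
  expect_equal(a$event, c(rep(FALSE, 4), TRUE))
  ## no-event participant untouched
  expect_equal(nrow(cp[cp$participant_id == "C"]), 12L)
  ## subtype-level key: "uti" event is at month 9
  cps <- apply_incident_censoring(pan, c("INFECTION", "uti"))
  expect_equal(max(cps[cps$participant_id == "A"]$month), 9L)
  ## at-risk months never increase; equal iff no occurrences
  expect_lte(nrow(cp), nrow(pan))
  cpn <- apply_incident_censoring(pan, "COVID19")
  expect_equal(nrow(cpn), nrow(pan))
})

test_that("panel construction is deterministic and validates inputs", {
  tc <- tiny_cohort()
  p1 <- suppressWarnings(build_panel(tc$participants, tc$episodes, tc$events))
  p2 <- suppressWarnings(build_panel(tc$participants, tc$episodes, tc$events))
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  bad <- copy(tc$events)[1, participant_id := "ZZ"]
  expect_error(build_panel(tc$participants, tc$episodes, bad), "unknown")
  ## pre-enrolment event: warned, excluded from analysis events
  pre <- copy(tc$events)[1, event_date := tc$participants$enrolment_date[1] - 10]
  expect_warning(build_panel(tc$participants, tc$episodes, pre),
                 "pre-enrolment")
})

test_that("episode normalization merges, truncates, and rejects bad input", {
  d0 <- as.Date("2020-01-01")
  ## same-drug overlap merges
  ep <- data.table(participant_id = "A", drug = "FINGOLIMOD",
                   start_date = d0 + c(0, 50), end_date = d0 + c(60, 120))
  out <- normalize_episodes(ep)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end_date, d0 + 120)
  ## cross-drug overlap: earlier truncated at later's start, with warning
  ep2 <- data.table(participant_id = "A",
                    drug = c("FINGOLIMOD", "RITUXIMAB"),
                    start_date = d0 + c(0, 40), end_date = d0 + c(100, 200))
  expect_warning(out2 <- normalize_episodes(ep2), "truncated")
  expect_equal(out2[drug == "FINGOLIMOD", end_date], d0 + 40)
  expect_error(normalize_episodes(
    data.table(participant_id = "A", drug = "FINGOLIMOD",
               start_date = d0 + 10, end_date = d0 + 10)), "end_date")
  expect_error(normalize_episodes(
    data.table(participant_id = "A", drug = "NOT_A_DRUG",
               start_date = d0, end_date = d0 + 10)), "unknown drug")
})

test_that("lymphopenia grading uses lower-inclusive half-open bins", {
  expect_equal(grade_lymphopenia(c(1200, 900, 600, 300, 150), 1000),
               c(0L, 1L, 2L, 3L, 4L))
  ## boundary values map to the less severe grade
  expect_equal(grade_lymphopenia(c(1000, 800, 500, 200), 1000),
               c(0L, 1L, 2L, 3L))
  expect_error(grade_lymphopenia(-1, 1000), "negative")
  expect_error(grade_lymphopenia(500, 700), "exceed 800")
})

test_that("liver classification uses strict 2.5x / 5x thresholds", {
  expect_equal(classify_liver(c(40, 3 * 40, 6 * 40), 40),
               c("NORMAL", "MODERATE", "SEVERE"))
  expect_equal(classify_liver(c(2.5, 5) * 40, 40), c("NORMAL", "MODERATE"))
  expect_error(classify_liver(10, 0), "positive")
})

test_that("EDSS progression compares to the most recent measurement", {
  d <- as.Date("2020-01-01") + c(0, 180, 360, 540)
  expect_equal(detect_edss_progression(d[1:3], c(3.0, 3.5, 4.5)), d[3])
  expect_equal(detect_edss_progression(d, c(3.0, 4.0, 3.0, 4.0)), d[c(2, 4)])
  expect_length(detect_edss_progression(d, c(3, 3, 3, 3)), 0)
  expect_length(detect_edss_progression(d[1], 3.0), 0)
  expect_error(detect_edss_progression(rev(d), c(3, 3, 3, 4)), "sorted")
})

test_that("lab outcome derivation finds first-onset events", {
  d0 <- as.Date("2020-01-01")
  labs <- data.table(
    participant_id = c("A", "A", "A", "B"),
    date = c(d0, d0 + 30, d0 + 60, d0),
    analyte = c("ALC", "ALC", "ALT", "ALT"),
    value = c(900, 300, 250, 30),
    lln = c(1000, 1000, 7, 7), uln = c(4000, 4000, 40, 40))
  out <- derive_lab_outcomes(labs)
  expect_equal(out[category == "LYMPHOPENIA_G3", event_date], d0 + 30)
  expect_equal(out[category == "LIVER_SEVERE", participant_id], "A")
  expect_false("B" %in% out$participant_id)
})
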