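## Shared fixtures, all built in code.

suppressMessages(library(data.table))

## A hand-built cohort: 3 participants, day-level control over episodes and
## events. Enrolment on the same date keeps month arithmetic easy to read.
tiny_cohort <- function() {
  d0 <- as.Date("2020-01-01")
  participants <- data.table(
    id = c("A", "B", "C"),
    sex = c("F", "M", "F"),
    birth_date = d0 - round(c(30, 45, 12) * 365.25),
    enrolment_date = d0,
    exit_date = d0 + 360,              # 12 months each
    baseline_edss = c(2, 3, 1.5)
  )
  ## A: NATALIZUMAB months 3-5 (days 90..179); B: untreated; C: interferon
  episodes <- data.table(
    participant_id = c("A", "C"),
    drug = c("NATALIZUMAB", "IFN_BETA_1A_IM"),
    start_date = c(d0 + 90, d0 + 0),
    end_date = c(d0 + 180, as.Date(NA))
  )
  events <- data.table(
    participant_id = c("A", "A", "B"),
    category = c("INFECTION", "INFECTION", "OTHER_SAE"),
    subtype = c("sepsis", "uti", NA),
    event_date = c(d0 + 4 * 30 + 10, d0 + 9 * 30 + 5, d0 + 200)
  )
  list(participants = participants, episodes = episodes, events = events)
}

tiny_panel <- function(exposure_def = "E1") {
  tc <- tiny_cohort()
  suppressWarnings(build_panel(tc$participants, tc$episodes, tc$events,
                               exposure_def = exposure_def))
}

## minimal censored-panel construction straight from cell counts: one row per
## patient-month with given exposure flag and (at most one) event per person
panel_from_cells <- function(n11, n10, n01, n00, weights = NULL) {
  rows <- list()
  pid <- 0L
  add <- function(k, exposed, event) {
    if (k == 0L) return(NULL)
    ## spread event months over distinct participants (incident logic)
    data.table(participant_id = sprintf("S%04d", seq_len(k) + pid),
               month = 0L, exp_X = exposed, event = event)
  }
  p <- rbindlist(list(
    {r <- add(n11, TRUE, TRUE); pid <- pid + n11; r},
    {r <- add(n10, TRUE, FALSE); pid <- pid + n10; r},
    {r <- add(n01, FALSE, TRUE); pid <- pid + n01; r},
    {r <- add(n00, FALSE, FALSE); pid <- pid + n00; r}
  ))
  p[, participant_id := sprintf("S%05d", .I)]   # ensure distinct ids
  p
}

## random small censored panel for identity sweeps: per-participant exposure
## spells and at most one event (already "incident-censored" by design)
random_panel <- function(n_pat = 30L, n_months = 24L) {
  g <- CJ(participant_id = sprintf("R%03d", seq_len(n_pat)),
          month = seq_len(n_months) - 1L)
  ## exposure: contiguous random spell per participant
  g[, exp_X := {
    s <- sample.int(n_months, 1L) - 1L
    len <- sample.int(n_months, 1L)
    month >= s & month < s + len
  }, by = participant_id]
  g[, event := FALSE]
  ## events: each participant has an event with prob 0.4 at a random month;
  ## censor months after it
  g[, keep := TRUE]
  for (p in unique(g$participant_id)) {
    if (runif(1) < 0.4) {
      em <- sample.int(n_months, 1L) - 1L
      g[participant_id == p & month == em, event := TRUE]
      g[participant_id == p & month > em, keep := FALSE]
    }
  }
  g <- g[keep == TRUE][, keep := NULL]
  g
}

## brute-force exposure oracle: day-by-day interval membership
naive_flag <- function(episode_days, m, def) {
  ## episode_days: integer days (relative to enrolment) on which any episode
  ## of the drug is active
  win <- switch(def,
    E1 = seq.int((m - 1L) * 30L, (m + 1L) * 30L - 1L),
    E2 = seq.int((m - 6L) * 30L, (m + 1L) * 30L - 1L),
    E3 = seq.int(-10000L, (m + 1L) * 30L - 1L))
  any(episode_days %in% win)
}

expect_close <- function(a, b, tol = 1e-8) expect_lt(abs(a - b), tol)

## Fixture: k affected participants on `drug` (event in an exposed month),
## plus exposed participants without events and untreated background with
## a few events so every measure is estimable.
gate_cohort <- function(drug, k_affected, n_exposed = 12L,
                        n_background = 30L, pediatric = FALSE) {
  d0 <- as.Date("2020-01-01")
  n <- n_exposed + n_background
  ids <- sprintf("G%03d", seq_len(n))
  age_days <- if (pediatric) round(15 * 365.25) else round(40 * 365.25)
  pt <- data.table(id = ids, sex = "F", birth_date = d0 - age_days,
                   enrolment_date = d0, exit_date = d0 + 24 * 30)
  eps <- data.table(participant_id = ids[seq_len(n_exposed)], drug = drug,
                    start_date = d0, end_date = d0 + 24 * 30)
  ev <- rbind(
    data.table(participant_id = ids[seq_len(k_affected)],
               category = "INFECTION", subtype = NA_character_,
               event_date = d0 + 5 * 30 + 3),
    data.table(participant_id = ids[n_exposed + 1:4],
               category = "INFECTION", subtype = NA_character_,
               event_date = d0 + 7 * 30 + 3))
  list(participants = pt, episodes = eps, events = ev)
}

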