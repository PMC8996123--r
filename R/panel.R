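## Panel module: the longitudinal patient-month data model.
##
## An analysis month is a fixed 30-day bin counted from each participant's
## own enrolment date (bin 0 starts on the enrolment day). Date intervals are
## half-open [start, end); an exposure episode touching any day of a bin sets
## that bin's "current month" exposure.

#' Exposure definitions
#'
#' The three windows under which a patient-month counts as exposed to a drug:
#' * `E1`: exposure within the month of interest or the previous month;
#' * `E2`: exposure within the month of interest or the preceding 6 months
#'   (the current month is included so that E1 implies E2 implies E3);
#' * `E3`: exposure at any prior time in the participant's treatment history,
#'   including pre-enrolment history.
#' @return Character vector of the three definition codes.
#' @export
exposure_definitions <- function() c("E1", "E2", "E3")

## trailing window width (months before the current one) per definition;
## E3 handled separately as "ever"
.exposure_lookback <- c(E1 = 1L, E2 = 6L)

#' Normalize exposure episodes
#'
#' Sorts episodes, merges overlapping or abutting episodes of the same drug,
#' and resolves overlaps between different drugs by truncating the earlier
#' episode at the later one's start (switch semantics, with a warning). Open
#' end dates (`NA`) are left open.
#'
#' @param episodes data.frame/data.table with columns `participant_id`,
#'   `drug`, `start_date`, `end_date` (and optionally `drug_class`).
#' @param vocab drug vocabulary, as from [dmt_vocabulary()].
#' @return A normalized `data.table` of episodes with `drug_class` filled in.
#' @export
normalize_episodes <- function(episodes, vocab = dmt_vocabulary()) {
  ep <- as.data.table(episodes)
  assert_that(all(c("participant_id", "drug", "start_date", "end_date")
                  %in% names(ep)),
              "episodes need participant_id, drug, start_date, end_date")
  ep[, start_date := as_date_strict(start_date, "start_date")]
  ep[, end_date := as_date_strict(end_date, "end_date")]
  ep[, drug_class := drug_class_of(drug, vocab)]
  bad <- ep[!is.na(end_date) & end_date <= start_date]
  if (nrow(bad) > 0L) stop_longsig("%d episode(s) with end_date <= start_date",
                                   nrow(bad))
  setorder(ep, participant_id, start_date, drug)

  ## merge same-drug overlaps/abutments
  ep[, grp := {
    s <- as.numeric(start_date)
    e <- as.numeric(ifelse(is.na(end_date), Inf, as.numeric(end_date)))
    cummax_end <- cummax(c(-Inf, head(e, -1L)))
    cumsum(s > cummax_end)
  }, by = .(participant_id, drug)]
  ep <- ep[, .(
    start_date = min(start_date),
    end_date = if (anyNA(end_date)) as.Date(NA) else max(end_date)
  ), by = .(participant_id, drug, drug_class, grp)][, grp := NULL]

  ## cross-drug overlaps: truncate the earlier episode at the later's start.
  ## After sorting by start, truncating each episode at its successor's start
  ## removes all overlaps in one pass (an overlap with episode i+2 implies an
  ## overlap with i+1, whose start is earlier).
  setorder(ep, participant_id, start_date, drug)
  nxt_start <- shift(ep$start_date, -1L)
  same_pid <- shift(ep$participant_id, -1L) == ep$participant_id
  clash <- !is.na(same_pid) & same_pid &
    (is.na(ep$end_date) | ep$end_date > nxt_start)
  trunc_n <- sum(clash)
  if (trunc_n > 0L) ep[clash, end_date := nxt_start[clash]]
  if (trunc_n > 0L) {
    warning(sprintf("%d overlapping episode(s) truncated at the next episode's start (switch semantics)",
                    trunc_n), call. = FALSE)
  }
  ep <- ep[is.na(end_date) | end_date > start_date]
  ## invariant check: no residual overlap
  ov <- ep[, {
    e <- as.numeric(ifelse(is.na(end_date), Inf, as.numeric(end_date)))
    .(bad = any(head(e, -1L) > as.numeric(start_date)[-1L]))
  }, by = participant_id][bad == TRUE]
  if (nrow(ov) > 0L) {
    stop_longsig("episodes still overlap after normalization for participant(s): %s",
                 paste(head(ov$participant_id, 5L), collapse = ", "))
  }
  ep[]
}

## expand normalized episodes to (participant_id, drug, drug_class, month)
## current-month exposure rows, censoring open ends at per-participant censor
episode_months <- function(ep, enrol, censor_m) {
  if (nrow(ep) == 0L) {
    return(data.table(participant_id = character(), drug = character(),
                      drug_class = character(), month = integer()))
  }
  x <- copy(ep)
  x[, enrolment := enrol[participant_id]]
  x[, cm := censor_m[participant_id]]
  x[, m0 := month_of(start_date, enrolment)]
  x[, m1 := ifelse(is.na(end_date), cm - 1L,
                   month_of(end_date - 1L, enrolment))]
  x <- x[m1 >= m0]
  x[, .(month = seq.int(m0, m1)), by = .(participant_id, drug, drug_class,
                                         idx = seq_len(nrow(x)))][
    , idx := NULL][]
}

#' Build the patient-month panel
#'
#' Constructs the unit-of-observation grid: one row per participant per
#' on-study 30-day month, with exposure flags per drug and per treatment
#' class under the chosen exposure definition, time-varying covariates
#' (last-observation-carried-forward EDSS, relapse count in the preceding six
#' months), and demographic/baseline covariates. Follow-up runs from
#' enrolment to the earliest of the participant's `exit_date`, death, or
#' `end_of_data`.
#'
#' Pre-enrolment episodes contribute to `E3` "ever" flags and to the
#' `prior_first_gen` stratification covariate; pre-enrolment events are kept
#' only as covariate history, never as outcomes (a warning is issued).
#'
#' @param participants data.frame with `id`, `sex`, `birth_date`,
#'   `enrolment_date`, optional `exit_date` and baseline covariate columns.
#' @param episodes exposure episodes (see [normalize_episodes()]); may
#'   include pre-enrolment history.
#' @param events adverse-event records: `participant_id`, `category`,
#'   `subtype`, `event_date`.
#' @param labs optional lab results: `participant_id`, `date`, `analyte`,
#'   `value`, `lln`, `uln`.
#' @param edss optional disability measurements: `participant_id`, `date`,
#'   `edss`.
#' @param exposure_def one of `"E1"`, `"E2"`, `"E3"`.
#' @param end_of_data administrative censoring date; default: latest date in
#'   any input record.
#' @param vocab drug vocabulary, as from [dmt_vocabulary()].
#' @return A `data.table` of class `pm_panel`, keyed by participant and
#'   month, carrying the normalized episodes, analysis events and exposure
#'   definition as attributes.
#' @export
build_panel <- function(participants, episodes, events, labs = NULL,
                        edss = NULL, exposure_def = "E1",
                        end_of_data = NULL, vocab = dmt_vocabulary()) {
  exposure_def <- match.arg(exposure_def, exposure_definitions())
  pt <- as.data.table(participants)
  assert_that(all(c("id", "sex", "birth_date", "enrolment_date") %in% names(pt)),
              "participants need id, sex, birth_date, enrolment_date")
  assert_that(anyDuplicated(pt$id) == 0L, "duplicate participant ids")
  pt[, birth_date := as_date_strict(birth_date, "birth_date")]
  pt[, enrolment_date := as_date_strict(enrolment_date, "enrolment_date")]
  assert_that(all(pt$birth_date < pt$enrolment_date),
              "birth_date must precede enrolment_date")

  ev <- as.data.table(events)
  assert_that(all(c("participant_id", "category", "event_date") %in% names(ev)),
              "events need participant_id, category, event_date")
  if (!"subtype" %in% names(ev)) ev[, subtype := NA_character_]
  ev[, event_date := as_date_strict(event_date, "event_date")]
  ep <- normalize_episodes(episodes, vocab)

  unknown <- setdiff(c(ep$participant_id, ev$participant_id), pt$id)
  if (length(unknown) > 0L) {
    stop_longsig("records reference unknown participant(s): %s",
                 paste(head(unknown, 5L), collapse = ", "))
  }

  enrol <- setNames(pt$enrolment_date, pt$id)
  if (is.null(end_of_data)) {
    exit_dates <- if ("exit_date" %in% names(pt)) {
      as_date_strict(pt$exit_date, "exit_date")
    } else as.Date(character())
    end_of_data <- max(c(ev$event_date, ep$start_date, ep$end_date,
                         pt$enrolment_date + 1L, exit_dates), na.rm = TRUE)
  }
  end_of_data <- as.Date(end_of_data)

  ## censoring: exit_date / death / end_of_data
  exit <- rep(end_of_data, nrow(pt))
  if ("exit_date" %in% names(pt)) {
    ed <- as_date_strict(pt$exit_date, "exit_date")
    exit <- pmin(exit, data.table::fifelse(is.na(ed), end_of_data, ed))
  }
  dsub <- ev[category == "DEATH"]
  death <- if (nrow(dsub) > 0L) {
    dsub[, .(dd = min(event_date)), by = participant_id]
  } else data.table(participant_id = character(), dd = as.Date(character()))
  dd <- death$dd[match(pt$id, death$participant_id)]
  ## death month is included in follow-up; censor at end of that bin
  dm_end <- anchor_of(month_of(dd, pt$enrolment_date) + 1L, pt$enrolment_date)
  exit <- pmin(exit, data.table::fifelse(is.na(dd), end_of_data, dm_end))

  fup_days <- as.numeric(exit - pt$enrolment_date)
  n_months <- pmax(0L, as.integer(ceiling(fup_days / DAYS_PER_MONTH)))
  dropped <- pt$id[n_months == 0L]
  if (length(dropped) > 0L) {
    warning(sprintf("%d participant(s) with no on-study follow-up dropped",
                    length(dropped)), call. = FALSE)
  }
  keep <- n_months > 0L
  censor_m <- setNames(n_months[keep], pt$id[keep])
  ptk <- pt[keep]

  ## month grid
  grid <- ptk[, .(month = seq.int(0L, censor_m[id] - 1L)), by = .(participant_id = id)]
  grid[, anchor_date := enrol[participant_id] + month * DAYS_PER_MONTH]

  ## split events: analysis events are on-study; earlier ones are history
  ev[, month := month_of(event_date, enrol[participant_id])]
  ev[, last_m := censor_m[participant_id]]
  pre <- ev[month < 0L]
  if (nrow(pre) > 0L) {
    warning(sprintf("%d pre-enrolment event(s) kept as covariate history only",
                    nrow(pre)), call. = FALSE)
  }
  ev_analysis <- ev[!is.na(last_m) & month >= 0L & month < last_m][, last_m := NULL]
  ev[, last_m := NULL]

  ## exposure month sets (current-month, bin-touching), incl. pre-enrolment
  ep_on <- ep[ep$participant_id %in% ptk$id]
  epm <- episode_months(ep_on, enrol, censor_m)

  add_flag <- function(grid, key_dt, keyval, col) {
    ## key_dt: (participant_id, month) exposed months (may include negatives)
    if (nrow(key_dt) == 0L) { grid[, (col) := FALSE]; return(invisible()) }
    if (exposure_def == "E3") {
      first <- key_dt[, .(m0 = min(month)), by = participant_id]
      grid[, (col) := FALSE]
      grid[first, (col) := month >= i.m0, on = "participant_id"]
    } else {
      lb <- .exposure_lookback[[exposure_def]]
      wm <- key_dt[, .(month = unique(rep(month, each = lb + 1L) +
                                        seq.int(0L, lb))),
                   by = participant_id]
      grid[, (col) := FALSE]
      grid[wm, (col) := TRUE, on = c("participant_id", "month")]
    }
    invisible()
  }

  drugs_present <- sort(unique(epm$drug))
  for (d in drugs_present) {
    add_flag(grid, epm[drug == d, .(participant_id, month)], d,
             paste0("exp_", d))
  }
  for (cl in c("FIRST_GEN", "SECOND_GEN")) {
    add_flag(grid, epm[drug_class == cl, .(participant_id, month)], cl,
             paste0("exp_class_", cl))
  }
  if (!"exp_class_FIRST_GEN" %in% names(grid)) grid[, exp_class_FIRST_GEN := FALSE]
  if (!"exp_class_SECOND_GEN" %in% names(grid)) grid[, exp_class_SECOND_GEN := FALSE]

  ## point-in-time class: latest-starting episode touching the bin
  grid[, cur_class := "NONE"]
  if (nrow(epm) > 0L) {
    epm_on <- epm[month >= 0L]
    if (nrow(epm_on) > 0L) {
      ## later episodes come later in epm (built in start order within drug);
      ## break ties by class precedence via ordering then last-one-wins
      cur <- epm_on[, .(cls = drug_class[.N], cur_drug = drug[.N]),
                    by = .(participant_id, month)]
      grid[cur, `:=`(cur_class = i.cls, cur_drug = i.cur_drug),
           on = c("participant_id", "month")]
    }
  }
  if (!"cur_drug" %in% names(grid)) grid[, cur_drug := NA_character_]

  ## demographics & baseline covariates
  grid[ptk, `:=`(sex = i.sex, birth_date = i.birth_date),
       on = c(participant_id = "id")]
  grid[, age := as.numeric(anchor_date - birth_date) / 365.25]
  grid[, pediatric := age < 18]
  grid[, birth_date := NULL]
  base_cols <- setdiff(names(ptk), c("id", "sex", "birth_date",
                                     "enrolment_date", "exit_date"))
  if (length(base_cols) > 0L) {
    grid[ptk, (base_cols) := mget(paste0("i.", base_cols)),
         on = c(participant_id = "id")]
  }
  ## prior first-generation DMT flag: declared baseline column OR pre-enrolment
  ## first-gen episode
  pre1g <- unique(epm[drug_class == "FIRST_GEN" & month < 0L, participant_id])
  if (!"prior_first_gen" %in% names(grid)) grid[, prior_first_gen := FALSE]
  grid[, prior_first_gen := as.logical(prior_first_gen) |
         participant_id %in% pre1g]

  ## time-varying covariates ------------------------------------------------
  ## relapses in the preceding 6 months (months m-6..m-1, incl. history)
  rel <- ev[category == "RELAPSE", .(participant_id, month)]
  grid[, relapses_6m := 0L]
  if (nrow(rel) > 0L) {
    relw <- rel[, .(participant_id = rep(participant_id, each = 6L),
                    month = rep(month, each = 6L) + seq.int(1L, 6L))]
    relw <- relw[, .(k = .N), by = .(participant_id, month)]
    grid[relw, relapses_6m := i.k, on = c("participant_id", "month")]
  }

  ## EDSS: last observation carried forward; fallback baseline_edss column
  grid[, edss := NA_real_]
  if (!is.null(edss)) {
    em <- as.data.table(edss)
    assert_that(all(c("participant_id", "date", "edss") %in% names(em)),
                "edss needs participant_id, date, edss")
    em[, date := as_date_strict(date, "edss date")]
    em[, month := month_of(date, enrol[participant_id])]
    em <- em[participant_id %in% ptk$id]
    setorder(em, participant_id, month, date)
    em <- em[, .(edss = edss[.N]), by = .(participant_id, month)]
    ## LOCF: for each grid row take the last measurement at or before it
    grid[, edss := em[grid, x.edss, on = c("participant_id", "month"),
                      roll = Inf]]
  }
  if ("baseline_edss" %in% names(grid)) {
    grid[is.na(edss), edss := as.numeric(baseline_edss)]
  }

  setkey(grid, participant_id, month)
  setattr(grid, "class", c("pm_panel", class(grid)))
  setattr(grid, "exposure_def", exposure_def)
  setattr(grid, "episodes", ep_on)
  setattr(grid, "events", ev_analysis)
  setattr(grid, "events_history", pre)
  setattr(grid, "censor_months", censor_m)
  setattr(grid, "drugs", drugs_present)
  setattr(grid, "vocab", vocab)
  grid[]
}

## first occurrence per participant of an event key
## event_key: category, or c(category, subtype)
incident_events <- function(panel, event_key) {
  ev <- attr(panel, "events")
  assert_that(!is.null(ev), "panel lacks an events attribute; use build_panel()")
  cat_ <- event_key[[1L]]
  sel <- ev[category == cat_]
  if (length(event_key) > 1L && !is.na(event_key[[2L]])) {
    sel <- sel[subtype == event_key[[2L]]]
  }
  if (nrow(sel) == 0L) {
    return(data.table(participant_id = character(), month = integer(),
                      event_date = as.Date(character())))
  }
  setorder(sel, participant_id, month, event_date)
  sel[, .(month = month[1L], event_date = event_date[1L]), by = participant_id]
}

#' Censor a panel at the first occurrence of an event
#'
#' Only incident events (the first recorded occurrence in a participant) are
#' analyzed; follow-up is censored upon occurrence, so all patient-months
#' after the first event month leave the at-risk set. Adds a logical `event`
#' column marking the (single) event month per affected participant.
#'
#' @param panel a `pm_panel` from [build_panel()].
#' @param event_key an event category (e.g. `"INFECTION"`) or a
#'   `c(category, subtype)` pair.
#' @return The censored panel (same class, `event` column added).
#' @export
apply_incident_censoring <- function(panel, event_key) {
  inc <- incident_events(panel, event_key)
  out <- copy(panel)
  out[, event := FALSE]
  if (nrow(inc) > 0L) {
    out[inc, first_m := i.month, on = "participant_id"]
    out <- out[is.na(first_m) | month <= first_m]
    out[!is.na(first_m) & month == first_m, event := TRUE]
    out[, first_m := NULL]
  }
  a <- attributes(panel)
  for (nm in setdiff(names(a), c("row.names", ".internal.selfref", "names",
                                 "index", "sorted"))) {
    setattr(out, nm, a[[nm]])
  }
  setattr(out, "event_key", event_key)
  out[]
}

#' Grade lymphopenia from an absolute lymphocyte count
#'
#' Grades follow the 800 / 500 / 200 cells per mm^3 boundaries, with
#' lower-inclusive half-open bins so each boundary value maps to the less
#' severe grade: grade 0 for ALC at or above the lower limit of normal (LLN),
#' grade 1 for 800 <= ALC < LLN, grade 2 for 500 <= ALC < 800, grade 3 for
#' 200 <= ALC < 500, grade 4 for ALC < 200.
#'
#' @param alc_value absolute lymphocyte count(s), cells/mm^3 (>= 0).
#' @param lower_limit_normal lower limit of the normal range (> 800).
#' @return Integer grade(s) in 0..4.
#' @export
#' @examples
#' grade_lymphopenia(c(1200, 900, 600, 300, 150), 1000)
grade_lymphopenia <- function(alc_value, lower_limit_normal) {
  assert_that(all(alc_value >= 0, na.rm = TRUE), "negative ALC value")
  assert_that(all(lower_limit_normal > 800, na.rm = TRUE),
              "lower limit of normal must exceed 800/mm^3")
  g <- data.table::fcase(
    alc_value >= lower_limit_normal, 0L,
    alc_value >= 800, 1L,
    alc_value >= 500, 2L,
    alc_value >= 200, 3L,
    default = 4L
  )
  g[is.na(alc_value)] <- NA_integer_
  g
}

#' Classify a liver-function test value
#'
#' Moderate and severe transaminase (ALT/AST) elevation are defined as
#' exceeding 2.5x and 5x the upper limit of normal, respectively (strict
#' inequalities at both multiples).
#'
#' @param value ALT or AST concentration(s), U/L (>= 0).
#' @param upper_limit_normal upper limit of the normal range (> 0).
#' @return Character: `"NORMAL"`, `"MODERATE"` or `"SEVERE"`.
#' @export
#' @examples
#' classify_liver(c(40, 120, 250), 40)
classify_liver <- function(value, upper_limit_normal) {
  assert_that(all(value >= 0, na.rm = TRUE), "negative liver test value")
  assert_that(all(upper_limit_normal > 0, na.rm = TRUE),
              "upper limit of normal must be positive")
  data.table::fcase(
    value > 5 * upper_limit_normal, "SEVERE",
    value > 2.5 * upper_limit_normal, "MODERATE",
    default = "NORMAL"
  )
}

#' Detect disability (EDSS) progression events
#'
#' A progression event occurs at each measurement scoring at least 1 point
#' higher than the immediately preceding measurement at or after baseline.
#'
#' @param dates measurement dates (sorted ascending).
#' @param scores EDSS scores in half-point steps, 0 to 10.
#' @return The dates at which progression occurred (possibly empty).
#' @export
#' @examples
#' detect_edss_progression(as.Date("2020-01-01") + c(0, 180, 360),
#'                         c(3.0, 3.5, 4.5))
detect_edss_progression <- function(dates, scores) {
  dates <- as_date_strict(dates, "EDSS date")
  assert_that(length(dates) == length(scores), "dates/scores length mismatch")
  assert_that(!is.unsorted(dates), "EDSS series must be date-sorted")
  assert_that(all(scores >= 0 & scores <= 10 & (scores * 2) %% 1 == 0),
              "EDSS scores must be 0-10 in 0.5 steps")
  if (length(scores) < 2L) return(dates[0L])
  idx <- which(diff(scores) >= 1.0) + 1L
  dates[idx]
}

#' Derive lab-based outcome events
#'
#' Converts lab records into first-onset outcome events usable by the cohort
#' machinery: `LYMPHOPENIA_G3` (first ALC measurement at grade 3 or worse),
#' `LIVER_MODERATE` and `LIVER_SEVERE` (first ALT/AST above 2.5x / 5x the
#' upper limit of normal; subtype records the analyte).
#'
#' @param labs lab records: `participant_id`, `date`, `analyte` (`ALC`,
#'   `ALT`, `AST`), `value`, `lln`, `uln`.
#' @return data.table shaped like an event file (`participant_id`,
#'   `category`, `subtype`, `event_date`).
#' @export
derive_lab_outcomes <- function(labs) {
  lb <- as.data.table(labs)
  assert_that(all(c("participant_id", "date", "analyte", "value") %in% names(lb)),
              "labs need participant_id, date, analyte, value")
  lb[, date := as_date_strict(date, "lab date")]
  out <- list()
  alc <- lb[analyte == "ALC"]
  if (nrow(alc) > 0L) {
    alc[, grade := grade_lymphopenia(value, lln)]
    g3 <- alc[grade >= 3L][order(date), .(event_date = date[1L]),
                           by = participant_id]
    if (nrow(g3) > 0L) {
      out[[length(out) + 1L]] <- g3[, .(participant_id,
                                        category = "LYMPHOPENIA_G3",
                                        subtype = NA_character_, event_date)]
    }
  }
  lfts <- lb[analyte %in% c("ALT", "AST")]
  if (nrow(lfts) > 0L) {
    lfts[, cls := classify_liver(value, uln)]
    for (lev in c("MODERATE", "SEVERE")) {
      sel <- if (lev == "MODERATE") lfts[cls %in% c("MODERATE", "SEVERE")]
             else lfts[cls == "SEVERE"]
      first <- sel[order(date), .(event_date = date[1L],
                                  subtype = analyte[1L]),
                   by = participant_id]
      if (nrow(first) > 0L) {
        out[[length(out) + 1L]] <-
          first[, .(participant_id, category = paste0("LIVER_", lev),
                    subtype, event_date)]
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table(participant_id = character(), category = character(),
                      subtype = character(), event_date = as.Date(character())))
  }
  rbindlist(out)[]
}
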