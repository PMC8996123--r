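## LEOPARD protopathic-bias filter: compares how often the first initiation
## of a drug falls shortly after vs shortly before the incident event. If
## initiation disproportionately follows the event, the drug was plausibly
## started because of the event's prodrome and the signal is discarded.

#' Count treatment initiations before and after incident events
#'
#' For each participant with an incident event of `event_key`, looks at the
#' participant's *first* initiation of `drug_key` (matching incident-event
#' logic). The initiation counts as "after" if it falls within
#' `[event, event + window)` and "before" if within `[event - window, event)`
#' (same-day ties therefore count as "after", the conservative choice that
#' favors discarding protopathic-like signals). Windows are
#' `window_months * 30` days on each side; initiations outside both windows
#' contribute to neither count.
#'
#' @param episodes normalized episode table (see [normalize_episodes()]).
#' @param events incident events: `participant_id`, `event_date` (as from
#'   the panel's incident-event bookkeeping), or a full event file plus
#'   `event_key`.
#' @param drug_key drug code (or `"CLASS:<name>"` for class-level initiation).
#' @param event_key event category or `c(category, subtype)`; ignored when
#'   `events` already holds one incident row per participant.
#' @param window_months symmetric comparison window, in 30-day months
#'   (default 1).
#' @return list `(n_before, n_after)`.
#' @export
count_initiations <- function(episodes, events, drug_key, event_key = NULL,
                              window_months = 1L) {
  assert_that(window_months >= 1, "window_months must be >= 1")
  ep <- as.data.table(episodes)
  ev <- as.data.table(events)
  if (!is.null(event_key)) {
    ev <- ev[ev$category == event_key[[1L]]]
    if (length(event_key) > 1L && !is.na(event_key[[2L]])) {
      ev <- ev[ev$subtype == event_key[[2L]]]
    }
    setorder(ev, participant_id, event_date)
    ev <- ev[, .(event_date = event_date[1L]), by = participant_id]
  }
  if (length(drug_key) == 1L && startsWith(drug_key, "CLASS:")) {
    cl <- sub("^CLASS:", "", drug_key)
    ep <- ep[ep$drug_class == cl]
  } else {
    ep <- ep[ep$drug %in% drug_key]
  }
  init <- ep[, .(init_date = min(start_date)), by = participant_id]
  x <- merge(ev[, .(participant_id, event_date)], init, by = "participant_id")
  if (nrow(x) == 0L) return(list(n_before = 0L, n_after = 0L))
  wd <- as.numeric(window_months) * DAYS_PER_MONTH
  d <- as.numeric(x$init_date - x$event_date)
  list(n_before = sum(d >= -wd & d < 0),
       n_after = sum(d >= 0 & d < wd))
}

#' One-sided binomial test for protopathic bias
#'
#' Tests H0: a treatment initiation near the incident event is equally
#' likely to fall before or after it, against the alternative that it is
#' more likely *after* (protopathic pattern). The exact one-sided p-value is
#' `Pr(X >= n_after)` for `X ~ Binomial(n_before + n_after, 1/2)`; the test
#' is carried out at the 50% significance level, so the signal is discarded
#' when `p < 0.5`.
#'
#' @param n_before,n_after nonnegative initiation counts.
#' @return list `(p_value, discard, untestable)`; with both counts zero the
#'   test is inapplicable and the signal is retained with
#'   `untestable = TRUE`.
#' @export
#' @examples
#' leopard_test(5, 5)    # p = 638/1024, retained
#' leopard_test(0, 6)    # p = 1/64, discarded
leopard_test <- function(n_before, n_after) {
  assert_that(n_before >= 0 && n_after >= 0, "negative counts")
  n <- n_before + n_after
  if (n == 0) {
    return(list(p_value = NA_real_, discard = FALSE, untestable = TRUE))
  }
  p <- pbinom(n_after - 1, size = n, prob = 0.5, lower.tail = FALSE)
  ## the tail equals exactly 1/2 when n is odd and n_after = (n+1)/2;
  ## guard the strict comparison against floating-point error there (the
  ## nearest attainable p values are far from 0.5, so the guard is safe)
  list(p_value = p, discard = p < 0.5 - 1e-9, untestable = FALSE)
}

## exact null rejection mass of the discrete test at alpha = 0.5 for a given
## total: Pr over X ~ Bin(n, 1/2) that p(X) < 0.5 (used for calibration
## checks of the simulator's null preset)
leopard_null_rejection_mass <- function(n_total) {
  vapply(n_total, function(n) {
    if (n == 0) return(0)
    k <- 0:n
    pvals <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
    sum(dbinom(k, n, 0.5)[pvals < 0.5])
  }, numeric(1))
}
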