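## Cohort module: new-user cohort selection, primary stratified episode
## analysis, secondary MSM exposure models (a)-(d), tertiary switch
## interaction, fitted by weighted time-varying proportional hazards or the
## pooled log-linear discrete-time equivalent.

#' Select the second-generation new-user cohort
#'
#' Participants who never received second-generation DMT prior to study
#' enrolment.
#'
#' @param participants participants table (`id`, `enrolment_date`, ...).
#' @param episodes episode table including retrospective (pre-enrolment)
#'   history; normalized or raw.
#' @param vocab drug vocabulary.
#' @return The subset of `participants` forming the new-user cohort.
#' @export
select_new_user_cohort <- function(participants, episodes,
                                   vocab = dmt_vocabulary()) {
  pt <- as.data.table(participants)
  ep <- normalize_episodes(episodes, vocab)
  enrol <- setNames(as.Date(pt$enrolment_date), pt$id)
  pre2g <- unique(ep[drug_class == "SECOND_GEN" &
                       start_date < enrol[participant_id], participant_id])
  pt[!pt$id %in% pre2g]
}

#' Build the primary-analysis episode table
#'
#' Within the new-user cohort, each participant contributes an initial
#' unexposed episode from enrolment to first second-generation (2G)
#' initiation and, if 2G is initiated on study, a subsequent exposed episode
#' from initiation to 2G cessation; follow-up is censored upon cessation of
#' 2G (and upon the first outcome event). Strata are defined by any
#' first-generation use prior to 2G initiation (or prior to the end of
#' follow-up when 2G is never started).
#'
#' @param panel a `pm_panel` built on the new-user cohort.
#' @param outcome_key event key passed to [apply_incident_censoring()]
#'   semantics: category or `c(category, subtype)`.
#' @return data.table with one row per episode: `participant_id`, `stratum`
#'   (`PRIOR_FIRST_GEN` / `NO_PRIOR_FIRST_GEN`), `exposed`, `start_month`,
#'   `end_month` (half-open), `outcome` (0/1), covariates at episode start
#'   (`edss`, `relapses_6m`), and Cox-ready `tstart`/`tstop`.
#' @export
build_primary_episodes <- function(panel, outcome_key) {
  p <- as.data.table(panel)
  inc <- incident_events(panel, outcome_key)
  cm <- attr(panel, "censor_months")

  per <- p[, {
    is2g <- cur_class == "SECOND_GEN"
    m2g <- if (any(is2g)) month[which(is2g)[1L]] else NA_integer_
    ## cessation: first non-2G month after initiation
    mend <- if (!is.na(m2g)) {
      aft <- month > m2g & !is2g
      if (any(aft)) month[which(aft)[1L]] else month[.N] + 1L
    } else NA_integer_
    .(m_init = m2g, m_cess = mend, m_max = month[.N] + 1L,
      prior_fg = isTRUE(prior_first_gen[1L]) ||
        any(cur_class == "FIRST_GEN" &
              month < data.table::fifelse(is.na(m2g), month[.N] + 1L, m2g)))
  }, by = participant_id]

  per[inc, outcome_m := i.month, on = "participant_id"]
  rows <- per[, {
    stop_m <- min(m_max, outcome_m + 1L, na.rm = TRUE)  # censor after outcome
    u_end <- min(data.table::fifelse(is.na(m_init), stop_m, m_init), stop_m)
    res <- list()
    if (u_end > 0L) {
      res[[1L]] <- data.table(exposed = FALSE, start_month = 0L,
                              end_month = u_end)
    }
    if (!is.na(m_init) && m_init < stop_m) {
      e_end <- min(m_cess, stop_m)
      if (e_end > m_init) {
        res[[length(res) + 1L]] <- data.table(exposed = TRUE,
                                              start_month = m_init,
                                              end_month = e_end)
      }
    }
    rbindlist(res)
  }, by = .(participant_id, prior_fg, outcome_m)]

  rows[, stratum := data.table::fifelse(prior_fg, "PRIOR_FIRST_GEN",
                                        "NO_PRIOR_FIRST_GEN")]
  rows[, outcome := as.integer(!is.na(outcome_m) & outcome_m >= start_month &
                                 outcome_m < end_month)]
  rows[, `:=`(tstart = start_month, tstop = end_month, prior_fg = NULL)]
  ## covariates at episode start
  cov <- p[, .(participant_id, month, edss, relapses_6m)]
  rows[cov, `:=`(edss = i.edss, relapses_6m = i.relapses_6m),
       on = c("participant_id", start_month = "month")]
  drop <- rows[end_month <= start_month]
  if (nrow(drop) > 0L) {
    message(sprintf("%d zero-length episode(s) dropped", nrow(drop)))
  }
  rows <- rows[end_month > start_month]
  rows[, outcome_m := NULL]
  setcolorder(rows, c("participant_id", "stratum", "exposed", "start_month",
                      "end_month", "tstart", "tstop", "outcome"))
  rows[]
}

#' Exposure covariate blocks for the secondary MSM analyses
#'
#' Builds, per participant-interval, the exposure covariates of the four
#' secondary exposure models:
#' * `A_CURRENT`: categorical current treatment class;
#' * `B_CARRYOVER`: current class plus indicators of exposure to any *other*
#'   class within the preceding `carryover_window` months;
#' * `C_CUMULATIVE`: cumulative months of exposure per class through the end
#'   of the current interval;
#' * `D_DECAYED`: time-weighted cumulative exposure, each past month
#'   contributing `2^(-lag / decay_half_life)` with `lag` the number of
#'   months before the interval start.
#'
#' @param panel month-level `pm_panel` (class history source).
#' @param ipanel interval panel from [interval_panel()].
#' @param model one of `"A_CURRENT"`, `"B_CARRYOVER"`, `"C_CUMULATIVE"`,
#'   `"D_DECAYED"`.
#' @param carryover_window months (default 6; models B and tertiary).
#' @param decay_half_life months (default 6; model D).
#' @return `ipanel` with the exposure covariate columns added; attribute
#'   `exposure_terms` names the model's regression terms.
#' @export
build_exposure_covariates <- function(panel, ipanel,
                                      model = c("A_CURRENT", "B_CARRYOVER",
                                                "C_CUMULATIVE", "D_DECAYED"),
                                      carryover_window = 6L,
                                      decay_half_life = 6L) {
  model <- match.arg(model)
  assert_that(carryover_window > 0 && decay_half_life > 0,
              "carryover window and half-life must be positive")
  ip <- copy(as.data.table(ipanel))
  ip[, cur_first := cur_class == "FIRST_GEN"]
  ip[, cur_second := cur_class == "SECOND_GEN"]
  terms <- c("cur_first", "cur_second")

  if (model != "A_CURRENT") {
    ph <- as.data.table(panel)[, .(participant_id, month, cur_class)]
    iv <- ip[, .(participant_id, interval, month0,
                 month_end = month0 + INTERVAL_MONTHS - 1L)]
    hist <- ph[iv, on = "participant_id", allow.cartesian = TRUE]
    if (model == "B_CARRYOVER") {
      hw <- hist[month >= month0 - carryover_window & month < month0]
      carry <- hw[, .(carry_first = any(cur_class == "FIRST_GEN"),
                      carry_second = any(cur_class == "SECOND_GEN")),
                  by = .(participant_id, interval)]
      ip[carry, `:=`(carry_first = i.carry_first,
                     carry_second = i.carry_second),
         on = c("participant_id", "interval")]
      for (cc in c("carry_first", "carry_second")) {
        ip[is.na(get(cc)), (cc) := FALSE]
      }
      ## carryover of any *other* class: zero when it is the current class
      ip[, carry_first := carry_first & !cur_first]
      ip[, carry_second := carry_second & !cur_second]
      terms <- c(terms, "carry_first", "carry_second")
    } else if (model == "C_CUMULATIVE") {
      hw <- hist[month <= month_end]
      cum <- hw[, .(cum_first = sum(cur_class == "FIRST_GEN"),
                    cum_second = sum(cur_class == "SECOND_GEN")),
                by = .(participant_id, interval)]
      ip[cum, `:=`(cum_first = i.cum_first, cum_second = i.cum_second),
         on = c("participant_id", "interval")]
      for (cc in c("cum_first", "cum_second")) ip[is.na(get(cc)), (cc) := 0L]
      terms <- c("cum_first", "cum_second")
    } else {
      hw <- hist[month < month0]
      hw[, wgt := 2^(-(month0 - month) / decay_half_life)]
      dec <- hw[, .(dec_first = sum(wgt[cur_class == "FIRST_GEN"]),
                    dec_second = sum(wgt[cur_class == "SECOND_GEN"])),
                by = .(participant_id, interval)]
      ip[dec, `:=`(dec_first = i.dec_first, dec_second = i.dec_second),
         on = c("participant_id", "interval")]
      for (cc in c("dec_first", "dec_second")) ip[is.na(get(cc)), (cc) := 0]
      terms <- c("dec_first", "dec_second")
    }
  }
  setattr(ip, "exposure_terms", terms)
  setattr(ip, "exposure_model", model)
  ip[]
}

#' Fit an outcome model
#'
#' Fits the treatment-effect model for a cohort analysis, either by weighted
#' time-varying Cox proportional hazards regression (`method = "cox"`,
#' months since enrolment as the time scale, Efron ties, robust
#' participant-clustered variance) or by the pooled log-linear discrete-time
#' equivalent (`method = "pooled"`: weighted Poisson regression over
#' person-time with robust variance). For episode tables (primary analysis)
#' both methods use `tstart`/`tstop`/`outcome`; for interval data the event
#' indicator and log person-time offset are used.
#'
#' @param data episode table (with `tstart`, `tstop`, `outcome`) or an
#'   interval panel with exposure covariates (see
#'   [build_exposure_covariates()]) plus `n_events` / `n_months` columns.
#' @param terms character vector of regression terms (for episode tables,
#'   default `"exposed"`).
#' @param weights optional numeric vector aligned with `data` rows.
#' @param method `"cox"` or `"pooled"`.
#' @param strata_col optional stratification column (primary analysis).
#' @return data.table: `term`, `estimate` (log hazard/rate ratio), `hr`,
#'   `se` (robust), `ci_low`, `ci_high`, `n_events`.
#' @export
fit_outcome_model <- function(data, terms = "exposed", weights = NULL,
                              method = c("cox", "pooled"),
                              strata_col = NULL) {
  method <- match.arg(method)
  d <- as.data.table(data)
  w <- weights %||% rep(1, nrow(d))
  n_events <- if ("outcome" %in% names(d)) sum(d$outcome > 0)
              else sum(d$n_events)
  if (n_events == 0L) stop_longsig("no events for this outcome; model aborted")
  rhs <- paste(terms, collapse = " + ")

  if (method == "cox") {
    assert_that(all(c("tstart", "tstop", "outcome") %in% names(d)),
                "cox method needs tstart/tstop/outcome columns")
    f <- paste("survival::Surv(tstart, tstop, outcome) ~", rhs)
    if (!is.null(strata_col)) {
      f <- paste(f, "+ survival::strata(", strata_col, ")")
    }
    dd <- as.data.frame(d)
    dd$.w <- w
    dd$.id <- d$participant_id
    fit <- survival::coxph(as.formula(f), data = dd, weights = .w,
                           cluster = .id, ties = "efron")
    sm <- summary(fit)
    est <- coef(fit)
    se <- sqrt(diag(fit$var))   # robust when cluster given
    keep <- !grepl("strata", names(est))
    res <- data.table(term = names(est)[keep], estimate = est[keep],
                      se = se[keep])
  } else {
    dd <- as.data.frame(d)
    if (all(c("tstart", "tstop") %in% names(d))) {
      dd$.pt <- d$tstop - d$tstart
      yv <- d$outcome
    } else {
      dd$.pt <- if ("n_months" %in% names(d)) d$n_months else 1
      yv <- if ("n_events" %in% names(d)) d$n_events else d$outcome
    }
    f <- as.formula(paste("yv ~", rhs, "+ offset(log(.pt))"))
    dd$yv <- yv
    fit <- suppressWarnings(glm(f, family = poisson(), data = dd, weights = w,
                                control = glm.control(epsilon = 1e-12,
                                                      maxit = 100L)))
    est <- coef(fit)
    V <- cluster_vcov(fit, d$participant_id)
    keep <- names(est) != "(Intercept)"
    res <- data.table(term = names(est)[keep], estimate = est[keep],
                      se = sqrt(diag(V))[keep])
  }
  bad <- !is.finite(res$estimate) | !is.finite(res$se) | res$se > 100
  if (any(bad)) {
    warning(sprintf("term(s) inestimable (collinearity or no variation): %s",
                    paste(res$term[bad], collapse = ", ")), call. = FALSE)
    res[bad, `:=`(estimate = NA_real_, se = NA_real_)]
  }
  z <- qnorm(0.975)
  res[, `:=`(hr = exp(estimate), ci_low = exp(estimate - z * se),
             ci_high = exp(estimate + z * se), n_events = n_events)]
  setcolorder(res, c("term", "estimate", "hr", "se", "ci_low", "ci_high",
                     "n_events"))
  res[]
}

#' Tertiary switch-interaction analysis
#'
#' Extends exposure model B with current-class-by-carryover product terms to
#' test whether the carryover effect of previous treatment depends on the
#' current treatment class.
#'
#' @param panel month-level panel.
#' @param ipanel interval panel with outcome columns `n_events`, `n_months`
#'   for the outcome of interest (see [interval_outcomes()]).
#' @param weights optional `iptw_weights`.
#' @param method passed to [fit_outcome_model()].
#' @return Effect estimates including the interaction terms.
#' @export
tertiary_interaction <- function(panel, ipanel, weights = NULL,
                                 method = "pooled") {
  ib <- build_exposure_covariates(panel, ipanel, "B_CARRYOVER")
  ib[, `:=`(int_2g_carry1g = cur_second & carry_first,
            int_1g_carry2g = cur_first & carry_second)]
  terms <- c(attr(ib, "exposure_terms"), "int_2g_carry1g", "int_1g_carry2g")
  wv <- NULL
  if (!is.null(weights)) {
    w <- as.data.table(weights)[, .(participant_id, interval, weight)]
    ib[w, wcol := i.weight, on = c("participant_id", "interval")]
    ib <- ib[!is.na(wcol)]
    wv <- ib$wcol
  }
  fit_outcome_model(ib, terms, weights = wv, method = method)
}

#' Attach interval-level outcome counts
#'
#' Adds `n_events` (incident occurrences of `outcome_key` in the interval,
#' at most one per participant given incident censoring) and `n_months`
#' (at-risk months) to an interval panel, applying incident-event censoring.
#'
#' @param panel month-level panel.
#' @param ipanel interval panel.
#' @param outcome_key event key.
#' @return The censored interval panel with outcome columns.
#' @export
interval_outcomes <- function(panel, ipanel, outcome_key) {
  cp <- apply_incident_censoring(panel, outcome_key)
  agg <- as.data.table(cp)[, .(n_events = sum(event), n_months = .N),
                           by = .(participant_id,
                                  interval = month %/% INTERVAL_MONTHS)]
  ip <- as.data.table(ipanel)
  if ("n_months" %in% names(ip)) ip[, n_months := NULL]
  out <- merge(ip, agg, by = c("participant_id", "interval"))
  out <- out[n_months > 0L]
  out[]
}
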