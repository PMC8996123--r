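## Weights module: 6-month-interval treatment models, stabilized inverse
## probability of treatment weights (marginal structural model), episode
## propensity weights, weighted contingency cells and balance diagnostics.

INTERVAL_MONTHS <- 6L

#' Aggregate a patient-month panel to 6-month intervals
#'
#' One row per participant per 6-month interval (six 30-day bins), carrying
#' the treatment class at the interval's first month, the previous interval's
#' class (`NONE` before enrolment), and covariate values at the interval
#' start (LOCF EDSS, relapses in the preceding 6 months, baseline columns).
#'
#' @param panel a `pm_panel` from [build_panel()].
#' @param interval_months interval length in 30-day months (default 6).
#' @return data.table keyed by participant and `interval`, with `month0`
#'   (first month index) and `n_months` (months observed in the interval).
#' @export
interval_panel <- function(panel, interval_months = INTERVAL_MONTHS) {
  p <- as.data.table(panel)
  p[, interval := month %/% interval_months]
  base_cols <- intersect(c("sex", "age", "pediatric", "prior_first_gen",
                           "disease_duration", "baseline_edss",
                           "comorbidities", "edss", "relapses_6m"),
                         names(p))
  first_row <- p[, c(.(month0 = month[1L], n_months = .N,
                       cur_class = cur_class[1L]),
                     lapply(.SD, `[`, 1L)),
                 by = .(participant_id, interval), .SDcols = base_cols]
  setorder(first_row, participant_id, interval)
  first_row[, prev_class := shift(cur_class, 1L, fill = "NONE"),
            by = participant_id]
  first_row[]
}

## build the design matrix for the treatment model
treatment_design <- function(ipanel, covariates, include_prev = TRUE) {
  terms <- c(if (include_prev) "prev_class", covariates)
  rhs <- paste(terms, collapse = " + ")
  f <- as.formula(paste("~", if (nchar(rhs)) rhs else "1"))
  dat <- as.data.frame(ipanel)
  dat$prev_class <- factor(dat$prev_class, levels = TREATMENT_CLASSES)
  if ("sex" %in% names(dat)) dat$sex <- factor(dat$sex)
  ok <- complete.cases(dat[, intersect(c(terms), names(dat)), drop = FALSE])
  list(X = model.matrix(f, dat[ok, , drop = FALSE]), ok = ok)
}

#' Fit the interval treatment-assignment model
#'
#' Multinomial (pooled) logistic model of the current-interval treatment
#' class (no treatment / first-generation / second-generation DMT) given the
#' previous interval's class and covariates. Used for both the numerator
#' (baseline covariates only) and denominator (plus time-varying covariates)
#' of stabilized IPT weights.
#'
#' @param ipanel interval panel from [interval_panel()].
#' @param covariates character vector of covariate column names.
#' @param include_prev include previous-interval class (default TRUE).
#' @return A fitted model with a `predict(model, newdata_ipanel)` method
#'   returning per-row probabilities for the three classes.
#' @export
fit_treatment_model <- function(ipanel, covariates = character(),
                                include_prev = TRUE) {
  des <- treatment_design(ipanel, covariates, include_prev)
  if (any(!des$ok)) {
    warning(sprintf("%d interval row(s) with missing covariates excluded from treatment model",
                    sum(!des$ok)), call. = FALSE)
  }
  y <- ipanel$cur_class[des$ok]
  fit <- fit_multinom(des$X, y, levels_ = TREATMENT_CLASSES)
  fit$covariates <- covariates
  fit$include_prev <- include_prev
  fit
}

## probabilities of the *observed* class per interval row
observed_prob <- function(model, ipanel) {
  des <- treatment_design(ipanel, model$covariates, model$include_prev)
  pr <- rep(NA_real_, nrow(ipanel))
  P <- predict(model, des$X)
  idx <- match(ipanel$cur_class[des$ok], model$levels)
  pr[des$ok] <- P[cbind(seq_len(nrow(P)), idx)]
  pr
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' Standard marginal-structural-model weights over 6-month intervals:
#' `w_i(t) = prod_{k <= t} Pr(A_k = a_ik | A_{k-1}, baseline) /
#'                          Pr(A_k = a_ik | A_{k-1}, covariate history)`,
#' with the covariate history entering the denominator as the
#' current-interval values plus previous class (first-order Markov). Weights
#' are truncated at configurable percentiles of the realized cumulative
#' weights (default 1st/99th).
#'
#' @param ipanel interval panel from [interval_panel()].
#' @param denominator fitted treatment model including time-varying
#'   covariates (see [fit_treatment_model()]).
#' @param numerator fitted model with baseline covariates only (defaults to
#'   previous-class-only).
#' @param truncate length-2 percentile bounds, or `NULL` to disable.
#' @return data.table (class `iptw_weights`) with `participant_id`,
#'   `interval`, `weight`, `truncated`; diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
stabilized_iptw <- function(ipanel, denominator, numerator = NULL,
                            truncate = c(0.01, 0.99)) {
  if (is.null(numerator)) {
    numerator <- fit_treatment_model(ipanel, character(), include_prev = TRUE)
  }
  p_num <- observed_prob(numerator, ipanel)
  p_den <- observed_prob(denominator, ipanel)
  if (any(!is.na(p_den) & p_den <= 1e-8)) {
    bad <- ipanel[which(p_den <= 1e-8)[1L]]
    stop_longsig("positivity violation: assignment probability ~0 for class %s at interval %d",
                 bad$cur_class, bad$interval)
  }
  out <- data.table(participant_id = ipanel$participant_id,
                    interval = ipanel$interval,
                    ratio = p_num / p_den)
  ## inverse full propensity of the observed class at this interval: the
  ## standard per-timepoint balance diagnostic weight (balances previous
  ## class and current covariates jointly across classes)
  out[, w_interval := 1 / p_den]
  drop_pid <- unique(out$participant_id[is.na(out$ratio)])
  if (length(drop_pid) > 0L) {
    warning(sprintf("%d participant(s) dropped from weighting (missing covariates)",
                    length(drop_pid)), call. = FALSE)
    out <- out[!participant_id %in% drop_pid]
  }
  setorder(out, participant_id, interval)
  out[, weight := cumprod(ratio), by = participant_id]
  out[, ratio := NULL]
  out[, truncated := FALSE]
  bounds <- c(-Inf, Inf)
  if (!is.null(truncate)) {
    bounds <- quantile(out$weight, truncate, names = FALSE)
    out[, truncated := weight < bounds[1L] | weight > bounds[2L]]
    out[, weight := pmin(pmax(weight, bounds[1L]), bounds[2L])]
  }
  setattr(out, "class", c("iptw_weights", class(out)))
  setattr(out, "diagnostics",
          list(mean = mean(out$weight), max = max(out$weight),
               min = min(out$weight), truncation_bounds = bounds,
               n_truncated = sum(out$truncated)))
  out[]
}

#' Episode-level propensity weights (primary cohort analysis)
#'
#' Each exposure episode is weighted in inverse proportion to the estimated
#' propensity of its observed exposure status, from a pooled logistic
#' regression of exposure on covariates measured at episode start, fit
#' separately within each prior-first-generation stratum.
#'
#' @param episode_table primary episode table (see
#'   [build_primary_episodes()]) with logical `exposed` and `stratum`.
#' @param covariates covariate column names measured at episode start.
#' @param truncate percentile bounds applied to the weights (default
#'   1st/99th; `NULL` to disable).
#' @return The episode table with `propensity` and `weight` columns added.
#' @export
episode_propensity_weights <- function(episode_table,
                                       covariates = c("edss", "relapses_6m"),
                                       truncate = c(0.01, 0.99)) {
  et <- copy(as.data.table(episode_table))
  covariates <- intersect(covariates, names(et))
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  et[, propensity := NA_real_]
  for (s in unique(et$stratum)) {
    idx <- et$stratum == s
    dat <- as.data.frame(et[idx])
    fit <- glm(as.formula(paste("exposed ~", rhs)), family = binomial(),
               data = dat)
    et$propensity[idx] <- predict(fit, type = "response")
  }
  et[, weight := data.table::fifelse(exposed, 1 / propensity,
                                     1 / (1 - propensity))]
  if (!is.null(truncate)) {
    bounds <- quantile(et$weight, truncate, names = FALSE)
    et[, weight := pmin(pmax(weight, bounds[1L]), bounds[2L])]
  }
  et[]
}

#' Weighted contingency cells
#'
#' Substitutes IPT-weighted equivalents of the four patient-month counts:
#' each cell is the sum of the weights of its patient-months, the interval
#' weight applying to all six months of its interval. Feeds the weighted
#' disproportionality and BCPNN pathways.
#'
#' @param panel an incident-censored `pm_panel`.
#' @param weights an `iptw_weights` table from [stabilized_iptw()].
#' @param drug_key as in [tabulate_panel()].
#' @param interval_months must match the weights' interval length.
#' @return A [contingency_table()] with real-valued cells.
#' @export
weighted_cells <- function(panel, weights, drug_key,
                           interval_months = INTERVAL_MONTHS) {
  p <- as.data.table(panel)
  p[, interval := month %/% interval_months]
  w <- as.data.table(weights)[, .(participant_id, interval, weight)]
  m <- w[p, on = c("participant_id", "interval")]
  known <- unique(w$participant_id)
  unmatched <- m[is.na(weight) & participant_id %in% known]
  if (nrow(unmatched) > 0L) {
    stop_longsig("%d patient-month(s) have no matching interval weight",
                 nrow(unmatched))
  }
  m <- m[!is.na(weight)]
  tabulate_panel(m_as_panel(m, panel), drug_key, weights = m$weight)
}

## reconstitute a panel-like object after a join (attributes lost by merge)
m_as_panel <- function(m, panel) {
  for (nm in c("events", "episodes", "exposure_def", "censor_months")) {
    setattr(m, nm, attr(panel, nm))
  }
  if (!"event" %in% names(m)) m[, event := FALSE]
  m
}

#' Covariate balance diagnostics
#'
#' Maximum pairwise weighted standardized mean difference of each covariate
#' across the three treatment classes. With `mode = "interval"` (default)
#' the standard per-timepoint diagnostic is used: each interval row is
#' weighted by its single-interval stabilized weight, which directly
#' assesses whether assignment at each decision point is independent of the
#' covariates in the weighted pseudo-population. `mode = "cumulative"` uses
#' the cumulative MSM weights instead.
#'
#' @param ipanel interval panel.
#' @param weights `iptw_weights` (or `NULL` for unweighted balance).
#' @param covariates covariate columns to assess.
#' @param mode `"interval"` or `"cumulative"` (ignored when `weights` is
#'   `NULL`).
#' @return data.table with `covariate` and `max_smd`.
#' @export
balance_table <- function(ipanel, weights = NULL,
                          covariates = c("edss", "relapses_6m"),
                          mode = c("interval", "cumulative")) {
  mode <- match.arg(mode)
  ip <- as.data.table(ipanel)
  if (!is.null(weights)) {
    wt <- as.data.table(weights)
    wcol <- if (mode == "interval" && "w_interval" %in% names(wt))
      "w_interval" else "weight"
    w <- wt[, .(participant_id, interval, weight = get(wcol))]
    ip <- w[ip, on = c("participant_id", "interval")]
    ip <- ip[!is.na(weight)]
  } else {
    ip[, weight := 1]
  }
  pairs <- utils::combn(TREATMENT_CLASSES, 2L, simplify = FALSE)
  rbindlist(lapply(intersect(covariates, names(ip)), function(cv) {
    x <- as.numeric(ip[[cv]])
    keep <- !is.na(x)
    smds <- vapply(pairs, function(pr) {
      abs(smd_pair(x[keep], ip$cur_class[keep], ip$weight[keep],
                   pr[1L], pr[2L]))
    }, numeric(1))
    data.table(covariate = cv, max_smd = max(smds, na.rm = TRUE))
  }))
}
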