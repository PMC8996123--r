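## Pipeline module: the tiered signal generation procedure.
##
## Level 1: minimum-report list (distinct exposed participants with the
##   incident event: >= 3 for second-generation drugs, >= 5 for
##   first-generation, >= 2 in the pediatric analysis).
## Level 2: lower 95% confidence bound of the ROR (equivalently the IRR)
##   strictly exceeds 1, per pathway (crude / subgrouped / IPTW-weighted).
## Level 3: BCPNN posterior null probability (FDR estimate) strictly below
##   5% and not discarded by the LEOPARD protopathic-bias filter.
## Shrinkage and the LEOPARD filter are evaluated for Level-2 signals only,
## mirroring the staged procedure.

#' Threshold configuration for the signal procedure
#'
#' @param min_participants_second_gen,min_participants_first_gen,min_participants_pediatric
#'   minimum-report criteria (distinct affected exposed participants).
#' @param fdr_threshold Level-3 gate (strict `<`).
#' @param ci_level confidence level of the Level-2 bound.
#' @return list of thresholds.
#' @export
threshold_config <- function(min_participants_second_gen = 3L,
                             min_participants_first_gen = 5L,
                             min_participants_pediatric = 2L,
                             fdr_threshold = 0.05, ci_level = 0.95) {
  th <- as.list(environment())
  assert_that(all(unlist(th) > 0) && fdr_threshold < 1, "invalid thresholds")
  th
}

## distinct participants whose incident event month is drug-exposed
count_affected <- function(panel, drug_key, event_key) {
  inc <- incident_events(panel, event_key)
  if (nrow(inc) == 0L) return(0L)
  p <- as.data.table(panel)
  sub <- p[inc[, .(participant_id, month)], on = c("participant_id", "month"),
           nomatch = 0L]
  if (nrow(sub) == 0L) return(0L)
  sum(exposure_flag(sub, drug_key))
}

#' Level-1 minimum-report list
#'
#' For every drug in the panel's vocabulary and every event key, counts the
#' distinct participants whose incident event occurred in a patient-month
#' exposed to the drug (under the panel's active exposure definition), and
#' applies the class-specific minimum-report criterion.
#'
#' @param panel a `pm_panel` (restricted to the pediatric months for the
#'   pediatric analysis).
#' @param thresholds from [threshold_config()].
#' @param event_keys event categories to scan (default [sae_categories()]).
#' @param population `"all"` or `"pediatric"` (threshold 2).
#' @return data.table `(drug, drug_class, event, n_participants, level1)`.
#' @export
level1_list <- function(panel, thresholds = threshold_config(),
                        event_keys = sae_categories(),
                        population = c("all", "pediatric")) {
  population <- match.arg(population)
  drugs <- attr(panel, "drugs")
  vocab <- attr(panel, "vocab") %||% dmt_vocabulary()
  grid <- CJ(drug = drugs, event = event_keys)
  grid[, drug_class := drug_class_of(drug, vocab)]
  grid[, n_participants := mapply(function(d, e)
    count_affected(panel, d, e), drug, event)]
  grid[, thr := data.table::fifelse(
    rep(population == "pediatric", .N),
    thresholds$min_participants_pediatric,
    data.table::fifelse(drug_class == "FIRST_GEN",
                        thresholds$min_participants_first_gen,
                        thresholds$min_participants_second_gen))]
  grid[, level1 := n_participants >= thr]
  grid[, thr := NULL]
  grid[]
}

#' Level-2 screen
#'
#' Flags records whose stored lower confidence bound strictly exceeds 1
#' (undefined estimates are never flagged; the reason is recorded).
#' @param records signal table with a `lower95` column.
#' @return The table with `level2` set.
#' @export
level2_screen <- function(records) {
  r <- copy(as.data.table(records))
  r[, level2 := !is.na(lower95) & lower95 > 1]
  r[]
}

#' Level-3 screen
#'
#' Flags Level-2 records with FDR estimate (posterior null probability)
#' strictly below the threshold and not discarded by LEOPARD; untestable
#' LEOPARD results retain the signal.
#' @param records signal table with `p_null`, `leopard_discard`, `level2`.
#' @param fdr_threshold strict gate (default 0.05).
#' @return The table with `level3` set.
#' @export
level3_screen <- function(records, fdr_threshold = 0.05) {
  r <- copy(as.data.table(records))
  r[, level3 := level2 & !is.na(p_null) & p_null < fdr_threshold &
      !data.table::fifelse(is.na(leopard_discard), FALSE, leopard_discard)]
  r[]
}

## default subgroup assignment: sex x age band x prior-first-gen, with
## subgroups under `min_pm` patient-months merged into "OTHER"
assign_subgroups <- function(panel, min_pm = 200L) {
  p <- as.data.table(panel)
  sg <- p[, .(subgroup = paste0(sex[1L],
                                data.table::fifelse(age[1L] < 40, "_U40", "_O40"),
                                data.table::fifelse(isTRUE(prior_first_gen[1L]),
                                                    "_PRIOR1G", "_NAIVE")),
              pm = .N), by = participant_id]
  size <- sg[, .(pm = sum(pm)), by = subgroup]
  small <- size[pm < min_pm, subgroup]
  if (length(small) > 0L) sg[subgroup %in% small, subgroup := "OTHER"]
  setNames(sg$subgroup, sg$participant_id)
}

## LEOPARD evaluation for one pair on a participant subset
leopard_eval <- function(panel, drug_key, event_key, window_months = 1L,
                         participants = NULL) {
  ep <- attr(panel, "episodes")
  inc <- incident_events(panel, event_key)
  if (!is.null(participants)) {
    ep <- ep[participant_id %in% participants]
    inc <- inc[participant_id %in% participants]
  }
  cnt <- count_initiations(ep, inc, drug_key, window_months = window_months)
  tst <- leopard_test(cnt$n_before, cnt$n_after)
  c(cnt, tst)
}

## stable per-record Monte-Carlo seed derived from the run seed
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647L) + 1L
}

#' Run the full signal generation procedure
#'
#' Executes the crude, subgrouped and IPTW-weighted analysis pathways for
#' every Level-1 drug-event pair under one exposure definition, producing
#' the complete signal table plus pooled, ranked Level-2 and Level-3 lists.
#'
#' @param cohort list with `participants`, `episodes`, `events`, and
#'   optionally `labs`/`edss` (as from [simulate_cohort()] or
#'   [read_cohort()]).
#' @param exposure_def `"E1"`, `"E2"` or `"E3"`.
#' @param pathways subset of `c("crude", "subgroup", "weighted")`.
#' @param thresholds from [threshold_config()].
#' @param event_keys event categories to scan.
#' @param population `"all"` or `"pediatric"` (pediatric: crude pathway
#'   only, threshold 2, patient-months with age < 18).
#' @param seed seed for the BCPNN Monte-Carlo draws.
#' @param n_mc Monte-Carlo draws per posterior (default 1e5).
#' @param leopard_window LEOPARD comparison window, months.
#' @param end_of_data passed to [build_panel()].
#' @return list: `signals` (one row per pair x pathway, plus per-subgroup
#'   detail rows), `level1`, `pooled_level2`, `pooled_level3`, `weights`
#'   diagnostics, and the echoed configuration.
#' @export
run_pathways <- function(cohort, exposure_def = "E1",
                         pathways = c("crude", "subgroup", "weighted"),
                         thresholds = threshold_config(),
                         event_keys = sae_categories(),
                         population = "all",
                         seed = 1L, n_mc = 1e5, leopard_window = 1L,
                         end_of_data = NULL) {
  pathways <- match.arg(pathways, c("crude", "subgroup", "weighted"),
                        several.ok = TRUE)
  if (population == "pediatric") pathways <- "crude"
  panel <- build_panel(cohort$participants, cohort$episodes, cohort$events,
                       labs = cohort$labs, edss = cohort$edss,
                       exposure_def = exposure_def, end_of_data = end_of_data)
  if (population == "pediatric") {
    panel_full <- panel
    panel <- panel[pediatric == TRUE]
    for (a in c("events", "episodes", "censor_months", "drugs", "vocab",
                "exposure_def")) {
      setattr(panel, a, attr(panel_full, a))
    }
    ped_ids <- unique(panel$participant_id)
    setattr(panel, "events",
            attr(panel_full, "events")[participant_id %in% ped_ids])
  }

  wts <- NULL
  if ("weighted" %in% pathways) {
    wts <- tryCatch({
      ip <- interval_panel(panel)
      den <- fit_treatment_model(ip, c("edss", "relapses_6m"))
      stabilized_iptw(ip, den)
    }, error = function(e) {
      warning("weighted pathway skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(wts)) pathways <- setdiff(pathways, "weighted")
  }
  subgroups <- if ("subgroup" %in% pathways) assign_subgroups(panel) else NULL

  l1 <- level1_list(panel, thresholds, event_keys, population)
  pairs <- l1[level1 == TRUE]
  rows <- list()
  detail <- list()
  idx <- 0L

  cp_cache <- new.env(parent = emptyenv())
  for (pi in seq_len(nrow(pairs))) {
    d <- pairs$drug[pi]; e <- pairs$event[pi]
    if (is.null(cp_cache[[e]])) {
      cp_cache[[e]] <- apply_incident_censoring(panel, e)
    }
    cp <- cp_cache[[e]]

    for (pw in pathways) {
      idx <- idx + 1L
      rec <- data.table(drug = d, drug2 = NA_character_, event = e,
                        exposure_def = exposure_def, pathway = toupper(pw),
                        subgroup = NA_character_,
                        n_participants = pairs$n_participants[pi])
      sub_detail <- NULL
      if (pw == "crude") {
        tab <- tabulate_panel(cp, d)
        rr_ <- ror(tab, thresholds$ci_level)
        rec <- fill_measures(rec, tab, thresholds$ci_level)
        rec[, lower95 := rr_$ci_low]
      } else if (pw == "weighted") {
        tab <- weighted_cells(cp, wts, d)
        rec <- fill_measures(rec, tab, thresholds$ci_level)
        wjoin <- join_weights(cp, wts)
        irr_w <- irr_from_panel(wjoin$panel, d, weights = wjoin$w,
                                method = "glm",
                                ci_level = thresholds$ci_level)
        rec[, lower95 := irr_w$ci_low]
      } else {
        sgs <- sort(unique(subgroups))
        sub_detail <- rbindlist(lapply(sgs, function(s) {
          pids <- names(subgroups)[subgroups == s]
          cps <- cp[participant_id %in% pids]
          if (nrow(cps) == 0L) return(NULL)
          tabs <- tabulate_panel(restore_attrs(cps, cp), d)
          rs <- ror(tabs, thresholds$ci_level)
          sr <- data.table(drug = d, drug2 = NA_character_, event = e,
                           exposure_def = exposure_def, pathway = "SUBGROUP",
                           subgroup = s,
                           n_participants = pairs$n_participants[pi])
          sr <- fill_measures(sr, tabs, thresholds$ci_level)
          sr[, lower95 := rs$ci_low]
          sr
        }))
        if (is.null(sub_detail) || nrow(sub_detail) == 0L) {
          sub_detail <- NULL
        } else {
          sub_detail <- level2_screen(sub_detail)
        }
        rec[, lower95 := suppressWarnings(
          max(c(sub_detail$lower95, -Inf), na.rm = TRUE))]
        if (!is.finite(rec$lower95)) rec[, lower95 := NA_real_]
        tab <- tabulate_panel(cp, d)   # pooled cells, reported for context
        rec <- fill_measures(rec, tab, thresholds$ci_level, keep_lower = TRUE)
      }
      rec <- level2_screen(rec)

      ## Level 3 inputs only for Level-2 signals
      rec[, `:=`(ic_mean = NA_real_, ic_q025 = NA_real_, ic_q975 = NA_real_,
                 p_null = NA_real_, leopard_before = NA_integer_,
                 leopard_after = NA_integer_, leopard_p = NA_real_,
                 leopard_discard = NA, leopard_untestable = NA)]
      if (rec$level2) {
        if (pw == "subgroup") {
          best <- list(p_null = NA_real_)
          sg_flag <- FALSE
          for (si in seq_len(nrow(sub_detail))) {
            if (!isTRUE(sub_detail$level2[si])) next
            s <- sub_detail$subgroup[si]
            pids <- names(subgroups)[subgroups == s]
            tabs <- contingency_table(sub_detail$n11[si], sub_detail$n10[si],
                                      sub_detail$n01[si], sub_detail$n00[si])
            post <- ic_posterior(tabs, n_mc = n_mc,
                                 seed = derive_seed(seed, idx * 100L + si))
            lp <- leopard_eval(panel, d, e, leopard_window, pids)
            ok <- post$p_null < thresholds$fdr_threshold &&
              !isTRUE(lp$discard)
            if (is.na(best$p_null) || post$p_null < best$p_null) {
              best <- c(post[c("ic_mean", "ic_q025", "ic_q975", "p_null")],
                        lp)
            }
            if (ok) sg_flag <- TRUE
          }
          if (!is.na(best$p_null)) {
            rec[, `:=`(ic_mean = best$ic_mean, ic_q025 = best$ic_q025,
                       ic_q975 = best$ic_q975, p_null = best$p_null,
                       leopard_before = best$n_before,
                       leopard_after = best$n_after,
                       leopard_p = best$p_value,
                       leopard_discard = best$discard,
                       leopard_untestable = best$untestable)]
          }
          rec[, level3 := level2 & sg_flag]
        } else {
          post <- ic_posterior(tab, n_mc = n_mc, seed = derive_seed(seed, idx))
          lp <- leopard_eval(panel, d, e, leopard_window)
          rec[, `:=`(ic_mean = post$ic_mean, ic_q025 = post$ic_q025,
                     ic_q975 = post$ic_q975, p_null = post$p_null,
                     leopard_before = lp$n_before, leopard_after = lp$n_after,
                     leopard_p = lp$p_value, leopard_discard = lp$discard,
                     leopard_untestable = lp$untestable)]
          rec <- level3_screen(rec, thresholds$fdr_threshold)
        }
      } else {
        rec[, level3 := FALSE]
      }
      rows[[length(rows) + 1L]] <- rec
      if (!is.null(sub_detail)) detail[[length(detail) + 1L]] <- sub_detail
    }
  }

  signals <- if (length(rows)) rbindlist(rows, fill = TRUE) else empty_signals()
  if (nrow(signals) > 0L) {
    ## running Bayesian FDR within each pathway's Level-2 list
    signals[, fdr := p_null]
    signals[, fdr_running := NA_real_]
    signals[level2 == TRUE & !is.na(p_null),
            fdr_running := fdr_for_list(p_null)$fdr_running, by = pathway]
  }
  pooled <- pool_and_rank(signals)
  list(signals = signals,
       subgroup_detail = if (length(detail)) rbindlist(detail) else NULL,
       level1 = l1, pooled_level2 = pooled$level2,
       pooled_level3 = pooled$level3,
       weights = wts,
       config = list(exposure_def = exposure_def, pathways = pathways,
                     thresholds = thresholds, population = population,
                     seed = seed, n_mc = n_mc,
                     leopard_window = leopard_window))
}

## helpers -------------------------------------------------------------------

fill_measures <- function(rec, tab, ci_level, keep_lower = FALSE) {
  rr_ <- ror(tab, ci_level); pr_ <- prr(tab, ci_level)
  rrr_ <- rrr(tab, ci_level)
  rec[, `:=`(n11 = tab$n11, n10 = tab$n10, n01 = tab$n01, n00 = tab$n00,
             ror = rr_$point, ror_lo = rr_$ci_low, ror_hi = rr_$ci_high,
             prr = pr_$point, prr_lo = pr_$ci_low, prr_hi = pr_$ci_high,
             rrr = rrr_$point, rrr_lo = rrr_$ci_low, rrr_hi = rrr_$ci_high,
             defined = rr_$defined)]
  rec
}

restore_attrs <- function(x, template) {
  for (a in c("events", "episodes", "exposure_def", "censor_months",
              "event_key", "drugs", "vocab")) {
    setattr(x, a, attr(template, a))
  }
  x
}

join_weights <- function(cp, wts, interval_months = INTERVAL_MONTHS) {
  p <- as.data.table(cp)
  p[, interval := month %/% interval_months]
  w <- as.data.table(wts)[, .(participant_id, interval, weight)]
  m <- w[p, on = c("participant_id", "interval")]
  m <- m[!is.na(weight)]
  list(panel = restore_attrs(m, cp), w = m$weight)
}

empty_signals <- function() {
  data.table(drug = character(), drug2 = character(), event = character(),
             exposure_def = character(), pathway = character(),
             subgroup = character(), n_participants = integer(),
             n11 = numeric(), n10 = numeric(), n01 = numeric(),
             n00 = numeric(), ror = numeric(), ror_lo = numeric(),
             ror_hi = numeric(), prr = numeric(), prr_lo = numeric(),
             prr_hi = numeric(), rrr = numeric(), rrr_lo = numeric(),
             rrr_hi = numeric(), defined = logical(), lower95 = numeric(),
             level2 = logical(), ic_mean = numeric(), ic_q025 = numeric(),
             ic_q975 = numeric(), p_null = numeric(),
             leopard_before = integer(), leopard_after = integer(),
             leopard_p = numeric(), leopard_discard = logical(),
             leopard_untestable = logical(), level3 = logical(),
             fdr = numeric(), fdr_running = numeric())
}

#' Pool pathway results and rank signals
#'
#' Pooled Level-2 and Level-3 lists keyed by (drug, event): signals are
#' ranked by the number of pathways flagging them (descending), then by the
#' best disproportionality statistic (Level 2: largest ROR lower bound) or
#' the lowest FDR estimate (Level 3), with lexicographic tie-breaks for
#' determinism.
#'
#' @param signals signal table from [run_pathways()].
#' @return list with `level2` and `level3` ranked data.tables.
#' @export
pool_and_rank <- function(signals) {
  s <- as.data.table(signals)
  if (nrow(s) == 0L) {
    return(list(level2 = s, level3 = s))
  }
  s2 <- s[level2 == TRUE]
  l2 <- if (nrow(s2) > 0L) {
    s2[, .(n_pathways = .N, best_stat = max(lower95, na.rm = TRUE),
           pathways = paste(sort(pathway), collapse = ",")),
       by = .(drug, drug2, event)]
  } else {
    data.table(drug = character(), drug2 = character(), event = character(),
               n_pathways = integer(), best_stat = numeric(),
               pathways = character())
  }
  setorder(l2, -n_pathways, -best_stat, drug, event, na.last = TRUE)
  s3 <- s[level3 == TRUE]
  l3 <- if (nrow(s3) > 0L) {
    s3[, .(n_pathways = .N, best_fdr = min(p_null, na.rm = TRUE),
           pathways = paste(sort(pathway), collapse = ",")),
       by = .(drug, drug2, event)]
  } else {
    data.table(drug = character(), drug2 = character(), event = character(),
               n_pathways = integer(), best_fdr = numeric(),
               pathways = character())
  }
  setorder(l3, -n_pathways, best_fdr, drug, event, na.last = TRUE)
  list(level2 = l2[], level3 = l3[])
}

#' Drug-drug-event interaction scan
#'
#' Scans pairs of drugs whose exposure windows overlap: pair exposure is the
#' set of patient-months qualifying for both drugs under the active exposure
#' definition (E2/E3 capture sequential exposure and washout), the
#' background is all other patient-months, and the Level 1-3 machinery is
#' reused (crude pathway; the minimum-report criterion uses the stricter of
#' the two drugs' thresholds; LEOPARD initiation is the later of the two
#' drugs' first initiations).
#'
#' @inheritParams run_pathways
#' @return Signal table for drug pairs (possibly empty).
#' @export
drug_drug_event_scan <- function(cohort, exposure_def = "E2",
                                 thresholds = threshold_config(),
                                 event_keys = sae_categories(),
                                 seed = 1L, n_mc = 1e5, leopard_window = 1L) {
  panel <- build_panel(cohort$participants, cohort$episodes, cohort$events,
                       labs = cohort$labs, edss = cohort$edss,
                       exposure_def = exposure_def)
  drugs <- attr(panel, "drugs")
  vocab <- attr(panel, "vocab")
  combos <- if (length(drugs) >= 2L) utils::combn(drugs, 2L, simplify = FALSE)
            else list()
  rows <- list(); idx <- 0L
  for (pr in combos) {
    co_months <- sum(exposure_flag(panel, pr))
    if (co_months == 0L) next
    cls <- drug_class_of(pr, vocab)
    thr <- if (any(cls == "FIRST_GEN")) thresholds$min_participants_first_gen
           else thresholds$min_participants_second_gen
    for (e in event_keys) {
      n_aff <- count_affected(panel, pr, e)
      if (n_aff < thr) next
      idx <- idx + 1L
      cp <- apply_incident_censoring(panel, e)
      tab <- tabulate_panel(cp, pr)
      rr_ <- ror(tab, thresholds$ci_level)
      rec <- data.table(drug = pr[1L], drug2 = pr[2L], event = e,
                        exposure_def = exposure_def, pathway = "CRUDE",
                        subgroup = NA_character_, n_participants = n_aff)
      rec <- fill_measures(rec, tab, thresholds$ci_level)
      rec[, lower95 := rr_$ci_low]
      rec <- level2_screen(rec)
      rec[, `:=`(ic_mean = NA_real_, ic_q025 = NA_real_, ic_q975 = NA_real_,
                 p_null = NA_real_, leopard_before = NA_integer_,
                 leopard_after = NA_integer_, leopard_p = NA_real_,
                 leopard_discard = NA, leopard_untestable = NA,
                 level3 = FALSE)]
      if (rec$level2) {
        post <- ic_posterior(tab, n_mc = n_mc, seed = derive_seed(seed, idx))
        lp <- leopard_pair_eval(panel, pr, e, leopard_window)
        rec[, `:=`(ic_mean = post$ic_mean, ic_q025 = post$ic_q025,
                   ic_q975 = post$ic_q975, p_null = post$p_null,
                   leopard_before = lp$n_before, leopard_after = lp$n_after,
                   leopard_p = lp$p_value, leopard_discard = lp$discard,
                   leopard_untestable = lp$untestable)]
        rec <- level3_screen(rec, thresholds$fdr_threshold)
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows)) rbindlist(rows, fill = TRUE) else empty_signals()
}

## LEOPARD for a drug pair: "initiation" is the later of the two drugs'
## first initiations (the moment co-exposure can begin)
leopard_pair_eval <- function(panel, pair, event_key, window_months) {
  ep <- attr(panel, "episodes")
  inc <- incident_events(panel, event_key)
  i1 <- ep[drug == pair[1L], .(d1 = min(start_date)), by = participant_id]
  i2 <- ep[drug == pair[2L], .(d2 = min(start_date)), by = participant_id]
  init <- merge(i1, i2, by = "participant_id")
  init[, start_date := pmax(d1, d2)]
  x <- merge(inc, init[, .(participant_id, start_date)],
             by = "participant_id")
  if (nrow(x) == 0L) {
    return(list(n_before = 0L, n_after = 0L, p_value = NA_real_,
                discard = FALSE, untestable = TRUE))
  }
  wd <- window_months * DAYS_PER_MONTH
  dd <- as.numeric(x$start_date - x$event_date)
  cnt <- list(n_before = sum(dd >= -wd & dd < 0),
              n_after = sum(dd >= 0 & dd < wd))
  c(cnt, leopard_test(cnt$n_before, cnt$n_after))
}

#' Interim analysis
#'
#' The simplified annual analysis: the crude-pathway single-drug signal scan
#' plus simple constant-hazard unadjusted Poisson regressions of the
#' occurrence of any SAE on the current treatment class (rate ratios vs no
#' treatment, with participant-clustered robust CIs).
#'
#' @inheritParams run_pathways
#' @return list `(signals, pooled_level2, pooled_level3, sae_rate_ratios)`.
#' @export
interim_run <- function(cohort, exposure_def = "E1",
                        thresholds = threshold_config(), seed = 1L,
                        n_mc = 1e5) {
  res <- run_pathways(cohort, exposure_def, pathways = "crude",
                      thresholds = thresholds, seed = seed, n_mc = n_mc)
  panel <- build_panel(cohort$participants, cohort$episodes, cohort$events,
                       labs = cohort$labs, edss = cohort$edss,
                       exposure_def = exposure_def)
  ## first SAE of any category, censoring thereafter
  ev <- attr(panel, "events")
  sae <- ev[category %in% sae_categories()]
  first <- sae[order(month), .(month = month[1L]), by = participant_id]
  p <- as.data.table(panel)
  p[first, first_m := i.month, on = "participant_id"]
  p <- p[is.na(first_m) | month <= first_m]
  p[, y := as.integer(!is.na(first_m) & month == first_m)]
  p[, cls := droplevels(factor(cur_class, levels = TREATMENT_CLASSES))]
  fit <- glm(y ~ cls, family = poisson(), data = p)
  V <- cluster_vcov(fit, p$participant_id)
  est <- coef(fit)[-1L]
  se <- sqrt(diag(V))[-1L]
  z <- qnorm(0.975)
  rrtab <- data.table(
    class = sub("^cls", "", names(est)),
    rate_ratio = exp(est),
    ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    n_events = sum(p$y))
  list(signals = res$signals, pooled_level2 = res$pooled_level2,
       pooled_level3 = res$pooled_level3, sae_rate_ratios = rrtab[])
}
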