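## Synthetic-cohort generator with known ground truth.
##
## The generative model works in discrete time on the same 30-day bins the
## analysis uses. Treatment class is re-assessed at regular decision points
## (default every 6 months) by a multinomial logit on the previous class and
## the observable covariates (last measured EDSS, relapses in the preceding
## 6 months); the confounding strength gamma scales the covariate
## coefficients. Event occurrence is Bernoulli per patient-month with hazard
## = baseline x planted rate ratio of the current exposure x an optional
## covariate multiplier (outcome-side confounding) x optional carryover and
## protopathic-prodrome multipliers. Because assignment never depends on the
## SAE events themselves, treatment paths are simulated first and SAE events
## second, which lets the protopathic scenario raise the hazard in the lead
## months *preceding* each initiation.

#' Simulation configuration
#'
#' All knobs of the synthetic cohort with their default "stated world"
#' values. See `vignette("longsig-methods")` for the rationale behind each
#' default.
#'
#' @param n_patients cohort size.
#' @param horizon_months administrative follow-up horizon (30-day months).
#' @param seed mandatory RNG seed.
#' @param gamma treatment-assignment confounding strength (scales the
#'   covariate coefficients in the class logits; 0 = randomized).
#' @param gamma_out outcome-side confounding strength (scales the covariate
#'   log-multiplier on SAE hazards).
#' @param rr named list of true rate ratios, keys `"DRUG|CATEGORY"` or
#'   `"CLASS:<class>|CATEGORY"`.
#' @param protopathic list(multiplier, lead_months, category): hazard
#'   multiplier in the `lead_months` before each treatment initiation.
#' @param carryover list(class, rr, window, only_when_class): hazard
#'   multiplier for `window` months after leaving `class` (optionally only
#'   while the current class is `only_when_class`).
#' @param decision_interval_months months between treatment re-assessments.
#' @param persistence logit bonus for staying in the previous treated class.
#' @param none_inertia logit bonus for remaining untreated.
#' @param intercepts class logits at a decision (vs NONE) for an average
#'   patient.
#' @param conf_coef covariate coefficients in the class-assignment logits
#'   (applied to second-generation; first-generation gets
#'   `first_gen_frac` of them).
#' @param first_gen_frac see above.
#' @param out_coef covariate coefficients in the outcome hazard
#'   log-multiplier.
#' @param event_hazards baseline monthly hazards per event category.
#' @param relapse_class_rr treatment effect on relapse hazard, per class.
#' @param withdraw_prob monthly probability of withdrawal.
#' @param pct_prior_first_gen,pct_prior_second_gen fractions with
#'   pre-enrolment exposure history.
#' @param labs_every_months lab sampling cadence.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L, horizon_months = 60L, seed = 1L,
                       gamma = 0, gamma_out = 0, rr = list(),
                       protopathic = list(multiplier = 1, lead_months = 1L,
                                          category = "INFECTION"),
                       carryover = list(class = NULL, rr = 1, window = 6L,
                                        only_when_class = NULL),
                       decision_interval_months = 6L,
                       persistence = 2.5, none_inertia = 1.0,
                       intercepts = c(FIRST_GEN = -1.2, SECOND_GEN = -0.7),
                       conf_coef = c(edss = 0.5, relapses_6m = 0.7),
                       first_gen_frac = 0.3,
                       out_coef = c(edss = 0.25, relapses_6m = 0.4),
                       event_hazards = c(INFECTION = 0.005,
                                         OPPORTUNISTIC_INFECTION = 8e-4,
                                         MALIGNANCY_TREATMENT_RELATED = 5e-4,
                                         DEATH = 4e-4, COVID19 = 0.002,
                                         OTHER_SAE = 0.004, RELAPSE = 0.03),
                       relapse_class_rr = c(NONE = 1, FIRST_GEN = 0.7,
                                            SECOND_GEN = 0.45),
                       withdraw_prob = 0.004,
                       pct_prior_first_gen = 0.35,
                       pct_prior_second_gen = 0.10,
                       labs_every_months = 3L) {
  assert_that(n_patients > 0, "n_patients must be positive")
  assert_that(!is.null(seed), "seed is mandatory")
  assert_that(all(unlist(rr) > 0), "rate ratios must be positive")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Named scenario presets
#'
#' Fixed, documented configurations for the validation experiments:
#' * `null`: all rate ratios 1, no confounding;
#' * `planted_signal`: RR(NATALIZUMAB, INFECTION) = 3, no confounding;
#' * `confounded`: RR(second-generation class, INFECTION) = 2 with
#'   assignment- and outcome-side confounding (`gamma = gamma_out = 1`), so
#'   sicker patients preferentially receive second-generation DMT and have
#'   elevated event hazards;
#' * `protopathic`: all RR = 1, infection hazard tripled in the month
#'   preceding each treatment initiation, frequent treatment cycling;
#' * `switching_carryover`: a carryover effect (RR 2 for 6 months after
#'   leaving first-generation DMT), expressed only while on
#'   second-generation DMT.
#'
#' @param name preset name.
#' @param ... overrides passed to [sim_config()] (e.g. `n_patients`, `seed`).
#' @return A `sim_config`.
#' @export
scenario_presets <- function(name = c("null", "planted_signal", "confounded",
                                      "protopathic", "switching_carryover"),
                             ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- switch(name,
    null = list(),
    planted_signal = list(rr = list("NATALIZUMAB|INFECTION" = 3)),
    confounded = list(gamma = 1.3, gamma_out = 1.3,
                      rr = list("CLASS:SECOND_GEN|INFECTION" = 2)),
    protopathic = list(
      protopathic = list(multiplier = 3, lead_months = 1L,
                         category = "INFECTION"),
      decision_interval_months = 3L, persistence = 1.2, none_inertia = 0.5,
      event_hazards = c(INFECTION = 0.01, OPPORTUNISTIC_INFECTION = 8e-4,
                        MALIGNANCY_TREATMENT_RELATED = 5e-4, DEATH = 4e-4,
                        COVID19 = 0.002, OTHER_SAE = 0.004, RELAPSE = 0.03)),
    switching_carryover = list(
      carryover = list(class = "FIRST_GEN", rr = 2, window = 6L,
                       only_when_class = "SECOND_GEN"))
  )
  cfg <- do.call(sim_config, utils::modifyList(base, over))
  cfg$preset <- name
  cfg
}

## rate-ratio lookup for (drug, class) x category, vectorized over months
rr_multiplier <- function(rrmap, drug, cls, category) {
  out <- rep(1, length(drug))
  if (length(rrmap) == 0L) return(out)
  for (key in names(rrmap)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    if (parts[2L] != category) next
    hit <- if (startsWith(parts[1L], "CLASS:")) {
      cls == sub("^CLASS:", "", parts[1L])
    } else drug == parts[1L] & !is.na(drug)
    out[hit] <- out[hit] * rrmap[[key]]
  }
  out
}

#' Simulate a synthetic cohort
#'
#' Generates participants, exposure episodes, adverse events, labs and EDSS
#' measurements in the file schemas consumed by [build_panel()], together
#' with the realized ground truth (true assignment probabilities per
#' decision point and the full configuration) for method validation.
#'
#' @param config a [sim_config()] or preset from [scenario_presets()].
#' @return list `(participants, episodes, events, labs, edss, truth,
#'   config)`; `truth$assignments` holds one row per participant-decision
#'   with the three true class probabilities.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(as.integer(cfg$seed))
  n <- as.integer(cfg$n_patients)
  M <- as.integer(cfg$horizon_months)
  vocab <- dmt_vocabulary()
  first_drugs <- vocab[drug_class == "FIRST_GEN", drug]
  second_drugs <- vocab[drug_class == "SECOND_GEN", drug]

  ## --- participants -------------------------------------------------------
  id <- sprintf("P%05d", seq_len(n))
  sex <- ifelse(runif(n) < 0.72, "F", "M")
  age0 <- pmin(pmax(rnorm(n, 40, 11), 12), 70)
  enrolment <- as.Date("2019-05-01") + floor(runif(n, 0, 365))
  birth <- enrolment - round(age0 * 365.25)
  disease_duration <- round(rgamma(n, shape = 2, scale = 4), 1)
  baseline_edss <- pmin(round(2 * pmax(rnorm(n, 2, 1.5), 0)) / 2, 6.5)
  comorbidities <- rpois(n, 0.8)
  exit_month <- pmin(rgeom(n, cfg$withdraw_prob) + 1L, M)

  ## pre-enrolment treatment history
  prior1g <- runif(n) < cfg$pct_prior_first_gen
  prior2g <- runif(n) < cfg$pct_prior_second_gen
  pre_eps <- list()
  if (any(prior1g)) {
    k <- which(prior1g)
    pre_eps[[1L]] <- data.table(
      participant_id = id[k],
      drug = sample(first_drugs, length(k), replace = TRUE),
      start_date = enrolment[k] - 365L * 3L,
      end_date = enrolment[k] - 365L)
  }
  if (any(prior2g)) {
    k <- which(prior2g)
    pre_eps[[length(pre_eps) + 1L]] <- data.table(
      participant_id = id[k],
      drug = sample(second_drugs, length(k), replace = TRUE),
      start_date = enrolment[k] - 300L,
      end_date = enrolment[k] - 60L)
  }

  ## --- pass 1: covariates, relapses, treatment path -----------------------
  dec <- as.integer(cfg$decision_interval_months)
  z <- rnorm(n)                      # latent disease activity, AR(1)
  rho <- 0.85
  edss_cur <- baseline_edss          # underlying disability
  edss_meas <- baseline_edss         # value in force (measured at decisions)
  rel_buf <- matrix(FALSE, n, 6L)    # relapse indicators, last 6 months
  cur_class <- rep("NONE", n)
  cur_drug <- rep(NA_character_, n)
  class_mat <- matrix("NONE", n, M)
  drug_mat <- matrix(NA_character_, n, M)
  edss_mat <- matrix(NA_real_, n, M)
  rel6_mat <- matrix(NA_integer_, n, M)
  relapse_mat <- matrix(FALSE, n, M)
  spell_id <- matrix(0L, n, M)       # distinct treated-spell counter
  spell_cnt <- rep(0L, n)
  truth_rows <- vector("list", ceiling(M / dec))
  edss_rows <- vector("list", ceiling(M / dec))
  ti <- 0L

  cc <- cfg$conf_coef
  for (m in seq_len(M) - 1L) {
    rel6 <- as.integer(rowSums(rel_buf))
    if (m %% dec == 0L) {
      ## EDSS review: small chance of 0.5-step worsening per review
      step <- runif(n) < plogis(-2.2 + 0.4 * z)
      edss_cur <- pmin(edss_cur + 0.5 * step, 10)
      edss_meas <- edss_cur
      ti <- ti + 1L
      edss_rows[[ti]] <- data.table(participant_id = id, month = m,
                                    edss = edss_meas)
      ## treatment decision: multinomial logit on prev class + covariates
      s <- cc[["edss"]] * (edss_meas - 2) + cc[["relapses_6m"]] * rel6
      l_none <- cfg$none_inertia * (cur_class == "NONE")
      l_1g <- cfg$intercepts[["FIRST_GEN"]] +
        cfg$persistence * (cur_class == "FIRST_GEN") +
        cfg$gamma * cfg$first_gen_frac * s
      l_2g <- cfg$intercepts[["SECOND_GEN"]] +
        cfg$persistence * (cur_class == "SECOND_GEN") +
        cfg$gamma * s
      mx <- pmax(l_none, l_1g, l_2g)
      e0 <- exp(l_none - mx); e1 <- exp(l_1g - mx); e2 <- exp(l_2g - mx)
      tot <- e0 + e1 + e2
      P <- cbind(NONE = e0 / tot, FIRST_GEN = e1 / tot, SECOND_GEN = e2 / tot)
      u <- runif(n)
      new_class <- ifelse(u < P[, 1L], "NONE",
                          ifelse(u < P[, 1L] + P[, 2L], "FIRST_GEN",
                                 "SECOND_GEN"))
      truth_rows[[ti]] <- data.table(
        participant_id = id, month = m, prev_class = cur_class,
        class = new_class, p_none = P[, 1L], p_first = P[, 2L],
        p_second = P[, 3L], edss = edss_meas, relapses_6m = rel6)
      changed <- new_class != cur_class
      enter <- changed & new_class != "NONE"
      if (any(enter)) {
        k <- which(enter)
        cur_drug[k] <- ifelse(new_class[k] == "FIRST_GEN",
                              sample(first_drugs, length(k), replace = TRUE),
                              sample(second_drugs, length(k), replace = TRUE))
        spell_cnt[k] <- spell_cnt[k] + 1L
      }
      cur_drug[changed & new_class == "NONE"] <- NA_character_
      cur_class <- new_class
    }
    class_mat[, m + 1L] <- cur_class
    drug_mat[, m + 1L] <- cur_drug
    edss_mat[, m + 1L] <- edss_meas
    rel6_mat[, m + 1L] <- rel6
    spell_id[, m + 1L] <- ifelse(cur_class == "NONE", 0L, spell_cnt)
    ## relapse events (depend on latent activity and treatment class)
    h_rel <- cfg$event_hazards[["RELAPSE"]] * exp(0.6 * z) *
      cfg$relapse_class_rr[cur_class]
    relapse_mat[, m + 1L] <- runif(n) < pmin(h_rel, 0.95)
    rel_buf <- cbind(rel_buf[, -1L, drop = FALSE], relapse_mat[, m + 1L])
    z <- rho * z + sqrt(1 - rho^2) * rnorm(n)
  }

  ## --- episodes from treated spells ---------------------------------------
  ## a spell's start day gets a uniform within-bin offset; treated->NONE
  ## cessation falls on the bin boundary so the analysis month grid matches
  ## the generative treatment state
  eps <- list()
  sp_off <- list()   # per (pid, spell) start day offset, for protopathic
  for (i in seq_len(n)) {
    Mi <- exit_month[i]
    si <- spell_id[i, seq_len(Mi)]
    if (all(si == 0L)) next
    r <- rle(si)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != 0L
    if (!any(keep)) next
    m0 <- starts[keep] - 1L
    m1 <- ends[keep]                  # exclusive month
    u <- floor(runif(length(m0), 0, DAYS_PER_MONTH))
    dr <- drug_mat[i, m0 + 1L]
    open_end <- m1 >= Mi
    eps[[length(eps) + 1L]] <- data.table(
      participant_id = id[i], drug = dr,
      start_date = enrolment[i] + m0 * DAYS_PER_MONTH + u,
      end_date = as.Date(ifelse(open_end, NA,
                                enrolment[i] + m1 * DAYS_PER_MONTH),
                         origin = "1970-01-01"))
    sp_off[[length(sp_off) + 1L]] <- data.table(
      participant_id = id[i], start_month = m0, start_day_offset = u)
  }
  episodes <- if (length(eps)) rbindlist(eps) else
    data.table(participant_id = character(), drug = character(),
               start_date = as.Date(character()),
               end_date = as.Date(character()))
  inits <- if (length(sp_off)) rbindlist(sp_off) else
    data.table(participant_id = character(), start_month = integer(),
               start_day_offset = numeric())

  ## --- pass 2: SAE events --------------------------------------------------
  pm <- data.table(
    pid = rep(seq_len(n), M), month = rep(seq_len(M) - 1L, each = n),
    cls = as.vector(class_mat), drg = as.vector(drug_mat),
    edss = as.vector(edss_mat), rel6 = as.vector(rel6_mat))
  pm <- pm[month < exit_month[pid]]
  pm[, participant_id := id[pid]]

  ## protopathic prodrome overlap fraction per patient-month
  pm[, prodrome_frac := 0]
  pm[, prodrome_lo := NA_real_]   # prodrome window within the bin, days
  pm[, prodrome_hi := NA_real_]
  pp <- cfg$protopathic
  if (pp$multiplier != 1 && nrow(inits) > 0L) {
    lead_d <- pp$lead_months * DAYS_PER_MONTH
    iw <- inits[, .(participant_id,
                    init_day = start_month * DAYS_PER_MONTH + start_day_offset)]
    iw <- iw[, .(lo = init_day - lead_d, hi = init_day), by = seq_len(nrow(iw))]
    iw[, seq_len := NULL]
    iw[, participant_id := inits$participant_id]
    ## months overlapped by each prodrome window
    iw[, m_lo := as.integer(floor(lo / DAYS_PER_MONTH))]
    iw[, m_hi := as.integer(floor((hi - 1) / DAYS_PER_MONTH))]
    iw <- iw[m_hi >= 0L]
    ov <- iw[, .(month = seq.int(max(m_lo, 0L), m_hi), lo = lo, hi = hi),
             by = .(participant_id, seq_len(nrow(iw)))][, seq_len := NULL]
    ov[, bin_lo := month * DAYS_PER_MONTH]
    ov[, o_lo := pmax(lo, bin_lo)]
    ov[, o_hi := pmin(hi, bin_lo + DAYS_PER_MONTH)]
    ov <- ov[o_hi > o_lo]
    ov <- ov[, .(frac = min(sum(o_hi - o_lo) / DAYS_PER_MONTH, 1),
                 p_lo = o_lo[1L] - bin_lo[1L], p_hi = o_hi[1L] - bin_lo[1L]),
             by = .(participant_id, month)]
    pm[ov, `:=`(prodrome_frac = i.frac, prodrome_lo = i.p_lo,
                prodrome_hi = i.p_hi), on = c("participant_id", "month")]
  }

  ## carryover multiplier: within `window` months after leaving `class`
  pm[, carry_mult := 1]
  co <- cfg$carryover
  if (!is.null(co$class) && co$rr != 1) {
    ph <- data.table(pid = rep(seq_len(n), M),
                     month = rep(seq_len(M) - 1L, each = n),
                     cls = as.vector(class_mat))
    src <- ph[cls == co$class]
    if (nrow(src) > 0L) {
      win <- src[, .(pid = rep(pid, each = co$window),
                     month = rep(month, each = co$window) +
                       seq_len(co$window))]
      win <- unique(win)
      pm[win, carry_applies := TRUE, on = c("pid", "month")]
      pm[is.na(carry_applies), carry_applies := FALSE]
      pm[cls == co$class, carry_applies := FALSE]   # must have *left* it
      if (!is.null(co$only_when_class)) {
        pm[cls != co$only_when_class, carry_applies := FALSE]
      }
      pm[carry_applies == TRUE, carry_mult := co$rr]
      pm[, carry_applies := NULL]
    }
  }

  conf_mult <- exp(cfg$gamma_out * (cfg$out_coef[["edss"]] * (pm$edss - 2) +
                                    cfg$out_coef[["relapses_6m"]] * pm$rel6))
  ev_rows <- list()
  clipped <- 0L
  for (cat_ in setdiff(names(cfg$event_hazards), "RELAPSE")) {
    h0 <- cfg$event_hazards[[cat_]]
    h <- h0 * rr_multiplier(cfg$rr, pm$drg, pm$cls, cat_) * conf_mult *
      pm$carry_mult
    if (pp$multiplier != 1 && cat_ == pp$category) {
      h <- h * (1 - pm$prodrome_frac + pp$multiplier * pm$prodrome_frac)
    }
    clipped <- clipped + sum(h > 0.99)
    hit <- runif(nrow(pm)) < pmin(h, 0.99)
    if (!any(hit)) next
    sel <- pm[hit]
    ## event day within bin: prodrome-weighted for the protopathic category
    day <- floor(runif(nrow(sel), 0, DAYS_PER_MONTH))
    if (pp$multiplier != 1 && cat_ == pp$category) {
      in_pro <- !is.na(sel$prodrome_lo)
      if (any(in_pro)) {
        f <- sel$prodrome_frac[in_pro]
        w_pro <- pp$multiplier * f / (pp$multiplier * f + (1 - f))
        pick <- runif(sum(in_pro)) < w_pro
        lo <- sel$prodrome_lo[in_pro]; hi <- sel$prodrome_hi[in_pro]
        d_pro <- floor(lo + runif(sum(in_pro)) * (hi - lo))
        day[in_pro][pick] <- d_pro[pick]
      }
    }
    ev_rows[[length(ev_rows) + 1L]] <- data.table(
      participant_id = sel$participant_id, category = cat_,
      subtype = NA_character_,
      event_date = enrolment[sel$pid] + sel$month * DAYS_PER_MONTH + day)
  }
  if (clipped > 0L) {
    warning(sprintf("%d hazard value(s) clipped to 0.99", clipped),
            call. = FALSE)
  }

  ## relapse events
  relw <- which(relapse_mat & col(relapse_mat) <= exit_month[row(relapse_mat)])
  if (length(relw) > 0L) {
    ri <- ((relw - 1L) %% n) + 1L
    rm <- ((relw - 1L) %/% n)
    ev_rows[[length(ev_rows) + 1L]] <- data.table(
      participant_id = id[ri], category = "RELAPSE", subtype = NA_character_,
      event_date = enrolment[ri] + rm * DAYS_PER_MONTH +
        floor(runif(length(ri), 0, DAYS_PER_MONTH)))
  }
  events <- if (length(ev_rows)) rbindlist(ev_rows) else
    data.table(participant_id = character(), category = character(),
               subtype = character(), event_date = as.Date(character()))

  ## death truncates follow-up: drop later records, close episodes
  dsub <- events[category == "DEATH"]
  deaths <- if (nrow(dsub) > 0L) {
    dsub[, .(death_date = min(event_date)), by = participant_id]
  } else dsub[, .(participant_id, death_date = event_date)]
  if (nrow(deaths) > 0L) {
    dmap <- setNames(deaths$death_date, deaths$participant_id)
    dm <- dmap[events$participant_id]
    events <- events[is.na(dm) | event_date <= dm]
    ## censor at end of the death month bin
    enrol_map <- setNames(enrolment, id)
    dbin_end <- enrol_map[deaths$participant_id] +
      (month_of(deaths$death_date, enrol_map[deaths$participant_id]) + 1L) *
      DAYS_PER_MONTH
    dend <- setNames(dbin_end, deaths$participant_id)
    de <- dend[episodes$participant_id]
    episodes <- episodes[is.na(de) | start_date < de]
    de <- dend[episodes$participant_id]
    fix <- !is.na(de) & (is.na(episodes$end_date) | episodes$end_date > de)
    episodes[fix, end_date := de[fix]]
    exit_adj <- dend[id]
  } else {
    exit_adj <- rep(as.Date(NA), n)
  }
  exit_date <- enrolment + exit_month * DAYS_PER_MONTH
  exit_date <- pmin(exit_date, data.table::fifelse(is.na(exit_adj),
                                                   exit_date, exit_adj))

  ## pre-enrolment history episodes join the on-study ones
  if (length(pre_eps) > 0L) {
    episodes <- rbindlist(c(pre_eps, list(episodes)), use.names = TRUE)
  }
  episodes[, drug_class := drug_class_of(drug, vocab)]
  setorder(episodes, participant_id, start_date)

  ## --- labs ----------------------------------------------------------------
  lab_months <- seq.int(0L, M - 1L, by = cfg$labs_every_months)
  lb <- data.table(pid = rep(seq_len(n), length(lab_months)),
                   month = rep(lab_months, each = n))
  lb <- lb[month < exit_month[pid]]
  lb[, cls := class_mat[cbind(pid, month + 1L)]]
  alc_meanlog <- log(data.table::fifelse(lb$cls == "SECOND_GEN", 1150, 1800))
  labs <- rbind(
    data.table(participant_id = id[lb$pid],
               date = enrolment[lb$pid] + lb$month * DAYS_PER_MONTH,
               analyte = "ALC",
               value = round(rlnorm(nrow(lb), alc_meanlog, 0.35)),
               lln = 1000, uln = 4000),
    data.table(participant_id = id[lb$pid],
               date = enrolment[lb$pid] + lb$month * DAYS_PER_MONTH,
               analyte = "ALT",
               value = round(rlnorm(nrow(lb),
                                    log(data.table::fifelse(
                                      lb$cls == "SECOND_GEN", 30, 25)), 0.5), 1),
               lln = 7, uln = 40))

  participants <- data.table(
    id = id, sex = sex, birth_date = birth, enrolment_date = enrolment,
    exit_date = exit_date, disease_duration = disease_duration,
    baseline_edss = baseline_edss, comorbidities = comorbidities,
    prior_first_gen = prior1g)

  edss_tab <- rbindlist(edss_rows)
  edss_tab <- edss_tab[month < exit_month[match(participant_id, id)]]
  edss_tab[, date := enrolment[match(participant_id, id)] +
             month * DAYS_PER_MONTH]
  edss_tab <- edss_tab[, .(participant_id, date, edss)]

  truth <- list(assignments = rbindlist(truth_rows), config = cfg,
                exit_month = setNames(exit_month, id))

  list(participants = participants, episodes = episodes, events = events,
       labs = labs, edss = edss_tab, truth = truth, config = cfg)
}
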