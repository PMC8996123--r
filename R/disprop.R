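## Disproportionality module: 2x2 patient-month contingency tables and the
## simple measures ROR / PRR / RRR / IRR with log-scale (Woolf/delta) CIs.

#' Construct a patient-month contingency table
#'
#' Cells follow the standard layout: `n11` exposed months with the event,
#' `n10` exposed months without, `n01` unexposed months with the event,
#' `n00` unexposed months without. Cells may be real-valued when weighted.
#'
#' @param n11,n10,n01,n00 nonnegative cell counts (patient-months).
#' @return An object of class `contingency_table` with derived margins
#'   `n1.` (exposed), `n0.` (unexposed), `n.1` (event), `n.0`, `n..`.
#' @export
#' @examples
#' contingency_table(2, 98, 1, 99)
contingency_table <- function(n11, n10, n01, n00) {
  cells <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  assert_that(all(is.finite(cells)) && all(cells >= 0),
              "contingency cells must be finite and nonnegative")
  out <- list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
              n1. = n11 + n10, n0. = n01 + n00,
              n.1 = n11 + n01, n.0 = n10 + n00,
              n.. = n11 + n10 + n01 + n00)
  class(out) <- "contingency_table"
  out
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2L, byrow = TRUE,
              dimnames = list(c("exposed", "unexposed"),
                              c("event", "no event")))
  cat("patient-month contingency table (n.. =", x$n.., ")\n")
  print(m)
  invisible(x)
}

measure_estimate <- function(measure, point, log_se, ci_level = 0.95,
                             defined = TRUE, reason = NA_character_) {
  if (!defined || !is.finite(point) || !is.finite(log_se)) {
    est <- list(measure = measure, point = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, log_se = NA_real_, ci_level = ci_level,
                defined = FALSE,
                reason = if (is.na(reason)) "undefined estimate" else reason)
  } else {
    z <- qnorm(1 - (1 - ci_level) / 2)
    est <- list(measure = measure, point = point,
                ci_low = point * exp(-z * log_se),
                ci_high = point * exp(z * log_se),
                log_se = log_se, ci_level = ci_level, defined = TRUE,
                reason = NA_character_)
  }
  class(est) <- "measure_estimate"
  est
}

#' @export
print.measure_estimate <- function(x, ...) {
  if (!x$defined) {
    cat(sprintf("%s: undefined (%s)\n", x$measure, x$reason))
  } else {
    cat(sprintf("%s = %.4g [%.4g, %.4g] (%d%% CI, log-SE %.3g)\n", x$measure,
                x$point, x$ci_low, x$ci_high, round(100 * x$ci_level),
                x$log_se))
  }
  invisible(x)
}

.check_cells <- function(tab, needed) {
  vals <- vapply(needed, function(nm) tab[[nm]], numeric(1))
  if (any(vals <= 0)) {
    return(sprintf("zero cell/margin (%s); no continuity correction applied",
                   paste(needed[vals <= 0], collapse = ", ")))
  }
  NA_character_
}

#' Reporting odds ratio
#'
#' `ROR = n11 * n00 / (n01 * n10)`, with a 95% Woolf (log-scale) confidence
#' interval, `SE = sqrt(1/n00 + 1/n01 + 1/n10 + 1/n11)`. Any zero cell yields
#' a flagged undefined (non-signal) estimate rather than a continuity
#' correction.
#'
#' @param table a [contingency_table()].
#' @param ci_level confidence level (default 0.95).
#' @return A `measure_estimate`.
#' @export
#' @examples
#' ror(contingency_table(2, 10, 1, 100))  # point estimate 20
ror <- function(table, ci_level = 0.95) {
  bad <- .check_cells(table, c("n11", "n10", "n01", "n00"))
  if (!is.na(bad)) return(measure_estimate("ROR", NA, NA, ci_level, FALSE, bad))
  point <- table$n11 * table$n00 / (table$n01 * table$n10)
  se <- sqrt(1 / table$n00 + 1 / table$n01 + 1 / table$n10 + 1 / table$n11)
  measure_estimate("ROR", point, se, ci_level)
}

#' Proportional reporting ratio
#'
#' `PRR = (n11 / n1.) / (n01 / n0.)`: the event rate in exposed
#' patient-months over the rate in unexposed patient-months (hence identical
#' to the incidence rate ratio in this longitudinal formulation).
#' Log-scale `SE = sqrt(1/n11 - 1/n1. + 1/n01 - 1/n0.)`.
#'
#' @inheritParams ror
#' @return A `measure_estimate`.
#' @export
prr <- function(table, ci_level = 0.95) {
  bad <- .check_cells(table, c("n11", "n01", "n1.", "n0."))
  if (!is.na(bad)) return(measure_estimate("PRR", NA, NA, ci_level, FALSE, bad))
  point <- (table$n11 / table$`n1.`) / (table$n01 / table$`n0.`)
  se2 <- 1 / table$n11 - 1 / table$`n1.` + 1 / table$n01 - 1 / table$`n0.`
  measure_estimate("PRR", point, sqrt(max(se2, 0)), ci_level)
}

#' Relative reporting ratio
#'
#' `RRR = n11 * n.. / (n.1 * n1.)`: the event rate in exposed patient-months
#' over the rate in all patient-months. Its base-2 logarithm is the crude
#' information component. Log-scale
#' `SE = sqrt(1/n11 - 1/n1. + 1/n.1 - 1/n..)` (standard approximation).
#'
#' @inheritParams ror
#' @return A `measure_estimate`.
#' @export
rrr <- function(table, ci_level = 0.95) {
  bad <- .check_cells(table, c("n11", "n1.", "n.1"))
  if (!is.na(bad)) return(measure_estimate("RRR", NA, NA, ci_level, FALSE, bad))
  point <- table$n11 * table$`n..` / (table$`n.1` * table$`n1.`)
  se2 <- 1 / table$n11 - 1 / table$`n1.` + 1 / table$`n.1` - 1 / table$`n..`
  measure_estimate("RRR", point, sqrt(max(se2, 0)), ci_level)
}

## resolve a drug key to the panel's exposure flag vector.
## keys: "DRUG", "CLASS:FIRST_GEN"/"CLASS:SECOND_GEN", or c(drug1, drug2)
## (pair exposure = months qualifying for both drugs).
exposure_flag <- function(panel, drug_key) {
  cols <- vapply(drug_key, function(k) {
    if (startsWith(k, "CLASS:")) paste0("exp_class_", sub("^CLASS:", "", k))
    else paste0("exp_", k)
  }, character(1))
  missing_cols <- setdiff(cols, names(panel))
  flag <- NULL
  for (cl in cols) {
    v <- if (cl %in% names(panel)) panel[[cl]] else rep(FALSE, nrow(panel))
    flag <- if (is.null(flag)) v else flag & v
  }
  flag
}

#' Tabulate a panel into a 2x2 patient-month table
#'
#' Cross-classifies the at-risk patient-months of an incident-censored panel
#' by exposure flag (for a drug, a treatment class `"CLASS:<name>"`, or a
#' drug pair) and event indicator. With weights, cells are sums of weights.
#'
#' @param panel an incident-censored `pm_panel` (see
#'   [apply_incident_censoring()]).
#' @param drug_key drug code, `"CLASS:FIRST_GEN"` / `"CLASS:SECOND_GEN"`, or
#'   a character vector of two drug codes (co-exposure).
#' @param weights optional numeric vector, one weight per panel row.
#' @return A [contingency_table()].
#' @export
tabulate_panel <- function(panel, drug_key, weights = NULL) {
  assert_that(nrow(panel) > 0L, "empty panel")
  assert_that("event" %in% names(panel),
              "panel is not incident-censored; call apply_incident_censoring()")
  w <- weights %||% rep(1, nrow(panel))
  assert_that(length(w) == nrow(panel), "weights length must match panel rows")
  ex <- exposure_flag(panel, drug_key)
  evv <- panel$event
  contingency_table(
    n11 = sum(w[ex & evv]),  n10 = sum(w[ex & !evv]),
    n01 = sum(w[!ex & evv]), n00 = sum(w[!ex & !evv])
  )
}

#' Incidence rate ratio from a panel
#'
#' Events per patient-month in exposed months divided by events per
#' patient-month in unexposed months; equals the PRR of the corresponding
#' (weighted) contingency table to numerical precision. `method = "glm"`
#' computes the same quantity as the exposure coefficient of a log-linear
#' Poisson rate model (with robust, participant-clustered standard errors
#' when weights are supplied, since weighted cells are not multinomial
#' counts).
#'
#' @inheritParams tabulate_panel
#' @param method `"direct"` (rate quotient, Woolf-type CI identical to
#'   [prr()]) or `"glm"` (log-linear model; robust CI under weighting).
#' @param ci_level confidence level.
#' @return A `measure_estimate` (measure `"IRR"`).
#' @export
irr_from_panel <- function(panel, drug_key, weights = NULL,
                           method = c("direct", "glm"), ci_level = 0.95) {
  method <- match.arg(method)
  tab <- tabulate_panel(panel, drug_key, weights)
  if (method == "direct") {
    est <- prr(tab, ci_level)
    est$measure <- "IRR"
    return(est)
  }
  bad <- .check_cells(tab, c("n11", "n01", "n1.", "n0."))
  if (!is.na(bad)) return(measure_estimate("IRR", NA, NA, ci_level, FALSE, bad))
  ex <- exposure_flag(panel, drug_key)
  y <- as.integer(panel$event)
  w <- weights %||% rep(1, nrow(panel))
  fit <- suppressWarnings(glm(y ~ ex, family = poisson(), weights = w,
                              control = glm.control(epsilon = 1e-14,
                                                    maxit = 100L)))
  b <- coef(fit)[["exTRUE"]]
  if (!is.finite(b)) {
    return(measure_estimate("IRR", NA, NA, ci_level, FALSE, "zero cell"))
  }
  if (is.null(weights)) {
    se <- sqrt(vcov(fit)["exTRUE", "exTRUE"])
  } else {
    V <- cluster_vcov(fit, panel$participant_id)
    se <- sqrt(V["exTRUE", "exTRUE"])
  }
  measure_estimate("IRR", exp(b), se, ci_level)
}
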