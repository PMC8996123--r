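## Bayesian shrinkage of the information component (BCPNN).
##
## Conjugate model in the Bate tradition: Beta(1,1) priors on the marginal
## exposure and event probabilities and a Dirichlet prior on the 2x2 cell
## probabilities whose components are proportional to the product of the
## posterior-mean marginals, scaled so that the joint prior count gamma11 = 1
## and the prior expectation of the information component IC =
## log2 P(drug,event)/(P(drug)P(event)) is zero. Point summaries use the
## standard moment approximation; tail quantities (credible bounds and the
## posterior null probability) come from seeded Monte Carlo sampling of the
## Dirichlet posterior, which is authoritative for the Level-3 gate.

#' BCPNN prior specification
#'
#' Hyperparameters of the conjugate shrinkage model. Defaults are the
#' standard "prior IC expectation zero" choice: `alpha1 = beta1 = 1`
#' (marginal Beta(1,1) priors, so `alpha = beta = 2`) and joint prior count
#' `gamma11 = 1`.
#' @param alpha1,beta1 marginal Beta prior counts for exposure / event.
#' @param gamma11 prior count on the joint (exposed, event) cell.
#' @return Named list of hyperparameters.
#' @export
bcpnn_prior <- function(alpha1 = 1, beta1 = 1, gamma11 = 1) {
  list(alpha1 = alpha1, alpha = 2 * alpha1, beta1 = beta1, beta = 2 * beta1,
       gamma11 = gamma11)
}

#' Posterior of the information component for one drug-event pair
#'
#' @param table a [contingency_table()]; weighted (real-valued) cells are
#'   accepted as effective counts (approximate; documented).
#' @param prior_spec from [bcpnn_prior()].
#' @param n_mc number of Monte-Carlo draws (default `1e5`).
#' @param seed integer seed for the Monte-Carlo draws (mandatory for
#'   reproducible pipelines).
#' @return An object of class `ic_posterior`: `ic_mean`, `ic_sd` (moment
#'   approximation, bits), `ic_q025`, `ic_q975` (Monte-Carlo credible
#'   bounds), `p_null` = Pr(IC <= 0 | data), and the Monte-Carlo mean
#'   `ic_mc_mean` for reference.
#' @export
#' @examples
#' ic_posterior(contingency_table(20, 80, 10, 190), seed = 1)
ic_posterior <- function(table, prior_spec = bcpnn_prior(), n_mc = 1e5,
                         seed = 1L) {
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  assert_that(all(cells >= 0), "negative cells")
  seed <- suppressWarnings(as.integer(seed))
  assert_that(length(seed) == 1L && !is.na(seed), "seed must be an integer")
  n11 <- table$n11; n1. <- table$`n1.`; n.1 <- table$`n.1`; N <- table$`n..`
  ps <- prior_spec
  ## posterior-mean marginals under Beta(alpha1, alpha - alpha1) priors
  q1 <- (n1. + ps$alpha1) / (N + ps$alpha)
  q2 <- (n.1 + ps$beta1) / (N + ps$beta)
  ## Dirichlet prior proportional to independence, scaled so gamma11 as given
  g11 <- ps$gamma11
  g10 <- g11 * (1 - q2) / q2
  g01 <- g11 * (1 - q1) / q1
  g00 <- g11 * (1 - q1) * (1 - q2) / (q1 * q2)
  gamma_tot <- g11 + g10 + g01 + g00          # = g11 / (q1 * q2)

  ## moment approximation (Bate-style closed form)
  ic_mean <- log2((n11 + g11) * (N + ps$alpha) * (N + ps$beta) /
                  ((N + gamma_tot) * (n1. + ps$alpha1) * (n.1 + ps$beta1)))
  ic_var <- (1 / log(2)^2) * (
    (N - n11 + gamma_tot - g11) / ((n11 + g11) * (1 + N + gamma_tot)) +
    (N - n1. + ps$alpha - ps$alpha1) / ((n1. + ps$alpha1) * (1 + N + ps$alpha)) +
    (N - n.1 + ps$beta - ps$beta1) / ((n.1 + ps$beta1) * (1 + N + ps$beta)))

  ## Monte Carlo from the Dirichlet posterior
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- rdirichlet_mat(as.integer(n_mc),
                          c(n11 + g11, table$n10 + g10,
                            table$n01 + g01, table$n00 + g00))
  p11 <- draws[, 1L]
  p1_ <- draws[, 1L] + draws[, 2L]
  p_1 <- draws[, 1L] + draws[, 3L]
  ic <- log2(p11 / (p1_ * p_1))
  qs <- quantile(ic, c(0.025, 0.975), names = FALSE, type = 7)

  out <- list(ic_mean = ic_mean, ic_sd = sqrt(ic_var),
              ic_q025 = qs[1L], ic_q975 = qs[2L],
              p_null = mean(ic <= 0), ic_mc_mean = mean(ic),
              n_mc = as.integer(n_mc), seed = as.integer(seed))
  class(out) <- "ic_posterior"
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.ic_posterior <- function(x, ...) {
  cat(sprintf("IC = %.3f bits (sd %.3f), 95%% CrI [%.3f, %.3f], Pr(IC<=0) = %.4f\n",
              x$ic_mean, x$ic_sd, x$ic_q025, x$ic_q975, x$p_null))
  invisible(x)
}

#' Per-signal and running FDR estimates for a list of posteriors
#'
#' Each signal's FDR statistic is its posterior null probability
#' `Pr(IC <= 0 | data)`; the ranked list's running FDR is the cumulative
#' mean of these probabilities after sorting ascending (the Bayesian FDR
#' construction). The Level-3 gate consumes the per-signal value.
#'
#' @param posteriors non-empty list of `ic_posterior` objects (or a numeric
#'   vector of null probabilities).
#' @return data.table with `p_null`, `fdr` (per-signal = `p_null`),
#'   `fdr_running` (cumulative mean in `p_null`-ascending order, reported in
#'   input order) and `rank`.
#' @export
#' @examples
#' fdr_for_list(c(0.01, 0.03, 0.2))
fdr_for_list <- function(posteriors) {
  if (is.list(posteriors)) {
    assert_that(length(posteriors) > 0L, "empty posterior list")
    p <- vapply(posteriors, function(x) x$p_null, numeric(1))
  } else {
    p <- as.numeric(posteriors)
    assert_that(length(p) > 0L, "empty posterior list")
  }
  ord <- order(p)
  running <- cumsum(p[ord]) / seq_along(p)
  out <- data.table(p_null = p, fdr = p, fdr_running = NA_real_,
                    rank = NA_integer_)
  out$fdr_running[ord] <- running
  out$rank[ord] <- seq_along(p)
  out[]
}
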