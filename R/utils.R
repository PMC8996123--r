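## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length of one analysis month, in days
#'
#' Analysis months are fixed 30-day bins counted from each participant's
#' enrolment date; calendar months are never used.
#' @keywords internal
DAYS_PER_MONTH <- 30L

## month bin index of a date relative to an enrolment date (bin 0 starts on
## the enrolment day; negative for retrospective history)
month_of <- function(date, enrolment) {
  as.integer(floor(as.numeric(as.Date(date) - as.Date(enrolment)) / DAYS_PER_MONTH))
}

## first calendar day of a month bin
anchor_of <- function(m, enrolment) as.Date(enrolment) + m * DAYS_PER_MONTH

stop_longsig <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_longsig(...)
  invisible(TRUE)
}

as_date_strict <- function(x, what = "date") {
  d <- tryCatch(as.Date(x), error = function(e) NULL)
  if (is.null(d) || anyNA(d[!is.na(x)])) {
    stop_longsig("unparseable %s value(s); ISO-8601 (YYYY-MM-DD) expected", what)
  }
  d
}

## Dirichlet sampler (n draws x length(alpha)); gamma construction
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n, ncol = k)
  g / rowSums(g)
}

## Cluster-robust (sandwich) covariance for a glm fit.
## bread = (X'WX)^-1 on the link scale, meat = sum over clusters of score
## outer products; the standard HC0-type estimator used for weighted
## Poisson/logistic rate models with repeated observations per participant.
cluster_vcov <- function(fit, cluster) {
  X <- model.matrix(fit)
  ## working residuals x working weights = score contributions per row
  r <- fit$residuals * fit$weights       # equals (y - mu) * prior weight adj.
  U <- X * r
  cluster <- as.character(cluster)
  Us <- rowsum(U, group = cluster, reorder = FALSE)
  bread <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  meat <- crossprod(Us)
  V <- bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

## standardized mean difference of x between two groups under weights w
smd_pair <- function(x, g, w, a, b) {
  ia <- g == a; ib <- g == b
  if (!any(ia) || !any(ib)) return(NA_real_)
  wa <- w[ia]; wb <- w[ib]
  ma <- sum(wa * x[ia]) / sum(wa)
  mb <- sum(wb * x[ib]) / sum(wb)
  va <- sum(wa * (x[ia] - ma)^2) / sum(wa)
  vb <- sum(wb * (x[ib] - mb)^2) / sum(wb)
  s <- sqrt((va + vb) / 2)
  if (s < .Machine$double.eps) return(0)
  (ma - mb) / s
}
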