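## Small multinomial-logit fitter (three treatment classes; reference class
## NONE). Fit by BFGS on the multinomial log-likelihood with analytic
## gradient; the design dimension is small (a handful of covariates plus
## previous-class dummies), so this is robust and fast and avoids an
## external dependency.

softmax_probs <- function(X, B) {
  ## B: p x (K-1) coefficients for classes 2..K vs class 1
  eta <- cbind(0, X %*% B)
  eta <- eta - apply(eta, 1L, max)
  ex <- exp(eta)
  ex / rowSums(ex)
}

fit_multinom <- function(X, y, weights = NULL, levels_ = NULL,
                         maxit = 50L) {
  levels_ <- levels_ %||% levels(factor(y))
  y <- factor(y, levels = levels_)
  seen <- table(y) > 0
  if (!all(seen)) {
    stop_longsig("treatment class(es) never observed: %s",
                 paste(levels_[!seen], collapse = ", "))
  }
  K <- length(levels_)
  p <- ncol(X)
  w <- weights %||% rep(1, nrow(X))
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_len(nrow(X)), as.integer(y))] <- 1

  nll <- function(B) {
    P <- softmax_probs(X, B)
    -sum(w * log(pmax(P[cbind(seq_len(nrow(X)), as.integer(y))], 1e-300)))
  }
  ## Newton-Raphson on the joint (K-1)*p coefficient vector; the Hessian is
  ## assembled from its p x p blocks H[j,k] = X' diag(w P_j (1{j=k} - P_k)) X
  B <- matrix(0, p, K - 1L)
  val <- nll(B)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    P <- softmax_probs(X, B)
    G <- crossprod(X, w * (P[, -1L, drop = FALSE] - Y[, -1L, drop = FALSE]))
    H <- matrix(0, p * (K - 1L), p * (K - 1L))
    for (j in seq_len(K - 1L)) {
      for (k in j:(K - 1L)) {
        wj <- w * P[, j + 1L] * ((j == k) - P[, k + 1L])
        blk <- crossprod(X * wj, X)
        rj <- (j - 1L) * p + seq_len(p); rk <- (k - 1L) * p + seq_len(p)
        H[rj, rk] <- blk
        if (j != k) H[rk, rj] <- blk
      }
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      Bn <- B - sc * matrix(step, p, K - 1L)
      vn <- nll(Bn)
      if (vn <= val + 1e-10 || sc < 1e-4) break
      sc <- sc / 2
    }
    moved <- max(abs(Bn - B))
    B <- Bn; val <- vn
    if (moved < 1e-9 || max(abs(G)) < 1e-8 * max(1, sum(w))) {
      converged <- TRUE
      break
    }
  }
  dimnames(B) <- list(colnames(X), levels_[-1L])
  if (max(abs(B)) > 15) {
    bad <- rownames(B)[which(abs(B) > 15, arr.ind = TRUE)[, 1L]]
    warning(sprintf("possible separation in treatment model (covariate(s): %s)",
                    paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  structure(list(coefficients = B, levels = levels_, converged = converged,
                 value = val, n = nrow(X)),
            class = "longsig_multinom")
}

#' @export
predict.longsig_multinom <- function(object, X, ...) {
  P <- softmax_probs(X, object$coefficients)
  colnames(P) <- object$levels
  P
}

#' @export
print.longsig_multinom <- function(x, ...) {
  cat("multinomial logit (reference:", x$levels[1L], "), n =", x$n, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
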