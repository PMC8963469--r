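#' @include utils.R
NULL

# NIPALS partial-least-squares regression with a single response.
# Predictors are autoscaled (centered, unit variance) so heterogeneous
# predictor sets (vegetation indices) contribute comparably and the
# weights are comparable across predictors; the response is centered.
# Returns weights W (p x A, scaled space), loadings P, Q, and regression
# coefficients for prediction.
plsrCore <- function(x, y, ncomp) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  ncomp <- min(ncomp, n - 1L, p)
  xm <- colMeans(x); ym <- mean(y)
  xs <- apply(x, 2L, stats::sd); xs[xs < 1e-12] <- 1
  E <- sweep(sweep(x, 2L, xm), 2L, xs, "/"); f <- y - ym
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    pv <- crossprod(E, t) / tt
    q <- sum(f * t) / tt
    E <- E - t %*% t(pv)
    f <- f - q * t
    W[, a] <- w; P[, a] <- pv; Q[a] <- q
  }
  if (ncomp < 1L) stop("PLSR: response orthogonal to predictors")
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  # B = W (P'W)^-1 Q
  B <- W %*% solve(crossprod(P, W), Q)
  list(ncomp = ncomp, xMean = xm, xScale = xs, yMean = ym, weights = W,
       loadings = P, yLoadings = Q, coef = as.numeric(B))
}

plsrPredict <- function(fit, newx) {
  E <- sweep(sweep(as.matrix(newx), 2L, fit$xMean), 2L, fit$xScale, "/")
  drop(E %*% fit$coef) + fit$yMean
}

# Tune the component count by k-fold cross-validated RMSE over 1..maxComp.
plsrTuneNcomp <- function(x, y, maxComp = 15L, k = 5L, seed = 1L) {
  n <- nrow(x)
  maxComp <- min(maxComp, n - ceiling(n / k) - 1L, ncol(x))
  folds <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  press <- numeric(maxComp)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- plsrCore(x[tr, , drop = FALSE], y[tr], maxComp)
    E <- sweep(sweep(x[!tr, , drop = FALSE], 2L, fit$xMean), 2L,
               fit$xScale, "/")
    # accumulate scores component by component to score every ncomp at once
    Tn <- E %*% fit$weights %*% solve(crossprod(fit$loadings, fit$weights))
    for (a in seq_len(fit$ncomp)) {
      pred <- fit$yMean +
        drop(Tn[, seq_len(a), drop = FALSE] %*% fit$yLoadings[seq_len(a)])
      press[a] <- press[a] + sum((y[!tr] - pred)^2)
    }
    if (fit$ncomp < maxComp)
      press[(fit$ncomp + 1L):maxComp] <- Inf
  }
  which.min(press[seq_len(maxComp)])
}
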