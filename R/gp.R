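#' @include utils.R
NULL

# Exact Gaussian-process regression with marginal-likelihood hyperparameter
# tuning. Inputs are standardized per column and the response centered and
# scaled internally. Kernels operate on the scaled distance
# r_ij = sqrt(sum_k ((x_ik - x_jk)/l_k)^2) with a single length scale
# (isotropic) or one per dimension (ARD).

gpKernels <- c("squared_exponential", "exponential", "matern52",
               "rational_quadratic")

# squared cross-distances per dimension are precomputed once; kernel values
# from r2 = sum_k d2_k / l_k^2
gpKernelValue <- function(kernel, r2, alpha = 2) {
  r <- sqrt(pmax(r2, 0))
  switch(kernel,
    squared_exponential = exp(-r2 / 2),
    exponential = exp(-r),
    matern52 = { s <- sqrt(5) * r; (1 + s + 5 * r2 / 3) * exp(-s) },
    rational_quadratic = (1 + r2 / (2 * alpha))^(-alpha),
    stop("unknown GP kernel: ", kernel))
}

# per-dimension squared-difference arrays between row sets
gpSqDiff <- function(x1, x2) {
  p <- ncol(x1)
  lapply(seq_len(p), function(k) outer(x1[, k], x2[, k], "-")^2)
}

gpScaledR2 <- function(d2, ell) {
  r2 <- 0
  if (length(ell) == 1L) {
    for (k in seq_along(d2)) r2 <- r2 + d2[[k]]
    r2 / ell^2
  } else {
    for (k in seq_along(d2)) r2 <- r2 + d2[[k]] / ell[k]^2
    r2
  }
}

gpNll <- function(theta, d2, y, kernel, ard, p) {
  nl <- if (ard) p else 1L
  ell <- exp(theta[seq_len(nl)])
  sf2 <- exp(2 * theta[nl + 1L]); sn2 <- exp(2 * theta[nl + 2L])
  alpha <- if (kernel == "rational_quadratic") exp(theta[nl + 3L]) else 2
  n <- length(y)
  K <- sf2 * gpKernelValue(kernel, gpScaledR2(d2, ell), alpha)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  a <- backsolve(ch, forwardsolve(t(ch), y))
  0.5 * sum(y * a) + sum(log(diag(ch))) + n / 2 * log(2 * pi)
}

# analytic gradient (squared-exponential only; other kernels use optim's
# finite differences over their <= 4 parameters)
gpNllGradSE <- function(theta, d2, y, kernel, ard, p) {
  nl <- if (ard) p else 1L
  ell <- exp(theta[seq_len(nl)])
  sf2 <- exp(2 * theta[nl + 1L]); sn2 <- exp(2 * theta[nl + 2L])
  n <- length(y)
  r2 <- gpScaledR2(d2, ell)
  Kf <- sf2 * exp(-r2 / 2)
  K <- Kf; diag(K) <- diag(K) + sn2 + 1e-8
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  Kinv <- chol2inv(ch)
  a <- Kinv %*% y
  A <- tcrossprod(a) - Kinv         # d(-logL)/dtheta = -0.5 tr(A dK/dtheta)
  g <- numeric(length(theta))
  if (ard) {
    for (k in seq_len(p)) {
      dK <- Kf * (d2[[k]] / ell[k]^2)
      g[k] <- -0.5 * sum(A * dK)
    }
  } else {
    dK <- Kf * r2
    g[1L] <- -0.5 * sum(A * dK)
  }
  g[nl + 1L] <- -0.5 * sum(A * (2 * Kf))
  g[nl + 2L] <- -0.5 * sum(diag(A)) * 2 * sn2
  g
}

#' Fit a Gaussian-process regression
#'
#' Exact GP regression with zero prior mean on standardized inputs and a
#' centered, scaled response. Hyperparameters (length scale(s), signal and
#' noise standard deviations, and the rational-quadratic shape) are tuned
#' by maximizing the log marginal likelihood. With `ard = TRUE` the kernel
#' carries one length scale per predictor (automatic relevance
#' determination); large fitted scales mark weak predictors.
#'
#' @param x numeric predictor matrix.
#' @param y numeric response.
#' @param kernel one of "squared_exponential", "exponential", "matern52",
#'   "rational_quadratic".
#' @param ard logical, per-dimension length scales (squared-exponential
#'   kernel only).
#' @param maxit optimizer iteration budget.
#' @param fixed optional list (`lengthScales`, `signalVar`, `noiseVar`,
#'   `alpha`) of frozen hyperparameters (standardized-input units); when
#'   given, no marginal-likelihood optimization is run (the cumulative
#'   retraining strategy refits with the architecture kept).
#' @return a "gpFit" list: hyperparameters, Cholesky solves and the
#'   training standardization.
#' @export
gpFit <- function(x, y, kernel = "squared_exponential", ard = FALSE,
                  maxit = 100L, fixed = NULL) {
  kernel <- match.arg(kernel, gpKernels)
  if (ard && kernel != "squared_exponential")
    stop("ARD length scales are implemented for the squared-exponential kernel")
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xc <- colMeans(x)
  xs <- apply(x, 2L, stats::sd); xs[xs < 1e-12] <- 1
  xstd <- sweep(sweep(x, 2L, xc), 2L, xs, "/")
  ym <- mean(y); ys <- stats::sd(y); if (!is.finite(ys) || ys < 1e-12) ys <- 1
  ystd <- (y - ym) / ys
  d2 <- gpSqDiff(xstd, xstd)
  nl <- if (ard) p else 1L
  if (!is.null(fixed)) {
    ell <- fixed$lengthScales; sf2 <- fixed$signalVar
    sn2 <- fixed$noiseVar; alpha <- fixed$alpha %||% 2
    K <- sf2 * gpKernelValue(kernel, gpScaledR2(d2, ell), alpha)
    diag(K) <- diag(K) + sn2 + 1e-8
    ch <- chol(K)
    a <- backsolve(ch, forwardsolve(t(ch), ystd))
    return(structure(list(kernel = kernel, ard = ard, lengthScales = ell,
                          signalVar = sf2, noiseVar = sn2, alpha = alpha,
                          xTrain = xstd, chol = ch, alphaVec = a,
                          xCenter = xc, xScale = xs, yMean = ym, yScale = ys,
                          nll = NA_real_),
                     class = "gpFit"))
  }
  theta0 <- c(rep(log(sqrt(p)), nl), log(1), log(0.3))
  if (kernel == "rational_quadratic") theta0 <- c(theta0, log(2))
  if (kernel == "squared_exponential") {
    # L-BFGS-B evaluates fn and gr at the same point: share one Cholesky
    # factorization between them through a small cache
    cache <- new.env(parent = emptyenv())
    prep <- function(th) {
      if (identical(cache$th, th)) return(TRUE)
      nl2 <- if (ard) p else 1L
      ell <- exp(th[seq_len(nl2)])
      sf2 <- exp(2 * th[nl2 + 1L]); sn2 <- exp(2 * th[nl2 + 2L])
      r2 <- gpScaledR2(d2, ell)
      Kf <- sf2 * exp(-r2 / 2)
      K <- Kf; diag(K) <- diag(K) + sn2 + 1e-8
      ch <- tryCatch(chol(K), error = function(e) NULL)
      cache$th <- th; cache$ell <- ell; cache$sf2 <- sf2; cache$sn2 <- sn2
      cache$r2 <- r2; cache$Kf <- Kf; cache$ch <- ch
      !is.null(ch)
    }
    fn <- function(th) {
      if (!prep(th)) return(1e10)
      a <- backsolve(cache$ch, forwardsolve(t(cache$ch), ystd))
      0.5 * sum(ystd * a) + sum(log(diag(cache$ch))) +
        length(ystd) / 2 * log(2 * pi)
    }
    grf <- function(th) {
      if (!prep(th)) return(rep(0, length(th)))
      Kinv <- chol2inv(cache$ch)
      a <- Kinv %*% ystd
      A <- tcrossprod(a) - Kinv
      g <- numeric(length(th))
      nl2 <- if (ard) p else 1L
      if (ard) {
        for (k in seq_len(p))
          g[k] <- -0.5 * sum(A * (cache$Kf * (d2[[k]] / cache$ell[k]^2)))
      } else {
        g[1L] <- -0.5 * sum(A * (cache$Kf * cache$r2))
      }
      g[nl2 + 1L] <- -0.5 * sum(A * (2 * cache$Kf))
      g[nl2 + 2L] <- -0.5 * sum(diag(A)) * 2 * cache$sn2
      g
    }
  } else {
    fn <- function(th) gpNll(th, d2, ystd, kernel, ard, p)
    grf <- NULL
  }
  opt <- stats::optim(theta0, fn, gr = grf,
                      method = "L-BFGS-B",
                      lower = c(rep(-4, nl), -4, -6,
                                if (kernel == "rational_quadratic") -3),
                      upper = c(rep(8, nl), 4, 2,
                                if (kernel == "rational_quadratic") 4),
                      control = list(maxit = maxit))
  th <- opt$par
  ell <- exp(th[seq_len(nl)])
  sf2 <- exp(2 * th[nl + 1L]); sn2 <- exp(2 * th[nl + 2L])
  alpha <- if (kernel == "rational_quadratic") exp(th[nl + 3L]) else 2
  K <- sf2 * gpKernelValue(kernel, gpScaledR2(d2, ell), alpha)
  diag(K) <- diag(K) + sn2 + 1e-8
  ch <- chol(K)
  a <- backsolve(ch, forwardsolve(t(ch), ystd))
  structure(list(kernel = kernel, ard = ard, lengthScales = ell,
                 signalVar = sf2, noiseVar = sn2, alpha = alpha,
                 xTrain = xstd, chol = ch, alphaVec = a,
                 xCenter = xc, xScale = xs, yMean = ym, yScale = ys,
                 nll = opt$value),
            class = "gpFit")
}

#' Predict from a Gaussian-process fit
#'
#' @param fit a "gpFit" object from [gpFit()].
#' @param newx numeric matrix of query points.
#' @param se logical, also return the predictive standard deviation
#'   (of the response, i.e. including the noise variance).
#' @return numeric predictions, or `list(mean, sd)` when `se = TRUE`.
#' @export
gpPredict <- function(fit, newx, se = FALSE) {
  newx <- as.matrix(newx)
  xstd <- sweep(sweep(newx, 2L, fit$xCenter), 2L, fit$xScale, "/")
  d2 <- gpSqDiff(xstd, fit$xTrain)
  Ks <- fit$signalVar *
    gpKernelValue(fit$kernel, gpScaledR2(d2, fit$lengthScales), fit$alpha)
  mu <- fit$yMean + fit$yScale * drop(Ks %*% fit$alphaVec)
  if (!se) return(mu)
  v <- forwardsolve(t(fit$chol), t(Ks))
  varf <- pmax(fit$signalVar - colSums(v^2), 0)
  list(mean = mu, sd = fit$yScale * sqrt(varf + fit$noiseVar))
}
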