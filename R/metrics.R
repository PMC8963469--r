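#' @include utils.R
NULL

#' Coefficient of determination
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), the conventional
#' mean-based denominator. Undefined for constant observations.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return numeric R2 (can be negative for out-of-sample predictions worse
#'   than the mean).
#' @export
r2Score <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst < .Machine$double.eps)
    stop("R2 undefined: constant observations")
  1 - sum((y - yhat)^2) / sst
}

#' Root-mean-square error (SPAD units)
#' @inheritParams r2Score
#' @export
rmseScore <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Mean absolute error (SPAD units)
#' @inheritParams r2Score
#' @export
maeScore <- function(y, yhat) mean(abs(y - yhat))

# one metrics row
metricsRow <- function(y, yhat, scope, strategy = NA_character_,
                       model = NA_character_, predictorSet = NA_character_) {
  data.frame(model = model, predictorSet = predictorSet, strategy = strategy,
             scope = scope, n = length(y),
             r2 = if (stats::var(y) > 0) r2Score(y, yhat) else NA_real_,
             rmse = rmseScore(y, yhat), mae = maeScore(y, yhat),
             stringsAsFactors = FALSE)
}
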