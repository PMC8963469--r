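#' @include models.R dataset.R metrics.R
NULL

#' Cross-validated goodness of fit
#'
#' k-fold cross-validation on the training set: tunable hyperparameters are
#' tuned once on the full training data, each fold refits with them frozen,
#' and the pooled out-of-fold predictions are scored with the conventional
#' mean-denominator R2.
#'
#' @param cfg a roster configuration ([rosterConfigs()]).
#' @param train a [SpadDataset].
#' @param k integer fold count (default 5).
#' @param seed integer RNG seed.
#' @return numeric cross-validated R2.
#' @export
crossValidateR2 <- function(cfg, train, k = 5L, seed = 1L) {
  stopifnot(is(train, "SpadDataset"))
  n <- length(train@y)
  if (n < k) stop("fewer samples than folds")
  if (stats::var(train@y) < .Machine$double.eps)
    stop("R2 undefined: constant response")
  full <- fitModel(cfg, train@x, train@y, seed = seed)
  hyper <- tunedHyper(full)
  folds <- withSeed(seed, sample(rep_len(seq_len(k), n)))
  pred <- numeric(n)
  for (fold in seq_len(k)) {
    tr <- folds != fold
    m <- fitModel(cfg, train@x[tr, , drop = FALSE], train@y[tr],
                  seed = seed + fold, hyper = hyper)
    pred[!tr] <- predictSpad(m, train@x[!tr, , drop = FALSE])
  }
  r2Score(train@y, pred)
}

#' Fit one model under the sequential strategy
#'
#' One model on all campaigns pooled: the entire ground-truth sequence
#' trains a single model that serves every campaign's predictions.
#'
#' @param cfg a roster configuration.
#' @param train a [SpadDataset] (any number of campaigns).
#' @param seed integer RNG seed.
#' @return a fitted [SpadModel].
#' @export
fitSequential <- function(cfg, train, seed = 1L) {
  stopifnot(is(train, "SpadDataset"))
  m <- fitModel(cfg, train@x, train@y, seed = seed)
  m@predictorSet <- train@predictorSet
  m
}

#' Fit one model under the cumulative retraining strategy
#'
#' Models are re-fitted as new campaigns arrive, on training sets that
#' reflect the most recent status of the plants: campaign 1 alone, then
#' the current and previous campaign together (t1; t1+t2; t2+t3; t3+t4;
#' t4+t5). Campaign i is predicted by model i. Tunable hyperparameters are
#' tuned on the first campaign and frozen afterwards (the fitted
#' architecture is kept while the training data moves); `retune = TRUE`
#' re-tunes at every step for ablation.
#'
#' @param cfg a roster configuration.
#' @param train a [SpadDataset] whose `campaignLevels` give the temporal
#'   order.
#' @param seed integer RNG seed.
#' @param retune logical, re-tune hyperparameters at every prefix.
#' @return list of fitted [SpadModel]s, one per campaign prefix, named by
#'   campaign label.
#' @export
fitRetraining <- function(cfg, train, seed = 1L, retune = FALSE) {
  stopifnot(is(train, "SpadDataset"))
  levels <- train@campaignLevels
  present <- unique(train@campaign)
  if (!all(levels %in% present))
    stop("missing campaign(s) in the training sequence: ",
         paste(setdiff(levels, present), collapse = ", "))
  hyper <- NULL
  models <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    window <- levels[max(1L, i - 1L):i]
    idx <- train@campaign %in% window
    m <- fitModel(cfg, train@x[idx, , drop = FALSE], train@y[idx],
                  seed = seed, hyper = if (retune) NULL else hyper)
    if (i == 1L && !retune) hyper <- tunedHyper(m)
    m@predictorSet <- train@predictorSet
    models[[i]] <- m
  }
  names(models) <- levels
  models
}

#' Validation metrics of a fitted model
#'
#' RMSE and MAE (and R2 where defined) on a validation set, overall and
#' per campaign.
#'
#' @param model a [SpadModel] (sequential) or list of [SpadModel]s
#'   (retraining; campaign i is predicted by prefix-model i).
#' @param validation a [SpadDataset].
#' @param strategy character tag recorded in the output.
#' @return data.frame of metrics rows (scope "overall" plus one per
#'   campaign).
#' @export
evaluateModel <- function(model, validation, strategy = "sequential") {
  stopifnot(is(validation, "SpadDataset"), length(validation@y) > 0L)
  if (is(model, "SpadModel")) {
    pred <- predictSpad(model, validation@x)
    id <- paste(model@config$family, model@config$variant, sep = "_")
    ps <- model@predictorSet
  } else {
    stopifnot(is.list(model), length(model) == length(validation@campaignLevels))
    pred <- numeric(length(validation@y))
    for (i in seq_along(validation@campaignLevels)) {
      idx <- validation@campaign == validation@campaignLevels[i]
      if (any(idx))
        pred[idx] <- predictSpad(model[[i]], validation@x[idx, , drop = FALSE])
    }
    id <- paste(model[[1L]]@config$family, model[[1L]]@config$variant,
                sep = "_")
    ps <- model[[1L]]@predictorSet
  }
  rows <- list(metricsRow(validation@y, pred, "overall", strategy, id, ps))
  for (cp in validation@campaignLevels) {
    idx <- validation@campaign == cp
    if (any(idx))
      rows <- c(rows, list(metricsRow(validation@y[idx], pred[idx], cp,
                                      strategy, id, ps)))
  }
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- pred
  out
}

#' Accuracy-threshold model selection
#'
#' Keeps the configurations whose overall validation RMSE and MAE are both
#' at or below the error threshold (default 5 SPAD units, the combined
#' meter accuracy and environmental-bias budget of a SPAD reading).
#'
#' @param records data.frame of metrics rows (scope "overall"; one row per
#'   model).
#' @param threshold numeric SPAD-unit threshold applied to both RMSE and
#'   MAE.
#' @return list with `selected` and `excluded` data.frames.
#' @export
selectModels <- function(records, threshold = 5) {
  if (!nrow(records))
    return(list(selected = records, excluded = records))
  keep <- records$rmse <= threshold & records$mae <= threshold
  list(selected = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}
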