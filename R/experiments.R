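#' @include strategies.R importance.R
NULL

#' Paired sequential-versus-retraining simulation experiment
#'
#' For each seed, simulates the five-campaign study (with or without
#' campaign drift), fits one model configuration under both learning
#' strategies and records the per-campaign validation RMSE of each. Under
#' drift the retraining strategy should win on the later campaigns; the
#' drift-off runs are the stationarity control.
#'
#' @param nSeeds integer number of simulation replicates.
#' @param drift logical, simulate with campaign drift.
#' @param cfg model configuration (default PLSR, the fastest roster member
#'   that exhibits both the drift effect and a clean stationary control).
#' @param predictorSet predictor set tag.
#' @param baseSeed integer offset added to every replicate seed.
#' @return data.frame with seed, campaign index, `rmseSequential`,
#'   `rmseRetraining`.
#' @export
strategyExperiment <- function(nSeeds = 20L, drift = TRUE,
                               cfg = rosterConfigs()$plsr_plsr,
                               predictorSet = "vis", baseSeed = 0L) {
  rows <- list()
  for (s in seq_len(nSeeds)) {
    seed <- baseSeed + s
    tab <- suppressWarnings(
      simulateSampleTable(defaultCampaigns(drift = drift), seed = seed))
    ds <- suppressWarnings(makeDataset(tab, predictorSet))
    sp <- splitDataset(ds, seed = seed + 1000L)
    mS <- fitSequential(cfg, sp$train, seed = seed)
    mR <- fitRetraining(cfg, sp$train, seed = seed)
    eS <- evaluateModel(mS, sp$validation, "sequential")
    eR <- evaluateModel(mR, sp$validation, "retraining")
    perS <- eS$rmse[eS$scope != "overall"]
    perR <- eR$rmse[eR$scope != "overall"]
    rows[[s]] <- data.frame(seed = seed, campaign = seq_along(perS),
                            rmseSequential = perS, rmseRetraining = perR)
  }
  do.call(rbind, rows)
}

#' Planted-signal consensus recovery experiment
#'
#' For each seed, draws n standardized noise predictors of which only the
#' first carries signal, runs the three-method importance analysis (PLSR
#' weights, random-forest importance, ARD-GPR weakness, each thresholded
#' by the quartile rule) and records whether the planted predictor reaches
#' consensus count 3.
#'
#' @param nSeeds integer replicates.
#' @param n,p sample size and predictor count.
#' @param baseSeed integer offset added to every replicate seed.
#' @return logical vector, one entry per seed: planted predictor flagged
#'   by all three methods.
#' @export
plantedSignalExperiment <- function(nSeeds = 50L, n = 500L, p = 20L,
                                    baseSeed = 0L) {
  vapply(seq_len(nSeeds), function(s) {
    seed <- baseSeed + s
    set.seed(seed)
    x <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- 3 * x[, 1L] + stats::rnorm(n, 0, 0.5)
    ds <- new("SpadDataset", x = x, y = y, campaign = rep("t", n),
              campaignLevels = "t", predictorSet = "vis")
    out <- importanceAnalysis(ds, seed = seed)
    out$table$nMethods[out$table$predictor == "x1"] == 3L
  }, logical(1))
}
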