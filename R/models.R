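#' @include AllClasses.R AllGenerics.R plsr.R gp.R metrics.R dataset.R
NULL

#' The 17-model regression roster
#'
#' Three categories of non-parametric regressors, seventeen configurations:
#' multivariate linear; PLSR; fine/medium/coarse decision trees; boosted
#' and bagged (random forest) ensembles of 60 medium trees; support-vector
#' regression with linear, quadratic, cubic and fine/medium/coarse Gaussian
#' kernels; Gaussian-process regression with exponential,
#' squared-exponential, Matern-5/2 and rational-quadratic kernels.
#'
#' @return named list of 17 model configurations (family, variant,
#'   hyperparams).
#' @examples
#' length(rosterConfigs())  # 17
#' @export
rosterConfigs <- function() {
  cfg <- function(family, variant, hyperparams = list())
    list(family = family, variant = variant, hyperparams = hyperparams)
  out <- list(
    cfg("linear", "ols"),
    cfg("plsr", "plsr", list(maxComp = 15L)),
    cfg("tree", "fine", list(minbucket = 4L)),
    cfg("tree", "medium", list(minbucket = 12L)),
    cfg("tree", "coarse", list(minbucket = 36L)),
    cfg("ensemble", "boosted", list(ntrees = 60L, minbucket = 12L)),
    cfg("ensemble", "bagged_rf", list(ntrees = 60L, minbucket = 12L)),
    cfg("svr", "linear"),
    cfg("svr", "quadratic"),
    cfg("svr", "cubic"),
    cfg("svr", "fine_gaussian"),
    cfg("svr", "medium_gaussian"),
    cfg("svr", "coarse_gaussian"),
    cfg("gpr", "exponential"),
    cfg("gpr", "squared_exponential"),
    cfg("gpr", "matern52"),
    cfg("gpr", "rational_quadratic")
  )
  names(out) <- vapply(out, function(cc) paste(cc$family, cc$variant, sep = "_"),
                       character(1))
  out
}

svrGamma <- function(variant, p) {
  # kernel scale sigma = sqrt(p)/4 (fine), sqrt(p) (medium), 4 sqrt(p)
  # (coarse); gamma = 1 / sigma^2
  switch(variant, fine_gaussian = 16 / p, medium_gaussian = 1 / p,
         coarse_gaussian = 1 / (16 * p))
}

# Fit one roster configuration. `hyper` freezes tuned hyperparameters
# (retraining strategy); when NULL tunable families tune here.
fitModel <- function(cfg, x, y, seed = 1L, hyper = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  hp <- utils::modifyList(cfg$hyperparams, if (is.null(hyper)) list() else hyper)
  fit <- withSeed(seed, switch(cfg$family,
    linear = {
      df <- data.frame(y = y, x, check.names = FALSE)
      stats::lm(y ~ ., data = df)
    },
    plsr = {
      if (is.null(hp$ncomp))
        hp$ncomp <- plsrTuneNcomp(x, y, maxComp = hp$maxComp %||% 15L,
                                  seed = seed)
      plsrCore(x, y, hp$ncomp)
    },
    tree = rpart::rpart(y ~ ., data = data.frame(y = y, x, check.names = FALSE),
                        control = rpart::rpart.control(
                          minbucket = hp$minbucket, minsplit = 2L * hp$minbucket,
                          cp = 1e-4, xval = 0L)),
    ensemble = {
      if (cfg$variant == "bagged_rf")
        randomForest::randomForest(x, y, ntree = hp$ntrees,
                                   nodesize = hp$minbucket,
                                   importance = TRUE)
      else
        xgboost::xgboost(x = x, y = y, nrounds = hp$ntrees,
                         max_depth = 6L, learning_rate = 0.1,
                         min_child_weight = hp$minbucket,
                         nthread = 1L)
    },
    svr = {
      kern <- switch(cfg$variant,
        linear = list(kernel = "linear"),
        quadratic = list(kernel = "polynomial", degree = 2L),
        cubic = list(kernel = "polynomial", degree = 3L),
        list(kernel = "radial", gamma = svrGamma(cfg$variant, ncol(x))))
      do.call(e1071::svm, c(list(x = x, y = y, type = "eps-regression",
                                 cost = 1, epsilon = 0.1, scale = TRUE), kern))
    },
    gpr = gpFit(x, y, kernel = cfg$variant,
                maxit = hp$maxit %||% 100L, fixed = hp$fixed),
    stop("unknown model family: ", cfg$family)))
  if (cfg$family == "plsr") cfg$hyperparams$ncomp <- fit$ncomp
  new("SpadModel", config = cfg, fit = fit, predictorSet = "unset",
      predictorNames = colnames(x), seed = as.integer(seed), scaling = list())
}

# tuned hyperparameters worth freezing for retraining
tunedHyper <- function(model) {
  switch(model@config$family,
    plsr = list(ncomp = model@config$hyperparams$ncomp),
    gpr = list(fixed = list(lengthScales = model@fit$lengthScales,
                            signalVar = model@fit$signalVar,
                            noiseVar = model@fit$noiseVar,
                            alpha = model@fit$alpha)),
    list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn SpadModel predict SPAD for new predictor rows
#' @export
setMethod("predictSpad", "SpadModel", function(object, newx, se = FALSE) {
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object@predictorNames))
    stop(sprintf(
      "predictor mismatch: model expects %d columns (%s ...), got %d",
      length(object@predictorNames), object@predictorNames[1L], ncol(newx)))
  colnames(newx) <- object@predictorNames
  fam <- object@config$family
  if (se && fam != "gpr")
    stop("predictive uncertainty is only available for GPR models")
  switch(fam,
    linear = {
      df <- data.frame(newx, check.names = FALSE)
      suppressWarnings(unname(stats::predict(object@fit, newdata = df)))
    },
    plsr = plsrPredict(object@fit, newx),
    tree = unname(stats::predict(object@fit,
      newdata = data.frame(newx, check.names = FALSE))),
    ensemble = {
      if (object@config$variant == "bagged_rf")
        unname(stats::predict(object@fit, newx))
      else
        stats::predict(object@fit, newx)
    },
    svr = unname(stats::predict(object@fit, newx)),
    gpr = {
      out <- gpPredict(object@fit, newx, se = se)
      if (se) out else out
    })
})
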