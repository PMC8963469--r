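#' @include models.R
NULL

#' PLSR predictor weights
#'
#' Per-component weight vectors of a fitted PLSR model (how strongly each
#' component depends on the original predictors) plus the aggregate
#' relevance per predictor, defined as the maximum absolute weight across
#' the retained components ("relevant in any component").
#'
#' @param model a [SpadModel] with family "plsr", or a raw NIPALS fit.
#' @param nComponents optional integer, use only the first components.
#' @return list with `weights` (p x A matrix) and `aggregate` (named
#'   numeric per predictor).
#' @export
plsrWeights <- function(model, nComponents = NULL) {
  fit <- if (is(model, "SpadModel")) {
    if (model@config$family != "plsr")
      stop("plsrWeights requires a PLSR model")
    model@fit
  } else model
  if (is.null(fit$weights)) stop("unfitted PLSR model")
  W <- fit$weights
  if (!is.null(nComponents)) {
    if (nComponents > ncol(W))
      stop(sprintf("model has %d components, %d requested", ncol(W),
                   nComponents))
    W <- W[, seq_len(nComponents), drop = FALSE]
  }
  agg <- apply(abs(W), 1L, max)
  if (is(model, "SpadModel")) names(agg) <- model@predictorNames
  list(weights = W, aggregate = agg)
}

#' Random-forest predictor importance
#'
#' Impurity-decrease importances of a bagged tree ensemble, normalized to
#' sum to one.
#'
#' @param model a [SpadModel] with family "ensemble", variant "bagged_rf",
#'   or a randomForest fit.
#' @return named numeric importances summing to 1.
#' @export
rfImportance <- function(model) {
  fit <- if (is(model, "SpadModel")) {
    if (model@config$family != "ensemble" ||
        model@config$variant != "bagged_rf")
      stop("rfImportance requires a bagged random-forest model")
    model@fit
  } else model
  imp <- tryCatch(randomForest::importance(fit, type = 2L),
                  error = function(e) stop("unfitted random forest"))
  v <- pmax(imp[, 1L], 0)
  if (sum(v) <= 0) v <- rep(1, length(v))
  out <- v / sum(v)
  if (is(model, "SpadModel")) names(out) <- model@predictorNames
  out
}

#' Fit an ARD Gaussian process for feature relevance
#'
#' Squared-exponential kernel with one length scale per predictor
#' (automatic relevance determination), tuned by marginal likelihood.
#' Inputs are standardized so the fitted length scales are comparable
#' across predictors.
#'
#' @param x numeric predictor matrix.
#' @param y numeric response.
#' @param maxit optimizer iteration budget.
#' @return a "gpFit" object with `ard = TRUE`.
#' @export
fitGprArd <- function(x, y, maxit = 40L) {
  gpFit(x, y, kernel = "squared_exponential", ard = TRUE, maxit = maxit)
}

#' GPR weakness index
#'
#' The fitted ARD length scale per predictor: the larger the scale, the
#' weaker the predictor (the kernel barely varies along it). Relevant
#' predictors are therefore the *lowest* quartile of this score.
#'
#' @param model a "gpFit" object with ARD length scales (see
#'   [fitGprArd()]), or a [SpadModel] wrapping one.
#' @return named numeric weakness scores (length scales, standardized
#'   input units).
#' @export
gprWeakness <- function(model) {
  fit <- if (is(model, "SpadModel")) model@fit else model
  if (!inherits(fit, "gpFit")) stop("gprWeakness requires a GP fit")
  if (!isTRUE(fit$ard))
    stop("unsupported configuration: isotropic kernel has no per-predictor (ARD) length scales")
  out <- fit$lengthScales
  if (!is.null(attr(fit, "unstandardized")) && attr(fit, "unstandardized"))
    warning("inputs were not standardized; length scales are not comparable")
  if (is(model, "SpadModel")) names(out) <- model@predictorNames
  else if (!is.null(colnames(fit$xTrain))) names(out) <- colnames(fit$xTrain)
  out
}

#' Quartile classification of relevance scores
#'
#' `top` mode keeps scores at or above the upper quartile Q3 (PLSR weights,
#' random-forest importance); `bottom` mode keeps scores at or below the
#' lower quartile Q1 (GPR weakness). Quartiles use linear interpolation
#' and comparisons are inclusive, so ties inflate (never deflate) the
#' relevant set.
#'
#' @param scores named numeric vector, length >= 4.
#' @param mode "top" or "bottom".
#' @return named logical vector: TRUE = relevant.
#' @examples
#' quartileClassify(setNames(1:8, letters[1:8]))  # Q3 = 6.25 -> g, h
#' @export
quartileClassify <- function(scores, mode = c("top", "bottom")) {
  mode <- match.arg(mode)
  if (length(scores) < 4L) stop("need at least 4 scores for quartiles")
  if (mode == "top") {
    q <- stats::quantile(scores, 0.75, type = 7, names = FALSE)
    scores >= q
  } else {
    q <- stats::quantile(scores, 0.25, type = 7, names = FALSE)
    scores <= q
  }
}

#' Merge contiguous relevant bands into ranges
#'
#' Groups of neighbouring bands within 10 nm of each other are reported as
#' a single variable at their central wavelength.
#'
#' @param wavelengths numeric relevant band centers in nm.
#' @param gap numeric merge distance in nm (default 10).
#' @return data.frame with `from`, `to`, `center`, `nBands`.
#' @export
mergeBandRanges <- function(wavelengths, gap = 10) {
  if (!length(wavelengths))
    return(data.frame(from = numeric(0), to = numeric(0),
                      center = numeric(0), nBands = integer(0)))
  wl <- sort(wavelengths)
  cluster <- cumsum(c(1, diff(wl) > gap))
  rows <- lapply(split(wl, cluster), function(g)
    data.frame(from = min(g), to = max(g), center = stats::median(g),
               nBands = length(g)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-method consensus of relevant predictors
#'
#' Union of the per-method relevant sets with the number of methods
#' flagging each predictor (1--3).
#'
#' @param sets named list of character vectors, the relevant predictor ids
#'   per method.
#' @return data.frame with `predictor` and `nMethods`, ordered by
#'   decreasing count.
#' @export
importanceConsensus <- function(sets) {
  if (!length(sets)) stop("need at least one relevant set")
  all <- sort(unique(unlist(sets)))
  count <- vapply(all, function(p)
    sum(vapply(sets, function(s) p %in% s, logical(1))), integer(1))
  out <- data.frame(predictor = all, nMethods = count,
                    stringsAsFactors = FALSE)
  out[order(-out$nMethods, out$predictor), , drop = FALSE]
}

#' Full three-method importance analysis of a training set
#'
#' Fits PLSR (cross-validation-tuned components), a bagged random forest
#' and an ARD squared-exponential GP on the training data, scores every
#' predictor by each method, applies the quartile rule (upper quartile for
#' PLSR weights and forest importance, lower quartile for GPR weakness)
#' and counts the per-predictor consensus.
#'
#' @param train a [SpadDataset].
#' @param seed integer RNG seed.
#' @return list with `table` (per-predictor scores, relevance flags,
#'   consensus count) and `consensus` (the [importanceConsensus()] output).
#' @export
importanceAnalysis <- function(train, seed = 1L) {
  stopifnot(is(train, "SpadDataset"))
  cfgs <- rosterConfigs()
  plsrM <- fitModel(cfgs$plsr_plsr, train@x, train@y, seed = seed)
  plsrM@predictorNames <- colnames(train@x)
  rfM <- fitModel(cfgs$ensemble_bagged_rf, train@x, train@y, seed = seed)
  rfM@predictorNames <- colnames(train@x)
  gprA <- withSeed(seed, fitGprArd(train@x, train@y))
  wPlsr <- plsrWeights(plsrM)$aggregate
  wRf <- rfImportance(rfM)
  wGpr <- gprWeakness(gprA)
  names(wGpr) <- colnames(train@x)
  relPlsr <- quartileClassify(wPlsr, "top")
  relRf <- quartileClassify(wRf, "top")
  relGpr <- quartileClassify(wGpr, "bottom")
  tab <- data.frame(predictor = colnames(train@x),
                    plsrWeight = unname(wPlsr), rfImportance = unname(wRf),
                    gprWeakness = unname(wGpr),
                    plsrRelevant = unname(relPlsr), rfRelevant = unname(relRf),
                    gprRelevant = unname(relGpr), stringsAsFactors = FALSE)
  tab$nMethods <- tab$plsrRelevant + tab$rfRelevant + tab$gprRelevant
  sets <- list(PLSR = tab$predictor[tab$plsrRelevant],
               RF = tab$predictor[tab$rfRelevant],
               GPR = tab$predictor[tab$gprRelevant])
  list(table = tab, consensus = importanceConsensus(sets))
}
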