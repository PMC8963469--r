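#' @include AllClasses.R sensor.R indices-registry.R io-samples.R
NULL

#' Assemble a predictor/response dataset from a sample table
#'
#' Resamples the table's 1-nm spectra onto the sensor grid and builds the
#' predictor matrix for one of the three predictor sets: all 272 bands, the
#' 145 registry-selected bands (exactly the column subset of the all-bands
#' matrix at [registryWavelengths()]), or the 60 vegetation indices.
#'
#' @param table sample data.frame ([simulateSampleTable()] layout). Tables
#'   already on the sensor grid (272 `w<nm>` columns at the band centers)
#'   are used as-is.
#' @param predictorSet "all_bands", "selected_bands" or "vis".
#' @param registry index registry (default [viRegistry()]).
#' @param sensor a [SensorModel].
#' @return a [SpadDataset].
#' @export
makeDataset <- function(table,
                        predictorSet = c("all_bands", "selected_bands", "vis"),
                        registry = viRegistry(), sensor = defaultSensor()) {
  predictorSet <- match.arg(predictorSet)
  checkSampleTable(table)
  wl <- spectrumColumns(table)
  spectra <- as.matrix(table[, names(wl), drop = FALSE])
  centers <- bandCenters(sensor)
  if (length(wl) == length(centers) && max(abs(wl - centers)) < 0.51) {
    bands <- spectra
  } else {
    bands <- gaussianResample(spectra, sensor, wavelengths = as.numeric(wl))
  }
  colnames(bands) <- sprintf("b%.3f", centers)
  x <- switch(predictorSet,
    all_bands = bands,
    selected_bands = {
      sel <- registryWavelengths(registry, sensor)
      bands[, colnames(bands) %in% sprintf("b%.3f", sel), drop = FALSE]
    },
    vis = {
      v <- t(apply(bands, 1L, function(s)
        suppressWarnings(computeAllIndices(registry, s, centers))))
      nBad <- sum(!is.finite(v))
      if (nBad > 0L) {
        warning(sprintf(
          "%d non-finite index value(s) imputed with the column median", nBad))
        for (j in which(colSums(!is.finite(v)) > 0L)) {
          bad <- !is.finite(v[, j])
          v[bad, j] <- stats::median(v[!bad, j])
        }
      }
      v
    })
  new("SpadDataset", x = x, y = table$spad,
      campaign = as.character(table$campaign),
      campaignLevels = unique(as.character(table$campaign)),
      predictorSet = predictorSet)
}

# row subset helper
datasetSlice <- function(ds, idx) {
  new("SpadDataset", x = ds@x[idx, , drop = FALSE], y = ds@y[idx],
      campaign = ds@campaign[idx], campaignLevels = ds@campaignLevels,
      predictorSet = ds@predictorSet)
}

#' Distribution-matched train/validation split
#'
#' Per-campaign stratified split: within each campaign the samples are
#' ordered by SPAD, dealt into `round((1 - trainFrac) * n)` equally sized
#' rank groups, and one member of each group is drawn (seeded) into the
#' validation set, so the two subsets have near-identical distributions.
#' A 108-sample campaign yields an 86/22 split at the default 0.8 fraction.
#'
#' @param dataset a [SpadDataset].
#' @param trainFrac numeric training fraction (default 0.8).
#' @param seed integer RNG seed.
#' @return list with `train` and `validation` [SpadDataset]s.
#' @export
splitDataset <- function(dataset, trainFrac = 0.8, seed = 1L) {
  stopifnot(is(dataset, "SpadDataset"))
  withSeed(seed, {
    valIdx <- integer(0)
    for (cp in dataset@campaignLevels) {
      idx <- which(dataset@campaign == cp)
      n <- length(idx)
      if (n < 5L)
        stop(sprintf("campaign %s has only %d samples; too small to stratify",
                     cp, n))
      nVal <- max(1L, round((1 - trainFrac) * n))
      ord <- idx[order(dataset@y[idx])]
      groups <- sort(rep_len(seq_len(nVal), n))
      picks <- vapply(split(ord, groups), function(g)
        if (length(g) == 1L) g else sample(g, 1L), integer(1))
      valIdx <- c(valIdx, picks)
    }
    list(train = datasetSlice(dataset, setdiff(seq_along(dataset@y), valIdx)),
         validation = datasetSlice(dataset, sort(valIdx)))
  })
}

#' Pearson correlation diagnostics of a dataset
#'
#' Correlation matrix of the response and every predictor: symmetric, unit
#' diagonal, entries in [-1, 1]. Constant columns are reported by name
#' (warning) and carry NA correlations rather than being silently filled.
#'
#' @param dataset a [SpadDataset].
#' @return numeric (p+1) x (p+1) matrix; first row/column is the SPAD
#'   response.
#' @export
correlationMatrix <- function(dataset) {
  stopifnot(is(dataset, "SpadDataset"))
  if (length(dataset@y) < 3L) stop("need at least 3 samples")
  m <- cbind(spad = dataset@y, dataset@x)
  sds <- apply(m, 2L, stats::sd)
  constant <- colnames(m)[sds < .Machine$double.eps]
  if (length(constant))
    warning("constant column(s), correlation undefined: ",
            paste(constant, collapse = ", "))
  r <- suppressWarnings(stats::cor(m))
  diag(r) <- 1
  r
}

#' Compare prediction and observation distributions per campaign
#'
#' Five-number summaries of the predictions and the validation
#' observations, campaign by campaign, with the median gap
#' (prediction - observation) and a flag where |gap| exceeds `bound`.
#' Campaigns present on one side only appear with NA on the other.
#'
#' @param predictions numeric predictions.
#' @param predCampaign character campaign label per prediction.
#' @param observed numeric validation observations.
#' @param obsCampaign character campaign label per observation.
#' @param bound numeric flag threshold in SPAD units (default 5).
#' @return data.frame with per-campaign summaries, `medianGap` and
#'   `flagged`.
#' @export
compareDistributions <- function(predictions, predCampaign, observed,
                                 obsCampaign, bound = 5) {
  campaigns <- unique(c(predCampaign, obsCampaign))
  rows <- lapply(campaigns, function(cp) {
    p <- predictions[predCampaign == cp]
    o <- observed[obsCampaign == cp]
    f5 <- function(v) if (length(v)) stats::quantile(v, c(0, .25, .5, .75, 1),
                                                     names = FALSE)
                      else rep(NA_real_, 5L)
    fp <- f5(p); fo <- f5(o)
    gap <- fp[3L] - fo[3L]
    data.frame(campaign = cp, nPred = length(p), nObs = length(o),
               predMin = fp[1], predQ1 = fp[2], predMedian = fp[3],
               predQ3 = fp[4], predMax = fp[5],
               obsMin = fo[1], obsQ1 = fo[2], obsMedian = fo[3],
               obsQ3 = fo[4], obsMax = fo[5],
               medianGap = gap,
               flagged = is.na(gap) | abs(gap) > bound,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
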