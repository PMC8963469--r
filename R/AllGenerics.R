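#' @include AllClasses.R
NULL

#' Band centers of a sensor or cube
#' @param x a [SensorModel] or [ReflectanceCube].
#' @return numeric wavelengths in nm.
#' @export
setGeneric("bandCenters", function(x) standardGeneric("bandCenters"))

#' Per-band FWHM of a sensor or cube
#' @param x a [SensorModel] or [ReflectanceCube].
#' @return numeric FWHM in nm.
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))

#' Raster values of a cube or map
#' @param x a [ReflectanceCube] or [PredictionMap].
#' @return the underlying array / matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' Predict SPAD from a fitted model
#'
#' @param object a [SpadModel].
#' @param newx numeric matrix of predictors (columns as at training).
#' @param se logical, also return predictive standard deviations
#'   (probabilistic models only).
#' @return numeric predictions, or a list with `mean` and `sd` when
#'   `se = TRUE`.
#' @export
setGeneric("predictSpad", function(object, newx, se = FALSE)
  standardGeneric("predictSpad"))

#' @describeIn SensorModel band centers accessor
#' @param x a SensorModel
#' @export
setMethod("bandCenters", "SensorModel", function(x) x@bandCenters)

#' @describeIn SensorModel FWHM accessor
#' @export
setMethod("fwhm", "SensorModel", function(x) x@fwhm)

#' @describeIn ReflectanceCube band centers of the cube's sensor grid
#' @param x a ReflectanceCube
#' @export
setMethod("bandCenters", "ReflectanceCube", function(x) x@sensor@bandCenters)

#' @describeIn ReflectanceCube FWHM of the cube's sensor grid
#' @export
setMethod("fwhm", "ReflectanceCube", function(x) x@sensor@fwhm)

#' @describeIn ReflectanceCube the lines x samples x bands array
#' @export
setMethod("values", "ReflectanceCube", function(x) x@data)

#' @describeIn PredictionMap the SPAD prediction matrix
#' @param x a PredictionMap
#' @export
setMethod("values", "PredictionMap", function(x) x@spad)

setMethod("show", "SensorModel", function(object) {
  cat(sprintf("SensorModel: %d bands, %.1f-%.1f nm, FWHM %.3g nm\n",
              length(object@bandCenters), min(object@bandCenters),
              max(object@bandCenters), object@fwhm[1L]))
})

setMethod("show", "CampaignSpec", function(object) {
  s <- object@spadSummary
  cat(sprintf(
    "CampaignSpec %s: n=%d, SPAD five-number (%.0f, %.0f, %.0f, %.0f, %.0f), drift %.2f\n",
    object@label, object@nSamples, s[1], s[2], s[3], s[4], s[5], object@drift))
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("ReflectanceCube: %d lines x %d samples x %d bands, GSD %.3f m\n",
              d[1], d[2], d[3], object@pixelSize))
})

setMethod("show", "SpadDataset", function(object) {
  cat(sprintf("SpadDataset [%s]: n=%d, p=%d, campaigns %s\n",
              object@predictorSet, nrow(object@x), ncol(object@x),
              paste(object@campaignLevels, collapse = ", ")))
})

setMethod("show", "SpadModel", function(object) {
  cat(sprintf("SpadModel: %s / %s on %s predictors\n",
              object@config$family, object@config$variant, object@predictorSet))
})

setMethod("show", "PredictionMap", function(object) {
  d <- dim(object@spad)
  cat(sprintf("PredictionMap: %d x %d px, %d valid, %d flagged invalid%s\n",
              d[1], d[2], sum(!is.na(object@spad)), object@nInvalid,
              if (length(object@sigma95)) ", with sigma95 layer" else ""))
})
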