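#' @include models.R indices-ops.R
NULL

spadRange <- c(0, 70)

#' Predict a SPAD map from a cube
#'
#' Applies a fitted model to every masked-in pixel of a reflectance cube
#' (band-predictor models) or vegetation-index cube array (VI-predictor
#' models). Retrievals outside the meter's [0, 70] operating range become
#' nodata gap pixels and are counted, not clipped. GPR models additionally
#' populate the sigma95 uncertainty layer (the half-width of the 95%
#' predictive interval).
#'
#' @param model a [SpadModel].
#' @param cube a [ReflectanceCube], or the 3-d array from [viCube()].
#' @param mask integer matrix; pixels with mask > 0 are predicted.
#' @param campaign character campaign label recorded in the provenance.
#' @param strategy character strategy tag recorded in the provenance.
#' @return a [PredictionMap].
#' @export
predictCube <- function(model, cube, mask, campaign = NA_character_,
                        strategy = NA_character_) {
  stopifnot(is(model, "SpadModel"))
  if (is(cube, "ReflectanceCube")) {
    d <- dim(cube@data)
    X <- matrix(cube@data, d[1L] * d[2L], d[3L])
    colnames(X) <- sprintf("b%.3f", bandCenters(cube))
  } else if (is.array(cube) && length(dim(cube)) == 3L) {
    d <- dim(cube)
    X <- matrix(cube, d[1L] * d[2L], d[3L])
    colnames(X) <- dimnames(cube)[[3L]]
  } else stop("cube must be a ReflectanceCube or a 3-d VI array")
  if (!identical(dim(mask), d[1:2]))
    stop("mask geometry does not match the cube")
  need <- model@predictorNames
  if (!all(need %in% colnames(X)))
    stop(sprintf(
      "predictor-set mismatch: model expects [%s ... %s] (%d), cube offers [%s ... %s] (%d)",
      need[1L], need[length(need)], length(need),
      colnames(X)[1L], colnames(X)[ncol(X)], ncol(X)))
  sel <- as.vector(mask) > 0
  spad <- matrix(NA_real_, d[1L], d[2L])
  sig <- matrix(numeric(0), 0L, 0L)
  nInvalid <- 0L
  if (any(sel)) {
    Xs <- X[sel, need, drop = FALSE]
    ok <- stats::complete.cases(Xs)
    pred <- rep(NA_real_, sum(sel))
    sdv <- rep(NA_real_, sum(sel))
    if (any(ok)) {
      if (model@config$family == "gpr") {
        out <- predictSpad(model, Xs[ok, , drop = FALSE], se = TRUE)
        pred[ok] <- out$mean
        sdv[ok] <- out$sd
      } else {
        pred[ok] <- predictSpad(model, Xs[ok, , drop = FALSE])
      }
    }
    bad <- !is.na(pred) & (pred < spadRange[1L] | pred > spadRange[2L])
    # flagged invalid = out-of-range retrievals plus pixels whose
    # predictor vector was incomplete (non-finite index values)
    nInvalid <- sum(bad) + sum(!ok)
    pred[bad] <- NA_real_
    spad[sel] <- pred
    if (model@config$family == "gpr") {
      sig <- matrix(NA_real_, d[1L], d[2L])
      sdv[bad] <- NA_real_
      sig[sel] <- 1.96 * sdv
    }
  }
  new("PredictionMap", spad = spad, sigma95 = sig, nInvalid = nInvalid,
      provenance = list(
        model = paste(model@config$family, model@config$variant, sep = "_"),
        predictorSet = model@predictorSet, strategy = strategy,
        campaign = campaign, seed = model@seed,
        version = as.character(utils::packageVersion("chlorospec"))))
}

#' 95% predictive-interval half-width of a GPR model
#'
#' 1.96 times the predictive standard deviation under the Gaussian
#' predictive law: the half-width of the central 95% interval.
#'
#' @param model a [SpadModel] with family "gpr", or a "gpFit".
#' @param x numeric matrix of query points.
#' @return numeric half-widths in SPAD units.
#' @export
sigma95 <- function(model, x) {
  if (is(model, "SpadModel")) {
    if (model@config$family != "gpr")
      stop("sigma95 is unsupported for non-probabilistic models")
    1.96 * predictSpad(model, x, se = TRUE)$sd
  } else if (inherits(model, "gpFit")) {
    1.96 * gpPredict(model, x, se = TRUE)$sd
  } else stop("sigma95 is unsupported for non-probabilistic models")
}

#' Aggregate a prediction map to the per-plant matrix
#'
#' Averages valid pixels per plant cell, following the sowing arrangement
#' (rows x columns) of the layout. Cells without any valid pixel are NA;
#' their count is attached as an attribute, along with the mean sigma95
#' matrix for probabilistic maps.
#'
#' @param map a [PredictionMap].
#' @param mask integer matrix assigning each pixel to a plant id (row-major
#'   plant order; 0 = non-plant).
#' @param layout the [FieldLayout] of the mask.
#' @return numeric nRows x nCols matrix of mean SPAD per plant, with
#'   attributes `nEmpty` (cells without valid pixels) and `sigma95`
#'   (matrix of mean half-widths, when available).
#' @export
plantAverage <- function(map, mask, layout) {
  stopifnot(is(map, "PredictionMap"), is(layout, "FieldLayout"))
  if (!identical(dim(mask), dim(map@spad)))
    stop("mask geometry does not match the map")
  nPlants <- layout@nRows * layout@nCols
  ids <- mask[mask > 0L]
  if (any(ids > nPlants))
    stop("layout error: mask contains plant ids beyond the layout grid")
  out <- matrix(NA_real_, layout@nRows, layout@nCols)
  sigOut <- if (length(map@sigma95))
    matrix(NA_real_, layout@nRows, layout@nCols) else NULL
  nEmpty <- 0L
  for (p in seq_len(nPlants)) {
    px <- mask == p
    if (!any(px)) next
    v <- map@spad[px]
    r <- (p - 1L) %/% layout@nCols + 1L
    cc <- (p - 1L) %% layout@nCols + 1L
    if (all(is.na(v))) { nEmpty <- nEmpty + 1L; next }
    out[r, cc] <- mean(v, na.rm = TRUE)
    if (!is.null(sigOut)) sigOut[r, cc] <- mean(map@sigma95[px], na.rm = TRUE)
  }
  attr(out, "nEmpty") <- nEmpty
  if (!is.null(sigOut)) attr(out, "sigma95") <- sigOut
  out
}
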