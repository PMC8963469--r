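#' @import methods
NULL

#' Spectral band model of the imaging instrument
#'
#' Holds the band centers and full-width-half-maximum (FWHM) values of the
#' 272-band, 400--1,000 nm pushbroom instrument grid onto which all spectra
#' are resampled. Band centers must be strictly increasing.
#'
#' @slot bandCenters numeric, band center wavelengths in nm.
#' @slot fwhm numeric, per-band FWHM in nm (recycled scalar allowed at
#'   construction).
#'
#' @seealso [defaultSensor()]
#' @export
setClass("SensorModel",
  representation(bandCenters = "numeric", fwhm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@bandCenters) != length(object@fwhm))
      msg <- c(msg, "bandCenters and fwhm must have equal length")
    if (any(diff(object@bandCenters) <= 0))
      msg <- c(msg, "bandCenters must be strictly increasing")
    if (any(object@fwhm <= 0))
      msg <- c(msg, "fwhm must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Per-campaign synthetic field conditions
#'
#' Describes one field campaign for the synthetic generator: the SPAD
#' five-number summary (min, Q1, median, Q3, max), the number of leaflet
#' samples, the green-peak and NIR-plateau reflectance statistics of the
#' campaign's spectra, and a drift scalar that perturbs the SPAD-to-spectrum
#' link to create campaign-specific non-stationarity.
#'
#' @slot label character campaign id, format YYYYMMDD.
#' @slot spadSummary numeric(5): min, Q1, median, Q3, max in SPAD units,
#'   non-decreasing and inside [0, 70].
#' @slot nSamples integer sample count (>= 0).
#' @slot greenPeakMean,greenPeakSd numeric green-peak reflectance fraction
#'   statistics in [0, 1].
#' @slot nirMean,nirSd numeric NIR-plateau reflectance fraction statistics.
#' @slot drift numeric multiplicative perturbation of the chlorophyll link
#'   (0 = the reference mapping).
#'
#' @seealso [defaultCampaigns()], [simulateSpad()]
#' @export
setClass("CampaignSpec",
  representation(label = "character", spadSummary = "numeric",
    nSamples = "integer", greenPeakMean = "numeric", greenPeakSd = "numeric",
    nirMean = "numeric", nirSd = "numeric", drift = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- object@spadSummary
    if (length(s) != 5L)
      msg <- c(msg, "spadSummary must have length 5 (min, Q1, median, Q3, max)")
    else {
      if (any(diff(s) < 0))
        msg <- c(msg, "spadSummary must be non-decreasing (min <= Q1 <= median <= Q3 <= max)")
      if (any(s < 0 | s > 70))
        msg <- c(msg, "spadSummary values must lie in [0, 70]")
    }
    if (object@nSamples < 0L) msg <- c(msg, "nSamples must be >= 0")
    refl <- c(object@greenPeakMean, object@nirMean)
    if (any(refl < 0 | refl > 1))
      msg <- c(msg, "reflectance statistics must lie in [0, 1]")
    if (object@greenPeakSd < 0 || object@nirSd < 0)
      msg <- c(msg, "reflectance sd must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Beer--Lambert leaf reflectance generator
#'
#' Parameters of the synthetic SPAD-to-spectrum mapping on the 1-nm,
#' 400--1,000 nm grid: a NIR-plateau baseline attenuated by
#' exp(-k(lambda) * c(SPAD)), with Gaussian absorber components at the
#' chlorophyll-a (~430, ~680 nm) and chlorophyll-b (~460, ~650 nm) features
#' and an exponential SPAD-to-absorber-strength link.
#'
#' @slot absorberCenters,absorberWidths,absorberStrengths numeric, Gaussian
#'   absorption components (nm, nm, dimensionless k at peak).
#' @slot visBase numeric baseline visible absorption level added below the
#'   red edge.
#' @slot linkRate numeric rate of the exponential SPAD link
#'   c(s) = exp(s / linkRate) - 1.
#' @slot noiseSd numeric per-wavelength additive reflectance noise sd.
#'
#' @seealso [defaultLeafModel()], [simulateLeafSpectrum()]
#' @export
setClass("LeafSpectrumModel",
  representation(absorberCenters = "numeric", absorberWidths = "numeric",
    absorberStrengths = "numeric", visBase = "numeric", linkRate = "numeric",
    noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@absorberCenters)
    if (length(object@absorberWidths) != n || length(object@absorberStrengths) != n)
      msg <- c(msg, "absorber center/width/strength vectors must match in length")
    if (any(object@absorberWidths <= 0)) msg <- c(msg, "absorber widths must be positive")
    if (object@linkRate <= 0) msg <- c(msg, "linkRate must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Sowing layout of the synthetic field
#'
#' The plant grid used by the cube generator and by plant-level aggregation:
#' plants on an nRows x nCols grid, split into nPlots plots, rendered at
#' pixelSize ground sampling distance with pxPerPlant x pxPerPlant pixels per
#' plant separated by soil gaps.
#'
#' @slot nRows,nCols integer plant grid dimensions.
#' @slot plantSpacing numeric plant spacing in m.
#' @slot nPlots integer number of plots; nRows * nCols must be divisible by it.
#' @slot pixelSize numeric ground sampling distance in m.
#' @slot pxPerPlant integer side length of the square pixel block per plant.
#' @slot gapPx integer soil pixels between neighbouring plant blocks.
#'
#' @seealso [fieldLayout()], [simulateCube()], [plantAverage()]
#' @export
setClass("FieldLayout",
  representation(nRows = "integer", nCols = "integer", plantSpacing = "numeric",
    nPlots = "integer", pixelSize = "numeric", pxPerPlant = "integer",
    gapPx = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nRows < 1L || object@nCols < 1L)
      msg <- c(msg, "nRows and nCols must be >= 1")
    if (object@nPlots < 1L || (object@nRows * object@nCols) %% object@nPlots != 0L)
      msg <- c(msg, "nRows * nCols plants must be divisible by nPlots")
    if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be positive")
    if (object@pxPerPlant < 1L) msg <- c(msg, "pxPerPlant must be >= 1")
    if (object@gapPx < 0L) msg <- c(msg, "gapPx must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Banded reflectance raster
#'
#' An in-memory hyperspectral data-cube: a lines x samples x bands array of
#' reflectance fractions on a [SensorModel] band grid. The band axis is
#' always last in memory regardless of on-disk interleave. Values are
#' reflectance fractions in [0, 1] or the nodata sentinel.
#'
#' @slot data numeric 3-d array, lines x samples x bands.
#' @slot sensor a [SensorModel].
#' @slot pixelSize numeric ground sampling distance in m.
#' @slot nodata numeric sentinel for invalid pixels.
#'
#' @seealso [readCube()], [writeCube()], [simulateCube()]
#' @export
setClass("ReflectanceCube",
  representation(data = "array", sensor = "SensorModel", pixelSize = "numeric",
    nodata = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
      msg <- c(msg, "data must be a 3-d array (lines x samples x bands)")
    else if (d[3L] != length(object@sensor@bandCenters))
      msg <- c(msg, sprintf("band count (%d) must equal sensor band count (%d)",
                            d[3L], length(object@sensor@bandCenters)))
    if (length(msg)) msg else TRUE
  }
)

#' Predictor/response dataset for the learning harness
#'
#' An n x p predictor matrix paired with SPAD responses and ordered campaign
#' labels. The predictor set tag records whether columns are all 272 bands,
#' the 145 registry-selected bands, or the 60 vegetation indices.
#'
#' @slot x numeric predictor matrix with column names.
#' @slot y numeric SPAD response.
#' @slot campaign character campaign label per row.
#' @slot campaignLevels character the ordered campaign sequence.
#' @slot predictorSet character tag: "all_bands", "selected_bands" or "vis".
#'
#' @seealso [makeDataset()], [splitDataset()]
#' @export
setClass("SpadDataset",
  representation(x = "matrix", y = "numeric", campaign = "character",
    campaignLevels = "character", predictorSet = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@x)
    if (length(object@y) != n || length(object@campaign) != n)
      msg <- c(msg, "x, y and campaign must agree in length")
    if (!all(object@campaign %in% object@campaignLevels))
      msg <- c(msg, "campaign labels must come from campaignLevels")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted SPAD regression model
#'
#' Wraps a fitted back-end estimator together with its roster configuration,
#' predictor-set tag, tuned hyperparameters and the seed used, so that
#' predictions, metrics and maps carry full provenance.
#'
#' @slot config list: family, variant, hyperparams.
#' @slot fit ANY, the back-end fit object.
#' @slot predictorSet character tag of the predictor matrix used.
#' @slot predictorNames character column names the model expects.
#' @slot seed integer seed used for fitting.
#' @slot scaling list with center/scale vectors applied to x (empty if none).
#'
#' @seealso [fitSequential()], [fitRetraining()], [predictSpad()]
#' @export
setClass("SpadModel",
  representation(config = "list", fit = "ANY", predictorSet = "character",
    predictorNames = "character", seed = "integer", scaling = "list"))

#' Pixel-level SPAD prediction map
#'
#' A raster of per-pixel SPAD predictions (with optional GPR uncertainty
#' half-widths) plus the provenance of the model run that produced it.
#' Invalid retrievals (outside the meter's [0, 70] operating range) and
#' masked-out pixels are NA.
#'
#' @slot spad numeric matrix of predictions in SPAD units (NA = nodata).
#' @slot sigma95 numeric matrix of 95% predictive-interval half-widths in
#'   SPAD units, or a 0 x 0 matrix when the model is not probabilistic.
#' @slot nInvalid integer count of predictions flagged outside [0, 70].
#' @slot provenance list: model id, strategy, predictor set, campaign, seed.
#'
#' @seealso [predictCube()], [plantAverage()]
#' @export
setClass("PredictionMap",
  representation(spad = "matrix", sigma95 = "matrix", nInvalid = "integer",
    provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@sigma95) &&
        !identical(dim(object@sigma95), dim(object@spad)))
      msg <- c(msg, "sigma95 must match spad dimensions when present")
    if (length(object@sigma95) && any(object@sigma95 < 0, na.rm = TRUE))
      msg <- c(msg, "sigma95 must be >= 0 where defined")
    if (length(msg)) msg else TRUE
  }
)
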