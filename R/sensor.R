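#' @include AllClasses.R
NULL

#' The 272-band instrument grid
#'
#' Constructs the default [SensorModel]: 272 evenly spaced band centers from
#' 400 to 1,000 nm with a constant 6 nm FWHM, matching the pushbroom camera
#' grid that all leaf spectra are resampled onto.
#'
#' @param nBands integer number of bands.
#' @param from,to numeric first and last band center in nm.
#' @param fwhm numeric FWHM in nm, recycled to all bands.
#' @return a [SensorModel].
#' @examples
#' sensor <- defaultSensor()
#' length(bandCenters(sensor))  # 272
#' @export
defaultSensor <- function(nBands = 272L, from = 400, to = 1000, fwhm = 6) {
  new("SensorModel", bandCenters = seq(from, to, length.out = nBands),
      fwhm = rep_len(fwhm, nBands))
}

#' Construct a campaign specification
#'
#' @param label character campaign id (YYYYMMDD).
#' @param spadSummary numeric(5) five-number SPAD summary
#'   (min, Q1, median, Q3, max).
#' @param nSamples integer leaflet sample count.
#' @param greenPeakMean,greenPeakSd,nirMean,nirSd numeric reflectance-fraction
#'   statistics of the campaign's green peak and NIR plateau.
#' @param drift numeric campaign perturbation of the SPAD-to-spectrum link.
#' @return a [CampaignSpec].
#' @export
campaignSpec <- function(label, spadSummary, nSamples,
                         greenPeakMean = 0.15, greenPeakSd = 0.03,
                         nirMean = 0.50, nirSd = 0.10, drift = 0) {
  new("CampaignSpec", label = as.character(label),
      spadSummary = as.numeric(spadSummary), nSamples = as.integer(nSamples),
      greenPeakMean = greenPeakMean, greenPeakSd = greenPeakSd,
      nirMean = nirMean, nirSd = nirSd, drift = drift)
}

#' Default five-campaign study conditions
#'
#' The five synthetic field campaigns emulating a fall--winter tomato growth
#' cycle (establishment through pre-harvest): 108 leaflet samples per
#' campaign (75 in the last, after plant losses), SPAD distributions rising
#' across the season, and campaign-level green-peak / NIR reflectance
#' statistics. Quartiles and medians follow the reported campaign
#' distributions; whisker ends not reported are fixed plausible values.
#' Campaign drift is on by default, creating the non-stationarity that the
#' retraining strategy exploits; `drift = FALSE` gives a stationary control.
#'
#' @param drift logical, apply per-campaign drift to the SPAD-to-spectrum
#'   link (default TRUE).
#' @return list of five [CampaignSpec] objects, in temporal order.
#' @examples
#' cps <- defaultCampaigns()
#' sapply(cps, function(cp) cp@nSamples)  # 108 108 108 108 75
#' @export
defaultCampaigns <- function(drift = TRUE) {
  d <- if (drift) c(0, 0.15, 0.30, 0.45, 0.60) else rep(0, 5)
  list(
    campaignSpec("20171109", c(21, 29, 33, 38, 45), 108L,
                 greenPeakMean = 0.18, greenPeakSd = 0.02,
                 nirMean = 0.49, nirSd = 0.03, drift = d[1]),
    campaignSpec("20171205", c(38, 45, 49, 54, 60), 108L,
                 nirMean = 0.56, drift = d[2]),
    campaignSpec("20171218", c(38, 48, 52, 56, 67), 108L, drift = d[3]),
    campaignSpec("20180103", c(40, 48, 53, 59, 66), 108L, drift = d[4]),
    campaignSpec("20180114", c(40, 50, 55, 60, 66), 75L,
                 nirMean = 0.45, drift = d[5])
  )
}

#' Default Beer--Lambert leaf spectrum model
#'
#' Gaussian absorber components at the chlorophyll-a (430, 680 nm) and
#' chlorophyll-b (460, 650 nm) features, a baseline visible absorption of
#' 0.366 (calibrated so the first campaign's ensemble green peak averages
#' 0.18 at a 0.49 NIR plateau), and an exponential SPAD link with rate 25.
#'
#' @param noiseSd numeric additive per-wavelength reflectance noise sd.
#' @return a [LeafSpectrumModel].
#' @export
defaultLeafModel <- function(noiseSd = 0.004) {
  new("LeafSpectrumModel",
      absorberCenters = c(430, 460, 650, 680),
      absorberWidths = c(25, 25, 30, 25),
      absorberStrengths = c(1.2, 0.9, 0.8, 1.1),
      visBase = 0.366, linkRate = 25, noiseSd = noiseSd)
}

#' Construct a field sowing layout
#'
#' Defaults describe the full experimental field: a 60 x 20 plant grid in
#' four plots of 300 plants, 1.5 m spacing, rendered at 0.007 m ground
#' sampling distance. See [miniFieldLayout()] for the small layout used in
#' fast full-pipeline runs.
#'
#' @param nRows,nCols integer plant grid dimensions.
#' @param plantSpacing numeric m between plants.
#' @param nPlots integer number of plots.
#' @param pixelSize numeric ground sampling distance in m.
#' @param pxPerPlant integer square pixel block side per plant.
#' @param gapPx integer soil pixels between plant blocks.
#' @return a [FieldLayout].
#' @export
fieldLayout <- function(nRows = 60L, nCols = 20L, plantSpacing = 1.5,
                        nPlots = 4L, pixelSize = 0.007, pxPerPlant = 3L,
                        gapPx = 1L) {
  new("FieldLayout", nRows = as.integer(nRows), nCols = as.integer(nCols),
      plantSpacing = plantSpacing, nPlots = as.integer(nPlots),
      pixelSize = pixelSize, pxPerPlant = as.integer(pxPerPlant),
      gapPx = as.integer(gapPx))
}

#' Mini field layout for fast end-to-end runs
#'
#' 12 x 5 plants (four plots of 15), 3 x 3 pixels per plant: keeps
#' simulate-to-map pipeline runs under a minute.
#'
#' @inheritParams fieldLayout
#' @return a [FieldLayout].
#' @export
miniFieldLayout <- function(pxPerPlant = 3L) {
  fieldLayout(nRows = 12L, nCols = 5L, nPlots = 4L, pxPerPlant = pxPerPlant)
}

#' Plants per plot of a layout
#' @param layout a [FieldLayout].
#' @return integer number of plants in each plot.
#' @export
plantsPerPlot <- function(layout) {
  stopifnot(is(layout, "FieldLayout"))
  (layout@nRows * layout@nCols) %/% layout@nPlots
}
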