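#' @include AllClasses.R sensor.R utils.R
NULL

# Inverse CDF of the piecewise-uniform law interpolating a five-number
# summary: the CDF passes through (min,0), (Q1,.25), (median,.5), (Q3,.75),
# (max,1) with uniform density inside each segment. Quantiles therefore
# match the summary exactly and the sample extremes converge quickly.
spadQuantile <- function(u, spadSummary) {
  stats::approx(c(0, 0.25, 0.5, 0.75, 1), spadSummary, xout = u,
                ties = "ordered")$y
}

#' Draw SPAD values for one campaign
#'
#' Samples `nSamples` SPAD readings from the piecewise-uniform distribution
#' whose five-number summary (min, Q1, median, Q3, max) equals the campaign
#' specification, truncated by construction to the meter's [0, 70] range.
#'
#' @param spec a [CampaignSpec].
#' @param seed integer RNG seed.
#' @return numeric vector of length `spec@nSamples`.
#' @examples
#' s <- simulateSpad(defaultCampaigns()[[1]], seed = 1)
#' summary(s)
#' @export
simulateSpad <- function(spec, seed) {
  stopifnot(is(spec, "CampaignSpec"))
  validObject(spec)
  if (spec@nSamples == 0L) return(numeric(0))
  withSeed(seed, spadQuantile(stats::runif(spec@nSamples), spec@spadSummary))
}

# Absorption coefficient spectrum k(lambda) at unit absorber strength.
# A logistic switch centered at 715 nm shuts pigment absorption off through
# the red edge, so deepening absorption shifts the inflection to longer
# wavelengths as chlorophyll rises.
leafAbsorption <- function(model, lambda = leafGrid()) {
  sw <- 1 / (1 + exp((lambda - 715) / 10))
  k <- rep(model@visBase, length(lambda))
  for (i in seq_along(model@absorberCenters)) {
    k <- k + model@absorberStrengths[i] *
      exp(-(lambda - model@absorberCenters[i])^2 /
            (2 * model@absorberWidths[i]^2))
  }
  sw * k
}

# Exponential SPAD -> absorber strength link (campaign drift multiplies it).
chlLink <- function(spad, model, drift = 0) {
  (exp(spad / model@linkRate) - 1) * (1 + drift)
}

#' Generate a 1-nm leaf reflectance spectrum for a SPAD value
#'
#' Beer--Lambert construction: a NIR-plateau baseline (drawn from the
#' campaign's NIR statistics) attenuated by `exp(-k(lambda) * c(SPAD))`.
#' Reflectance at 680 nm is strictly decreasing in SPAD and the red-edge
#' inflection moves to longer wavelengths as SPAD rises.
#'
#' @param spad numeric SPAD value in [0, 70].
#' @param model a [LeafSpectrumModel].
#' @param campaign a [CampaignSpec] (supplies NIR statistics and drift).
#' @param seed integer RNG seed, or NULL to draw from the current stream.
#' @param noise logical; FALSE gives the deterministic mean spectrum at the
#'   campaign's mean NIR level.
#' @return numeric reflectance spectrum on [leafGrid()] (601 values), in
#'   [0, 1].
#' @export
simulateLeafSpectrum <- function(spad, model = defaultLeafModel(),
                                 campaign = defaultCampaigns()[[1]],
                                 seed = NULL, noise = TRUE) {
  if (!is.numeric(spad) || length(spad) != 1L || is.na(spad) ||
      spad < 0 || spad > 70)
    stop("spad must be a single value in [0, 70]")
  lambda <- leafGrid()
  k <- leafAbsorption(model, lambda)
  cc <- chlLink(spad, model, campaign@drift)
  gen <- function() {
    nir <- if (noise)
      min(0.85, max(0.15, stats::rnorm(1, campaign@nirMean, campaign@nirSd)))
    else campaign@nirMean
    r <- nir * exp(-k * cc)
    # noise-free spectra stay unfloored so the 680 nm ordering is strict
    if (noise) r <- clampRefl(r + stats::rnorm(length(lambda), 0,
                                               model@noiseSd))
    r
  }
  if (is.null(seed)) gen() else withSeed(seed, gen())
}

#' Simulate the multi-campaign leaflet sample table
#'
#' Draws SPAD readings and matching 1-nm leaf spectra for every campaign:
#' three leaflets per sampled plant, reproducing the five-campaign structure
#' (108 samples in campaigns 1--4, 75 in the last). Columns are `campaign`,
#' `plant_id`, `leaflet_id`, `spad`, then one reflectance column per
#' wavelength (`w400` ... `w1000`).
#'
#' @param campaigns list of [CampaignSpec] (default [defaultCampaigns()]).
#' @param model a [LeafSpectrumModel].
#' @param seed integer RNG seed.
#' @param leafletsPerPlant integer leaflets sampled per plant.
#' @return data.frame sample table.
#' @export
simulateSampleTable <- function(campaigns = defaultCampaigns(),
                                model = defaultLeafModel(), seed = 1,
                                leafletsPerPlant = 3L) {
  withSeed(seed, {
    out <- lapply(campaigns, function(cp) {
      n <- cp@nSamples
      if (n == 0L) return(NULL)
      spad <- spadQuantile(stats::runif(n), cp@spadSummary)
      spectra <- t(vapply(spad, function(s)
        simulateLeafSpectrum(s, model, cp, seed = NULL, noise = TRUE),
        numeric(length(leafGrid()))))
      colnames(spectra) <- paste0("w", leafGrid())
      nPlants <- ceiling(n / leafletsPerPlant)
      data.frame(campaign = cp@label,
                 plant_id = rep(seq_len(nPlants), each = leafletsPerPlant)[seq_len(n)],
                 leaflet_id = rep(seq_len(leafletsPerPlant), nPlants)[seq_len(n)],
                 spad = spad, spectra, check.names = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Synthetic sandy-loam soil background spectrum
#'
#' @param sensor a [SensorModel]; the spectrum is returned on its band grid.
#' @return numeric reflectance fractions, brightening from ~0.12 at 400 nm
#'   to ~0.35 at 1,000 nm.
#' @export
soilSpectrum <- function(sensor = defaultSensor()) {
  lam <- bandCenters(sensor)
  u <- (lam - 400) / 600
  0.12 + 0.23 * u^0.8
}

#' Default reflectances of the six gray calibration panels
#' @return numeric(6) flat panel reflectance fractions.
#' @export
defaultPanelReflectances <- function() c(0.03, 0.06, 0.12, 0.24, 0.40, 0.56)

#' Simulate a field reflectance (or radiance) data-cube
#'
#' Renders the plant grid of `layout` on the 272-band sensor grid: each
#' plant is a `pxPerPlant` x `pxPerPlant` block whose pixels carry the
#' Gaussian-resampled leaf spectrum for that plant's SPAD value, on a soil
#' background, with six flat gray calibration panels in a strip to the
#' right of the field. In radiance mode the cube stores
#' `(R - offset) / gain` per band, so an empirical-line fit against the
#' panels recovers `gain` and `offset`.
#'
#' @param layout a [FieldLayout].
#' @param plantSpads numeric nRows x nCols matrix of per-plant SPAD values.
#' @param model a [LeafSpectrumModel].
#' @param spec a [CampaignSpec] controlling NIR statistics and drift.
#' @param seed integer RNG seed.
#' @param sensor a [SensorModel].
#' @param noise logical per-pixel spectral noise.
#' @param mode "reflectance" or "radiance".
#' @param gains,offsets numeric per-band affine calibration (radiance mode).
#' @param panelReflectances numeric(6) flat panel reflectances.
#' @return list with elements `cube` (a [ReflectanceCube]), `mask` (integer
#'   matrix, plant id per pixel, 0 = non-plant), `panelMask` (integer
#'   matrix, panel id 1..6 or 0), `panelReflectances`, and `plantSpads`.
#' @examples
#' lay <- miniFieldLayout()
#' spads <- matrix(runif(60, 25, 60), lay@nRows, lay@nCols)
#' field <- simulateCube(lay, spads, seed = 1)
#' field$cube
#' @export
simulateCube <- function(layout, plantSpads, model = defaultLeafModel(),
                         spec = defaultCampaigns()[[1]], seed = 1,
                         sensor = defaultSensor(), noise = TRUE,
                         mode = c("reflectance", "radiance"),
                         gains = NULL, offsets = NULL,
                         panelReflectances = defaultPanelReflectances()) {
  mode <- match.arg(mode)
  stopifnot(is(layout, "FieldLayout"))
  if (!is.matrix(plantSpads) ||
      !identical(dim(plantSpads), c(layout@nRows, layout@nCols)))
    stop(sprintf("plantSpads must be a %d x %d matrix matching the layout",
                 layout@nRows, layout@nCols))
  nb <- length(bandCenters(sensor))
  if (mode == "radiance") {
    if (is.null(gains)) gains <- rep(2, nb)
    if (is.null(offsets)) offsets <- rep(0.05, nb)
    stopifnot(length(gains) == nb, length(offsets) == nb)
  }
  px <- layout@pxPerPlant; gap <- layout@gapPx
  cell <- px + gap
  lines <- layout@nRows * cell + gap
  panelSide <- 2L
  panelStrip <- 2L + panelSide            # gap + panel block width
  fieldCols <- layout@nCols * cell + gap
  samples <- fieldCols + panelStrip
  withSeed(seed, {
    cube <- array(NA_real_, c(lines, samples, nb))
    soil <- soilSpectrum(sensor)
    for (i in seq_len(lines)) for (j in seq_len(samples)) {
      s <- soil
      if (noise) s <- s + stats::rnorm(nb, 0, model@noiseSd)
      cube[i, j, ] <- clamp01(s)
    }
    mask <- matrix(0L, lines, samples)
    for (r in seq_len(layout@nRows)) for (cc in seq_len(layout@nCols)) {
      pid <- (r - 1L) * layout@nCols + cc
      rows <- (gap + (r - 1L) * cell) + seq_len(px)
      cols <- (gap + (cc - 1L) * cell) + seq_len(px)
      leaf1 <- simulateLeafSpectrum(plantSpads[r, cc], model, spec,
                                    seed = NULL, noise = FALSE)
      base <- gaussianResample(leaf1, sensor)
      for (i in rows) for (j in cols) {
        v <- base
        if (noise) {
          nirScale <- max(0.15, min(0.85,
            stats::rnorm(1, spec@nirMean, spec@nirSd))) / spec@nirMean
          v <- clampRefl(v * nirScale + stats::rnorm(nb, 0, model@noiseSd))
        }
        cube[i, j, ] <- v
        mask[i, j] <- pid
      }
    }
    panelMask <- matrix(0L, lines, samples)
    panelRows <- floor(seq(1, lines - panelSide + 1,
                           length.out = length(panelReflectances)))
    for (p in seq_along(panelReflectances)) {
      rows <- panelRows[p] + seq_len(panelSide) - 1L
      cols <- fieldCols + 2L + seq_len(panelSide)
      for (i in rows) for (j in cols) {
        v <- rep(panelReflectances[p], nb)
        if (noise) v <- clampRefl(v + stats::rnorm(nb, 0, model@noiseSd / 2))
        cube[i, j, ] <- v
        panelMask[i, j] <- p
      }
    }
    if (mode == "radiance")
      cube <- sweep(sweep(cube, 3L, offsets, "-"), 3L, gains, "/")
    list(cube = new("ReflectanceCube", data = cube, sensor = sensor,
                    pixelSize = layout@pixelSize, nodata = -9999),
         mask = mask, panelMask = panelMask,
         panelReflectances = panelReflectances, plantSpads = plantSpads)
  })
}

#' Mean panel spectra of a simulated cube
#'
#' Averages the pixels of each calibration panel, giving the per-band
#' panel matrix that [empiricalLineFit()] consumes.
#'
#' @param field list returned by [simulateCube()].
#' @return numeric bands x panels matrix.
#' @export
panelSpectra <- function(field) {
  nb <- dim(field$cube@data)[3L]
  ids <- sort(unique(field$panelMask[field$panelMask > 0L]))
  out <- vapply(ids, function(p) {
    idx <- which(field$panelMask == p, arr.ind = TRUE)
    colMeans(t(apply(idx, 1L, function(ij) field$cube@data[ij[1], ij[2], ])))
  }, numeric(nb))
  out
}
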