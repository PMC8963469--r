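#' @include AllClasses.R sensor.R preprocess.R
NULL

#' Sample a spectrum at a wavelength (nearest-band snapping)
#'
#' @param spectrum numeric reflectance values.
#' @param wavelength numeric query in nm.
#' @param wavelengths numeric band grid of the spectrum.
#' @return the value of the nearest band center.
#' @export
sampleBand <- function(spectrum, wavelength,
                       wavelengths = bandCenters(defaultSensor())) {
  if (wavelength < min(wavelengths) || wavelength > max(wavelengths))
    stop(sprintf("wavelength %.1f nm outside the grid span [%.1f, %.1f]",
                 wavelength, min(wavelengths), max(wavelengths)))
  spectrum[which.min(abs(wavelengths - wavelength))]
}

#' First-derivative spectrum (per nm)
#'
#' Savitzky--Golay first derivative with the same window/order defaults as
#' the smoothing step, scaled by the band spacing to per-nm units.
#'
#' @param spectrum numeric vector.
#' @param wavelengths numeric band grid (assumed evenly spaced).
#' @param window,polyorder Savitzky--Golay parameters.
#' @return numeric derivative spectrum, same length as the input.
#' @export
derivativeSpectrum <- function(spectrum,
                               wavelengths = bandCenters(defaultSensor()),
                               window = 11L, polyorder = 2L) {
  if (length(spectrum) < window)
    stop("spectrum too short for the derivative window")
  spacing <- mean(diff(wavelengths))
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = as.integer(window),
                                m = 1L, ts = spacing))
}

# Upper convex hull (monotone chain) over points sorted by x; returns hull
# y-values interpolated at every x.
upperHullValues <- function(x, y) {
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2L) {
      a <- idx[length(idx) - 1L]; b <- idx[length(idx)]
      # drop b if it lies below the chord a--i
      if ((y[b] - y[a]) * (x[i] - x[a]) <= (y[i] - y[a]) * (x[b] - x[a]))
        idx <- idx[-length(idx)]
      else break
    }
    idx <- c(idx, i)
  }
  stats::approx(x[idx], y[idx], xout = x)$y
}

#' Continuum removal over a wavelength range
#'
#' Divides the spectrum by its upper convex hull over `[range[1],
#' range[2]]`: continuum-removed values lie in (0, 1] and band depth is
#' 1 - CR. A linear (or convex-free) spectrum has CR identically 1.
#'
#' @param spectrum numeric reflectance values.
#' @param wavelengths numeric band grid.
#' @param range numeric(2) window in nm (>= 3 bands inside).
#' @return list with `wavelengths`, `cr` (continuum-removed spectrum) and
#'   `depth` (1 - cr), all restricted to the window.
#' @export
continuumRemoval <- function(spectrum,
                             wavelengths = bandCenters(defaultSensor()),
                             range = c(550, 750)) {
  inside <- wavelengths >= range[1L] & wavelengths <= range[2L]
  if (sum(inside) < 3L)
    stop("continuum removal needs at least 3 bands inside the range")
  x <- wavelengths[inside]; y <- spectrum[inside]
  if (any(y <= 0))
    stop("non-positive reflectance inside the continuum-removal range")
  hull <- upperHullValues(x, y)
  cr <- pmin(y / hull, 1)
  list(wavelengths = x, cr = cr, depth = 1 - cr)
}

#' Red-edge inflection position
#'
#' `max_derivative`: wavelength of the maximum first derivative in the
#' 680--760 nm window. `four_point`: the linear-interpolation formula on
#' R(670), R(700), R(740), R(780):
#' REP = 700 + 40 * ((R670 + R780)/2 - R700) / (R740 - R700).
#'
#' @param spectrum numeric reflectance values.
#' @param wavelengths numeric band grid covering 670--780 nm.
#' @param method "max_derivative" or "four_point".
#' @return red-edge position in nm.
#' @export
redEdgePosition <- function(spectrum,
                            wavelengths = bandCenters(defaultSensor()),
                            method = c("max_derivative", "four_point")) {
  method <- match.arg(method)
  if (min(wavelengths) > 670 || max(wavelengths) < 780)
    stop("spectrum must cover 670-780 nm for red-edge estimation")
  if (method == "max_derivative") {
    d <- derivativeSpectrum(spectrum, wavelengths)
    win <- wavelengths >= 680 & wavelengths <= 760
    if (max(d[win]) <= 0)
      stop("undefined red-edge position: no positive slope in 680-760 nm")
    wavelengths[win][which.max(d[win])]
  } else {
    r670 <- sampleBand(spectrum, 670, wavelengths)
    r700 <- sampleBand(spectrum, 700, wavelengths)
    r740 <- sampleBand(spectrum, 740, wavelengths)
    r780 <- sampleBand(spectrum, 780, wavelengths)
    if (r740 == r700)
      stop("undefined red-edge position: flat 700-740 nm segment")
    700 + 40 * ((r670 + r780) / 2 - r700) / (r740 - r700)
  }
}

# Per-spectrum evaluation context handed to index formulas: nearest-band
# sampler R, lazily cached first derivative D and its window maxima, the
# continuum-removal summaries, and the red-edge estimators.
spectrumContext <- function(spectrum, wavelengths) {
  env <- new.env(parent = emptyenv())
  getD <- function() {
    if (is.null(env$d)) env$d <- derivativeSpectrum(spectrum, wavelengths)
    env$d
  }
  getCR <- function(lo, hi) {
    key <- paste0("cr", lo, "_", hi)
    if (is.null(env[[key]]))
      env[[key]] <- continuumRemoval(spectrum, wavelengths, c(lo, hi))
    env[[key]]
  }
  list(
    R = function(wl) sampleBand(spectrum, wl, wavelengths),
    D = function(wl) sampleBand(getD(), wl, wavelengths),
    maxD = function(lo, hi) {
      d <- getD(); win <- wavelengths >= lo & wavelengths <= hi
      max(d[win])
    },
    repMax = function() redEdgePosition(spectrum, wavelengths,
                                        "max_derivative"),
    rep4 = function() redEdgePosition(spectrum, wavelengths, "four_point"),
    crDepthAt = function(wl, lo, hi) {
      cr <- getCR(lo, hi)
      cr$depth[which.min(abs(cr$wavelengths - wl))]
    },
    crValueAt = function(wl, lo, hi) {
      cr <- getCR(lo, hi)
      cr$cr[which.min(abs(cr$wavelengths - wl))]
    },
    maxBandDepth = function(lo, hi) max(getCR(lo, hi)$depth),
    depthArea = function(lo, hi) {
      cr <- getCR(lo, hi)
      x <- cr$wavelengths; y <- cr$depth
      sum(diff(x) * (y[-1] + y[-length(y)]) / 2)   # trapezoid, nm units
    }
  )
}

#' Evaluate one vegetation index on a spectrum
#'
#' @param defn an index definition from [viRegistry()].
#' @param spectrum numeric reflectance values.
#' @param wavelengths numeric band grid.
#' @return numeric index value; non-finite results trigger a warning naming
#'   the index but are returned (never silently dropped).
#' @export
computeIndex <- function(defn, spectrum,
                         wavelengths = bandCenters(defaultSensor())) {
  ctx <- spectrumContext(spectrum, wavelengths)
  v <- tryCatch(defn$formula(ctx), error = function(e) NaN)
  if (!is.finite(v))
    warning(sprintf("index %s evaluated non-finite (division by zero?)",
                    defn$name))
  v
}

#' Evaluate the full index registry on a spectrum
#'
#' @param registry list of index definitions ([viRegistry()]).
#' @param spectrum numeric reflectance values.
#' @param wavelengths numeric band grid.
#' @return named numeric vector, one value per index in registry order;
#'   non-finite entries trigger a single warning naming the indices.
#' @export
computeAllIndices <- function(registry, spectrum,
                              wavelengths = bandCenters(defaultSensor())) {
  ctx <- spectrumContext(spectrum, wavelengths)
  out <- vapply(registry, function(d)
    tryCatch(d$formula(ctx), error = function(e) NaN), numeric(1))
  names(out) <- vapply(registry, `[[`, character(1), "name")
  bad <- names(out)[!is.finite(out)]
  if (length(bad))
    warning("non-finite index value(s): ", paste(bad, collapse = ", "))
  out
}

#' Unique band centers referenced by a registry
#'
#' Point wavelengths are snapped to the nearest band center; window-based
#' formulations (derivative maxima, continuum-removal ranges, red-edge
#' windows) contribute every band center inside their declared ranges.
#'
#' @param registry list of index definitions.
#' @param sensor a [SensorModel] defining the band grid.
#' @return sorted numeric vector of unique band centers in nm.
#' @export
registryWavelengths <- function(registry, sensor = defaultSensor()) {
  centers <- bandCenters(sensor)
  snap <- function(wl) centers[which.min(abs(centers - wl))]
  used <- numeric(0)
  for (d in registry) {
    if (length(d$wavelengths))
      used <- c(used, vapply(d$wavelengths, snap, numeric(1)))
    if (length(d$ranges))
      for (rg in d$ranges)
        used <- c(used, centers[centers >= rg[1L] & centers <= rg[2L]])
  }
  sort(unique(used))
}

#' Per-pixel vegetation-index cube
#'
#' Evaluates the registry on every masked-in pixel of a reflectance cube;
#' soil/nodata pixels propagate as NA.
#'
#' @param cube a [ReflectanceCube] on the sensor grid.
#' @param registry list of index definitions.
#' @param mask optional integer matrix; only pixels with mask > 0 are
#'   evaluated.
#' @return numeric lines x samples x indices array with index names on the
#'   third dimension.
#' @export
viCube <- function(cube, registry, mask = NULL) {
  stopifnot(is(cube, "ReflectanceCube"))
  wl <- bandCenters(cube)
  d <- dim(cube@data)
  nm <- vapply(registry, `[[`, character(1), "name")
  out <- array(NA_real_, c(d[1L], d[2L], length(registry)),
               dimnames = list(NULL, NULL, nm))
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    if (!is.null(mask) && mask[i, j] <= 0L) next
    s <- cube@data[i, j, ]
    if (anyNA(s)) next
    out[i, j, ] <- suppressWarnings(computeAllIndices(registry, s, wl))
  }
  out
}
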