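#' @include AllClasses.R sensor.R utils.R
NULL

# Truncated-Gaussian spectral-response weight matrix: rows = input grid,
# columns = sensor bands. sigma = FWHM / 2.3548; support +-3 sigma, clipped
# to the sensor span, renormalised.
srfWeights <- function(wavelengths, sensor) {
  centers <- bandCenters(sensor)
  sig <- fwhm(sensor) / 2.3548
  span <- range(centers)
  W <- matrix(0, length(wavelengths), length(centers))
  for (b in seq_along(centers)) {
    lo <- max(centers[b] - 3 * sig[b], span[1L])
    hi <- min(centers[b] + 3 * sig[b], span[2L])
    if (min(wavelengths) > lo + 1e-9 || max(wavelengths) < hi - 1e-9)
      stop(sprintf(
        "coverage error: input grid [%.1f, %.1f] nm does not cover the +-3 sigma support [%.1f, %.1f] of band %d (%.2f nm)",
        min(wavelengths), max(wavelengths), lo, hi, b, centers[b]))
    inside <- wavelengths >= lo & wavelengths <= hi
    w <- exp(-(wavelengths[inside] - centers[b])^2 / (2 * sig[b]^2))
    W[inside, b] <- w / sum(w)
  }
  W
}

#' Resample a 1-nm spectrum onto the sensor band grid
#'
#' Each output band is the normalised Gaussian-weighted average of the 1-nm
#' samples, with sigma = FWHM / 2.3548 and the spectral response truncated
#' at +-3 sigma (renormalised). Inputs extending beyond 400--1,000 nm (e.g.
#' full-range field spectroradiometer spectra) are cropped to the sensor
#' span first. The operator is linear in the spectrum.
#'
#' @param spectrum numeric vector on `wavelengths`, or a matrix with one
#'   spectrum per row.
#' @param sensor a [SensorModel].
#' @param wavelengths numeric input grid in nm (default [leafGrid()]).
#' @return numeric vector (or matrix) with one value per sensor band.
#' @examples
#' r <- gaussianResample(rep(0.3, 601))
#' length(r)      # 272
#' range(r)       # constant spectra are invariant
#' @export
gaussianResample <- function(spectrum, sensor = defaultSensor(),
                             wavelengths = leafGrid()) {
  isMat <- is.matrix(spectrum)
  m <- if (isMat) spectrum else matrix(spectrum, nrow = 1L)
  if (ncol(m) != length(wavelengths))
    stop("spectrum length must match the wavelength grid")
  span <- range(bandCenters(sensor))
  keep <- wavelengths >= span[1L] & wavelengths <= span[2L]
  m <- m[, keep, drop = FALSE]
  W <- srfWeights(wavelengths[keep], sensor)
  out <- m %*% W
  if (isMat) out else drop(out)
}

#' Fit the per-band empirical-line calibration
#'
#' Ordinary least squares of reflectance on radiance, one regression per
#' band, using the gray calibration panels: reflectance = gain * radiance +
#' offset. Exact on noise-free affine data; residuals on the fitting panels
#' are zero-mean by construction.
#'
#' @param panelRadiance numeric bands x panels matrix of at-sensor radiance.
#' @param panelReflectance numeric bands x panels matrix of known panel
#'   reflectances (a vector is recycled across bands).
#' @return list with `gains`, `offsets` (per band), `residuals`
#'   (bands x panels) and `rmse` per band.
#' @export
empiricalLineFit <- function(panelRadiance, panelReflectance) {
  if (is.vector(panelReflectance))
    panelReflectance <- matrix(panelReflectance, nrow(panelRadiance),
                               length(panelReflectance), byrow = TRUE)
  stopifnot(identical(dim(panelRadiance), dim(panelReflectance)))
  if (ncol(panelRadiance) < 2L)
    stop("at least 2 panels are required for the per-band regression")
  nb <- nrow(panelRadiance)
  gains <- offsets <- numeric(nb)
  for (b in seq_len(nb)) {
    x <- panelRadiance[b, ]; y <- panelReflectance[b, ]
    vx <- stats::var(x)
    if (!is.finite(vx) || vx < .Machine$double.eps * max(1, mean(x)^2))
      stop(sprintf(
        "rank deficiency: all panels have identical radiance in band %d", b))
    gains[b] <- stats::cov(x, y) / vx
    offsets[b] <- mean(y) - gains[b] * mean(x)
  }
  fitted <- panelRadiance * gains + offsets
  res <- panelReflectance - fitted
  list(gains = gains, offsets = offsets, residuals = res,
       rmse = sqrt(rowMeans(res^2)))
}

#' Apply an empirical-line calibration to a radiance cube
#'
#' Converts at-sensor radiance to surface reflectance per band; results
#' outside [0, 1] are clipped and counted.
#'
#' @param cube a [ReflectanceCube] holding radiance values.
#' @param gains,offsets numeric per-band calibration (length = band count).
#' @return list with `cube` (reflectance [ReflectanceCube]) and `nClipped`
#'   (count of clipped values).
#' @export
applyEmpiricalLine <- function(cube, gains, offsets) {
  stopifnot(is(cube, "ReflectanceCube"))
  nb <- dim(cube@data)[3L]
  if (length(gains) != nb || length(offsets) != nb)
    stop(sprintf("gains/offsets length (%d/%d) must equal band count (%d)",
                 length(gains), length(offsets), nb))
  refl <- sweep(sweep(cube@data, 3L, gains, "*"), 3L, offsets, "+")
  nClipped <- sum(refl < 0 | refl > 1, na.rm = TRUE)
  refl <- clamp01(refl)
  out <- cube
  out@data <- refl
  list(cube = out, nClipped = nClipped)
}

#' Savitzky--Golay smoothing of a spectrum
#'
#' Local least-squares polynomial smoothing; polynomial inputs of degree
#' <= `polyorder` are fixed points (including at the endpoints, which are
#' handled by one-sided polynomial fits).
#'
#' @param spectrum numeric vector.
#' @param window odd integer filter length in bands (> polyorder).
#' @param polyorder integer polynomial degree.
#' @return smoothed numeric vector of the same length.
#' @export
savgolSmooth <- function(spectrum, window = 11L, polyorder = 2L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window >= length(spectrum))
    stop(sprintf("window (%d) must be smaller than the spectrum length (%d)",
                 window, length(spectrum)))
  as.numeric(signal::sgolayfilt(spectrum, p = polyorder, n = window))
}

#' Savitzky--Golay smoothing of every cube pixel
#'
#' @param cube a [ReflectanceCube].
#' @param window,polyorder see [savgolSmooth()].
#' @return the smoothed [ReflectanceCube].
#' @export
smoothCube <- function(cube, window = 11L, polyorder = 2L) {
  stopifnot(is(cube, "ReflectanceCube"))
  d <- dim(cube@data)
  out <- cube
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    s <- cube@data[i, j, ]
    if (!anyNA(s)) out@data[i, j, ] <- savgolSmooth(s, window, polyorder)
  }
  out
}

# Pixels x bands matrix view of the cube (optionally under a mask).
cubeMatrix <- function(cube, mask = NULL) {
  d <- dim(cube@data)
  m <- matrix(cube@data, d[1L] * d[2L], d[3L])
  if (!is.null(mask)) m[as.vector(mask) > 0, , drop = FALSE] else m
}

#' Minimum-noise-fraction denoising of a cube
#'
#' Estimates the noise covariance from horizontal 1-pixel shift differences
#' (within the plant mask when given, avoiding soil/plant edges), computes
#' the noise-whitened principal components ordered by signal-to-noise, and
#' reconstructs the cube from the leading `k` components. With `k` equal to
#' the band count the transform is an isomorphism and reconstruction is
#' exact to numerical tolerance. When `k` is NULL, components with
#' noise-whitened eigenvalue > 1 are retained.
#'
#' @param cube a [ReflectanceCube].
#' @param k integer retained components, or NULL for the eigenvalue rule.
#' @param mask optional integer matrix; only pixels with mask > 0 inform
#'   the covariance estimates (the whole cube is still transformed).
#' @return list with `cube` (denoised), `eigenvalues` (noise-whitened,
#'   decreasing) and `k` (components retained).
#' @export
mnfDenoise <- function(cube, k = NULL, mask = NULL) {
  stopifnot(is(cube, "ReflectanceCube"))
  d <- dim(cube@data)
  nb <- d[3L]
  if (!is.null(k)) {
    if (k <= 0) stop("k must be positive")
    if (k > nb) stop("k cannot exceed the band count")
  }
  # horizontal shift differences for the noise estimate
  left <- cube@data[, -d[2L], , drop = FALSE]
  right <- cube@data[, -1L, , drop = FALSE]
  dif <- matrix(left - right, ncol = nb)
  if (!is.null(mask)) {
    ok <- as.vector(mask[, -ncol(mask)] > 0 & mask[, -1L] > 0)
    dif <- dif[ok, , drop = FALSE]
  }
  if (nrow(dif) < 2L)
    stop("not enough pixel pairs to estimate the noise covariance")
  Cn <- stats::cov(dif) / 2
  X <- cubeMatrix(cube)
  mu <- colMeans(X)
  Cs <- stats::cov(X)
  noiseScale <- mean(diag(Cn))
  if (noiseScale < .Machine$double.eps * mean(diag(Cs) + 1)) {
    warning("estimated noise covariance is (near) zero; returning the cube unchanged")
    return(list(cube = cube, eigenvalues = rep(Inf, nb), k = nb))
  }
  ridge <- 1e-10 * noiseScale
  ch <- tryCatch(chol(Cn), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular noise covariance; ridge regularization applied")
    ch <- chol(Cn + diag(1e-6 * noiseScale, nb))
  } else if (min(diag(ch))^2 < 1e-12 * noiseScale) {
    warning("ill-conditioned noise covariance; ridge regularization applied")
    ch <- chol(Cn + diag(ridge, nb))
  }
  Wn <- backsolve(ch, diag(nb))           # Cn^(-1/2), upper-tri inverse
  M <- crossprod(Wn, Cs %*% Wn)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  Tm <- Wn %*% eg$vectors                 # bands x comps forward transform
  if (is.null(k)) k <- max(1L, sum(eg$values > 1))
  Y <- sweep(X, 2L, mu) %*% Tm
  Tinv <- solve(Tm)
  Xr <- Y[, seq_len(k), drop = FALSE] %*% Tinv[seq_len(k), , drop = FALSE]
  Xr <- sweep(Xr, 2L, mu, "+")
  out <- cube
  out@data <- array(Xr, d)
  list(cube = out, eigenvalues = eg$values, k = k)
}
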