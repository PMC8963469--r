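test_that("Gaussian resampling yields 272 bands and preserves constants", {
  out <- gaussianResample(rep(0.3, 601))
  expect_length(out, 272L)
  expect_equal(out, rep(0.3, 272L), tolerance = 1e-12)
})

test_that("resampling a linear ramp matches brute-force SRF quadrature", {
  lam <- leafGrid()
  ramp <- (lam - 400) / 600
  out <- gaussianResample(ramp)
  sensor <- defaultSensor()
  centers <- bandCenters(sensor)
  # brute-force quadrature oracle with the same truncated-Gaussian SRF
  oracle <- vapply(seq_along(centers), function(b) {
    sig <- fwhm(sensor)[b] / 2.3548
    lo <- max(centers[b] - 3 * sig, 400); hi <- min(centers[b] + 3 * sig, 1000)
    inside <- lam >= lo & lam <= hi
    w <- exp(-(lam[inside] - centers[b])^2 / (2 * sig^2))
    sum(w * ramp[inside]) / sum(w)
  }, numeric(1))
  expect_equal(out, oracle, tolerance = 1e-10)
  # interior bands equal the ramp at the band center up to the 1-nm grid
  # discretization of the SRF (the weight grid is not exactly symmetric
  # around non-integer band centers)
  interior <- centers > 400 + 3 * 6 / 2.3548 & centers < 1000 - 3 * 6 / 2.3548
  expect_lt(max(abs(out[interior] - (centers[interior] - 400) / 600)), 5e-5)
})

test_that("resampling is linear and full-range inputs are cropped first", {
  set.seed(1)
  r1 <- runif(601); r2 <- runif(601)
  lhs <- gaussianResample(2 * r1 + 3 * r2)
  rhs <- 2 * gaussianResample(r1) + 3 * gaussianResample(r2)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # full spectroradiometer range 350-2500 nm: cropped, same result
  wlFull <- 350:2500
  spFull <- rep(0.25, length(wlFull))
  expect_equal(gaussianResample(spFull, wavelengths = wlFull),
               rep(0.25, 272L), tolerance = 1e-12)
})

test_that("insufficient spectral coverage raises a coverage error", {
  wl <- 500:1000
  expect_error(gaussianResample(rep(0.3, length(wl)), wavelengths = wl),
               "coverage")
})

test_that("empirical line is exact on affine data and matches normal equations", {
  nb <- 272L
  panels <- defaultPanelReflectances()
  reflPan <- matrix(panels, nb, 6L, byrow = TRUE)
  # identity: radiance equals reflectance
  fit <- empiricalLineFit(reflPan, reflPan)
  expect_equal(fit$gains, rep(1, nb), tolerance = 1e-12)
  expect_equal(fit$offsets, rep(0, nb), tolerance = 1e-12)
  # synthetic gain/offset recovered to <= 1e-10
  gains <- seq(2, 3, length.out = nb); offsets <- seq(0.05, 0.15,
                                                      length.out = nb)
  radPan <- sweep(sweep(reflPan, 1L, offsets, "-"), 1L, gains, "/")
  fit2 <- empiricalLineFit(radPan, reflPan)
  expect_lt(max(abs(fit2$gains - gains) / gains), 1e-10)
  expect_lt(max(abs(fit2$offsets - offsets)), 1e-10)
  # independently coded normal equations for one band
  b <- 100L
  x <- radPan[b, ]; y <- reflPan[b, ]
  A <- cbind(1, x)
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(fit2$offsets[b], beta[1L], tolerance = 1e-10)
  expect_equal(fit2$gains[b], beta[2L], tolerance = 1e-10)
  # rank deficiency: identical panels in one band
  bad <- radPan; bad[5L, ] <- 1
  expect_error(empiricalLineFit(bad, reflPan), "band 5")
})

test_that("applying the empirical line converts, clips and counts", {
  lay <- fieldLayout(nRows = 2L, nCols = 2L, nPlots = 1L, pxPerPlant = 1L)
  spads <- matrix(c(30, 40, 50, 60), 2, 2)
  nb <- 272L
  gains <- rep(2.5, nb); offsets <- rep(0.1, nb)
  rad <- simulateCube(lay, spads, seed = 2, noise = FALSE, mode = "radiance",
                      gains = gains, offsets = offsets)
  refl <- simulateCube(lay, spads, seed = 2, noise = FALSE)
  out <- applyEmpiricalLine(rad$cube, gains, offsets)
  expect_lt(max(abs(out$cube@data - refl$cube@data)), 1e-6)
  # identity calibration returns the input
  ident <- applyEmpiricalLine(refl$cube, rep(1, nb), rep(0, nb))
  expect_equal(ident$cube@data, refl$cube@data, tolerance = 1e-12)
  expect_identical(ident$nClipped, 0L)
  # negative results are clipped to 0 and counted
  neg <- applyEmpiricalLine(refl$cube, rep(1, nb), rep(-0.5, nb))
  expect_gt(neg$nClipped, 0L)
  expect_true(all(neg$cube@data >= 0))
  expect_error(applyEmpiricalLine(refl$cube, rep(1, 10L), rep(0, 10L)),
               "length")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and matches convolution", {
  x <- seq_len(101)
  quad <- 2 + 0.3 * x - 0.01 * x^2
  expect_equal(savgolSmooth(quad, 11L, 2L), quad, tolerance = 1e-9)
  expect_equal(savgolSmooth(rep(5, 50), 11L, 2L), rep(5, 50),
               tolerance = 1e-12)
  expect_error(savgolSmooth(quad, 10L, 2L), "odd")
  expect_error(savgolSmooth(quad, 3L, 3L), "polyorder")
  expect_error(savgolSmooth(rep(1, 5), 11L, 2L), "length")
  # interior values equal direct convolution with analytic SG coefficients
  set.seed(2)
  noisy <- quad + rnorm(101, 0, 0.5)
  sm <- savgolSmooth(noisy, 11L, 2L)
  # analytic projection coefficients: e1' (A'A)^-1 A' with A_ij = i^j
  offs <- -5:5
  A <- outer(offs, 0:2, "^")
  h <- (solve(t(A) %*% A, t(A)))[1L, ]
  direct <- vapply(6:96, function(i) sum(h * noisy[i + offs]), numeric(1))
  expect_equal(sm[6:96], direct, tolerance = 1e-9)
})

test_that("full-rank MNF reconstructs the cube; truncation denoises", {
  lay <- fieldLayout(nRows = 4L, nCols = 4L, nPlots = 1L, pxPerPlant = 3L)
  set.seed(5)
  spads <- matrix(runif(16, 25, 60), 4, 4)
  clean <- simulateCube(lay, spads, seed = 6, noise = FALSE)
  noisySd <- 0.01
  noisy <- clean$cube
  set.seed(7)
  noisy@data <- clean$cube@data +
    array(rnorm(length(clean$cube@data), 0, noisySd), dim(clean$cube@data))
  # full rank: isomorphism
  full <- suppressWarnings(mnfDenoise(noisy, k = 272L))
  relErr <- sqrt(mean((full$cube@data - noisy@data)^2)) /
    sqrt(mean(noisy@data^2))
  expect_lt(relErr, 1e-6)
  # truncation reduces MSE against the clean cube
  den <- suppressWarnings(mnfDenoise(noisy, k = 10L, mask = clean$mask))
  mseNoisy <- mean((noisy@data - clean$cube@data)^2)
  mseDen <- mean((den$cube@data - clean$cube@data)^2)
  expect_lt(mseDen, mseNoisy)
  # eigenvalues ordered by SNR and consistent with an independent
  # generalized-eigenvalue oracle
  expect_true(all(diff(den$eigenvalues) <= 1e-8))
  X <- matrix(noisy@data, prod(dim(noisy@data)[1:2]), 272L)
  d <- dim(noisy@data)
  dif <- matrix(noisy@data[, -d[2], ] - noisy@data[, -1, ], ncol = 272L)
  Cn <- cov(dif) / 2
  Cs <- cov(X)
  oracleEv <- sort(Re(eigen(solve(Cn + diag(1e-10 * mean(diag(Cn)), 272L),
                                  Cs))$values), decreasing = TRUE)
  got <- suppressWarnings(mnfDenoise(noisy, k = 272L))$eigenvalues
  expect_equal(got[1:20], oracleEv[1:20], tolerance = 1e-3)
  expect_error(mnfDenoise(noisy, k = 0L), "positive")
})

test_that("duplicate-pixel cubes (zero noise estimate) pass through with a warning", {
  sensor <- defaultSensor()
  one <- gaussianResample(simulateLeafSpectrum(40, noise = FALSE))
  a <- array(rep(one, each = 12L), c(3L, 4L, 272L))
  cube <- new("ReflectanceCube", data = a, sensor = sensor, pixelSize = 0.007,
              nodata = -9999)
  expect_warning(out <- mnfDenoise(cube, k = 5L), "unchanged|zero")
  expect_equal(out$cube@data, cube@data, tolerance = 1e-12)
})
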