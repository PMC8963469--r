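# Shared fixtures, built once per test run.

.fixtures <- new.env()

# default five-campaign sample table (drift on), memoized
sharedTable <- function() {
  if (is.null(.fixtures$table))
    .fixtures$table <- suppressWarnings(simulateSampleTable(seed = 101))
  .fixtures$table
}

sharedDataset <- function(set = "vis") {
  key <- paste0("ds_", set)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- suppressWarnings(makeDataset(sharedTable(), set))
  .fixtures[[key]]
}

# a small noise-free leaf spectrum on the sensor grid
leafSpectrum272 <- function(spad = 40, campaign = defaultCampaigns()[[1]]) {
  gaussianResample(simulateLeafSpectrum(spad, campaign = campaign,
                                        noise = FALSE))
}

# piecewise-linear fixture spectrum for closed-form index checks:
# fully specified, positive, with a green bump and a red-edge ramp
fixtureSpectrum <- function(wl = bandCenters(defaultSensor())) {
  stats::approx(x = c(400, 500, 550, 640, 680, 700, 740, 780, 900, 1000),
                y = c(0.08, 0.10, 0.22, 0.10, 0.06, 0.10, 0.40, 0.50,
                      0.48, 0.44),
                xout = wl)$y
}

# nearest-band lookup used by the independently coded index oracles
nearestValue <- function(spectrum, wl, grid = bandCenters(defaultSensor())) {
  spectrum[which.min(abs(grid - wl))]
}
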