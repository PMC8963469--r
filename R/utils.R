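# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# argument order matters: pmin/pmax take attributes (dims) from x
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# noisy leaf/panel pixels: floor at 1e-3 (sensor dark level) so ratio and
# continuum operators stay defined
clampRefl <- function(x) pmin(pmax(x, 0.001), 1)

# 1-nm wavelength grid of the synthetic leaf model / field spectra.
#' Native 1-nm wavelength grid (400--1,000 nm)
#' @return integer vector 400:1000 (nm).
#' @export
leafGrid <- function() 400:1000
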