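#' @include AllClasses.R sensor.R
NULL

# ENVI on-disk element order (fastest axis first):
#   bsq: sample, line, band   bil: sample, band, line   bip: band, sample, line
# In memory the cube is always [line, sample, band].

enviBase <- function(path) sub("\\.hdr$", "", path)

formatEnviList <- function(x, digits = 10) {
  paste0("{ ", paste(formatC(x, digits = digits, format = "g"),
                     collapse = ", "), " }")
}

writeEnviHeader <- function(path, lines, samples, bands, interleave,
                            pixelSize = NA, wavelength = NULL, fwhm = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ENVI", con)
  writeLines(sprintf("samples = %d", samples), con)
  writeLines(sprintf("lines = %d", lines), con)
  writeLines(sprintf("bands = %d", bands), con)
  writeLines("header offset = 0", con)
  writeLines("file type = ENVI Standard", con)
  writeLines("data type = 4", con)
  writeLines(sprintf("interleave = %s", interleave), con)
  writeLines("byte order = 0", con)
  if (!is.na(pixelSize))
    writeLines(sprintf("pixel size = { %g, %g }", pixelSize, pixelSize), con)
  if (!is.null(wavelength)) {
    writeLines("wavelength units = Nanometers", con)
    writeLines(paste("wavelength =", formatEnviList(wavelength)), con)
  }
  if (!is.null(fwhm))
    writeLines(paste("fwhm =", formatEnviList(fwhm)), con)
  invisible(path)
}

parseEnviHeader <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1L]))
    stop("not an ENVI header: ", path)
  # re-join multi-line { ... } values
  joined <- paste(txt[-1L], collapse = "\n")
  fields <- list()
  pat <- "(?s)([a-z ]+?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, joined, perl = TRUE)[[1L]]
  starts <- m; lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(joined, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("(?s)^([a-z ]+?)\\s*=.*$", "\\1", piece, perl = TRUE))
    val <- trimws(sub("(?s)^[a-z ]+?\\s*=\\s*", "", piece, perl = TRUE))
    fields[[key]] <- val
  }
  fields
}

enviNumericList <- function(val) {
  as.numeric(strsplit(gsub("[{}]", "", val), ",")[[1L]])
}

readEnviArray <- function(base, hdr) {
  lines <- as.integer(hdr[["lines"]]); samples <- as.integer(hdr[["samples"]])
  bands <- as.integer(hdr[["bands"]])
  dtype <- as.integer(hdr[["data type"]])
  if (is.na(dtype) || dtype != 4L)
    stop("unsupported ENVI data type (only 4 = float32 is handled): ", dtype)
  interleave <- tolower(hdr[["interleave"]])
  binPath <- paste0(base, ".dat")
  if (!file.exists(binPath)) binPath <- base
  if (!file.exists(binPath)) stop("binary image file not found for ", base)
  nExpect <- as.numeric(lines) * samples * bands
  nBytes <- file.info(binPath)$size
  if (nBytes != nExpect * 4)
    stop(sprintf(
      "corrupt file: %s declares %d x %d x %d float32 values (%d bytes) but holds %d bytes",
      binPath, lines, samples, bands, nExpect * 4, nBytes))
  raw <- readBin(binPath, "numeric", n = nExpect, size = 4L,
                 endian = "little")
  a <- switch(interleave,
    bsq = aperm(array(raw, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(raw, c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop("unknown interleave: ", interleave))
  a
}

#' Write a reflectance cube as an ENVI-style raster
#'
#' Emits `<base>.dat` (float32, little-endian, chosen interleave) and
#' `<base>.hdr` with the samples/lines/bands/interleave/data type/
#' wavelength/fwhm keys third-party ENVI readers need.
#'
#' @param cube a [ReflectanceCube].
#' @param path output base path (a trailing `.hdr` is stripped).
#' @param interleave "bsq", "bil" or "bip".
#' @return the base path, invisibly.
#' @seealso [readCube()]
#' @export
writeCube <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(is(cube, "ReflectanceCube"))
  interleave <- match.arg(interleave)
  base <- enviBase(path)
  d <- dim(cube@data)
  perm <- switch(interleave, bsq = c(2L, 1L, 3L), bil = c(2L, 3L, 1L),
                 bip = c(3L, 2L, 1L))
  writeBin(as.vector(aperm(cube@data, perm)), paste0(base, ".dat"),
           size = 4L, endian = "little")
  writeEnviHeader(paste0(base, ".hdr"), d[1L], d[2L], d[3L], interleave,
                  pixelSize = cube@pixelSize,
                  wavelength = bandCenters(cube), fwhm = fwhm(cube))
  invisible(base)
}

#' Read an ENVI-style reflectance cube
#'
#' Validates that the binary size matches the header declaration (corrupt
#' files are rejected) and that a wavelength list is present; BSQ, BIL and
#' BIP interleaves are normalised to the in-memory
#' lines x samples x bands layout.
#'
#' @param path header path or base path of the cube.
#' @return a [ReflectanceCube].
#' @export
readCube <- function(path) {
  base <- enviBase(path)
  hdrPath <- paste0(base, ".hdr")
  if (!file.exists(hdrPath)) stop("header not found: ", hdrPath)
  hdr <- parseEnviHeader(hdrPath)
  if (is.null(hdr[["wavelength"]]))
    stop("metadata error: header lacks a wavelength list: ", hdrPath)
  a <- readEnviArray(base, hdr)
  wl <- enviNumericList(hdr[["wavelength"]])
  fw <- if (!is.null(hdr[["fwhm"]])) enviNumericList(hdr[["fwhm"]])
        else rep(6, length(wl))
  px <- if (!is.null(hdr[["pixel size"]]))
    enviNumericList(hdr[["pixel size"]])[1L] else NA_real_
  new("ReflectanceCube", data = a,
      sensor = new("SensorModel", bandCenters = wl, fwhm = fw),
      pixelSize = px, nodata = -9999)
}

#' Write a single-band mask raster with the geometry of a cube
#'
#' @param mask integer/numeric matrix (lines x samples).
#' @param path output base path.
#' @param pixelSize numeric ground sampling distance in m.
#' @return the base path, invisibly.
#' @export
writeMask <- function(mask, path, pixelSize = NA) {
  base <- enviBase(path)
  writeBin(as.vector(t(mask)) * 1.0, paste0(base, ".dat"), size = 4L,
           endian = "little")
  writeEnviHeader(paste0(base, ".hdr"), nrow(mask), ncol(mask), 1L, "bsq",
                  pixelSize = pixelSize)
  invisible(base)
}

#' Read a single-band mask raster
#' @param path header path or base path.
#' @return integer matrix (lines x samples).
#' @export
readMask <- function(path) {
  base <- enviBase(path)
  hdr <- parseEnviHeader(paste0(base, ".hdr"))
  a <- readEnviArray(base, hdr)
  matrix(as.integer(round(a[, , 1L])), dim(a)[1L], dim(a)[2L])
}
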