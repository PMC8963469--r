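#' @include utils.R
NULL

sampleKeyCols <- c("campaign", "plant_id", "leaflet_id", "spad")

#' Wavelength columns of a sample table
#' @param table sample data.frame.
#' @return named numeric vector: wavelengths (nm) keyed by column name.
#' @export
spectrumColumns <- function(table) {
  cols <- grep("^w[0-9.]+$", names(table), value = TRUE)
  wl <- as.numeric(sub("^w", "", cols))
  names(wl) <- cols
  wl
}

checkSampleTable <- function(table) {
  missing <- setdiff(sampleKeyCols, names(table))
  if (length(missing))
    stop("schema error: sample table lacks column(s): ",
         paste(missing, collapse = ", "))
  wl <- spectrumColumns(table)
  if (!length(wl))
    stop("schema error: sample table has no wavelength columns (w<nm>)")
  if (any(is.na(wl)))
    stop("schema error: wavelength columns failed to parse as numbers")
  key <- paste(table$campaign, table$plant_id, table$leaflet_id)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (campaign, plant, leaflet) keys: ",
         paste(unique(key[duplicated(key)])[1:3], collapse = "; "))
  invisible(table)
}

#' Write a leaflet sample table as CSV
#'
#' UTF-8, '.' decimal separator; columns `campaign`, `plant_id`,
#' `leaflet_id`, `spad`, then one `w<nm>` column per wavelength.
#'
#' @param table sample data.frame ([simulateSampleTable()] layout).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSamples <- function(table, path) {
  checkSampleTable(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a leaflet sample table from CSV
#'
#' Validates the schema (SPAD column, parsable wavelength columns) and key
#' integrity (no duplicate campaign/plant/leaflet triples); campaign row
#' order is preserved.
#'
#' @param path CSV path.
#' @return data.frame sample table.
#' @export
readSamples <- function(path) {
  table <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                           colClasses = c(campaign = "character"))
  checkSampleTable(table)
  table
}

#' Per-campaign sample counts of a table
#' @param table sample data.frame.
#' @return named integer vector in campaign order of appearance.
#' @export
campaignCounts <- function(table) {
  lev <- unique(table$campaign)
  out <- vapply(lev, function(l) sum(table$campaign == l), integer(1))
  names(out) <- lev
  out
}
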