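#' @include indices-ops.R
NULL

# One registry entry. `wavelengths` are the point bands the formulation
# samples; `ranges` are windows whose every band participates (derivative
# maxima, continuum-removal hulls, red-edge search windows). `invariance`
# records the scale-invariance class asserted by the test-suite:
# "ratio" (invariant to R -> cR), "nd" (normalized difference, invariant,
# zero on flat spectra), "none".
vi <- function(name, group, wavelengths, formula, citation,
               ranges = list(), invariance = "none") {
  list(name = name, group = group, wavelengths = wavelengths,
       ranges = ranges, formula = formula, citation = citation,
       invariance = invariance)
}

#' The 60-index pigment vegetation-index registry
#'
#' Sixty vegetation indices correlated with leaf chlorophyll, arranged in
#' nine groups (broadband greenness, narrowband greenness, light-use
#' efficiency, senescence, stress on pigments, water content, reflectance-
#' based leaf chlorophyll, derivative-based leaf chlorophyll,
#' continuum-removed). Formulations follow the canonical cited sources;
#' entries marked "reconstruction" fill registry slots from the same index
#' families where no exact formulation is published. On the default
#' 272-band grid the registry references exactly 145 unique band centers
#' (see [registryWavelengths()]).
#'
#' @return list of 60 index definitions, each with `name`, `group`,
#'   `wavelengths`, `ranges`, `formula`, `citation`, `invariance`.
#' @examples
#' reg <- viRegistry()
#' length(reg)                                   # 60
#' length(registryWavelengths(reg))              # 145
#' @export
viRegistry <- function() {
  list(
    ## -- broadband greenness ------------------------------------------------
    vi("NDVI", "broadband_greenness", c(800, 670),
       function(s) (s$R(800) - s$R(670)) / (s$R(800) + s$R(670)),
       "Rouse et al. 1974", invariance = "nd"),
    vi("SRI", "broadband_greenness", c(800, 670),
       function(s) s$R(800) / s$R(670),
       "Jordan 1969", invariance = "ratio"),
    vi("EVI", "broadband_greenness", c(800, 670, 475),
       function(s) 2.5 * (s$R(800) - s$R(670)) /
         (s$R(800) + 6 * s$R(670) - 7.5 * s$R(475) + 1),
       "Huete et al. 2002"),
    vi("ARVI", "broadband_greenness", c(800, 670, 475),
       function(s) {
         rb <- 2 * s$R(670) - s$R(475)
         (s$R(800) - rb) / (s$R(800) + rb)
       },
       "Kaufman & Tanre 1992", invariance = "nd"),
    vi("LAI", "broadband_greenness", c(800, 670, 475),
       function(s) 3.618 * (2.5 * (s$R(800) - s$R(670)) /
         (s$R(800) + 6 * s$R(670) - 7.5 * s$R(475) + 1)) - 0.118,
       "Boegh et al. 2002"),

    ## -- narrowband greenness -----------------------------------------------
    vi("RENDVI", "narrowband_greenness", c(750, 705),
       function(s) (s$R(750) - s$R(705)) / (s$R(750) + s$R(705)),
       "Gitelson & Merzlyak 1994", invariance = "nd"),
    vi("mRENDVI", "narrowband_greenness", c(750, 705, 445),
       function(s) (s$R(750) - s$R(705)) /
         (s$R(750) + s$R(705) - 2 * s$R(445)),
       "Sims & Gamon 2002"),
    vi("mSR705", "narrowband_greenness", c(750, 705, 445),
       function(s) (s$R(750) - s$R(445)) / (s$R(705) - s$R(445)),
       "Sims & Gamon 2002"),
    vi("VREI1", "narrowband_greenness", c(740, 720),
       function(s) s$R(740) / s$R(720),
       "Vogelmann et al. 1993", invariance = "ratio"),
    vi("VREI2", "narrowband_greenness", c(734, 747, 715, 726),
       function(s) (s$R(734) - s$R(747)) / (s$R(715) + s$R(726)),
       "Vogelmann et al. 1993", invariance = "nd"),
    vi("VREI3", "narrowband_greenness", c(734, 747, 715, 720),
       function(s) (s$R(734) - s$R(747)) / (s$R(715) + s$R(720)),
       "Vogelmann et al. 1993", invariance = "nd"),
    vi("REPI4", "narrowband_greenness", c(670, 700, 740, 780),
       function(s) s$rep4(),
       "Guyot & Baret 1988 four-point interpolation"),
    vi("PSSRa", "narrowband_greenness", c(800, 680),
       function(s) s$R(800) / s$R(680),
       "Blackburn 1998", invariance = "ratio"),
    vi("PSNDa", "narrowband_greenness", c(800, 680),
       function(s) (s$R(800) - s$R(680)) / (s$R(800) + s$R(680)),
       "Blackburn 1998", invariance = "nd"),

    ## -- light-use efficiency -----------------------------------------------
    vi("PRI", "light_use_efficiency", c(531, 570),
       function(s) (s$R(531) - s$R(570)) / (s$R(531) + s$R(570)),
       "Gamon et al. 1992", invariance = "nd"),
    vi("SIPI", "light_use_efficiency", c(800, 445, 680),
       function(s) (s$R(800) - s$R(445)) / (s$R(800) - s$R(680)),
       "Penuelas et al. 1995", invariance = "ratio"),
    vi("RGRI", "light_use_efficiency", c(690, 550),
       function(s) s$R(690) / s$R(550),
       "Gamon & Surfus 1999 (band-ratio form)", invariance = "ratio"),

    ## -- senescence ----------------------------------------------------------
    vi("PSRI", "senescence", c(680, 500, 750),
       function(s) (s$R(680) - s$R(500)) / s$R(750),
       "Merzlyak et al. 1999", invariance = "ratio"),
    vi("NPQI", "senescence", c(415, 435),
       function(s) (s$R(415) - s$R(435)) / (s$R(415) + s$R(435)),
       "Barnes et al. 1992", invariance = "nd"),
    vi("NPCI", "senescence", c(680, 430),
       function(s) (s$R(680) - s$R(430)) / (s$R(680) + s$R(430)),
       "Penuelas et al. 1994", invariance = "nd"),
    vi("Ctr1", "senescence", c(695, 420),
       function(s) s$R(695) / s$R(420),
       "Carter 1994 stress ratio", invariance = "ratio"),

    ## -- stress on pigments ---------------------------------------------------
    vi("CRI1", "stress_pigments", c(510, 550),
       function(s) 1 / s$R(510) - 1 / s$R(550),
       "Gitelson et al. 2002"),
    vi("CRI2", "stress_pigments", c(510, 700),
       function(s) 1 / s$R(510) - 1 / s$R(700),
       "Gitelson et al. 2002"),
    vi("ARI1", "stress_pigments", c(550, 700),
       function(s) 1 / s$R(550) - 1 / s$R(700),
       "Gitelson et al. 2001"),
    vi("ARI2", "stress_pigments", c(800, 550, 700),
       function(s) s$R(800) * (1 / s$R(550) - 1 / s$R(700)),
       "Gitelson et al. 2001"),

    ## -- water content --------------------------------------------------------
    vi("WBI", "water_content", c(900, 970),
       function(s) s$R(900) / s$R(970),
       "Penuelas et al. 1997", invariance = "ratio"),
    vi("NWI3", "water_content", c(970, 880),
       function(s) (s$R(970) - s$R(880)) / (s$R(970) + s$R(880)),
       "Babar et al. 2006", invariance = "nd"),
    vi("NWI2", "water_content", c(970, 850),
       function(s) (s$R(970) - s$R(850)) / (s$R(970) + s$R(850)),
       "Babar et al. 2006", invariance = "nd"),

    ## -- leaf chlorophyll, reflectance-based ----------------------------------
    vi("SAVI", "chl_reflectance", c(800, 670),
       function(s) 1.5 * (s$R(800) - s$R(670)) / (s$R(800) + s$R(670) + 0.5),
       "Huete 1988"),
    vi("OSAVI", "chl_reflectance", c(800, 670),
       function(s) 1.16 * (s$R(800) - s$R(670)) / (s$R(800) + s$R(670) + 0.16),
       "Rondeaux et al. 1996"),
    vi("MCARI", "chl_reflectance", c(700, 670, 550),
       function(s) ((s$R(700) - s$R(670)) - 0.2 * (s$R(700) - s$R(550))) *
         (s$R(700) / s$R(670)),
       "Daughtry et al. 2000"),
    vi("MCARI_OSAVI", "chl_reflectance", c(700, 670, 550, 800),
       function(s) {
         mcari <- ((s$R(700) - s$R(670)) - 0.2 * (s$R(700) - s$R(550))) *
           (s$R(700) / s$R(670))
         osavi <- 1.16 * (s$R(800) - s$R(670)) / (s$R(800) + s$R(670) + 0.16)
         mcari / osavi
       },
       "Daughtry et al. 2000"),
    vi("TCARI", "chl_reflectance", c(700, 670, 550),
       function(s) 3 * ((s$R(700) - s$R(670)) -
         0.2 * (s$R(700) - s$R(550)) * (s$R(700) / s$R(670))),
       "Haboudane et al. 2002"),
    vi("TCARI_OSAVI", "chl_reflectance", c(700, 670, 550, 800),
       function(s) {
         tcari <- 3 * ((s$R(700) - s$R(670)) -
           0.2 * (s$R(700) - s$R(550)) * (s$R(700) / s$R(670)))
         osavi <- 1.16 * (s$R(800) - s$R(670)) / (s$R(800) + s$R(670) + 0.16)
         tcari / osavi
       },
       "Haboudane et al. 2002"),
    vi("MTVI2", "chl_reflectance", c(800, 550, 670),
       function(s) 1.5 * (1.2 * (s$R(800) - s$R(550)) -
         2.5 * (s$R(670) - s$R(550))) /
         sqrt((2 * s$R(800) + 1)^2 - (6 * s$R(800) - 5 * sqrt(s$R(670))) - 0.5),
       "Haboudane et al. 2004"),
    vi("GNDVI", "chl_reflectance", c(800, 550),
       function(s) (s$R(800) - s$R(550)) / (s$R(800) + s$R(550)),
       "Gitelson et al. 1996", invariance = "nd"),
    vi("NDCI1", "chl_reflectance", c(762, 527),
       function(s) (s$R(762) - s$R(527)) / (s$R(762) + s$R(527)),
       "Richardson et al. 2002", invariance = "nd"),
    vi("NDCI2", "chl_reflectance", c(720, 700),
       function(s) (s$R(720) - s$R(700)) / (s$R(720) + s$R(700)),
       "red-edge normalized-difference family (reconstruction)",
       invariance = "nd"),
    vi("CIgreen", "chl_reflectance", c(780, 550),
       function(s) s$R(780) / s$R(550) - 1,
       "Gitelson et al. 2003", invariance = "ratio"),
    vi("CIrededge", "chl_reflectance", c(780, 710),
       function(s) s$R(780) / s$R(710) - 1,
       "Gitelson et al. 2003", invariance = "ratio"),
    vi("MTCI", "chl_reflectance", c(754, 709, 681),
       function(s) (s$R(754) - s$R(709)) / (s$R(709) - s$R(681)),
       "Dash & Curran 2004", invariance = "ratio"),
    vi("Maccioni", "chl_reflectance", c(780, 710, 680),
       function(s) (s$R(780) - s$R(710)) / (s$R(780) - s$R(680)),
       "Maccioni et al. 2001", invariance = "ratio"),
    vi("TVI", "chl_reflectance", c(750, 550, 670),
       function(s) 0.5 * (120 * (s$R(750) - s$R(550)) -
         200 * (s$R(670) - s$R(550))),
       "Broge & Leblanc 2001"),

    ## -- leaf chlorophyll, derivative-based -----------------------------------
    vi("Datt", "chl_derivative", c(715, 705),
       function(s) s$D(715) / s$D(705),
       "Datt 1999 derivative ratio", invariance = "ratio"),
    vi("D720", "chl_derivative", 720,
       function(s) s$D(720),
       "first derivative at 720 nm"),
    vi("D730", "chl_derivative", 730,
       function(s) s$D(730),
       "first derivative at 730 nm"),
    vi("D700", "chl_derivative", 700,
       function(s) s$D(700),
       "first derivative at 700 nm"),
    vi("DSR1", "chl_derivative", c(725, 702),
       function(s) s$D(725) / s$D(702),
       "derivative simple ratio (le Maire et al. 2004)",
       invariance = "ratio"),
    vi("DSR2", "chl_derivative", c(735, 720),
       function(s) s$D(735) / s$D(720),
       "derivative simple ratio family (reconstruction)",
       invariance = "ratio"),
    vi("DPI", "chl_derivative", c(688, 710, 697),
       function(s) (s$D(688) * s$D(710)) / s$D(697)^2,
       "double-peak index (Zarco-Tejada et al. 2003)", invariance = "ratio"),
    vi("FDNDVI", "chl_derivative", c(730, 525),
       function(s) (s$D(730) - s$D(525)) / (s$D(730) + s$D(525)),
       "first-derivative normalized difference", invariance = "nd"),
    vi("EGFN", "chl_derivative", c(500, 550, 680, 760),
       function(s) {
         dre <- s$maxD(680, 760); dg <- s$maxD(500, 550)
         (dre - dg) / (dre + dg)
       },
       "edge-green first-derivative normalized ratio (Penuelas et al. 1994)",
       ranges = list(c(680, 760), c(500, 550)), invariance = "nd"),
    vi("EGFR", "chl_derivative", c(500, 550, 680, 760),
       function(s) s$maxD(680, 760) / s$maxD(500, 550),
       "edge-green first-derivative ratio (Penuelas et al. 1994)",
       ranges = list(c(680, 760), c(500, 550)), invariance = "ratio"),
    vi("REPmax", "chl_derivative", c(680, 760),
       function(s) s$repMax(),
       "maximum-first-derivative red-edge position",
       ranges = list(c(680, 760))),

    ## -- continuum-removed ----------------------------------------------------
    vi("MBD", "continuum_removed", c(520, 750),
       function(s) s$maxBandDepth(520, 750),
       "maximum band depth of the chlorophyll absorption feature",
       ranges = list(c(520, 750)), invariance = "ratio"),
    vi("AUC", "continuum_removed", c(520, 750),
       function(s) s$depthArea(520, 750),
       "area under the band-depth curve (520-750 nm)",
       ranges = list(c(520, 750)), invariance = "ratio"),
    vi("ANMB", "continuum_removed", c(520, 750),
       function(s) s$depthArea(520, 750) / s$maxBandDepth(520, 750),
       "area normalized to maximum band depth (Malenovsky et al. 2006)",
       ranges = list(c(520, 750)), invariance = "ratio"),
    vi("LPSDI", "continuum_removed", c(640, 660, 520, 750),
       function(s) s$crDepthAt(660, 520, 750) - s$crDepthAt(640, 520, 750),
       "leaf plant-stress detection index (reconstruction)",
       ranges = list(c(520, 750)), invariance = "ratio"),
    vi("CR670", "continuum_removed", c(670, 520, 750),
       function(s) s$crValueAt(670, 520, 750),
       "continuum-removed reflectance at 670 nm",
       ranges = list(c(520, 750)), invariance = "ratio"),
    vi("WBD970", "continuum_removed", c(970, 955, 985),
       function(s) s$maxBandDepth(955, 985),
       "continuum-removed depth of the 970 nm water feature (reconstruction)",
       ranges = list(c(955, 985)), invariance = "ratio")
  )
}

#' Registry as a machine-readable table
#'
#' @param registry list of index definitions (default [viRegistry()]).
#' @return data.frame with name, group, wavelengths (semicolon-joined),
#'   ranges, citation and invariance class.
#' @export
registryTable <- function(registry = viRegistry()) {
  data.frame(
    name = vapply(registry, `[[`, character(1), "name"),
    group = vapply(registry, `[[`, character(1), "group"),
    wavelengths = vapply(registry, function(d)
      paste(d$wavelengths, collapse = ";"), character(1)),
    ranges = vapply(registry, function(d)
      paste(vapply(d$ranges, function(rg) paste(rg, collapse = "-"),
                   character(1)), collapse = ";"), character(1)),
    citation = vapply(registry, `[[`, character(1), "citation"),
    invariance = vapply(registry, `[[`, character(1), "invariance"),
    stringsAsFactors = FALSE)
}
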