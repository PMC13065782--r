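# Domain constants: band registry, sensor codes, class registries,
# thematic cross-walk tables, tasseled-cap coefficients, base spectra
# used by the synthetic-scene generator.

#' Spectral band names used throughout the package
#' @export
BAND_NAMES <- c("blue", "green", "red", "nir", "swir1", "swir2")

# bands entering the medoid distance (green, red, NIR, SWIR1, SWIR2)
MEDOID_BANDS <- c("green", "red", "nir", "swir1", "swir2")

#' Sensor codes carried in QA provenance (Landsat 4-9, Sentinel-2a/b)
#' @export
SENSOR_CODES <- c(4L, 5L, 7L, 8L, 9L, 21L, 22L)

# spectral index / transform registry fed to temporal segmentation
INDEX_NAMES <- c(BAND_NAMES, "NDVI", "NBR", "NDMI", "NDSI",
                 "TCB", "TCG", "TCW", "TCA")

# direction in which vegetation recovery moves each index; used by the
# segmentation recovery-rate rule (+1 recovery increases the index)
INDEX_RECOVERY_SIGN <- c(
  blue = -1L, green = -1L, red = -1L, nir = 1L, swir1 = -1L, swir2 = -1L,
  NDVI = 1L, NBR = 1L, NDMI = 1L, NDSI = -1L,
  TCB = -1L, TCG = 1L, TCW = 1L, TCA = 1L)

# Tasseled-cap coefficients (Crist 1985 reflectance-factor set, TM bands
# 1-5,7). Configurable via the `coefs` argument of tasseledCap().
TC_COEFS <- rbind(
  TCB = c(0.2043, 0.4158, 0.5524, 0.5741, 0.3124, 0.2303),
  TCG = c(-0.1603, -0.2819, -0.4934, 0.7940, -0.0002, -0.1446),
  TCW = c(0.0315, 0.2021, 0.3102, 0.1594, -0.6806, -0.6109))
colnames(TC_COEFS) <- BAND_NAMES

#' Change-process classes of the joint response design
#' @export
CHANGE_PROCESSES <- c("Fire", "Harvest", "Mechanical", "Structural Decline",
                      "Spectral Decline", "Wind/Ice", "Hydrology", "Debris",
                      "Other", "Growth/Recovery", "Stable")

#' Land-cover classes of the joint response design
#' @export
COVER_CLASSES <- c("Tree", "Tall Shrub", "Shrub", "Grass/Forb/Herbaceous",
                   "Barren or Impervious", "Snow or Ice", "Water")

#' Land-use classes of the joint response design
#' @export
USE_CLASSES <- c("Agriculture", "Developed", "Forest", "Non-Forest Wetland",
                 "Other", "Rangeland or Pasture")

# cover succession ladder, lowest to highest
SUCCESSION <- c("Barren or Impervious" = 1L, "Grass/Forb/Herbaceous" = 2L,
                "Shrub" = 3L, "Tall Shrub" = 3L, "Tree" = 4L)

# --- Change cross-walk: change process -> Level 3 -> 2 -> 1 ----------------
CHANGE_XWALK <- data.frame(
  process = c("Structural Decline", "Spectral Decline", "Fire", "Harvest",
              "Mechanical", "Wind/Ice", "Hydrology", "Debris", "Other",
              "Growth/Recovery", "Stable"),
  level3 = c("Slow Loss", "Slow Loss", "Fast Loss", "Fast Loss", "Fast Loss",
             "Fast Loss", "Fast Loss", "Fast Loss", "Fast Loss",
             "Gain", "Stable"),
  level2 = c("Loss", "Loss", "Loss", "Loss", "Loss", "Loss", "Loss", "Loss",
             "Loss", "Gain", "Stable"),
  level1 = c("Loss", "Loss", "Loss", "Loss", "Loss", "Loss", "Loss", "Loss",
             "Loss", "Stable", "Stable"),
  stringsAsFactors = FALSE)

# --- Land-cover cross-walk: primary/secondary -> Level 4 -> 3 -> 2 -> 1 ----
LANDCOVER_XWALK <- data.frame(
  primary = c("Tree", "Tall Shrub", "Shrub", "Grass/Forb/Herbaceous",
              "Barren or Impervious", "Tall Shrub", "Shrub",
              "Grass/Forb/Herbaceous", "Barren or Impervious",
              "Grass/Forb/Herbaceous", "Barren or Impervious",
              "Barren or Impervious", "Snow or Ice", "Water"),
  secondary = c(NA, "Tree", "Tree", "Tree", "Tree", NA, NA, "Shrub", "Shrub",
                NA, "Grass/Forb/Herbaceous", NA, NA, NA),
  level4 = c("Tree", "Tall Shrub and Tree Mix", "Shrub and Tree Mix",
             "Grass/Forb/Herb and Tree Mix", "Barren and Tree Mix",
             "Tall Shrub", "Shrub", "Grass/Forb/Herb and Shrub Mix",
             "Barren and Shrub Mix", "Grass/Forb/Herb",
             "Barren and Grass/Forb/Herb Mix", "Barren or Impervious",
             "Snow or Ice", "Water"),
  level3 = c("Tree", "Tree", "Tree", "Tree", "Tree", "Shrub", "Shrub",
             "Shrub", "Shrub", "Grass/Forb/Herb", "Grass/Forb/Herb",
             "Barren or Impervious", "Snow or Ice", "Water"),
  level2 = c(rep("Tree Vegetated", 5), rep("Non-Tree Vegetated", 6),
             rep("Non-Vegetated", 3)),
  level1 = c(rep("Vegetated", 11), rep("Non-Vegetated", 3)),
  stringsAsFactors = FALSE)

# --- Land-use cross-walk: Level 3 -> 2 -> 1 --------------------------------
LANDUSE_XWALK <- data.frame(
  level3 = c("Agriculture", "Developed", "Forest", "Non-Forest Wetland",
             "Other", "Rangeland or Pasture"),
  level2 = c("Agriculture", "Developed", "Forest", "Other", "Other",
             "Rangeland or Pasture"),
  level1 = c("Anthropogenic", "Anthropogenic", "Non-Anthropogenic",
             "Non-Anthropogenic", "Non-Anthropogenic", "Non-Anthropogenic"),
  stringsAsFactors = FALSE)

# --- base reflectance spectra for the scene generator ----------------------
# columns follow BAND_NAMES; rows are cover archetypes
BASE_SPECTRA <- rbind(
  "Tree"                  = c(0.030, 0.050, 0.040, 0.450, 0.180, 0.090),
  "Tall Shrub"            = c(0.040, 0.070, 0.070, 0.380, 0.200, 0.110),
  "Shrub"                 = c(0.050, 0.080, 0.090, 0.320, 0.220, 0.130),
  "Grass/Forb/Herbaceous" = c(0.060, 0.100, 0.120, 0.350, 0.280, 0.180),
  "Barren or Impervious"  = c(0.120, 0.160, 0.200, 0.280, 0.350, 0.300),
  "Snow or Ice"           = c(0.800, 0.850, 0.800, 0.700, 0.100, 0.080),
  "Water"                 = c(0.060, 0.070, 0.050, 0.030, 0.020, 0.010))
colnames(BASE_SPECTRA) <- BAND_NAMES
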