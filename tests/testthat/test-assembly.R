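# Map assembly and the thematic cross-walks.

makeConfCube <- function(values, classes, product = "Change",
                         years = 2005L) {
  new("ConfidenceCube",
      values = array(values, c(nrow(values), 1, ncol(values)),
                     dimnames = list(NULL, years, classes)),
      classes = classes, product = product, years = years)
}

test_that("thresholded argmax picks the highest passing change class", {
  classes <- c("Fast Loss", "Slow Loss", "Gain", "Stable")
  conf <- matrix(c(0.35, 0.10, 0.05, 0.50), 1, dimnames = list(NULL, classes))
  cube <- makeConfCube(conf, classes)
  th <- c("Fast Loss" = 0.29, "Slow Loss" = 0.29, "Gain" = 0.29)
  m <- assembleMap(cube, thresholds = th, stable_class = "Stable")
  expect_identical(classRegistry(m)[classCodes(m)[1, 1]], "Fast Loss")
  # all change classes below threshold: stable fallback
  conf2 <- matrix(c(0.10, 0.10, 0.05, 0.75), 1,
                  dimnames = list(NULL, classes))
  m2 <- assembleMap(makeConfCube(conf2, classes), thresholds = th,
                    stable_class = "Stable")
  expect_identical(classRegistry(m2)[classCodes(m2)[1, 1]], "Stable")
})

test_that("a forbidding rule passes the win to the next eligible class", {
  classes <- c("Developed", "Forest")
  conf <- matrix(c(0.7, 0.3), 1, dimnames = list(NULL, classes))
  cube <- makeConfCube(conf, classes, product = "Land Use")
  rules <- list(list(class = "Developed", mask = "nodev",
                     action = "forbid"))
  masks <- list(nodev = matrix(TRUE, 1, 1))
  m <- assembleMap(cube, rules = rules, masks = masks)
  expect_identical(classRegistry(m)[classCodes(m)[1, 1]], "Forest")
  # same rule with the mask off leaves Developed in place
  m2 <- assembleMap(cube, rules = rules,
                    masks = list(nodev = matrix(FALSE, 1, 1)))
  expect_identical(classRegistry(m2)[classCodes(m2)[1, 1]], "Developed")
  # a rule naming an unknown mask is a configuration error
  expect_error(assembleMap(cube, rules = list(list(class = "Developed",
                                                   mask = "zzz",
                                                   action = "forbid")),
                           masks = masks), "unknown ancillary mask")
})

test_that("assembly with an empty ruleset equals thresholded argmax", {
  set.seed(40)
  classes <- c("Fast Loss", "Slow Loss", "Gain", "Stable")
  n <- 200
  raw <- matrix(runif(n * 4), n)
  conf <- raw / rowSums(raw)
  colnames(conf) <- classes
  th <- c("Fast Loss" = 0.29, "Slow Loss" = 0.25, "Gain" = 0.29)
  codes <- assembleRecords(conf, seq_len(n), thresholds = th,
                           stable_class = "Stable")
  oracle <- vapply(seq_len(n), function(i) {
    cand <- classes[1:3][conf[i, 1:3] >= th[classes[1:3]]]
    if (!length(cand)) return("Stable")
    cand[which.max(conf[i, cand])]
  }, character(1))
  expect_identical(classes[codes], oracle)
  # every assembled non-stable record meets its class threshold
  picked <- classes[codes]
  nz <- picked != "Stable"
  expect_true(all(conf[cbind(which(nz), match(picked[nz], classes))] >=
                    th[picked[nz]]))
})

test_that("change cross-walk follows the published binning", {
  expect_identical(crosswalkChange("Fire", 3), "Fast Loss")
  expect_identical(crosswalkChange("Fire", 2), "Loss")
  expect_identical(crosswalkChange("Fire", 1), "Loss")
  expect_identical(crosswalkChange("Growth/Recovery", 3), "Gain")
  expect_identical(crosswalkChange("Growth/Recovery", 1), "Stable")
  expect_identical(crosswalkChange(c("Structural Decline",
                                     "Spectral Decline"), 3),
                   c("Slow Loss", "Slow Loss"))
  expect_identical(crosswalkChange("Stable", 1), "Stable")
  # level-3 names roll down too, and composition equals the direct column
  for (p in CHANGE_PROCESSES) {
    expect_identical(crosswalkChange(crosswalkChange(p, 3), 1),
                     crosswalkChange(p, 1))
  }
  expect_error(crosswalkChange("Comet", 3), "unknown class")
})

test_that("land-cover cross-walk respects succession and never mixes water", {
  expect_identical(crosswalkLandCover("Shrub", "Tree"), "Shrub and Tree Mix")
  expect_identical(crosswalkLandCover("Shrub", "Tree", level = 3), "Tree")
  expect_identical(crosswalkLandCover("Shrub", "Tree", level = 2),
                   "Tree Vegetated")
  expect_identical(crosswalkLandCover("Shrub", "Tree", level = 1),
                   "Vegetated")
  expect_identical(crosswalkLandCover("Barren or Impervious",
                                      "Grass/Forb/Herbaceous"),
                   "Barren and Grass/Forb/Herb Mix")
  expect_identical(crosswalkLandCover("Barren or Impervious",
                                      "Grass/Forb/Herbaceous", level = 3),
                   "Grass/Forb/Herb")
  expect_identical(crosswalkLandCover("Tree"), "Tree")
  # lower-successional secondaries are ignored
  expect_identical(crosswalkLandCover("Tree", "Shrub"), "Tree")
  # the highest eligible secondary wins
  expect_identical(crosswalkLandCover("Grass/Forb/Herbaceous",
                                      list(c("Shrub", "Tree"))),
                   "Grass/Forb/Herb and Tree Mix")
  # water and snow never carry mixes
  expect_identical(crosswalkLandCover("Water", "Tree"), "Water")
  expect_identical(crosswalkLandCover("Snow or Ice", "Tree"), "Snow or Ice")
})

test_that("land-use cross-walk matches the published columns", {
  expect_identical(crosswalkLandUse("Non-Forest Wetland", 2), "Other")
  expect_identical(crosswalkLandUse("Non-Forest Wetland", 1),
                   "Non-Anthropogenic")
  expect_identical(crosswalkLandUse("Agriculture", 2), "Agriculture")
  expect_identical(crosswalkLandUse("Agriculture", 1), "Anthropogenic")
  expect_identical(crosswalkLandUse("Forest", 1), "Non-Anthropogenic")
  expect_error(crosswalkLandUse("Plaza", 2), "unknown class")
})

test_that("cross-walks are total and compose across levels", {
  # every level-4 land-cover class rolls down consistently
  l4 <- unique(crosswalkLandCover(COVER_CLASSES))
  for (x in l4) {
    l3 <- crosswalkLandCover(x, level = 3)
    l2 <- crosswalkLandCover(x, level = 2)
    l1 <- crosswalkLandCover(x, level = 1)
    expect_false(any(is.na(c(l3, l2, l1))))
  }
  for (u in USE_CLASSES) {
    expect_identical(crosswalkLandUse(crosswalkLandUse(u, 3), 1),
                     crosswalkLandUse(u, 1))
  }
})

test_that("map series cross-walking relabels codes consistently", {
  classes <- c("Fast Loss", "Gain", "Stable")
  codes <- matrix(c(1L, 2L, 3L, 1L), 2)
  m <- new("ClassMapSeries", codes = codes, classes = classes,
           product = "Change", level = 3L, years = c(2001L, 2002L))
  m1 <- crosswalkMapSeries(m, 1L)
  lab <- classRegistry(m1)[classCodes(m1)]
  expect_identical(lab, c("Loss", "Stable", "Stable", "Loss"))
})
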