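test_that("ImageVolume enforces its invariants", {
  v <- ImageVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 5))
  expect_identical(dim(v), c(4L, 4L, 2L))
  expect_identical(unname(voxelSpacing(v)), c(1, 1, 5))
  expect_error(ImageVolume(array(-1, c(2, 2, 2))), ">= 0")
  expect_error(ImageVolume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)))
  expect_error(ImageVolume(matrix(0, 3, 3)))
})

test_that("TIFF volumes load with ascending z and raw integer units", {
  set.seed(11)
  d <- array(sample(0:65535, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  path <- tempfile(fileext = ".tif")
  saveVolume(ImageVolume(d, spacing = c(1, 1, 2)), path)
  v <- loadVolume(path, spacing = c(1, 1, 2))
  expect_identical(dim(v), c(4L, 5L, 3L))
  # page-by-page reference read: page k must equal data[,,k]
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  for (k in 1:3) {
    expect_equal(imageData(v)[, , k], matrix(as.numeric(pages[[k]]), 4, 5))
    expect_equal(imageData(v)[, , k], d[, , k])
  }
  # loading does not mutate intensities
  expect_equal(sum(imageData(v)), sum(as.numeric(d)))
})

test_that("raw binary volumes round-trip losslessly with their sidecar", {
  set.seed(12)
  d <- array(rexp(6 * 4 * 5), c(6, 4, 5))
  path <- tempfile(fileext = ".bin")
  saveVolume(ImageVolume(d, spacing = c(0.5, 0.5, 2), name = "rawvol"), path)
  v <- loadVolume(path)           # spacing comes from the sidecar
  expect_identical(imageData(v), d)
  expect_identical(unname(voxelSpacing(v)), c(0.5, 0.5, 2))
  v2 <- loadVolume(path, spacing = c(1, 1, 1))   # explicit override wins
  expect_identical(unname(voxelSpacing(v2)), c(1, 1, 1))
})

test_that("volume loading reports missing files and bad metadata", {
  expect_error(loadVolume(tempfile(fileext = ".tif"), spacing = c(1, 1, 1)),
               "not found")
  path <- tempfile(fileext = ".tif")
  saveVolume(ImageVolume(array(0, c(2, 2, 1))), path)
  expect_error(loadVolume(path), "spacing")
  expect_error(loadVolume(path, spacing = c(1, -1, 1)), "positive")
})

test_that("detection records round-trip through CSV exactly", {
  rec <- randomDetectionRecord(50, seed = 99)
  path <- tempfile(fileext = ".csv")
  writeDetections(rec, path)
  back <- readDetections(path)
  expect_equal(nucleiTable(back), nucleiTable(rec), tolerance = 1e-12)
  expect_identical(volumeName(back), volumeName(rec))
  expect_equal(voxelSpacing(back), voxelSpacing(rec))
  expect_identical(back@configSnapshot$tag, "fixture")
})

test_that("empty records produce a header-only CSV and read back empty", {
  path <- tempfile(fileext = ".csv")
  writeDetections(DetectionRecord(), path)
  lines <- readLines(path)
  expect_identical(sum(!grepl("^#", lines)), 1L)
  expect_identical(nrow(nucleiTable(readDetections(path))), 0L)
})

test_that("single-nucleus record writes its fields verbatim", {
  rec <- DetectionRecord(data.frame(id = 1L, x = 10.5, y = 20.0, z = 3.0,
                                    diameter = 12.0, status = "seeded"))
  path <- tempfile(fileext = ".csv")
  writeDetections(rec, path)
  body <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  expect_identical(body[2], "1,10.5,20,3,12,seeded")
})

test_that("malformed detection rows are reported with line numbers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z,diameter,status",
               "1,1,2,3,4,seeded",
               "2,oops,2,3,4,seeded",
               "3,1,2,3,4,seeded"), path)
  expect_error(readDetections(path), "line 3")
  expect_identical(nrow(nucleiTable(readGroundTruth(
    textConnectionPath(c("id,x,y,z,diameter,status",
                         "1,1,2,3,4,truth",
                         "2,5,6,7,8,truth",
                         "3,9,9,9,4,truth"))))), 3L)
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("id,x,y,z,diameter,status", "1,1,2,3,4"), path2)
  expect_error(readDetections(path2), "6 fields")
})

test_that("configs and shape models serialize losslessly as JSON", {
  cfg <- detectionConfig(nuclearDiameter = 9.5, noiseThreshold = 3.25,
                         nRays = 12, priors = c(0.3, 0.7))
  p <- tempfile(fileext = ".json")
  saveConfig(cfg, p)
  back <- loadConfig(p)
  expect_equal(unclass(back), unclass(cfg))
  expect_error(loadConfig(tempfile()), "not found")

  m <- fixtureModel()
  pm <- tempfile(fileext = ".json")
  saveShapeModel(m, pm)
  m2 <- loadShapeModel(pm)
  expect_equal(m2@memberMean, m@memberMean)
  expect_equal(m2@memberCov, m@memberCov)
  expect_equal(m2@distractorCov, m@distractorCov)
  expect_equal(m2@priors, m@priors)
  expect_identical(m2@nTraining, m@nTraining)
})
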