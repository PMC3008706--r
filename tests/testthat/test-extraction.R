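# a single isolated nucleus rendered without modes/noise, for exact claims
isolatedScene <- function() {
  fixture("isolatedScene", function() {
    generateScene(sceneSpec(nNuclei = 1L, shape = c(40L, 40L, 16L),
                            centers = rbind(c(19, 19, 19)), radii = 3.5,
                            intensities = 100, modeCount = 0L, noiseSd = 0,
                            fading = 0, seed = 8))
  })
}

test_that("an isolated nucleus claims exactly its own slice stack", {
  scene <- isolatedScene()
  cfg <- fixtureConfig()
  model <- fixtureModel()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  expect_identical(nrow(seeds), 1L)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  info <- sliceInfo(slices)
  seedSlice <- info$id[info$z == seeds$z[1] & info$y == seeds$y[1] &
                         info$x == seeds$x[1]]
  ext <- extractNucleus(seedSlice, slices, model, cfg)
  # all member slices stack on the nuclear column, contiguous in z
  mem <- info[match(ext$memberSliceIds, info$id), ]
  expect_true(all(sqrt((mem$y - 19)^2 + (mem$x - 19)^2) < 3.5))
  expect_identical(as.integer(sort(mem$z)),
                   seq(min(mem$z), max(mem$z)))
  expect_gte(nrow(mem), 3)
  expect_identical(ext$nucleus$status, "seeded")
  expect_equal(ext$nucleus$diameter, 2 * max(mem$radius))
})

test_that("a seed with no claimable neighbors forms a single-slice nucleus", {
  scene <- isolatedScene()
  cfg <- fixtureConfig()
  filtered <- dogFilter(scene$volume, cfg)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  info <- sliceInfo(slices)
  # a lone synthetic slice set: keep only one plane
  lone <- new("SliceSet", info = info[info$z == info$z[1], , drop = FALSE],
              endpoints = sliceEndpoints(slices)[info$z == info$z[1]],
              spacing = voxelSpacing(slices))
  ext <- extractNucleus(sliceInfo(lone)$id[1], lone, fixtureModel(), cfg)
  expect_identical(length(ext$memberSliceIds), 1L)
})

test_that("extractAll is deterministic and claims all slices of clean scenes", {
  scene <- isolatedScene()
  cfg <- fixtureConfig()
  model <- fixtureModel()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  r1 <- extractAll(seeds, slices, model, cfg)
  r2 <- extractAll(seeds, slices, model, cfg)
  expect_identical(r1@claims, r2@claims)
  expect_identical(nrow(r1@nuclei), 1L)
  expect_identical(length(unclaimedSlices(r1)), 0L)
  # zero seeds: everything stays unclaimed
  r0 <- extractAll(seeds[0, ], slices, model, cfg)
  expect_identical(nrow(r0@nuclei), 0L)
  expect_identical(sort(unclaimedSlices(r0)), sort(sliceInfo(slices)$id))
})

test_that("a dim nucleus masked by a bright neighbor is recovered", {
  # stacked in z at zero boundary gap, 3x intensity ratio: the dim nucleus is
  # not a 3D maximum but its unclaimed slices seed recovery
  scene <- generateScene(sceneSpec(
    nNuclei = 2L, shape = c(64L, 64L, 20L),
    centers = rbind(c(32, 32, 20), c(32, 32, 27)),
    radii = 3.5, intensities = c(150, 50), modeCount = 0L, seed = 7))
  cfg <- fixtureConfig()
  model <- fixtureModel()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  r0 <- suppressWarnings(extractAll(seeds, slices, model, cfg))
  fnBefore <- matchDetections(scene$truth, resultRecordForTest(r0, scene))$falseNegatives
  r1 <- recoverOverlooked(r0, model, cfg)
  fnAfter <- matchDetections(scene$truth, resultRecordForTest(r1, scene))$falseNegatives
  if (nrow(seeds) == 1L) {
    expect_gte(r1@stageLog$nRecovered, 1L)
    expect_lt(fnAfter, fnBefore)
    expect_true("recovered" %in% r1@nuclei$status)
  } else {
    succeed("both nuclei seeded directly; nothing to recover")
  }
})

test_that("recovery leaves fully claimed results unchanged and ignores lone slices", {
  scene <- isolatedScene()
  cfg <- fixtureConfig()
  model <- fixtureModel()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  r0 <- extractAll(seeds, slices, model, cfg)
  r1 <- recoverOverlooked(r0, model, cfg)
  expect_identical(r1@nuclei$id, r0@nuclei$id)
  expect_identical(r1@stageLog$nRecovered, 0L)
  # one isolated unclaimed slice does not qualify as a cluster
  rLone <- extractAll(seeds[0, ],
                      new("SliceSet",
                          info = sliceInfo(slices)[1, , drop = FALSE],
                          endpoints = sliceEndpoints(slices)[1],
                          spacing = voxelSpacing(slices)),
                      model, cfg)
  rLone2 <- recoverOverlooked(rLone, model, cfg)
  expect_identical(nrow(rLone2@nuclei), 0L)
})

test_that("conflict resolution leaves non-overlapping results unchanged", {
  scene <- isolatedScene()
  cfg <- fixtureConfig()
  model <- fixtureModel()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  r0 <- extractAll(seeds, slices, model, cfg)
  r1 <- resolveConflicts(r0, model, cfg)
  expect_identical(r1@nuclei$id, r0@nuclei$id)
  expect_identical(r1@claims, r0@claims)
})

test_that("two adjacent nuclei disputing boundary slices split to the stronger claim", {
  # side-by-side in z with sub-plane gap: both seeds claim across the seam
  scene <- generateScene(sceneSpec(
    nNuclei = 2L, shape = c(64L, 64L, 20L),
    centers = rbind(c(32, 32, 20), c(32, 34, 28.2)),
    radii = 3.5, intensities = c(110, 100), modeCount = 0L, seed = 9))
  cfg <- fixtureConfig()
  model <- fixtureModel()
  det <- suppressWarnings(detectNuclei(scene$volume, model, cfg))
  # post-resolution invariants: unique claims, contiguity
  claims <- det@result@claims
  expect_identical(anyDuplicated(claims$sliceId), 0L)
  rep <- matchDetections(scene$truth, detectionRecord(det))
  expect_identical(rep$falseNegatives + rep$falsePositives, 0L)
})

test_that("infeasible splits fall back to merging", {
  # hand-built conflict where splitting cannot keep both nuclei contiguous:
  # nucleus A holds planes 1..3, nucleus B planes 1..3 with both centers on
  # plane 2 and every slice contested
  info <- data.frame(id = 1:3, y = 10, x = 10, z = 1:3, area = 28,
                     radius = 3, meanIntensity = 50, peakResponse = 10,
                     nRays = 16L, truncatedFrac = 0)
  slices <- new("SliceSet", info = info,
                endpoints = rep(list(cbind(y = c(7, 13, 13, 7),
                                           x = c(7, 7, 13, 13))), 3),
                spacing = c(x = 1, y = 1, z = 2.5))
  model <- fixtureModel()
  claims <- rbind(
    data.frame(sliceId = 1:3, nucleusId = 1L, logOdds = c(5, 15, 5)),
    data.frame(sliceId = 1:3, nucleusId = 2L, logOdds = c(6, 15, 6)))
  nuclei <- rbind(
    data.frame(id = 1L, centerSliceId = 2L, y = 10, x = 10, z = 2,
               diameter = 6, totalClaim = 25, status = "seeded"),
    data.frame(id = 2L, centerSliceId = 2L, y = 10, x = 10, z = 2,
               diameter = 6, totalClaim = 27, status = "seeded"))
  res <- new("SegmentationResult", slices = slices, nuclei = nuclei,
             members = list(`1` = 1:3, `2` = 1:3), claims = claims,
             stageLog = list())
  out <- resolveConflicts(res, model, fixtureConfig())
  expect_identical(nrow(out@nuclei), 1L)
  expect_identical(out@nuclei$status, "merged")
  expect_identical(anyDuplicated(out@claims$sliceId), 0L)
  expect_identical(out@stageLog$nMerged, 1L)
})

test_that("the full pipeline is deterministic and satisfies its invariants", {
  det1 <- fixtureBenchmarkDetection()
  det2 <- suppressWarnings(detectNuclei(fixtureBenchmarkScene()$volume,
                                        fixtureModel(), fixtureConfig()))
  expect_equal(nucleiTable(det1), nucleiTable(det2))
  claims <- det1@result@claims
  expect_identical(anyDuplicated(claims$sliceId), 0L)
  info <- sliceInfo(det1@result@slices)
  for (nid in det1@result@nuclei$id) {
    zz <- sort(info$z[match(det1@result@members[[as.character(nid)]],
                            info$id)])
    expect_identical(as.integer(zz), seq(zz[1], zz[length(zz)]))
  }
})

test_that("an empty volume detects nothing", {
  v <- ImageVolume(array(0, c(32, 32, 8)), spacing = c(1, 1, 2.5))
  det <- detectNuclei(v, fixtureModel(), fixtureConfig())
  expect_identical(nrow(nucleiTable(det)), 0L)
})
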