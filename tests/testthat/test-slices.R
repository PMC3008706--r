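test_that("ray casting recovers an analytic disk boundary at sub-pixel accuracy", {
  plane <- diskResponsePlane(31, c(16, 16), radius = 6)
  rays <- castRays(plane, c(16, 16), nRays = 16, maxLen = 12)
  expect_identical(nrow(rays), 16L)
  expect_true(all(abs(rays$length - 6) <= 0.25))
  expect_false(any(rays$truncated))
})

test_that("rays truncate at the maximum length on all-positive response", {
  plane <- matrix(1, 31, 31)
  rays <- castRays(plane, c(16, 16), nRays = 16, maxLen = 10)
  expect_true(all(rays$truncated))
  expect_true(all(rays$length == 10))
})

test_that("requested ray counts are honored and bad centers rejected", {
  plane <- diskResponsePlane(31, c(16, 16), radius = 5)
  expect_identical(nrow(castRays(plane, c(16, 16), nRays = 7, maxLen = 10)), 7L)
  expect_error(castRays(plane, c(40, 16), maxLen = 10), "outside")
  expect_error(castRays(plane, c(2, 2), maxLen = 10), "positive")
})

test_that("ray pruning follows the neighbor-median factor rule", {
  ep <- function(lens) {
    th <- 2 * pi * (seq_along(lens) - 1) / length(lens)
    data.frame(y = 10 + sin(th) * lens, x = 10 + cos(th) * lens,
               length = lens, truncated = FALSE)
  }
  expect_identical(nrow(pruneRays(ep(rep(5, 16)))), 16L)          # all equal
  pruned <- pruneRays(ep(c(rep(5, 8), 20, rep(5, 7))))            # one long
  expect_identical(nrow(pruned), 15L)
  expect_false(20 %in% pruned$length)
  expect_identical(nrow(pruneRays(ep(c(rep(5, 8), 4, rep(5, 7))))), 16L)
  short <- pruneRays(ep(c(rep(5, 8), 1, rep(5, 7))))              # one short
  expect_false(1 %in% short$length)
  expect_error(pruneRays(ep(c(3, 3))), "at least 3")
})

test_that("slice measurement matches closed-form polygon geometry", {
  th <- 2 * pi * (0:15) / 16
  r0 <- 6
  ep <- data.frame(y = 16 + r0 * sin(th), x = 16 + r0 * cos(th))
  raw <- matrix(7, 31, 31)
  filt <- diskResponsePlane(31, c(16, 16), radius = r0)
  sl <- buildSlice(c(16, 16, 3), ep, raw, filt)
  areaClosed <- 0.5 * 16 * r0^2 * sin(2 * pi / 16)
  expect_equal(sl$area, areaClosed, tolerance = 1e-9)
  expect_equal(sl$radius, sqrt(areaClosed / pi), tolerance = 1e-9)
  expect_equal(sl$meanIntensity, 7)
  expect_identical(sl$z, 3L)
})

test_that("interior mean intensity matches the brute-force point-in-polygon oracle", {
  set.seed(31)
  raw <- matrix(runif(31 * 31, 0, 50), 31, 31)
  raw[, 1:16] <- raw[, 1:16] + 100          # half-plane intensity pattern
  th <- 2 * pi * (0:15) / 16
  ep <- data.frame(y = 16 + (5 + runif(16, -1, 1)) * sin(th),
                   x = 16 + (5 + runif(16, -1, 1)) * cos(th))
  filt <- diskResponsePlane(31, c(16, 16), radius = 6)
  sl <- buildSlice(c(16, 16, 1), ep, raw, filt)
  expect_equal(sl$meanIntensity, oracleMeanIntensity(raw, ep$y, ep$x))
})

test_that("ray-cast radii track analytic disks within 5% across 3-15 px", {
  for (r0 in c(3, 5, 8, 11, 15)) {
    plane <- diskResponsePlane(41, c(21, 21), radius = r0)
    rays <- castRays(plane, c(21, 21), nRays = 16, maxLen = 20)
    expect_lt(abs(mean(rays$length) - r0) / r0, 0.05)
  }
})

test_that("polygon area is stable under rotation of an elliptical boundary", {
  areas <- vapply(seq(0, pi / 2, length.out = 5), function(phi) {
    n <- 41
    yy <- matrix(seq_len(n), n, n) - 21
    xx <- t(matrix(seq_len(n), n, n)) - 21
    u <- cos(phi) * xx + sin(phi) * yy
    v <- -sin(phi) * xx + cos(phi) * yy
    resp <- 1 - sqrt((u / 7)^2 + (v / 5)^2)    # rotated ellipse
    rays <- castRays(resp, c(21, 21), nRays = 16, maxLen = 20)
    sl <- buildSlice(c(21, 21, 1), rays, matrix(1, n, n), resp)
    sl$area
  }, numeric(1))
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.1)
})

test_that("segmentAllSlices covers every ground-truth cross-section of separated nuclei", {
  scene <- generateScene(sceneSpec(
    nNuclei = 5L, shape = c(96L, 96L, 16L), spacing = c(1, 1, 2.5),
    centers = rbind(c(20, 20, 15), c(20, 70, 25), c(70, 20, 20),
                    c(70, 70, 12), c(45, 45, 28)),
    radii = 3.5, intensities = 100, modeCount = 0L, seed = 5))
  cfg <- fixtureConfig()
  filtered <- dogFilter(scene$volume, cfg)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  info <- sliceInfo(slices)
  expect_gte(nrow(info), 14)
  mem <- scene$membership
  hit <- vapply(seq_len(nrow(mem)), function(i) {
    on <- info[info$z == mem$z[i], , drop = FALSE]
    any(sqrt((on$y - mem$y[i])^2 + (on$x - mem$x[i])^2) <= mem$radius[i])
  }, logical(1))
  expect_true(all(hit))
  # slices on ground-truth planes: one per nucleus per plane
  onTruth <- sum(vapply(seq_len(nrow(info)), function(i) {
    rows <- mem[mem$z == info$z[i], , drop = FALSE]
    any(sqrt((rows$y - info$y[i])^2 + (rows$x - info$x[i])^2) <= rows$radius)
  }, logical(1)))
  expect_gte(onTruth, nrow(mem) - 1)
  # every slice center is a 2D maximum of its plane
  m2 <- find2dMaxima(filtered, cfg$baseThreshold)
  expect_true(all(paste(info$y, info$x, info$z) %in%
                    paste(m2$y, m2$x, m2$z)))
})

test_that("a zero volume segments to an empty slice set", {
  v <- ImageVolume(array(0, c(24, 24, 6)), spacing = c(1, 1, 2.5))
  cfg <- detectionConfig(nuclearDiameter = 7, noiseThreshold = 2)
  slices <- segmentAllSlices(v, dogFilter(v, cfg), cfg)
  expect_identical(nrow(sliceInfo(slices)), 0L)
})

test_that("slice polygons export as a QC overlay CSV", {
  scene <- fixtureBenchmarkScene()
  cfg <- fixtureConfig()
  slices <- segmentAllSlices(scene$volume, dogFilter(scene$volume, cfg), cfg)
  p <- tempfile(fileext = ".csv")
  writeSliceOverlay(slices, p)
  ov <- read.csv(p)
  expect_setequal(unique(ov$sliceId), sliceInfo(slices)$id)
})
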