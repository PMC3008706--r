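mkSlice <- function(y, x, z, radius = 4, intensity = 50) {
  list(y = y, x = x, z = z, radius = radius, meanIntensity = intensity)
}

test_that("feature vectors behave analytically in forced cases", {
  ctr <- mkSlice(10, 10, 5)
  cand <- mkSlice(10, 10, 6)
  expect_equal(unname(computeFeatures(cand, ctr, ctr)), rep(0, 7) + c(1, rep(0, 6)))

  half <- mkSlice(10, 10, 4, radius = 2)
  f <- computeFeatures(half, ctr, ctr)
  expect_equal(unname(f),
               c(-1, 0, log(0.5), 0, 0, log(0.5), 0))
  expect_error(computeFeatures(mkSlice(10, 10, 5), ctr, ctr), "distinct planes")
  expect_error(computeFeatures(cand, mkSlice(10, 10, 5, radius = 0), ctr),
               "radius")
})

test_that("features match an independently coded formula on random slices", {
  set.seed(41)
  for (rep in 1:20) {
    ctr <- mkSlice(runif(1, 5, 20), runif(1, 5, 20), 5,
                   radius = runif(1, 2, 6), intensity = runif(1, 10, 90))
    dz <- sample(c(-3, -2, 2, 3), 1)
    cand <- mkSlice(runif(1, 5, 20), runif(1, 5, 20), 5 + dz,
                    radius = runif(1, 2, 6), intensity = runif(1, 10, 90))
    interv <- mkSlice(runif(1, 5, 20), runif(1, 5, 20), 5 + sign(dz),
                      radius = runif(1, 2, 6), intensity = runif(1, 10, 90))
    got <- computeFeatures(cand, ctr, interv)
    want <- c(cand$z - ctr$z,
              sqrt((cand$y - ctr$y)^2 + (cand$x - ctr$x)^2) / ctr$radius,
              log(cand$radius) - log(ctr$radius),
              log(cand$meanIntensity) - log(ctr$meanIntensity),
              sqrt((cand$y - interv$y)^2 + (cand$x - interv$x)^2) /
                interv$radius,
              log(cand$radius) - log(interv$radius),
              log(cand$meanIntensity) - log(interv$meanIntensity))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("features are invariant to a common intensity rescaling", {
  ctr <- mkSlice(10, 10, 5, radius = 4, intensity = 40)
  cand <- mkSlice(11, 12, 7, radius = 3, intensity = 25)
  interv <- mkSlice(10.5, 11, 6, radius = 3.6, intensity = 33)
  f1 <- computeFeatures(cand, ctr, interv)
  scale <- function(s, k) { s$meanIntensity <- s$meanIntensity * k; s }
  f2 <- computeFeatures(scale(cand, 17), scale(ctr, 17), scale(interv, 17))
  expect_equal(f1, f2, tolerance = 1e-12)
})

simTwoClass <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(49, 0, 0.2), 7, 7)
  memberCov <- crossprod(A) + diag(0.5, 7)
  B <- matrix(rnorm(49, 0, 0.3), 7, 7)
  distractorCov <- crossprod(B) + diag(0.8, 7)
  memberMean <- c(0, 0.2, -0.1, -0.3, 0.1, -0.1, -0.2)
  distractorMean <- c(-0.2, 1.5, 0, -0.2, 1.0, 0, -0.1)
  F <- rbind(MASS::mvrnorm(n, memberMean, memberCov),
             MASS::mvrnorm(n, distractorMean, distractorCov))
  list(features = F,
       labels = rep(c("member", "distractor"), each = n),
       memberMean = memberMean, memberCov = memberCov,
       distractorMean = distractorMean, distractorCov = distractorCov)
}

test_that("training recovers the generating Gaussians from 500 draws per class", {
  sim <- simTwoClass(500, seed = 42)
  m <- trainShapeModel(sim$features, sim$labels)
  se <- sqrt(diag(sim$memberCov) / 500)
  expect_true(all(abs(m@memberMean - sim$memberMean) < 3 * se))
  seD <- sqrt(diag(sim$distractorCov) / 500)
  expect_true(all(abs(m@distractorMean - sim$distractorMean) < 3 * seD))
  frob <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
  expect_lt(frob(m@memberCov, sim$memberCov), 0.15)
  expect_lt(frob(m@distractorCov, sim$distractorCov), 0.15)
  expect_equal(unname(m@priors), c(0.5, 0.5))
})

test_that("swapping labels swaps the class models exactly", {
  sim <- simTwoClass(60, seed = 43)
  m1 <- trainShapeModel(sim$features, sim$labels)
  swapped <- ifelse(sim$labels == "member", "distractor", "member")
  m2 <- trainShapeModel(sim$features, swapped)
  expect_equal(m1@memberMean, m2@distractorMean)
  expect_equal(m1@memberCov, m2@distractorCov)
  expect_equal(m1@distractorMean, m2@memberMean)
})

test_that("underpopulated classes fail with the class named", {
  sim <- simTwoClass(30, seed = 44)
  keep <- c(rep(TRUE, 30), rep(c(TRUE, FALSE), c(5, 25)))
  expect_error(trainShapeModel(sim$features[keep, ], sim$labels[keep]),
               "distractor")
  # degenerate duplicated examples train once the floor is relaxed
  f2 <- sim$features[c(1, 1, 31, 31), ]
  m <- trainShapeModel(f2, sim$labels[c(1, 1, 31, 31)], minPerClass = 2L)
  expect_true(all(diag(m@memberCov) > 0))          # ridge only
  expect_lt(max(abs(m@memberCov[upper.tri(m@memberCov)])), 1e-12)
})

test_that("classification is maximum likelihood with conservative ties", {
  sim <- simTwoClass(200, seed = 45)
  m <- trainShapeModel(sim$features, sim$labels)
  # equal covariances and priors: each class mean classifies as its own class
  m@distractorCov <- m@memberCov
  m@priors <- c(member = 0.5, distractor = 0.5)
  atMember <- classifySlice(m@memberMean, m)
  expect_identical(atMember$label, "member")
  expect_gt(atMember$logOdds, 0)
  atDistractor <- classifySlice(m@distractorMean, m)
  expect_identical(atDistractor$label, "distractor")
  expect_lt(atDistractor$logOdds, 0)
  # antisymmetry under swapping class models
  swapped <- new("ShapeModel", memberMean = m@distractorMean,
                 memberCov = m@distractorCov, distractorMean = m@memberMean,
                 distractorCov = m@memberCov,
                 priors = c(member = unname(m@priors["distractor"]),
                            distractor = unname(m@priors["member"])),
                 nTraining = m@nTraining, regularization = m@regularization)
  set.seed(46)
  for (i in 1:10) {
    f <- rnorm(7)
    expect_equal(classifySlice(f, m)$logOdds,
                 -classifySlice(f, swapped)$logOdds, tolerance = 1e-9)
  }
})

test_that("parameter estimates converge at roughly the 1/sqrt(n) rate", {
  errs <- vapply(c(100, 1000, 10000), function(n) {
    sim <- simTwoClass(n, seed = 47)
    m <- trainShapeModel(sim$features, sim$labels)
    sqrt(sum((m@memberMean - sim$memberMean)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_gt(errs[1] / errs[3], 3)   # ~sqrt(100) ideally; loose bound
})

test_that("training worksheets round-trip and feed training", {
  scene <- fixtureBenchmarkScene()
  cfg <- fixtureConfig()
  filtered <- dogFilter(scene$volume, cfg)
  seeds <- find3dMaxima(filtered, cfg$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, cfg)
  ws <- trainingCandidates(slices, seeds, cfg)
  expect_gt(nrow(ws), 0)
  expect_true(all(is.na(ws$label)))
  p <- tempfile(fileext = ".csv")
  writeWorksheet(ws, p)
  back <- readWorksheet(p)
  expect_identical(nrow(back), nrow(ws))          # candidate count preserved
  expect_equal(back$centerOffset, ws$centerOffset)
  # seeds with no nearby slices contribute no candidate rows
  lone <- trainingCandidates(slices,
                             data.frame(y = 1L, x = 1L, z = 1L,
                                        response = 10), cfg)
  expect_identical(nrow(lone), 0L)
})
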