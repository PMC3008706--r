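# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fixtureModel <- function() fixture("model", defaultShapeModel)

fixtureConfig <- function() fixture("config", function() {
  sceneConfig(sceneSpec())
})

fixtureBenchmarkScene <- function() fixture("benchmark", function() {
  generateScene(sceneSpec())
})

fixtureBenchmarkDetection <- function() fixture("benchmarkDet", function() {
  suppressWarnings(detectNuclei(fixtureBenchmarkScene()$volume,
                                fixtureModel(), fixtureConfig()))
})

# analytic disk response plane: positive inside `radius`, negative outside,
# linear across the boundary
diskResponsePlane <- function(n, center, radius, slope = 1) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  d <- sqrt((yy - center[1])^2 + (xx - center[2])^2)
  slope * (radius - d)
}

textConnectionPath <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}

randomDetectionRecord <- function(n, seed = 1, spacing = c(1, 1, 2.5)) {
  set.seed(seed)
  DetectionRecord(
    data.frame(id = seq_len(n),
               x = runif(n, 1, 100), y = runif(n, 1, 100),
               z = runif(n, 1, 20),
               diameter = runif(n, 4, 12),
               status = sample(c("seeded", "recovered", "merged"), n,
                               replace = TRUE)),
    volumeName = "random", spacing = spacing,
    configSnapshot = list(tag = "fixture"))
}

resultRecordForTest <- function(result, scene) {
  nz <- result@nuclei
  DetectionRecord(
    data.frame(id = nz$id, x = nz$x, y = nz$y, z = nz$z,
               diameter = nz$diameter, status = nz$status),
    volumeName = volumeName(scene$truth),
    spacing = voxelSpacing(scene$truth))
}
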