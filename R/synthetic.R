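#' Specification of a synthetic nuclear scene
#'
#' Describes a volume of blurred globular nuclei sampled on widely spaced z
#' planes, reproducing the difficulties of real optically sectioned data:
#' inter-nuclear intensity variation (dim nuclei masked by bright neighbors),
#' intra-nuclear intensity modes (uneven signal that splits detections),
#' z elongation of the blur (stretching along the light path), fading of
#' signal with depth, additive noise, and a controllable nearest-neighbor
#' boundary separation — the scene variable that predicts detection error.
#'
#' The default scene (25 nuclei, 128 x 128 x 20 voxels at 1 x 1 x 2.5
#' micrometers, separation 1.0 slice spacings, seed 42) is the package's
#' benchmark anchor.
#'
#' @param nNuclei number of nuclei.
#' @param shape volume dimensions (y, x, z) in voxels.
#' @param spacing micrometers per voxel step (x, y, z).
#' @param radiusMean,radiusSd nuclear radius distribution, micrometers.
#' @param separation target mean nearest-neighbor boundary separation in
#'   units of slice spacing; may be negative (interpenetrating bounding
#'   spheres) down to a hard floor of -0.5.
#' @param separationTol acceptable deviation of the realized mean separation
#'   (slice spacings, default 0.25).
#' @param intensityMean,intensitySd per-nucleus intensity distribution.
#' @param modeCount,modeAmplitude intra-nuclear intensity modes: count of
#'   bright sub-nuclear spots and their amplitude as a fraction of the
#'   nucleus intensity.
#' @param modePlacement \code{"random"} places modes uniformly inside the
#'   ellipsoid (general uneven signal); \code{"zBipolar"} places two modes at
#'   the upper and lower z poles, the asymmetry that splits a nucleus into
#'   redundant top/bottom detections.
#' @param axisRatioMax maximum semi-axis ratio of the ellipsoids (mild shape
#'   variability; default 1.2, capped at 1.5).
#' @param blurSigma optical blur, micrometers (in-plane).
#' @param elongation factor by which the blur is stretched along z (the
#'   axial point-spread width of confocal optics is typically 2-3 times the
#'   lateral width; default 2.5).
#' @param fading fractional intensity loss per plane with depth.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed random seed; fixes the scene exactly.
#' @param centers,radii,intensities optional explicit overrides (physical
#'   micrometers / micrometers / intensity units) for constructing exact test
#'   geometries; when \code{centers} is given placement sampling is skipped.
#' @return validated list of class \code{sceneSpec}.
#' @seealso [generateScene()], [generateBenchmarkSeries()]
#' @export
sceneSpec <- function(nNuclei = 25L,
                      shape = c(128L, 128L, 20L),
                      spacing = c(1, 1, 2.5),
                      radiusMean = 3.5, radiusSd = 0.5,
                      separation = 1.0, separationTol = 0.25,
                      intensityMean = 100, intensitySd = 30,
                      modeCount = 2L, modeAmplitude = 0.5,
                      modePlacement = c("random", "zBipolar"),
                      axisRatioMax = 1.2,
                      blurSigma = 1, elongation = 2.5,
                      fading = 0.02, noiseSd = 2,
                      seed = 42L,
                      centers = NULL, radii = NULL, intensities = NULL) {
  if (nNuclei < 0) stop("nNuclei must be >= 0")
  if (any(shape < 1)) stop("shape must be positive")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (radiusSd < 0 || intensitySd < 0 || noiseSd < 0)
    stop("standard deviations must be >= 0")
  if (separation < -0.5)
    stop("separation below -0.5 slice spacings defeats the notion of distinct nuclei")
  if (axisRatioMax < 1 || axisRatioMax > 1.5)
    stop("axisRatioMax must be in [1, 1.5]")
  if (fading < 0 || fading >= 1) stop("fading must be in [0, 1)")
  spec <- list(nNuclei = as.integer(nNuclei), shape = as.integer(shape),
               spacing = as.numeric(spacing), radiusMean = radiusMean,
               radiusSd = radiusSd, separation = separation,
               separationTol = separationTol, intensityMean = intensityMean,
               intensitySd = intensitySd, modeCount = as.integer(modeCount),
               modeAmplitude = modeAmplitude,
               modePlacement = match.arg(modePlacement),
               axisRatioMax = axisRatioMax,
               blurSigma = blurSigma, elongation = elongation,
               fading = fading, noiseSd = noiseSd, seed = as.integer(seed),
               centers = centers, radii = radii, intensities = intensities)
  class(spec) <- "sceneSpec"
  spec
}

# mean nearest-neighbor boundary separation (physical / z spacing) given
# physical centers (n x 3: y, x, z micrometers) and bounding radii
meanBoundarySeparation <- function(centers, R, zSpacing) {
  n <- nrow(centers)
  if (n < 2) return(NA_real_)
  sep <- vapply(seq_len(n), function(i) {
    d <- sqrt(rowSums(sweep(centers, 2, centers[i, ])^2)) - R - R[i]
    min(d[-i])
  }, numeric(1))
  unname(mean(sep) / zSpacing)
}

# Sequential placement: each nucleus after the first is set at boundary gap
# ~g from a randomly chosen anchor, rejecting positions that come closer
# than g to any other nucleus, so the realized nearest-neighbor separation
# tracks g.
placeCenters <- function(n, R, g, lo, hi, zSpacing, maxTries = 500L) {
  centers <- matrix(NA_real_, n, 3)
  centers[1, ] <- stats::runif(3, lo, hi)
  if (n == 1) return(centers)
  for (i in 2:n) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      j <- sample.int(i - 1L, 1L)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      gap <- g + stats::rnorm(1, 0, 0.2 * zSpacing)
      cand <- centers[j, ] + u * (R[i] + R[j] + gap)
      if (any(cand < lo | cand > hi)) next
      d <- sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE], 2,
                              cand)^2)) - R[seq_len(i - 1)] - R[i]
      if (any(d < min(gap, g) - 1e-9)) next
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("cannot place %d nuclei at boundary gap %.2f um in this volume; reduce density or separation",
                   n, g))
  }
  centers
}

#' Generate a synthetic volume with known ground truth
#'
#' Nucleus centers are placed by rejection sampling so that the realized mean
#' nearest-neighbor boundary separation lands within \code{separationTol}
#' slice spacings of the target (the gap is re-calibrated and placement
#' repeated when it does not). Each nucleus is rendered as an ellipsoidal
#' intensity blob with optional intra-nuclear bright modes, blurred
#' anisotropically (z width times the elongation factor), faded with depth,
#' and corrupted with additive Gaussian noise clamped at zero.
#'
#' @param spec a [sceneSpec()].
#' @return list with elements \code{volume} ([ImageVolume-class]),
#'   \code{truth} ([DetectionRecord-class], status \code{"truth"};
#'   coordinates in voxels, diameters in in-plane pixels),
#'   \code{membership} (data.frame of per-plane ground-truth cross-sections:
#'   nucleusId, z, y, x, radius — planes whose cross-section equivalent
#'   radius reaches 2 px), \code{geometry} (per-nucleus centers in voxels,
#'   semi-axes in micrometers, intensities), \code{spec} (the input spec),
#'   \code{clean} (pre-noise, pre-fading rendered array) and
#'   \code{realizedSeparation}.
#' @export
generateScene <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"))
  set.seed(spec$seed)
  n <- spec$nNuclei
  sp <- spec$spacing
  names(sp) <- c("x", "y", "z")
  xyRef <- mean(sp[c("x", "y")])
  shape <- spec$shape
  extent <- (shape - 1) * c(sp["y"], sp["x"], sp["z"])   # physical (y,x,z)

  radii <- if (!is.null(spec$radii)) rep_len(spec$radii, n) else
    pmax(0.5, stats::rnorm(n, spec$radiusMean, spec$radiusSd))
  # weakly expressing nuclei are several-fold dimmer than their neighbors,
  # not arbitrarily close to zero: floor the draw at a quarter of the mean
  intensities <- if (!is.null(spec$intensities))
    rep_len(spec$intensities, n) else
    pmax(0.25 * spec$intensityMean,
         stats::rnorm(n, spec$intensityMean, spec$intensitySd))
  # mild random semi-axis scales; z semi-axis uses the same radius scale
  ax <- matrix(stats::runif(3 * n, 1, spec$axisRatioMax), n, 3)
  ax <- ax / rowMeans(ax)
  semi <- radii * ax                                     # columns: y, x, z
  Rbound <- pmax(semi[, 1], semi[, 2])                   # largest-slice radius

  realized <- NA_real_
  if (!is.null(spec$centers)) {
    centers <- matrix(as.numeric(spec$centers), ncol = 3)
    realized <- meanBoundarySeparation(centers, Rbound, sp["z"])
  } else if (n > 0) {
    margin <- pmax(semi[, 1], semi[, 2], semi[, 3]) + 2 * spec$blurSigma
    lo <- max(margin); hi <- extent - max(margin)
    if (any(hi <= lo))
      stop("volume too small for the requested nuclei")
    g <- spec$separation * sp["z"]
    for (iter in seq_len(10L)) {
      centers <- placeCenters(n, Rbound, g, lo, hi, sp["z"])
      realized <- meanBoundarySeparation(centers, Rbound, sp["z"])
      if (n < 2 || abs(realized - spec$separation) <= spec$separationTol)
        break
      g <- g + (spec$separation - realized) * sp["z"]
      if (iter == 10L)
        stop(sprintf("could not realize separation %.2f (achieved %.2f)",
                     spec$separation, realized))
    }
  } else {
    centers <- matrix(numeric(), 0, 3)
  }

  clean <- array(0, shape)
  ys <- (seq_len(shape[1]) - 1) * sp["y"]
  xs <- (seq_len(shape[2]) - 1) * sp["x"]
  zs <- (seq_len(shape[3]) - 1) * sp["z"]
  for (i in seq_len(n)) {
    c0 <- centers[i, ]
    iy <- which(abs(ys - c0[1]) <= semi[i, 1])
    ix <- which(abs(xs - c0[2]) <= semi[i, 2])
    iz <- which(abs(zs - c0[3]) <= semi[i, 3])
    if (!length(iy) || !length(ix) || !length(iz)) next
    qy <- ((ys[iy] - c0[1]) / semi[i, 1])^2
    qx <- ((xs[ix] - c0[2]) / semi[i, 2])^2
    qz <- ((zs[iz] - c0[3]) / semi[i, 3])^2
    q <- outer(outer(qy, qx, "+"), qz, "+")
    blob <- ifelse(q <= 1, intensities[i], 0)
    if (spec$modeCount > 0 && spec$modeAmplitude > 0) {
      for (m in seq_len(spec$modeCount)) {
        if (spec$modePlacement == "zBipolar") {
          # alternate between the upper and lower z pole
          u <- c(0, 0, if (m %% 2 == 1) 1 else -1)
          rho <- 0.55
        } else {
          # mode center uniform inside 60% of the ellipsoid
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          rho <- 0.6 * stats::runif(1)^(1 / 3)
        }
        mc <- c0 + u * rho * semi[i, ]
        sig <- 0.35 * min(semi[i, ])
        d2 <- outer(outer((ys[iy] - mc[1])^2, (xs[ix] - mc[2])^2, "+"),
                    (zs[iz] - mc[3])^2, "+")
        blob <- blob + ifelse(q <= 1,
                              spec$modeAmplitude * intensities[i] *
                                exp(-d2 / (2 * sig^2)), 0)
      }
    }
    clean[iy, ix, iz] <- clean[iy, ix, iz, drop = FALSE] + blob
  }

  sigmaVox <- c(y = spec$blurSigma / sp["y"], x = spec$blurSigma / sp["x"],
                z = spec$blurSigma * spec$elongation / sp["z"])
  blurred <- gaussianSmooth3d(clean, pmax(sigmaVox, 0.2))
  if (spec$fading > 0) {
    for (k in seq_len(shape[3]))
      blurred[, , k] <- blurred[, , k] * (1 - spec$fading)^(k - 1)
  }
  noisy <- blurred
  if (spec$noiseSd > 0)
    noisy <- noisy + array(stats::rnorm(length(noisy), 0, spec$noiseSd),
                           dim = shape)
  noisy <- pmax(noisy, 0)

  volume <- ImageVolume(noisy, spacing = sp,
                        name = sprintf("synthetic-seed%d", spec$seed))

  truth <- if (n > 0) {
    data.frame(id = seq_len(n),
               x = centers[, 2] / sp["x"] + 1,
               y = centers[, 1] / sp["y"] + 1,
               z = centers[, 3] / sp["z"] + 1,
               diameter = 2 * Rbound / xyRef,
               status = "truth")
  } else emptyNucleiTable()
  truthRec <- DetectionRecord(truth, volumeName = volume@name, spacing = sp,
                              configSnapshot = list(seed = spec$seed))

  membership <- list()
  for (i in seq_len(n)) {
    for (k in seq_len(shape[3])) {
      t <- (zs[k] - centers[i, 3]) / semi[i, 3]
      if (abs(t) >= 1) next
      f <- sqrt(1 - t^2)
      radPx <- f * Rbound[i] / xyRef
      if (radPx < 2) next
      membership[[length(membership) + 1L]] <- data.frame(
        nucleusId = i, z = k,
        y = centers[i, 1] / sp["y"] + 1, x = centers[i, 2] / sp["x"] + 1,
        radius = radPx)
    }
  }
  membership <- if (length(membership)) do.call(rbind, membership) else
    data.frame(nucleusId = integer(), z = integer(), y = numeric(),
               x = numeric(), radius = numeric())

  geometry <- if (n > 0) {
    data.frame(id = seq_len(n),
               y = centers[, 1] / sp["y"] + 1,
               x = centers[, 2] / sp["x"] + 1,
               z = centers[, 3] / sp["z"] + 1,
               semiY = semi[, 1], semiX = semi[, 2], semiZ = semi[, 3],
               intensity = intensities)
  } else {
    data.frame(id = integer(), y = numeric(), x = numeric(), z = numeric(),
               semiY = numeric(), semiX = numeric(), semiZ = numeric(),
               intensity = numeric())
  }

  list(volume = volume, truth = truthRec, membership = membership,
       geometry = geometry, spec = spec, clean = clean,
       realizedSeparation = realized)
}

#' Benchmark series over a range of separations
#'
#' One scene per requested separation, all other parameters held fixed; the
#' per-scene seed is offset from the base seed so scenes are independent yet
#' reproducible. Used to trace the detection-error-versus-separation curve.
#'
#' @param separations numeric vector of target separations (slice spacings).
#' @param baseSpec a [sceneSpec()] providing all other parameters.
#' @return list of scenes as returned by [generateScene()].
#' @export
generateBenchmarkSeries <- function(separations, baseSpec = sceneSpec()) {
  lapply(seq_along(separations), function(i) {
    spec <- baseSpec
    spec$separation <- separations[i]
    spec$seed <- baseSpec$seed + i
    generateScene(spec)
  })
}

# Assign each segmented slice to the ground-truth nucleus that generated its
# signal: first by containment in the geometric cross-section on the same
# plane; slices on blur-fringe planes (the optical blur extends a nucleus's
# image beyond its geometric z extent) fall back to the nearest nucleus whose
# blurred footprint can reach them. NA when no nucleus accounts for the slice.
assignSlicesToTruth <- function(slices, scene) {
  info <- sliceInfo(slices)
  membership <- scene$membership
  geom <- scene$geometry
  sp <- voxelSpacing(scene$volume)
  blurZ <- scene$spec$blurSigma * scene$spec$elongation
  vapply(seq_len(nrow(info)), function(i) {
    rows <- membership[membership$z == info$z[i], , drop = FALSE]
    if (nrow(rows)) {
      d <- sqrt((rows$y - info$y[i])^2 + (rows$x - info$x[i])^2)
      ok <- d <= rows$radius
      if (any(ok))
        return(as.integer(rows$nucleusId[ok][which.min(d[ok])]))
    }
    if (is.null(geom) || !nrow(geom)) return(NA_integer_)
    dxy <- sqrt(((geom$y - info$y[i]) * sp["y"])^2 +
                  ((geom$x - info$x[i]) * sp["x"])^2)
    dz <- abs(geom$z - info$z[i]) * sp["z"]
    reach <- dxy <= pmax(geom$semiY, geom$semiX) &
      dz <= geom$semiZ + 2 * blurZ
    if (!any(reach)) return(NA_integer_)
    cand <- which(reach)
    as.integer(geom$id[cand[which.min(dxy[cand] + dz[cand])]])
  }, integer(1))
}

#' Auto-labeled training data from a synthetic scene
#'
#' Runs filtering and slice segmentation on the scene, builds the candidate
#' worksheet exactly as [trainingCandidates()] would for manual labeling, and
#' fills the labels from ground truth: a candidate is a \code{member} when its
#' slice belongs to the same ground-truth nucleus as the center slice, a
#' \code{distractor} otherwise. Candidate pairs whose center slice matches no
#' ground-truth nucleus are dropped.
#'
#' @param scene a scene from [generateScene()].
#' @param config a [detectionConfig()].
#' @return list with \code{features} (matrix), \code{labels} (character) and
#'   \code{worksheet} (the labeled data.frame).
#' @export
sceneTrainingLabels <- function(scene, config = detectionConfig()) {
  filtered <- dogFilter(scene$volume, config)
  seeds <- find3dMaxima(filtered, config$noiseThreshold)
  slices <- segmentAllSlices(scene$volume, filtered, config)
  ws <- trainingCandidates(slices, seeds, config)
  owner <- assignSlicesToTruth(slices, scene)
  info <- sliceInfo(slices)
  ctrOwner <- owner[match(ws$centerSliceId, info$id)]
  candOwner <- owner[match(ws$candidateSliceId, info$id)]
  keep <- !is.na(ctrOwner)
  ws <- ws[keep, , drop = FALSE]
  ws$label <- ifelse(!is.na(candOwner[keep]) &
                       candOwner[keep] == ctrOwner[keep],
                     "member", "distractor")
  fl <- worksheetFeatures(ws)
  list(features = fl$features, labels = fl$labels, worksheet = ws)
}

#' Configuration matched to a synthetic scene
#'
#' The analog of tuning the two key parameters on a reference frame: the
#' nuclear diameter is taken from the scene's radius distribution and the
#' noise threshold is set relative to the scene intensity scale so that
#' bright nuclei seed 3D maxima while dim-nucleus slices still clear the
#' 2D base threshold.
#'
#' @param spec a [sceneSpec()].
#' @param ... overrides forwarded to [detectionConfig()].
#' @return a [detectionConfig()].
#' @export
sceneConfig <- function(spec, ...) {
  xyRef <- mean(spec$spacing[1:2])
  args <- list(nuclearDiameter = 2 * spec$radiusMean / xyRef,
               noiseThreshold = 0.02 * spec$intensityMean)
  override <- list(...)
  args[names(override)] <- override
  do.call(detectionConfig, args)
}
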