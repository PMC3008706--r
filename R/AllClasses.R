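#' @import methods
NULL

#' ImageVolume: a single-channel 3D intensity volume
#'
#' Container for an optically sectioned fluorescence volume. Voxel data are
#' stored as a 3D array indexed \code{[y, x, z]} (rows are y, columns are x,
#' the third dimension runs over optical sections in ascending z). Voxel
#' coordinates throughout the package are 1-based, and the physical position
#' of voxel \code{v} along an axis is \code{(v - 1) * spacing} micrometers.
#'
#' @slot data numeric 3D array of non-negative intensities, indexed (y, x, z).
#' @slot spacing named numeric of length 3 (\code{x}, \code{y}, \code{z}):
#'   physical micrometers per voxel step. z spacing is typically larger than
#'   x/y (anisotropic optical sectioning); the ratio is carried, never assumed
#'   equal to one.
#' @slot name free-text identifier.
#'
#' @seealso [loadVolume()], [dogFilter()]
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", name = "character"))

setValidity("ImageVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array (y, x, z)")
  if (any(dim(d) < 1L)) return("all three dimensions must be >= 1")
  if (!all(is.finite(d))) return("all intensities must be finite")
  if (any(d < 0)) return("all intensities must be >= 0")
  s <- object@spacing
  if (length(s) != 3L || !all(is.finite(s)) || any(s <= 0))
    return("spacing must be 3 positive reals (x, y, z)")
  if (!identical(names(s), c("x", "y", "z")))
    return("spacing must be named c(x=, y=, z=)")
  TRUE
})

#' FilteredVolume: Difference-of-Gaussians response of an ImageVolume
#'
#' Signed band-pass response sharing the source volume's geometry. The DoG
#' kernel acts as a matched filter for a blurred globular object against a
#' dark background: its response is positive inside nucleus-scaled blobs,
#' negative just outside, and (near) zero over constant regions, so nuclear
#' boundaries appear as zero crossings.
#'
#' @slot response numeric 3D array, same shape as the source data.
#' @slot sigmaInner,sigmaOuter named numeric of length 3 (\code{y},
#'   \code{x}, \code{z}): per-axis Gaussian widths in voxels.
#' @slot spacing voxel spacing inherited from the source.
#' @slot sourceName identifier of the source volume.
#'
#' @seealso [dogFilter()], [find3dMaxima()], [find2dMaxima()]
#' @export
setClass("FilteredVolume",
  representation(response = "array", sigmaInner = "numeric",
                 sigmaOuter = "numeric", spacing = "numeric",
                 sourceName = "character"))

setValidity("FilteredVolume", function(object) {
  if (length(dim(object@response)) != 3L)
    return("response must be a 3D array")
  for (nm in c("sigmaInner", "sigmaOuter")) {
    s <- slot(object, nm)
    if (length(s) != 3L || any(!is.finite(s)) || any(s <= 0))
      return(sprintf("%s must be 3 positive reals", nm))
  }
  TRUE
})

#' SliceSet: polygonal nuclear cross-sections segmented from one volume
#'
#' One row of \code{info} per retained slice: \code{id}, center voxel
#' coordinates \code{y}, \code{x} (real) and plane \code{z} (integer),
#' polygon \code{area} (px^2), \code{radius} (equivalent radius
#' \code{sqrt(area/pi)}, px), \code{meanIntensity} (raw-image units over the
#' polygon interior), \code{peakResponse} (filtered units at the center),
#' \code{nRays} (surviving ray endpoints) and \code{truncatedFrac}.
#' \code{endpoints} holds, per slice, a matrix of boundary vertices
#' (columns \code{y}, \code{x}) in angular order.
#'
#' @slot info data.frame as described above.
#' @slot endpoints list of numeric matrices, parallel to \code{info} rows.
#' @slot spacing voxel spacing of the source volume.
#'
#' @seealso [segmentAllSlices()], [sliceInfo()], [sliceEndpoints()]
#' @export
setClass("SliceSet",
  representation(info = "data.frame", endpoints = "list",
                 spacing = "numeric"))

setValidity("SliceSet", function(object) {
  need <- c("id", "y", "x", "z", "area", "radius", "meanIntensity",
            "peakResponse", "nRays", "truncatedFrac")
  if (!all(need %in% names(object@info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@info) != length(object@endpoints))
    return("endpoints list must parallel info rows")
  if (anyDuplicated(object@info$id)) return("slice ids must be unique")
  if (nrow(object@info) && any(object@info$radius <= 0))
    return("equivalent radius must be > 0")
  TRUE
})

#' ShapeModel: two-class 7-D Gaussian model of slice membership
#'
#' Maximum-likelihood Gaussian class models over the 7-dimensional feature
#' vector describing a candidate slice relative to a nuclear center slice and
#' to the closest intervening slice (see [computeFeatures()]). The
#' \code{member} class models slices that belong to the nucleus under
#' consideration; the \code{distractor} class models slices of nearby other
#' nuclei.
#'
#' @slot memberMean,distractorMean numeric length-7 class means.
#' @slot memberCov,distractorCov 7x7 covariance matrices (ridge-regularized,
#'   symmetric positive definite).
#' @slot priors named numeric (\code{member}, \code{distractor}) summing to 1.
#' @slot nTraining named integer: training example counts per class.
#' @slot regularization ridge value added to covariance diagonals.
#'
#' @seealso [trainShapeModel()], [classifySlice()], [defaultShapeModel()]
#' @export
setClass("ShapeModel",
  representation(memberMean = "numeric", memberCov = "matrix",
                 distractorMean = "numeric", distractorCov = "matrix",
                 priors = "numeric", nTraining = "integer",
                 regularization = "numeric"))

setValidity("ShapeModel", function(object) {
  if (length(object@memberMean) != 7L || length(object@distractorMean) != 7L)
    return("class means must have length 7")
  for (nm in c("memberCov", "distractorCov")) {
    cv <- slot(object, nm)
    if (!all(dim(cv) == c(7L, 7L))) return(sprintf("%s must be 7x7", nm))
    if (max(abs(cv - t(cv))) > 1e-8 * (1 + max(abs(cv))))
      return(sprintf("%s must be symmetric", nm))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) return(sprintf("%s must be positive definite", nm))
  }
  p <- object@priors
  if (length(p) != 2L || abs(sum(p) - 1) > 1e-8 || any(p <= 0))
    return("priors must be two positive numbers summing to 1")
  TRUE
})

#' DetectionRecord: nuclear detections (or ground truth) for one volume
#'
#' @slot nuclei data.frame with columns \code{id} (unique integer),
#'   \code{x}, \code{y}, \code{z} (centroid in voxel coordinates, real),
#'   \code{diameter} (in-plane pixels, twice the largest member slice's
#'   equivalent radius) and \code{status} (one of \code{seeded},
#'   \code{recovered}, \code{merged}, or \code{truth} for ground truth).
#' @slot volumeName identifier of the volume the record refers to.
#' @slot spacing voxel spacing (x, y, z micrometers) of that volume.
#' @slot configSnapshot list: the configuration the record was produced with
#'   (empty for ground truth).
#'
#' @seealso [writeDetections()], [readDetections()], [matchDetections()]
#' @export
setClass("DetectionRecord",
  representation(nuclei = "data.frame", volumeName = "character",
                 spacing = "numeric", configSnapshot = "list"))

setValidity("DetectionRecord", function(object) {
  nz <- object@nuclei
  need <- c("id", "x", "y", "z", "diameter", "status")
  if (!all(need %in% names(nz)))
    return(paste("nuclei must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nz$id)) return("nucleus ids must be unique")
  if (nrow(nz) && !all(is.finite(nz$x) & is.finite(nz$y) & is.finite(nz$z)))
    return("centroids must be finite")
  TRUE
})

#' SegmentationResult: the working state of slice-to-nucleus assembly
#'
#' Holds all segmented slices, the current set of nuclei, and the claims
#' nuclei have laid on slices. Before conflict resolution a slice may carry
#' claims from several nuclei; [resolveConflicts()] arbitrates so that
#' afterwards every slice has at most one claimant.
#'
#' @slot slices the [SliceSet-class] the nuclei are assembled from.
#' @slot nuclei data.frame: \code{id}, \code{centerSliceId}, centroid
#'   \code{y}, \code{x}, \code{z} (real voxel coordinates), \code{diameter}
#'   (px), \code{totalClaim} (sum of member claim strengths) and
#'   \code{status}.
#' @slot members named list mapping nucleus id to the integer ids of its
#'   member slices, ordered by plane (contiguous in z).
#' @slot claims data.frame: \code{sliceId}, \code{nucleusId}, \code{logOdds}.
#' @slot stageLog list of per-stage counters (seeds found, slices segmented,
#'   nuclei recovered, merges performed, splits performed).
#'
#' @seealso [extractAll()], [recoverOverlooked()], [resolveConflicts()]
#' @export
setClass("SegmentationResult",
  representation(slices = "SliceSet", nuclei = "data.frame",
                 members = "list", claims = "data.frame",
                 stageLog = "list"))

setValidity("SegmentationResult", function(object) {
  nz <- object@nuclei
  need <- c("id", "centerSliceId", "y", "x", "z", "diameter", "totalClaim",
            "status")
  if (!all(need %in% names(nz)))
    return(paste("nuclei must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(nz$id)) return("nucleus ids must be unique")
  if (nrow(nz) && !identical(sort(as.character(nz$id)),
                             sort(names(object@members))))
    return("members list must be keyed by nucleus id")
  info <- object@slices@info
  for (i in seq_len(nrow(nz))) {
    ids <- object@members[[as.character(nz$id[i])]]
    if (length(ids) < 1L) return("every nucleus needs >= 1 member slice")
    zz <- sort(info$z[match(ids, info$id)])
    if (!identical(as.integer(zz), as.integer(seq(zz[1], zz[length(zz)]))))
      return(sprintf("nucleus %d member planes are not contiguous", nz$id[i]))
    cz <- info$z[match(nz$centerSliceId[i], info$id)]
    if (!(cz %in% zz))
      return(sprintf("nucleus %d center plane outside member interval",
                     nz$id[i]))
  }
  TRUE
})

#' NucleusDetection: full output of the detection pipeline
#'
#' Produced by [detectNuclei()]. Carries the final [DetectionRecord-class],
#' the intermediate records after each algorithm stage (initial seeded
#' extraction, recovery of overlooked nuclei, conflict resolution) for
#' stage-wise error accounting, the final [SegmentationResult-class], and a
#' stage log of counters.
#'
#' @slot record final [DetectionRecord-class].
#' @slot stageRecords named list of [DetectionRecord-class]: \code{initial},
#'   \code{recovered}, \code{final}.
#' @slot result final [SegmentationResult-class].
#' @slot stageLog list of per-stage counters.
#' @export
setClass("NucleusDetection",
  representation(record = "DetectionRecord", stageRecords = "list",
                 result = "SegmentationResult", stageLog = "list"))
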