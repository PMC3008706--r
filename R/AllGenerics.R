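#' Accessors for blobslice classes
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors raw intensity array of an [ImageVolume-class].
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @describeIn accessors voxel spacing (named x, y, z, micrometers).
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @describeIn accessors identifier of a volume or record.
#' @export
setGeneric("volumeName", function(x) standardGeneric("volumeName"))

#' @describeIn accessors signed DoG response array of a
#'   [FilteredVolume-class].
#' @export
setGeneric("responseData", function(x) standardGeneric("responseData"))

#' @describeIn accessors per-slice geometry/intensity table of a
#'   [SliceSet-class].
#' @export
setGeneric("sliceInfo", function(x) standardGeneric("sliceInfo"))

#' @describeIn accessors list of polygon vertex matrices of a
#'   [SliceSet-class].
#' @export
setGeneric("sliceEndpoints", function(x) standardGeneric("sliceEndpoints"))

#' @describeIn accessors nuclei table of a [DetectionRecord-class],
#'   [SegmentationResult-class] or [NucleusDetection-class].
#' @export
setGeneric("nucleiTable", function(x) standardGeneric("nucleiTable"))

#' @describeIn accessors final [DetectionRecord-class] of a
#'   [NucleusDetection-class].
#' @export
setGeneric("detectionRecord", function(x) standardGeneric("detectionRecord"))

#' @describeIn accessors per-stage [DetectionRecord-class] list of a
#'   [NucleusDetection-class].
#' @export
setGeneric("stageRecords", function(x) standardGeneric("stageRecords"))

#' @describeIn accessors per-stage counter list.
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))

setMethod("imageData", "ImageVolume", function(x) x@data)
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
setMethod("voxelSpacing", "FilteredVolume", function(x) x@spacing)
setMethod("voxelSpacing", "SliceSet", function(x) x@spacing)
setMethod("voxelSpacing", "DetectionRecord", function(x) x@spacing)
setMethod("volumeName", "ImageVolume", function(x) x@name)
setMethod("volumeName", "FilteredVolume", function(x) x@sourceName)
setMethod("volumeName", "DetectionRecord", function(x) x@volumeName)
setMethod("responseData", "FilteredVolume", function(x) x@response)
setMethod("sliceInfo", "SliceSet", function(x) x@info)
setMethod("sliceEndpoints", "SliceSet", function(x) x@endpoints)
setMethod("nucleiTable", "DetectionRecord", function(x) x@nuclei)
setMethod("nucleiTable", "SegmentationResult", function(x) x@nuclei)
setMethod("nucleiTable", "NucleusDetection", function(x) x@record@nuclei)
setMethod("detectionRecord", "NucleusDetection", function(x) x@record)
setMethod("stageRecords", "NucleusDetection", function(x) x@stageRecords)
setMethod("stageLog", "NucleusDetection", function(x) x@stageLog)
setMethod("stageLog", "SegmentationResult", function(x) x@stageLog)

#' @describeIn accessors dimensions (y, x, z) of the intensity grid.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @describeIn accessors dimensions (y, x, z) of the response grid.
#' @export
setMethod("dim", "FilteredVolume", function(x) dim(x@response))

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume '%s': %d x %d x %d (y,x,z), spacing %.3g/%.3g/%.3g um\n",
              object@name, d[1], d[2], d[3],
              object@spacing["x"], object@spacing["y"], object@spacing["z"]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "FilteredVolume", function(object) {
  d <- dim(object@response)
  cat(sprintf("FilteredVolume of '%s': %d x %d x %d, DoG sigma (y,x,z) %s / %s voxels\n",
              object@sourceName, d[1], d[2], d[3],
              paste(signif(object@sigmaInner, 3), collapse = ","),
              paste(signif(object@sigmaOuter, 3), collapse = ",")))
})

setMethod("show", "SliceSet", function(object) {
  cat(sprintf("SliceSet: %d slices across %d planes\n",
              nrow(object@info), length(unique(object@info$z))))
})

setMethod("show", "ShapeModel", function(object) {
  cat("ShapeModel (7-D two-class Gaussian)\n")
  cat(sprintf("  trained on %d member / %d distractor examples; priors %.3f/%.3f\n",
              object@nTraining["member"], object@nTraining["distractor"],
              object@priors["member"], object@priors["distractor"]))
})

setMethod("show", "DetectionRecord", function(object) {
  cat(sprintf("DetectionRecord '%s': %d nuclei", object@volumeName,
              nrow(object@nuclei)))
  if (nrow(object@nuclei))
    cat(sprintf(" (%s)", paste(sprintf("%d %s", table(object@nuclei$status),
                                       names(table(object@nuclei$status))),
                               collapse = ", ")))
  cat("\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: %d nuclei from %d slices (%d unclaimed)\n",
              nrow(object@nuclei), nrow(object@slices@info),
              length(unclaimedSlices(object))))
})

setMethod("show", "NucleusDetection", function(object) {
  cat(sprintf("NucleusDetection: %d nuclei", nrow(object@record@nuclei)))
  sl <- object@stageLog
  if (length(sl))
    cat(sprintf(" (seeds %s, recovered %s, merged %s)",
                sl$nSeeds, sl$nRecovered, sl$nMerged))
  cat("\n")
})
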