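#' Construct an ImageVolume
#'
#' @param data numeric 3D array indexed (y, x, z); intensities are kept as
#'   real numbers in their source units, never rescaled.
#' @param spacing numeric length 3: micrometers per voxel step along x, y, z.
#' @param name free-text identifier.
#' @return an [ImageVolume-class].
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 2)), spacing = c(1, 1, 5))
#' dim(v)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), name = "volume") {
  data <- array(as.numeric(data), dim = dim(data))
  spacing <- as.numeric(spacing)
  names(spacing) <- c("x", "y", "z")
  new("ImageVolume", data = data, spacing = spacing, name = name)
}

#' Load a 3D volume from disk
#'
#' Two formats are supported. Multi-page grayscale TIFF: each page is one
#' optical section; page order maps to ascending z; 8/16-bit integer samples
#' are read in their raw units. Raw binary arrays: a file of little-endian
#' values in (y, x, z) order with fastest-varying y, accompanied by a JSON
#' sidecar \code{<path>.json} holding \code{shape} (y, x, z), \code{dtype}
#' (\code{uint8}, \code{uint16} or \code{float64}), \code{order}
#' (\code{"yxz"}) and optionally \code{spacing}.
#'
#' @param path path to a \code{.tif}/\code{.tiff} stack or a raw \code{.bin}
#'   array with JSON sidecar.
#' @param spacing micrometers per voxel step along x, y, z; required for TIFF
#'   (no metadata parsing), overrides the sidecar for raw arrays if given.
#' @param name identifier; defaults to the file name.
#' @return an [ImageVolume-class]. Intensities are cast to doubles without
#'   rescaling.
#' @seealso [saveVolume()]
#' @export
loadVolume <- function(path, spacing = NULL, name = basename(path)) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (is.null(spacing))
      stop("spacing must be supplied when loading TIFF volumes")
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (any(!vapply(pages, is.matrix, logical(1))))
      stop("TIFF pages must be single-channel (grayscale) 2D images")
    d <- dim(pages[[1]])
    if (any(vapply(pages, function(p) !identical(dim(p), d), logical(1))))
      stop("all TIFF pages must share the same dimensions")
    data <- array(0, c(d[1], d[2], length(pages)))
    for (k in seq_along(pages)) data[, , k] <- as.numeric(pages[[k]])
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("raw volume requires a JSON sidecar at ", sidecar)
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!identical(meta$order, "yxz"))
      stop("raw volume sidecar must declare order 'yxz'")
    shape <- as.integer(meta$shape)
    if (length(shape) != 3L) stop("sidecar shape must have 3 entries (y,x,z)")
    n <- prod(shape)
    vals <- switch(as.character(meta$dtype),
      uint8  = as.numeric(readBin(path, "integer", n, size = 1,
                                  signed = FALSE)),
      uint16 = as.numeric(readBin(path, "integer", n, size = 2,
                                  signed = FALSE, endian = "little")),
      float64 = readBin(path, "double", n, size = 8, endian = "little"),
      stop("unsupported dtype: ", meta$dtype))
    if (length(vals) != n) stop("raw volume shorter than declared shape")
    data <- array(vals, dim = shape)
    if (is.null(spacing) && !is.null(meta$spacing))
      spacing <- as.numeric(meta$spacing)
  }
  if (is.null(spacing)) stop("voxel spacing unavailable; pass spacing=")
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be 3 positive reals (x, y, z)")
  ImageVolume(data, spacing = spacing, name = name)
}

#' Save a volume to disk
#'
#' TIFF output writes one 16-bit grayscale page per plane; intensities must
#' lie in [0, 65535] and are rounded (use the raw format for lossless
#' round-tripping of arbitrary real intensities). Raw output writes
#' little-endian float64 in (y, x, z) order plus the JSON sidecar consumed by
#' [loadVolume()].
#'
#' @param volume an [ImageVolume-class].
#' @param path destination ending in \code{.tif}/\code{.tiff} or \code{.bin}.
#' @return the path, invisibly.
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "ImageVolume"))
  d <- imageData(volume)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(d) > 65535 || min(d) < 0)
      stop("TIFF output requires intensities in [0, 65535]")
    pages <- lapply(seq_len(dim(d)[3]),
                    function(k) round(d[, , k]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    writeBin(as.numeric(d), path, size = 8, endian = "little")
    jsonlite::write_json(
      list(shape = dim(d), dtype = "float64", order = "yxz",
           spacing = as.numeric(voxelSpacing(volume)), name = volume@name),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Construct a DetectionRecord
#'
#' @param nuclei data.frame with columns id, x, y, z, diameter, status
#'   (voxel coordinates, 1-based; diameter in in-plane pixels).
#' @param volumeName identifier of the originating volume.
#' @param spacing voxel spacing (x, y, z micrometers).
#' @param configSnapshot list of configuration values the record was produced
#'   with (may be empty).
#' @return a [DetectionRecord-class].
#' @export
DetectionRecord <- function(nuclei = emptyNucleiTable(),
                            volumeName = "volume",
                            spacing = c(1, 1, 1),
                            configSnapshot = list()) {
  spacing <- as.numeric(spacing)
  names(spacing) <- c("x", "y", "z")
  nuclei <- as.data.frame(nuclei)[, c("id", "x", "y", "z", "diameter",
                                      "status")]
  nuclei$id <- as.integer(nuclei$id)
  nuclei$status <- as.character(nuclei$status)
  rownames(nuclei) <- NULL
  new("DetectionRecord", nuclei = nuclei, volumeName = volumeName,
      spacing = spacing, configSnapshot = configSnapshot)
}

emptyNucleiTable <- function() {
  data.frame(id = integer(), x = numeric(), y = numeric(), z = numeric(),
             diameter = numeric(), status = character())
}

#' Write / read detection records as CSV
#'
#' One row per nucleus with columns \code{id, x, y, z, diameter, status}
#' (x, y, z are 1-based voxel coordinates; diameter is in in-plane pixels).
#' Metadata (volume name, voxel spacing, configuration snapshot) are carried
#' on \code{#}-prefixed header comment lines so that
#' \code{readDetections(writeDetections(r))} reproduces the record exactly up
#' to floating-point text precision (15 significant digits are written).
#'
#' @param record a [DetectionRecord-class].
#' @param path CSV file path.
#' @return \code{writeDetections} returns the path invisibly;
#'   \code{readDetections} and \code{readGroundTruth} return a
#'   [DetectionRecord-class]. Malformed rows are reported with their line
#'   numbers.
#' @export
writeDetections <- function(record, path) {
  stopifnot(is(record, "DetectionRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# volume_name: %s", record@volumeName),
    sprintf("# spacing: %s",
            paste(format(record@spacing, digits = 15), collapse = " ")),
    sprintf("# config: %s",
            as.character(jsonlite::toJSON(record@configSnapshot,
                                          auto_unbox = TRUE, digits = NA,
                                          null = "null")))), con)
  nz <- record@nuclei
  writeLines("id,x,y,z,diameter,status", con)
  if (nrow(nz)) {
    fmt <- function(v) vapply(v, function(x) format(x, digits = 15),
                              character(1))
    writeLines(paste(nz$id, fmt(nz$x), fmt(nz$y), fmt(nz$z),
                     fmt(nz$diameter), nz$status, sep = ","), con)
  }
  invisible(path)
}

#' @rdname writeDetections
#' @export
readDetections <- function(path) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  lines <- readLines(path)
  isComment <- grepl("^#", lines)
  meta <- lines[isComment]
  body <- lines[!isComment]
  getMeta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  volumeName <- getMeta("volume_name", "volume")
  spacing <- as.numeric(strsplit(getMeta("spacing", "1 1 1"), " +")[[1]])
  cfgTxt <- getMeta("config", "{}")
  config <- tryCatch(jsonlite::parse_json(cfgTxt, simplifyVector = TRUE),
                     error = function(e) list())
  if (is.null(config)) config <- list()
  if (!length(body) || body[1] != "id,x,y,z,diameter,status")
    stop("missing or unrecognized CSV header in ", path)
  nuclei <- emptyNucleiTable()
  if (length(body) > 1) {
    lineNo <- which(!isComment)[-1]          # file line number of each row
    parts <- strsplit(body[-1], ",", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad))
      stop("malformed row (expected 6 fields) at line ",
           paste(lineNo[bad], collapse = ", "), " of ", path)
    m <- do.call(rbind, parts)
    num <- suppressWarnings(apply(m[, 1:5, drop = FALSE], 2, as.numeric))
    num <- matrix(num, ncol = 5)
    bad <- which(rowSums(!is.finite(num)) > 0)
    if (length(bad))
      stop("non-numeric value at line ", paste(lineNo[bad], collapse = ", "),
           " of ", path)
    nuclei <- data.frame(id = as.integer(num[, 1]), x = num[, 2],
                         y = num[, 3], z = num[, 4], diameter = num[, 5],
                         status = m[, 6])
  }
  DetectionRecord(nuclei, volumeName = volumeName, spacing = spacing,
                  configSnapshot = as.list(config))
}

#' @rdname writeDetections
#' @export
readGroundTruth <- readDetections

#' Serialize / load a trained shape model as JSON
#'
#' Covariance matrices are stored row-major; the file carries class means,
#' covariances, priors, training counts and the regularization ridge.
#'
#' @param model a [ShapeModel-class].
#' @param path JSON file path.
#' @return \code{loadShapeModel} returns a [ShapeModel-class].
#' @export
saveShapeModel <- function(model, path) {
  stopifnot(is(model, "ShapeModel"))
  obj <- list(class = "blobslice.ShapeModel",
              member_mean = model@memberMean,
              member_cov = as.vector(t(model@memberCov)),
              distractor_mean = model@distractorMean,
              distractor_cov = as.vector(t(model@distractorCov)),
              priors = as.list(model@priors),
              n_training = as.list(model@nTraining),
              regularization = model@regularization)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveShapeModel
#' @export
loadShapeModel <- function(path) {
  if (!file.exists(path)) stop("shape model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "blobslice.ShapeModel"))
    stop("not a blobslice shape model: ", path)
  asCov <- function(v) matrix(as.numeric(v), 7, 7, byrow = TRUE)
  new("ShapeModel",
      memberMean = as.numeric(obj$member_mean),
      memberCov = asCov(obj$member_cov),
      distractorMean = as.numeric(obj$distractor_mean),
      distractorCov = asCov(obj$distractor_cov),
      priors = c(member = as.numeric(obj$priors$member),
                 distractor = as.numeric(obj$priors$distractor)),
      nTraining = c(member = as.integer(obj$n_training$member),
                    distractor = as.integer(obj$n_training$distractor)),
      regularization = as.numeric(obj$regularization))
}

#' Bundled default shape model
#'
#' A shape model trained on a crowded synthetic training scene (see the
#' package scripts directory for the generating code). Useful as a starting
#' point; retrain with [trainShapeModel()] on labeled data from your own
#' images for best results.
#'
#' @return a [ShapeModel-class].
#' @export
defaultShapeModel <- function() {
  loadShapeModel(system.file("extdata", "default_shape_model.json",
                             package = "blobslice", mustWork = TRUE))
}
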