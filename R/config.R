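#' Detection configuration
#'
#' The pipeline is tuned primarily through two intuitive parameters: the
#' expected in-plane nuclear diameter (which sets the DoG filter scale) and
#' the noise threshold applied to filtered maxima. The remaining parameters
#' are advanced knobs with defaults that rarely need changing.
#'
#' @param nuclearDiameter expected in-plane nuclear diameter, pixels (> 0).
#' @param noiseThreshold minimum filtered response for a 3D maximum to seed a
#'   nucleus, in filtered-intensity units (>= 0).
#' @param baseThreshold response threshold for 2D (per-plane) maxima; slices
#'   of dim nuclei must survive for the recovery stage, so this defaults to
#'   \code{noiseThreshold / 2}.
#' @param nRays number of rays cast from each 2D maximum (default 16).
#' @param maxRayFactor maximum ray length as a multiple of
#'   \code{nuclearDiameter} (default 1).
#' @param pruneFactor a ray is discarded when its length differs from the
#'   median of its two angular neighbors' lengths by more than this factor
#'   (default 2).
#' @param minRays minimum surviving rays for a slice to be kept (default 8).
#' @param recoveryRadiusFactor radius of the spherical neighborhood searched
#'   for clusters of unclaimed slices, as a multiple of
#'   \code{nuclearDiameter / 2} (physical units; default 1).
#' @param minCluster minimum number of unclaimed slices (the slice itself
#'   included) within the recovery neighborhood for an overlooked nucleus to
#'   be seeded (default 2, i.e. "multiple").
#' @param overlapSlices minimum number of shared slices for two nuclei to
#'   enter conflict resolution (default 1: any shared slice).
#' @param covRegularization ridge added to shape-model covariance diagonals,
#'   as a fraction of the mean diagonal (default 1e-4).
#' @param sigmaRatio outer/inner Gaussian width ratio of the DoG (default
#'   1.6, the classic Laplacian-of-Gaussian-approximating ratio).
#' @param priors optional length-2 override of shape-model class priors
#'   (member, distractor); \code{NULL} keeps empirical frequencies.
#'
#' @return a validated named list of class \code{blobsliceConfig}.
#' @examples
#' cfg <- detectionConfig(nuclearDiameter = 10, noiseThreshold = 2)
#' cfg$sigmaRatio
#' @export
detectionConfig <- function(nuclearDiameter = 10,
                            noiseThreshold = 1,
                            baseThreshold = NULL,
                            nRays = 16L,
                            maxRayFactor = 1,
                            pruneFactor = 2,
                            minRays = 8L,
                            recoveryRadiusFactor = 1,
                            minCluster = 2L,
                            overlapSlices = 1L,
                            covRegularization = 1e-4,
                            sigmaRatio = 1.6,
                            priors = NULL) {
  if (!is.numeric(nuclearDiameter) || nuclearDiameter <= 0)
    stop("nuclearDiameter must be > 0")
  if (!is.numeric(noiseThreshold) || noiseThreshold < 0)
    stop("noiseThreshold must be >= 0")
  if (is.null(baseThreshold)) baseThreshold <- noiseThreshold / 2
  if (baseThreshold < 0) stop("baseThreshold must be >= 0")
  if (nRays < 3) stop("nRays must be >= 3")
  if (pruneFactor <= 1) stop("pruneFactor must be > 1")
  if (!is.null(priors)) {
    if (length(priors) != 2 || any(priors <= 0))
      stop("priors must be two positive numbers")
    priors <- priors / sum(priors)
  }
  cfg <- list(nuclearDiameter = nuclearDiameter,
              noiseThreshold = noiseThreshold,
              baseThreshold = baseThreshold,
              nRays = as.integer(nRays),
              maxRayFactor = maxRayFactor,
              pruneFactor = pruneFactor,
              minRays = as.integer(minRays),
              recoveryRadiusFactor = recoveryRadiusFactor,
              minCluster = as.integer(minCluster),
              overlapSlices = as.integer(overlapSlices),
              covRegularization = covRegularization,
              sigmaRatio = sigmaRatio,
              priors = priors)
  class(cfg) <- "blobsliceConfig"
  cfg
}

#' Write / read a configuration as JSON
#'
#' @param config a \code{blobsliceConfig} from [detectionConfig()].
#' @param path file path.
#' @return \code{loadConfig} returns a \code{blobsliceConfig}; keys absent
#'   from the file keep their defaults.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "blobsliceConfig"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(detectionConfig))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(detectionConfig, raw)
}

#' @export
print.blobsliceConfig <- function(x, ...) {
  cat("blobslice detection configuration\n")
  cat(sprintf("  nuclearDiameter: %g px, noiseThreshold: %g\n",
              x$nuclearDiameter, x$noiseThreshold))
  adv <- setdiff(names(x), c("nuclearDiameter", "noiseThreshold"))
  for (k in adv)
    cat(sprintf("  %s: %s\n", k,
                if (is.null(x[[k]])) "NULL" else paste(signif(unlist(x[[k]]), 4),
                                                       collapse = ", ")))
  invisible(x)
}
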