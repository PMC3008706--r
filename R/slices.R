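# Bilinear interpolation of a plane at real (y, x); coordinates outside the
# grid return NA.
bilinear <- function(plane, y, x) {
  ny <- nrow(plane); nx <- ncol(plane)
  if (y < 1 || y > ny || x < 1 || x > nx) return(NA_real_)
  y0 <- floor(y); x0 <- floor(x)
  y0 <- min(y0, ny - 1L); x0 <- min(x0, nx - 1L)
  if (ny == 1L) y0 <- 1L
  if (nx == 1L) x0 <- 1L
  fy <- y - y0; fx <- x - x0
  y1 <- min(y0 + 1L, ny); x1 <- min(x0 + 1L, nx)
  (1 - fy) * ((1 - fx) * plane[y0, x0] + fx * plane[y0, x1]) +
    fy * ((1 - fx) * plane[y1, x0] + fx * plane[y1, x1])
}

#' Cast rays from a slice center to zero crossings of the filtered plane
#'
#' From a 2D response maximum, \code{nRays} evenly spaced rays march outward
#' in 0.5-pixel steps with bilinear interpolation of the response. Each ray
#' terminates at the sub-pixel zero crossing (linear interpolation between
#' the bracketing samples); rays that reach \code{maxLen} or the image border
#' without crossing zero terminate there and are flagged truncated.
#'
#' @param filteredPlane 2D matrix of filtered response (one z plane).
#' @param center length-2 numeric (y, x), 1-based; the response there must be
#'   positive.
#' @param nRays number of rays (default 16).
#' @param maxLen maximum ray length in pixels.
#' @return data.frame with one row per ray: \code{y}, \code{x} (endpoint),
#'   \code{length} (pixels from center), \code{truncated} (logical). Rows are
#'   in angular order (angle \code{2*pi*k/nRays}, k = 0..nRays-1, measured
#'   from the +x axis toward +y).
#' @seealso [pruneRays()], [buildSlice()]
#' @export
castRays <- function(filteredPlane, center, nRays = 16L, maxLen = 10) {
  y0 <- center[1]; x0 <- center[2]
  if (y0 < 1 || y0 > nrow(filteredPlane) || x0 < 1 || x0 > ncol(filteredPlane))
    stop("ray-cast center lies outside the plane")
  v0 <- bilinear(filteredPlane, y0, x0)
  if (!is.finite(v0) || v0 <= 0)
    stop("ray-cast center must have positive filtered response")
  step <- 0.5
  out <- data.frame(y = numeric(nRays), x = numeric(nRays),
                    length = numeric(nRays), truncated = logical(nRays))
  for (k in seq_len(nRays)) {
    th <- 2 * pi * (k - 1) / nRays
    dy <- sin(th); dx <- cos(th)
    tPrev <- 0; vPrev <- v0
    t <- step
    len <- NA_real_; trunc <- FALSE
    repeat {
      if (t > maxLen + 1e-9) { len <- maxLen; trunc <- TRUE; break }
      v <- bilinear(filteredPlane, y0 + dy * t, x0 + dx * t)
      if (is.na(v)) { len <- tPrev; trunc <- TRUE; break }
      if (v < 0) {
        len <- tPrev + (t - tPrev) * vPrev / (vPrev - v)
        break
      }
      if (v == 0) { len <- t; break }
      tPrev <- t; vPrev <- v
      t <- t + step
    }
    out$y[k] <- y0 + dy * len
    out$x[k] <- x0 + dx * len
    out$length[k] <- len
    out$truncated[k] <- trunc
  }
  out
}

#' Discard rays unusually longer or shorter than their angular neighbors
#'
#' A ray is discarded when its length deviates from the running median of
#' itself and its two angular neighbors by a factor greater than
#' \code{pruneFactor}, or smaller than \code{1/pruneFactor}. The 3-point
#' median keeps a single outlier from contaminating its neighbors'
#' references. All decisions use the original lengths; survivors keep angular
#' order. Truncated rays participate with their truncated length.
#'
#' @param rays data.frame from [castRays()] (>= 3 rows).
#' @param pruneFactor neighbor-relative deviation factor (default 2).
#' @return the surviving subset of \code{rays}.
#' @export
pruneRays <- function(rays, pruneFactor = 2) {
  n <- nrow(rays)
  if (n < 3) stop("pruneRays needs at least 3 rays")
  L <- rays$length
  prevL <- L[c(n, seq_len(n - 1))]
  nextL <- L[c(seq_len(n)[-1], 1)]
  ref <- vapply(seq_len(n), function(i) median(c(prevL[i], L[i], nextL[i])),
                numeric(1))
  ratio <- ifelse(ref > 0, L / ref, ifelse(L > 0, Inf, 1))
  keep <- ratio <= pruneFactor & ratio >= 1 / pruneFactor
  rays[keep, , drop = FALSE]
}

# Even-odd point-in-polygon for pixel centers; vectorized crossing count.
pointsInPolygon <- function(py, px, vy, vx) {
  n <- length(vy)
  inside <- rep(FALSE, length(py))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

shoelaceArea <- function(vy, vx) {
  n <- length(vy)
  j <- c(seq_len(n)[-1], 1)
  abs(sum(vx * vy[j] - vx[j] * vy)) / 2
}

#' Measure a polygonal nuclear slice
#'
#' Builds the per-slice measurements used by the shape model: polygon area by
#' the shoelace formula over the (angular-ordered) ray endpoints, equivalent
#' radius \code{sqrt(area/pi)}, mean raw intensity over pixels whose centers
#' fall inside the polygon (even-odd rule; falls back to the center pixel for
#' degenerate tiny polygons) and the filtered response at the center.
#'
#' @param center length-3 numeric (y, x, z).
#' @param endpoints matrix or data.frame of boundary points with columns
#'   \code{y}, \code{x}, in angular order (>= 3 rows).
#' @param rawPlane matrix of raw intensities for plane z.
#' @param filteredPlane matrix of filtered response for plane z.
#' @return a list with elements \code{y, x, z, area, radius, meanIntensity,
#'   peakResponse, endpoints}; \code{NULL} when the polygon is degenerate
#'   (zero area).
#' @export
buildSlice <- function(center, endpoints, rawPlane, filteredPlane) {
  ep <- as.matrix(as.data.frame(endpoints)[, c("y", "x")])
  if (nrow(ep) < 3) stop("a slice polygon needs at least 3 endpoints")
  area <- shoelaceArea(ep[, "y"], ep[, "x"])
  if (area <= 0) return(NULL)
  ymin <- max(1L, floor(min(ep[, "y"]))); ymax <- min(nrow(rawPlane), ceiling(max(ep[, "y"])))
  xmin <- max(1L, floor(min(ep[, "x"]))); xmax <- min(ncol(rawPlane), ceiling(max(ep[, "x"])))
  gy <- rep(ymin:ymax, times = xmax - xmin + 1)
  gx <- rep(xmin:xmax, each = ymax - ymin + 1)
  inside <- pointsInPolygon(gy, gx, ep[, "y"], ep[, "x"])
  meanIntensity <- if (any(inside)) {
    mean(rawPlane[cbind(gy[inside], gx[inside])])
  } else {
    rawPlane[round(center[1]), round(center[2])]
  }
  list(y = center[1], x = center[2], z = as.integer(center[3]),
       area = area, radius = sqrt(area / pi),
       meanIntensity = meanIntensity,
       peakResponse = bilinear(filteredPlane, center[1], center[2]),
       endpoints = ep)
}

#' Segment every candidate nuclear slice in a volume
#'
#' For each per-plane 2D response maximum above the base threshold, casts
#' rays to the zero crossings of the filtered plane, prunes outlier rays and
#' measures the resulting polygon. A candidate is rejected when fewer than
#' \code{minRays} rays survive pruning, when more than half its rays were
#' truncated (likely a noise ridge rather than a nucleus), or when the
#' polygon is degenerate.
#'
#' @param volume the raw [ImageVolume-class].
#' @param filtered the matching [FilteredVolume-class].
#' @param config a [detectionConfig()].
#' @return a [SliceSet-class] with unique slice ids; slice centers are the
#'   surviving 2D maxima.
#' @export
segmentAllSlices <- function(volume, filtered, config = detectionConfig()) {
  stopifnot(is(volume, "ImageVolume"), is(filtered, "FilteredVolume"))
  maxima <- find2dMaxima(filtered, config$baseThreshold)
  resp <- responseData(filtered)
  raw <- imageData(volume)
  maxLen <- config$maxRayFactor * config$nuclearDiameter
  rows <- list()
  eps <- list()
  for (i in seq_len(nrow(maxima))) {
    z <- maxima$z[i]
    rays <- castRays(resp[, , z], c(maxima$y[i], maxima$x[i]),
                     nRays = config$nRays, maxLen = maxLen)
    truncFrac <- mean(rays$truncated)
    kept <- pruneRays(rays, config$pruneFactor)
    if (nrow(kept) < config$minRays || truncFrac > 0.5) next
    sl <- buildSlice(c(maxima$y[i], maxima$x[i], z), kept,
                     raw[, , z], resp[, , z])
    if (is.null(sl)) next
    rows[[length(rows) + 1L]] <- data.frame(
      y = sl$y, x = sl$x, z = sl$z, area = sl$area, radius = sl$radius,
      meanIntensity = sl$meanIntensity, peakResponse = sl$peakResponse,
      nRays = nrow(kept), truncatedFrac = truncFrac)
    eps[[length(eps) + 1L]] <- sl$endpoints
  }
  info <- if (length(rows)) {
    cbind(data.frame(id = seq_along(rows)), do.call(rbind, rows))
  } else {
    data.frame(id = integer(), y = numeric(), x = numeric(), z = integer(),
               area = numeric(), radius = numeric(), meanIntensity = numeric(),
               peakResponse = numeric(), nRays = integer(),
               truncatedFrac = numeric())
  }
  rownames(info) <- NULL
  new("SliceSet", info = info, endpoints = eps,
      spacing = voxelSpacing(volume))
}

#' Export slice polygons for visual quality control
#'
#' Writes one CSV row per polygon vertex (sliceId, z, vertex, y, x) so that
#' overlays can be drawn with external tools.
#'
#' @param slices a [SliceSet-class].
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeSliceOverlay <- function(slices, path) {
  info <- sliceInfo(slices)
  eps <- sliceEndpoints(slices)
  rows <- lapply(seq_len(nrow(info)), function(i) {
    ep <- eps[[i]]
    data.frame(sliceId = info$id[i], z = info$z[i],
               vertex = seq_len(nrow(ep)), y = ep[, "y"], x = ep[, "x"])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sliceId = integer(), z = integer(), vertex = integer(),
               y = numeric(), x = numeric())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
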