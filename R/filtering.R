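# Separable Gaussian machinery. Convolution along one axis is expressed as a
# banded matrix product: for axis length n and kernel radius r, B[i, j] sums
# the kernel weights that map (reflected) source index j onto target i, so
# conv(A) = B %*% unfold(A). Reflect padding repeats the edge sample
# (d c b a | a b c d | d c b a), which preserves constants exactly.

gaussKernel1d <- function(sigma, maxRadius = Inf) {
  r <- max(1L, ceiling(3 * sigma))
  if (r > maxRadius) {
    warning(sprintf("Gaussian kernel radius %d exceeds volume extent; clamping to %d",
                    r, maxRadius))
    r <- max(1L, as.integer(maxRadius))
  }
  x <- seq(-r, r)
  k <- exp(-0.5 * (x / sigma)^2)
  k / sum(k)
}

reflectIndex <- function(idx, n) {
  # mirror with edge repeat; iterate for kernels wider than the axis
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 1L - idx, idx)
    idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  }
  idx
}

convBandMatrix <- function(kernel, n) {
  r <- (length(kernel) - 1L) / 2L
  B <- matrix(0, n, n)
  for (o in seq(-r, r)) {
    src <- reflectIndex(seq_len(n) + o, n)
    w <- kernel[o + r + 1L]
    B[cbind(seq_len(n), src)] <- B[cbind(seq_len(n), src)] + w
  }
  B
}

convolveAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- convBandMatrix(kernel, d[axis]) %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

gaussianSmooth3d <- function(arr, sigma) {
  # sigma: length-3 (y, x, z) in voxels
  d <- dim(arr)
  for (axis in 1:3) {
    k <- gaussKernel1d(sigma[axis], maxRadius = d[axis] - 1L)
    arr <- convolveAxis(arr, k, axis)
  }
  arr
}

#' 3D Difference-of-Gaussians filtering
#'
#' Convolves the volume with the difference of two 3D Gaussians, computed
#' separably per axis. The inner width is \code{nuclearDiameter / 4} in-plane
#' (so the inner Gaussian's full width approximates the nuclear radius) and
#' the outer width is \code{sigmaRatio} times that. Along z both widths are
#' divided by the anisotropy ratio (z spacing over mean x/y spacing, floor of
#' 0.5 voxel) so the kernel is isotropic in physical units. Boundaries use
#' reflect padding; the response of a constant volume is zero everywhere.
#'
#' @param volume an [ImageVolume-class].
#' @param config a [detectionConfig()]; \code{nuclearDiameter} sets the
#'   filter scale.
#' @return a [FilteredVolume-class] whose response grid has the shape of the
#'   input.
#' @examples
#' v <- ImageVolume(array(100, c(16, 16, 8)), spacing = c(1, 1, 2))
#' f <- dogFilter(v, detectionConfig(nuclearDiameter = 6))
#' max(abs(responseData(f)))  # constants are annihilated
#' @export
dogFilter <- function(volume, config = detectionConfig()) {
  stopifnot(is(volume, "ImageVolume"))
  sp <- voxelSpacing(volume)
  sigmaIn <- config$nuclearDiameter / 4
  sigmaOut <- config$sigmaRatio * sigmaIn
  zRatio <- sp["z"] / mean(sp[c("x", "y")])
  sIn <- c(y = sigmaIn, x = sigmaIn, z = max(0.5, sigmaIn / zRatio))
  sOut <- c(y = sigmaOut, x = sigmaOut, z = max(0.5, sigmaOut / zRatio))
  d <- imageData(volume)
  resp <- gaussianSmooth3d(d, sIn) - gaussianSmooth3d(d, sOut)
  new("FilteredVolume", response = resp, sigmaInner = sIn, sigmaOuter = sOut,
      spacing = sp, sourceName = volume@name)
}

# Neighborhood local-maximum scan shared by the 2D and 3D finders.
# Returns positions that are >= all neighbors in `offsets` and > at least
# one, with value > threshold; plateaus (equal-valued, mutually adjacent
# candidates) contribute one position each, the lexicographically smallest
# by (y, x, z). Out-of-bounds neighbors compare as -Inf, so maxima at the
# volume border are kept.
localMaximaScan <- function(resp, offsets, threshold) {
  d <- dim(resp)
  geAll <- array(TRUE, d)
  gtAny <- array(FALSE, d)
  idxRange <- function(n, o) {
    dst <- seq(max(1L, 1L - o), min(n, n - o))
    list(dst = dst, src = dst + o)
  }
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    ry <- idxRange(d[1], o[1]); rx <- idxRange(d[2], o[2])
    rz <- idxRange(d[3], o[3])
    shifted <- array(-Inf, d)
    shifted[ry$dst, rx$dst, rz$dst] <- resp[ry$src, rx$src, rz$src]
    geAll <- geAll & (resp >= shifted)
    gtAny <- gtAny | (resp > shifted)
  }
  cand <- which(geAll & gtAny & (resp > threshold))
  if (!length(cand)) {
    return(data.frame(y = integer(), x = integer(), z = integer(),
                      response = numeric()))
  }
  pos <- arrayInd(cand, d)
  val <- resp[cand]
  keep <- resolvePlateaus(pos, val, offsets)
  pos <- pos[keep, , drop = FALSE]
  val <- val[keep]
  ord <- order(pos[, 1], pos[, 2], pos[, 3])
  data.frame(y = pos[ord, 1], x = pos[ord, 2], z = pos[ord, 3],
             response = val[ord])
}

# Group equal-valued adjacent candidates into plateau components; keep the
# (y,x,z)-lexicographically smallest member of each component.
resolvePlateaus <- function(pos, val, offsets) {
  n <- nrow(pos)
  if (n <= 1L) return(rep(TRUE, n))
  key <- paste(pos[, 1], pos[, 2], pos[, 3], sep = ",")
  lookup <- seq_len(n)
  names(lookup) <- key
  comp <- rep(0L, n)
  nextComp <- 0L
  ord <- order(pos[, 1], pos[, 2], pos[, 3])
  for (i in ord) {
    if (comp[i] > 0L) next
    nextComp <- nextComp + 1L
    queue <- i
    comp[i] <- nextComp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(offsets, 2, as.integer(pos[cur, ]), "+")
      nbKey <- paste(nb[, 1], nb[, 2], nb[, 3], sep = ",")
      hit <- lookup[nbKey]
      hit <- hit[!is.na(hit)]
      hit <- hit[comp[hit] == 0L & val[hit] == val[cur]]
      if (length(hit)) {
        comp[hit] <- nextComp
        queue <- c(queue, hit)
      }
    }
  }
  # first candidate (in lexicographic order) of each component wins
  keep <- rep(FALSE, n)
  seen <- logical(nextComp)
  for (i in ord) {
    if (!seen[comp[i]]) { seen[comp[i]] <- TRUE; keep[i] <- TRUE }
  }
  keep
}

offsets26 <- function() {
  g <- as.matrix(expand.grid(y = -1:1, x = -1:1, z = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

offsets8 <- function() {
  g <- as.matrix(expand.grid(y = -1:1, x = -1:1, z = 0L))
  g[rowSums(abs(g[, 1:2, drop = FALSE])) > 0, , drop = FALSE]
}

#' Candidate nuclear centers: 3D maxima of the filtered volume
#'
#' A seed is a voxel whose response exceeds the noise threshold, is greater
#' than or equal to all 26-connected neighbors and strictly greater than at
#' least one. Plateau ties are broken deterministically: one seed per plateau
#' component at its lexicographically smallest (y, x, z) position. Maxima at
#' the volume border are kept (late embryos touch image edges).
#'
#' @param filtered a [FilteredVolume-class].
#' @param noiseThreshold minimum response for a seed.
#' @return data.frame with columns \code{y}, \code{x}, \code{z} (1-based
#'   voxel position) and \code{response}, ordered lexicographically.
#' @seealso [find2dMaxima()]
#' @export
find3dMaxima <- function(filtered, noiseThreshold) {
  stopifnot(is(filtered, "FilteredVolume"))
  localMaximaScan(responseData(filtered), offsets26(), noiseThreshold)
}

#' Candidate slice centers: per-plane 2D maxima of the filtered volume
#'
#' Within each z plane, voxels above the base threshold that are >= all
#' 8-connected in-plane neighbors and > at least one. The base threshold
#' defaults to half the noise threshold so that slices of dim nuclei survive
#' for the recovery stage. Every 3D maximum position is also a 2D maximum of
#' its plane.
#'
#' @param filtered a [FilteredVolume-class].
#' @param baseThreshold minimum response for a slice-center candidate.
#' @return data.frame as in [find3dMaxima()].
#' @export
find2dMaxima <- function(filtered, baseThreshold) {
  stopifnot(is(filtered, "FilteredVolume"))
  localMaximaScan(responseData(filtered), offsets8(), baseThreshold)
}
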