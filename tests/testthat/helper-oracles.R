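# Independent reference implementations used as oracles. These deliberately
# avoid the package's computational paths: dense (non-separable) convolution,
# exhaustive neighborhood scans, brute-force assignment by permutation.

# dense 3D convolution with an explicit 3D kernel and mirror (edge-repeating)
# boundary handling, by direct summation over kernel offsets
oracleDenseConv3d <- function(arr, k1y, k1x, k1z) {
  d <- dim(arr)
  ry <- (length(k1y) - 1) / 2; rx <- (length(k1x) - 1) / 2
  rz <- (length(k1z) - 1) / 2
  refl <- function(idx, n) {
    while (any(idx < 1 | idx > n)) {
      idx <- ifelse(idx < 1, 1 - idx, idx)
      idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    }
    idx
  }
  out <- array(0, d)
  for (oy in -ry:ry) for (ox in -rx:rx) for (oz in -rz:rz) {
    w <- k1y[oy + ry + 1] * k1x[ox + rx + 1] * k1z[oz + rz + 1]
    src <- arr[refl(seq_len(d[1]) + oy, d[1]),
               refl(seq_len(d[2]) + ox, d[2]),
               refl(seq_len(d[3]) + oz, d[3]), drop = FALSE]
    out <- out + w * src
  }
  out
}

# normalized Gaussian taps computed through dnorm rather than the package's
# kernel code
oracleGaussTaps <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), 0, sigma)
  k / sum(k)
}

# DoG response by dense convolution, mirroring the sigma conventions
oracleDog <- function(volume, config) {
  sp <- voxelSpacing(volume)
  sIn <- config$nuclearDiameter / 4
  sOut <- config$sigmaRatio * sIn
  zr <- sp["z"] / mean(sp[c("x", "y")])
  g <- function(s) {
    oracleDenseConv3d(imageData(volume), oracleGaussTaps(s),
                      oracleGaussTaps(s), oracleGaussTaps(max(0.5, s / zr)))
  }
  g(sIn) - g(sOut)
}

# exhaustive local-maximum scan (no plateau logic; intended for volumes with
# continuous noise where exact ties do not occur)
oracleMaxima <- function(resp, threshold, connectivity = c("26", "8")) {
  connectivity <- match.arg(connectivity)
  d <- dim(resp)
  hits <- NULL
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    v <- resp[y, x, z]
    if (v <= threshold) next
    geAll <- TRUE; gtAny <- FALSE
    zr <- if (connectivity == "26") (z - 1):(z + 1) else z
    for (zz in zr) for (xx in (x - 1):(x + 1)) for (yy in (y - 1):(y + 1)) {
      if (yy == y && xx == x && zz == z) next
      if (yy < 1 || yy > d[1] || xx < 1 || xx > d[2] || zz < 1 || zz > d[3]) {
        gtAny <- TRUE          # out-of-bounds neighbors compare as -Inf
        next
      }
      nb <- resp[yy, xx, zz]
      if (v < nb) geAll <- FALSE
      if (v > nb) gtAny <- TRUE
    }
    if (geAll && gtAny) hits <- rbind(hits, c(y, x, z, v))
  }
  if (is.null(hits)) {
    return(data.frame(y = integer(), x = integer(), z = integer(),
                      response = numeric()))
  }
  out <- data.frame(y = hits[, 1], x = hits[, 2], z = hits[, 3],
                    response = hits[, 4])
  out[order(out$y, out$x, out$z), ]
}

# minimal-cost one-to-one assignment by exhaustive permutation (n <= 8)
oracleAssign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 8)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    cst <- sum(cost[cbind(seq_len(n), cols)])
    if (cst < bestCost) { bestCost <- cst; best <- cols }
  }
  list(assign = best, cost = bestCost)
}

# brute-force point-in-polygon mean intensity (even-odd rule re-derived via
# angle summation on a fine grid membership test)
oracleMeanIntensity <- function(plane, vy, vx) {
  inside <- function(py, px) {
    n <- length(vy); cnt <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      y1 <- vy[i]; y2 <- vy[j]; x1 <- vx[i]; x2 <- vx[j]
      if ((y1 > py) != (y2 > py)) {
        xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
        if (px < xc) cnt <- cnt + 1
      }
    }
    cnt %% 2 == 1
  }
  vals <- c()
  for (y in seq_len(nrow(plane))) for (x in seq_len(ncol(plane)))
    if (inside(y, x)) vals <- c(vals, plane[y, x])
  mean(vals)
}
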