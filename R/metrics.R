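# Minimal-cost assignment of rows to columns (n <= m) by the classic
# potentials-based shortest-augmenting-path method (O(n^2 m)). Returns, for
# each row, the assigned column index. Used for optimal truth-to-detection
# matching; unit-tested against a brute-force permutation oracle.
solveAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)              # p[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign[p[j + 1]] <- j
  assign
}

physicalCenters <- function(record) {
  nz <- nucleiTable(record)
  sp <- voxelSpacing(record)
  cbind(x = (nz$x - 1) * sp["x"], y = (nz$y - 1) * sp["y"],
        z = (nz$z - 1) * sp["z"])
}

#' Match detections against ground truth and compute error rates
#'
#' Optimal one-to-one matching between truth and detected centroids,
#' minimizing total physical distance (not greedy nearest, so the result is
#' deterministic and order-independent); pairs farther apart than
#' \code{tolerance} are rejected. Unmatched truth nuclei are false negatives;
#' unmatched detections are false positives. Rates are percentages of the
#' ground-truth count, and \code{totalError = fpRate + fnRate}.
#'
#' @param truth,detected [DetectionRecord-class] objects sharing the same
#'   coordinate frame and voxel spacing (a spacing mismatch is an error).
#' @param tolerance maximum physical match distance, micrometers; defaults to
#'   half the mean truth diameter (the nuclear radius).
#' @return list of class \code{EvaluationReport}: \code{nTruth},
#'   \code{nDetected}, \code{matches} (data.frame truthId, detectedId,
#'   distance), \code{falseNegatives}, \code{falsePositives}, \code{fnRate},
#'   \code{fpRate}, \code{totalError} (percent).
#' @seealso [nuclearSeparation()]
#' @export
matchDetections <- function(truth, detected, tolerance = NULL) {
  stopifnot(is(truth, "DetectionRecord"), is(detected, "DetectionRecord"))
  if (max(abs(voxelSpacing(truth) - voxelSpacing(detected))) > 1e-9)
    stop("truth and detected records have different voxel spacing")
  tz <- nucleiTable(truth); dz <- nucleiTable(detected)
  sp <- voxelSpacing(truth)
  if (is.null(tolerance)) {
    tolerance <- if (nrow(tz)) {
      mean(tz$diameter) / 2 * mean(sp[c("x", "y")])
    } else Inf
  }
  nT <- nrow(tz); nD <- nrow(dz)
  matches <- data.frame(truthId = integer(), detectedId = integer(),
                        distance = numeric())
  if (nT > 0 && nD > 0) {
    pT <- physicalCenters(truth); pD <- physicalCenters(detected)
    dist <- sqrt(outer(pT[, 1], pD[, 1], "-")^2 +
                   outer(pT[, 2], pD[, 2], "-")^2 +
                   outer(pT[, 3], pD[, 3], "-")^2)
    BIG <- max(tolerance[is.finite(tolerance)], max(dist), 1) * 1e6
    cost <- ifelse(dist <= tolerance, dist, BIG)
    flip <- nT > nD
    a <- if (flip) solveAssignment(t(cost)) else solveAssignment(cost)
    pairs <- if (flip) cbind(a, seq_len(nD)) else cbind(seq_len(nT), a)
    ok <- dist[pairs] <= tolerance
    pairs <- pairs[ok, , drop = FALSE]
    matches <- data.frame(truthId = tz$id[pairs[, 1]],
                          detectedId = dz$id[pairs[, 2]],
                          distance = dist[pairs])
  }
  fn <- nT - nrow(matches)
  fp <- nD - nrow(matches)
  rate <- function(k) if (nT > 0) 100 * k / nT else NA_real_
  report <- list(nTruth = nT, nDetected = nD, matches = matches,
                 falseNegatives = fn, falsePositives = fp,
                 fnRate = rate(fn), fpRate = rate(fp),
                 totalError = rate(fn) + rate(fp),
                 tolerance = tolerance)
  class(report) <- "EvaluationReport"
  report
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: %d truth vs %d detected\n", x$nTruth,
              x$nDetected))
  cat(sprintf("  matches %d, FN %d (%.2f%%), FP %d (%.2f%%), total error %.2f%%\n",
              nrow(x$matches), x$falseNegatives, x$fnRate,
              x$falsePositives, x$fpRate, x$totalError))
  invisible(x)
}

#' Mean nearest-neighbor nuclear separation
#'
#' For each nucleus, the boundary-to-boundary distance to its nearest
#' neighbor: physical center distance minus both bounding-circle radii (half
#' the recorded diameter, converted to micrometers with the in-plane
#' spacing), minimized over neighbors. The mean over nuclei is expressed in
#' units of slice spacing (the z step), the scale at which z sampling either
#' does or does not capture the gaps between nuclei. Negative values mean the
#' bounding spheres interpenetrate.
#'
#' @param record a [DetectionRecord-class] whose \code{diameter} column holds
#'   twice the largest-slice equivalent radius (pixels).
#' @return the mean separation (slice-spacing units), or \code{NA} with a
#'   warning when fewer than 2 nuclei are present.
#' @export
nuclearSeparation <- function(record) {
  stopifnot(is(record, "DetectionRecord"))
  nz <- nucleiTable(record)
  if (nrow(nz) < 2) {
    warning("nuclear separation undefined for fewer than 2 nuclei")
    return(NA_real_)
  }
  sp <- voxelSpacing(record)
  p <- physicalCenters(record)
  r <- nz$diameter / 2 * mean(sp[c("x", "y")])
  n <- nrow(nz)
  sep <- vapply(seq_len(n), function(i) {
    d <- sqrt((p[, 1] - p[i, 1])^2 + (p[, 2] - p[i, 2])^2 +
                (p[, 3] - p[i, 3])^2) - r - r[i]
    min(d[-i])
  }, numeric(1))
  unname(mean(sep) / sp["z"])
}

#' Write an evaluation report as JSON
#'
#' @param report an \code{EvaluationReport} from [matchDetections()].
#' @param path JSON file path.
#' @param separation optional separation statistic to embed.
#' @return the path, invisibly.
#' @export
writeEvaluationReport <- function(report, path, separation = NULL) {
  obj <- unclass(report)
  if (!is.null(separation)) obj$separationMean <- separation
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
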