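# A nucleus's claim on its own center slice: the log odds of the all-zero
# feature vector (a slice coincident with its center). Finite and
# model-consistent, so merge/split scores remain comparable.
centerSelfClaim <- function(model) {
  classifySlice(rep(0, 7), model)$logOdds
}

# Walk plane-by-plane up then down from a center slice, claiming the nearest
# in-plane candidate on each adjacent plane while the shape model calls it a
# member. Claiming stops at the first non-member or absent candidate, which
# enforces plane contiguity by construction.
extractClaims <- function(slices, centerSliceId, model, config) {
  info <- sliceInfo(slices)
  ctr <- sliceRow(slices, centerSliceId)
  ids <- centerSliceId
  lo <- centerSelfClaim(model)
  for (dir in c(1L, -1L)) {
    prev <- ctr
    z <- ctr$z + dir
    repeat {
      onPlane <- info[info$z == z & info$id != ctr$id, , drop = FALSE]
      if (!nrow(onPlane)) break
      d <- sqrt((onPlane$y - ctr$y)^2 + (onPlane$x - ctr$x)^2)
      gate <- d < onPlane$radius + ctr$radius
      if (!any(gate)) break
      onPlane <- onPlane[gate, , drop = FALSE]
      cand <- onPlane[which.min(d[gate]), ]
      cls <- classifySlice(computeFeatures(cand, ctr, prev), model)
      if (cls$label != "member") break
      ids <- c(ids, cand$id)
      lo <- c(lo, cls$logOdds)
      prev <- cand
      z <- z + dir
    }
  }
  list(sliceIds = ids, logOdds = lo, centerSliceId = centerSliceId)
}

nucleusSummary <- function(slices, sliceIds, logOdds, centerSliceId, id,
                           status) {
  info <- sliceInfo(slices)
  rows <- info[match(sliceIds, info$id), ]
  w <- pmax(rows$meanIntensity, 1e-12)
  data.frame(id = as.integer(id), centerSliceId = as.integer(centerSliceId),
             y = sum(rows$y * w) / sum(w), x = sum(rows$x * w) / sum(w),
             z = sum(rows$z * w) / sum(w),
             diameter = 2 * max(rows$radius),
             totalClaim = sum(logOdds), status = status)
}

orderByPlane <- function(slices, sliceIds) {
  info <- sliceInfo(slices)
  sliceIds[order(info$z[match(sliceIds, info$id)])]
}

#' Assemble one nucleus from a seed slice
#'
#' The slice corresponding to a 3D response maximum attempts to claim slices
#' above and below it: walking plane by plane away from the seed, the nearest
#' in-plane candidate (within the sum of candidate and center radii) is
#' classified against the shape model, and claiming continues while the
#' classifier answers member, stopping at the first non-member or absent
#' candidate. A bare seed with no claimable neighbors forms a valid
#' single-slice nucleus.
#'
#' @param seedSliceId id of the seed slice within \code{slices}.
#' @param slices a [SliceSet-class].
#' @param model a trained [ShapeModel-class].
#' @param config a [detectionConfig()].
#' @param id nucleus id to assign.
#' @param status one of \code{"seeded"}, \code{"recovered"}.
#' @return list with \code{nucleus} (one-row summary data.frame),
#'   \code{memberSliceIds} (ordered by plane) and \code{claims} (data.frame
#'   sliceId, nucleusId, logOdds).
#' @export
extractNucleus <- function(seedSliceId, slices, model,
                           config = detectionConfig(), id = 1L,
                           status = "seeded") {
  cl <- extractClaims(slices, seedSliceId, model, config)
  list(nucleus = nucleusSummary(slices, cl$sliceIds, cl$logOdds,
                                cl$centerSliceId, id, status),
       memberSliceIds = orderByPlane(slices, cl$sliceIds),
       claims = data.frame(sliceId = as.integer(cl$sliceIds),
                           nucleusId = as.integer(id),
                           logOdds = cl$logOdds))
}

emptyClaims <- function() {
  data.frame(sliceId = integer(), nucleusId = integer(), logOdds = numeric())
}

emptyNucleusFrame <- function() {
  data.frame(id = integer(), centerSliceId = integer(), y = numeric(),
             x = numeric(), z = numeric(), diameter = numeric(),
             totalClaim = numeric(), status = character())
}

#' Extract nuclei from all 3D-maximum seeds
#'
#' Seeds are processed in descending filtered-response order (brighter nuclei
#' claim first, mirroring how bright neighbors overshadow dim ones). Each
#' seed is mapped to the slice segmented at its voxel position; seeds whose
#' slice was rejected during segmentation are skipped with a warning.
#' Multiple nuclei may claim the same slice at this stage; arbitration
#' happens in [resolveConflicts()].
#'
#' @param seeds data.frame from [find3dMaxima()].
#' @param slices a [SliceSet-class].
#' @param model a trained [ShapeModel-class].
#' @param config a [detectionConfig()].
#' @return a [SegmentationResult-class].
#' @export
extractAll <- function(seeds, slices, model, config = detectionConfig()) {
  info <- sliceInfo(slices)
  ord <- order(-seeds$response, seeds$y, seeds$x, seeds$z)
  nuclei <- list(); members <- list(); claims <- list()
  nid <- 0L
  nSkipped <- 0L
  for (s in ord) {
    hit <- which(info$z == seeds$z[s] & info$y == seeds$y[s] &
                   info$x == seeds$x[s])
    if (!length(hit)) {
      nSkipped <- nSkipped + 1L
      warning(sprintf("seed at (y=%d, x=%d, z=%d) has no segmented slice; skipped",
                      seeds$y[s], seeds$x[s], seeds$z[s]))
      next
    }
    nid <- nid + 1L
    ext <- extractNucleus(info$id[hit[1]], slices, model, config, id = nid,
                          status = "seeded")
    nuclei[[nid]] <- ext$nucleus
    members[[as.character(nid)]] <- ext$memberSliceIds
    claims[[nid]] <- ext$claims
  }
  nucleiDf <- if (nid) do.call(rbind, nuclei) else emptyNucleusFrame()
  claimsDf <- if (nid) do.call(rbind, claims) else emptyClaims()
  rownames(nucleiDf) <- NULL; rownames(claimsDf) <- NULL
  new("SegmentationResult", slices = slices, nuclei = nucleiDf,
      members = members, claims = claimsDf,
      stageLog = list(nSeeds = nrow(seeds), nSlices = nrow(info),
                      nSeeded = nid, nSeedsSkipped = nSkipped,
                      nRecovered = 0L, nMerged = 0L, nSplit = 0L))
}

#' Slice ids not claimed by any nucleus
#'
#' @param result a [SegmentationResult-class].
#' @return integer vector of slice ids.
#' @export
unclaimedSlices <- function(result) {
  setdiff(sliceInfo(result@slices)$id, unique(result@claims$sliceId))
}

#' Recover overlooked (dim) nuclei from unclaimed slices
#'
#' Dim nuclei masked by brighter neighbors are not 3D response maxima, but
#' their slices survive segmentation and remain unclaimed. Iteratively, any
#' spherical physical neighborhood (radius \code{recoveryRadiusFactor *
#' nuclearDiameter / 2}, in micrometers) containing \code{minCluster} or more
#' unclaimed slices seeds an overlooked nucleus at the locally brightest
#' unclaimed slice (by filtered response at its center); the nucleus is then
#' extracted from the full slice set, claimed slices included, and the search
#' repeats until no qualifying cluster remains. Each pass claims at least the
#' seeding slice, so termination is bounded by the slice count.
#'
#' @param result a [SegmentationResult-class] from [extractAll()].
#' @param model a trained [ShapeModel-class].
#' @param config a [detectionConfig()].
#' @return the augmented [SegmentationResult-class]; recovered nuclei carry
#'   status \code{"recovered"}.
#' @export
recoverOverlooked <- function(result, model, config = detectionConfig()) {
  slices <- result@slices
  info <- sliceInfo(slices)
  sp <- voxelSpacing(slices)
  radius <- config$recoveryRadiusFactor * (config$nuclearDiameter / 2) *
    mean(sp[c("x", "y")])
  nRecovered <- 0L
  repeat {
    un <- unclaimedSlices(result)
    if (length(un) < config$minCluster) break
    u <- info[info$id %in% un, , drop = FALSE]
    py <- (u$y - 1) * sp["y"]; px <- (u$x - 1) * sp["x"]
    pz <- (u$z - 1) * sp["z"]
    counts <- vapply(seq_len(nrow(u)), function(i) {
      sum((py - py[i])^2 + (px - px[i])^2 + (pz - pz[i])^2 <= radius^2)
    }, numeric(1))
    qualify <- counts >= config$minCluster
    if (!any(qualify)) break
    q <- u[qualify, , drop = FALSE]
    seedSlice <- q[order(-q$peakResponse, q$id)[1], ]
    nid <- max(result@nuclei$id, 0L) + 1L
    ext <- extractNucleus(seedSlice$id, slices, model, config, id = nid,
                          status = "recovered")
    result@nuclei <- rbind(result@nuclei, ext$nucleus)
    result@members[[as.character(nid)]] <- ext$memberSliceIds
    result@claims <- rbind(result@claims, ext$claims)
    nRecovered <- nRecovered + 1L
  }
  result@stageLog$nRecovered <- nRecovered
  rownames(result@nuclei) <- NULL
  result
}

# Score the merged configuration of two nuclei: union of their slices, center
# at the slice closest to the geometric middle of the set, every other slice
# scored against that center. Planes holding two slices keep the
# higher-scoring one; the member set is trimmed to the contiguous plane run
# containing the center. Returns NULL when the union cannot form a nucleus.
scoreMerge <- function(result, idA, idB, model, config) {
  slices <- result@slices
  info <- sliceInfo(slices)
  U <- union(result@members[[as.character(idA)]],
             result@members[[as.character(idB)]])
  rows <- info[match(U, info$id), ]
  mid <- c(mean(rows$y), mean(rows$x), mean(rows$z))
  ctrIdx <- which.min((rows$y - mid[1])^2 + (rows$x - mid[2])^2 +
                        (rows$z - mid[3])^2)
  ctr <- rows[ctrIdx, ]
  lo <- numeric(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    lo[i] <- if (rows$id[i] == ctr$id) {
      centerSelfClaim(model)
    } else {
      interv <- findIntervening(rows[i, ], ctr, rows)
      classifySlice(computeFeatures(rows[i, ], ctr, interv), model)$logOdds
    }
  }
  # one slice per plane: keep the stronger score
  keep <- rep(TRUE, nrow(rows))
  for (p in unique(rows$z)) {
    at <- which(rows$z == p)
    if (length(at) > 1L) {
      best <- at[which.max(lo[at])]
      if (ctr$id %in% rows$id[at]) best <- at[rows$id[at] == ctr$id]
      keep[setdiff(at, best)] <- FALSE
    }
  }
  # contiguity: maximal plane run containing the center plane
  planes <- sort(unique(rows$z[keep]))
  runStart <- ctr$z; runEnd <- ctr$z
  while ((runStart - 1L) %in% planes) runStart <- runStart - 1L
  while ((runEnd + 1L) %in% planes) runEnd <- runEnd + 1L
  keep <- keep & rows$z >= runStart & rows$z <= runEnd
  if (!any(keep)) return(NULL)
  list(score = sum(lo[keep]), sliceIds = rows$id[keep], logOdds = lo[keep],
       centerSliceId = ctr$id)
}

isContiguousWithCenter <- function(info, sliceIds, centerSliceId) {
  if (!(centerSliceId %in% sliceIds)) return(FALSE)
  zz <- sort(info$z[match(sliceIds, info$id)])
  identical(as.integer(zz), as.integer(seq(zz[1], zz[length(zz)])))
}

# Score the split configuration: each contested slice goes to the nucleus
# with the stronger claim, subject to both nuclei remaining plane-contiguous
# around their centers. Small contested sets are enumerated exhaustively;
# returns NULL when no valid assignment exists.
scoreSplit <- function(result, idA, idB, config) {
  info <- sliceInfo(result@slices)
  mA <- result@members[[as.character(idA)]]
  mB <- result@members[[as.character(idB)]]
  contested <- intersect(mA, mB)
  claimOf <- function(nid, sid) {
    cl <- result@claims
    v <- cl$logOdds[cl$nucleusId == nid & cl$sliceId == sid]
    if (length(v)) v[1] else -Inf
  }
  ctrA <- result@nuclei$centerSliceId[result@nuclei$id == idA]
  ctrB <- result@nuclei$centerSliceId[result@nuclei$id == idB]
  k <- length(contested)
  assignments <- if (k <= 12L) {
    expand.grid(rep(list(c(TRUE, FALSE)), k))   # TRUE = goes to A
  } else {
    as.data.frame(t(vapply(contested, function(s)
      claimOf(idA, s) >= claimOf(idB, s), logical(1))))
  }
  best <- NULL
  for (r in seq_len(nrow(assignments))) {
    toA <- contested[as.logical(assignments[r, ])]
    toB <- setdiff(contested, toA)
    newA <- c(setdiff(mA, contested), toA)
    newB <- c(setdiff(mB, contested), toB)
    if (!length(newA) || !length(newB)) next
    if (!isContiguousWithCenter(info, newA, ctrA)) next
    if (!isContiguousWithCenter(info, newB, ctrB)) next
    score <- sum(vapply(newA, function(s) claimOf(idA, s), numeric(1))) +
      sum(vapply(newB, function(s) claimOf(idB, s), numeric(1)))
    if (is.null(best) || score > best$score)
      best <- list(score = score, toA = toA, toB = toB)
  }
  best
}

updateNucleusRow <- function(result, nid) {
  ids <- result@members[[as.character(nid)]]
  i <- which(result@nuclei$id == nid)
  cl <- result@claims
  lo <- vapply(ids, function(s)
    cl$logOdds[cl$nucleusId == nid & cl$sliceId == s][1], numeric(1))
  row <- nucleusSummary(result@slices, ids, lo,
                        result@nuclei$centerSliceId[i], nid,
                        result@nuclei$status[i])
  result@nuclei[i, ] <- row
  result
}

#' Resolve conflicting claims by merging nuclei or splitting their overlap
#'
#' Redundant detections of one nucleus (typically its upper and lower halves,
#' seeded separately by uneven intensity) reveal themselves as overlapping
#' claims. For every pair of nuclei sharing at least \code{overlapSlices}
#' slices, two configurations are scored against the shape model: merging (a
#' single nucleus from the union of the slices, centered on the slice closest
#' to the geometric middle of the set) and splitting (each contested slice to
#' the nucleus with the stronger claim, subject to both nuclei remaining
#' plane-contiguous). The higher-scoring configuration is applied; when no
#' valid split exists the pair is merged. Pairs are processed in descending
#' shared-slice order and scores are recomputed after every applied decision,
#' so the procedure is greedy but deterministic. Afterwards every slice has
#' at most one claimant.
#'
#' @param result a [SegmentationResult-class] after extraction/recovery.
#' @param model a trained [ShapeModel-class].
#' @param config a [detectionConfig()].
#' @return the resolved [SegmentationResult-class]; merged nuclei carry
#'   status \code{"merged"}.
#' @export
resolveConflicts <- function(result, model, config = detectionConfig()) {
  nMerged <- 0L; nSplit <- 0L
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 10L * max(1L, nrow(result@nuclei) + nrow(result@claims)))
      stop("conflict resolution failed to converge")   # defensive; unreachable
    # find the pair sharing the most slices
    dup <- result@claims[duplicated(result@claims$sliceId) |
                           duplicated(result@claims$sliceId, fromLast = TRUE), ]
    if (!nrow(dup)) break
    pairCount <- list()
    for (sid in unique(dup$sliceId)) {
      nids <- sort(dup$nucleusId[dup$sliceId == sid])
      for (a in seq_along(nids)) for (b in seq_along(nids)) if (a < b) {
        key <- paste(nids[a], nids[b])
        pairCount[[key]] <- (pairCount[[key]] %||% 0L) + 1L
      }
    }
    counts <- unlist(pairCount)
    counts <- counts[counts >= config$overlapSlices]
    if (!length(counts)) break
    key <- names(counts)[order(-counts, names(counts))][1]
    ids <- as.integer(strsplit(key, " ")[[1]])
    idA <- ids[1]; idB <- ids[2]
    merge <- scoreMerge(result, idA, idB, model, config)
    split <- scoreSplit(result, idA, idB, config)
    useMerge <- is.null(split) ||
      (!is.null(merge) && merge$score > split$score)
    if (useMerge && is.null(merge))
      stop("neither merge nor split is feasible for nuclei ", idA, ", ", idB)
    if (useMerge) {
      released <- setdiff(union(result@members[[as.character(idA)]],
                                result@members[[as.character(idB)]]),
                          merge$sliceIds)
      nid <- max(result@nuclei$id) + 1L
      result@nuclei <- result@nuclei[!result@nuclei$id %in% c(idA, idB), ]
      result@members[[as.character(idA)]] <- NULL
      result@members[[as.character(idB)]] <- NULL
      result@claims <- result@claims[!result@claims$nucleusId %in%
                                       c(idA, idB), ]
      result@nuclei <- rbind(result@nuclei,
                             nucleusSummary(result@slices, merge$sliceIds,
                                            merge$logOdds,
                                            merge$centerSliceId, nid,
                                            "merged"))
      result@members[[as.character(nid)]] <-
        orderByPlane(result@slices, merge$sliceIds)
      result@claims <- rbind(result@claims,
                             data.frame(sliceId = as.integer(merge$sliceIds),
                                        nucleusId = nid,
                                        logOdds = merge$logOdds))
      nMerged <- nMerged + 1L
    } else {
      lostByA <- split$toB; lostByB <- split$toA
      cl <- result@claims
      drop <- (cl$nucleusId == idA & cl$sliceId %in% lostByA) |
        (cl$nucleusId == idB & cl$sliceId %in% lostByB)
      result@claims <- cl[!drop, ]
      result@members[[as.character(idA)]] <-
        orderByPlane(result@slices,
                     setdiff(result@members[[as.character(idA)]], lostByA))
      result@members[[as.character(idB)]] <-
        orderByPlane(result@slices,
                     setdiff(result@members[[as.character(idB)]], lostByB))
      result <- updateNucleusRow(result, idA)
      result <- updateNucleusRow(result, idB)
      nSplit <- nSplit + 1L
    }
    rownames(result@nuclei) <- NULL
    rownames(result@claims) <- NULL
  }
  result@stageLog$nMerged <- nMerged
  result@stageLog$nSplit <- nSplit
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resultRecord <- function(result, volumeName, spacing, config) {
  nz <- result@nuclei
  rec <- data.frame(id = nz$id, x = nz$x, y = nz$y, z = nz$z,
                    diameter = nz$diameter, status = nz$status)
  snapshot <- if (inherits(config, "blobsliceConfig")) unclass(config)
  else as.list(config)
  snapshot <- snapshot[!vapply(snapshot, is.null, logical(1))]
  DetectionRecord(rec, volumeName = volumeName, spacing = spacing,
                  configSnapshot = snapshot)
}

#' Run the full detection pipeline on a volume
#'
#' Executes every stage in order: DoG filtering, 3D/2D maxima, slice
#' segmentation, seeded nuclear extraction, recovery of overlooked nuclei,
#' and conflict resolution. Intermediate detection records after each stage
#' are retained so that per-stage error accounting (how much recovery lowers
#' false negatives, how much conflict resolution lowers false positives) can
#' be computed against ground truth.
#'
#' @param volume an [ImageVolume-class].
#' @param model a trained [ShapeModel-class] (see [defaultShapeModel()],
#'   [trainShapeModel()]).
#' @param config a [detectionConfig()].
#' @return a [NucleusDetection-class].
#' @examples
#' \donttest{
#' scene <- generateScene(sceneSpec(nNuclei = 6, shape = c(64, 64, 16)))
#' det <- detectNuclei(scene$volume, defaultShapeModel(),
#'                     detectionConfig(nuclearDiameter = 10,
#'                                     noiseThreshold = 2))
#' nucleiTable(det)
#' }
#' @export
detectNuclei <- function(volume, model, config = detectionConfig()) {
  stopifnot(is(volume, "ImageVolume"), is(model, "ShapeModel"))
  filtered <- dogFilter(volume, config)
  seeds <- find3dMaxima(filtered, config$noiseThreshold)
  slices <- segmentAllSlices(volume, filtered, config)
  res0 <- extractAll(seeds, slices, model, config)
  res1 <- recoverOverlooked(res0, model, config)
  res2 <- resolveConflicts(res1, model, config)
  sp <- voxelSpacing(volume)
  recs <- list(initial = resultRecord(res0, volume@name, sp, config),
               recovered = resultRecord(res1, volume@name, sp, config),
               final = resultRecord(res2, volume@name, sp, config))
  log <- res2@stageLog
  log$nRecovered <- res1@stageLog$nRecovered
  log$nFinal <- nrow(res2@nuclei)
  res2@stageLog <- log
  new("NucleusDetection", record = recs$final, stageRecords = recs,
      result = res2, stageLog = log)
}
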