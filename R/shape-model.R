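FEATURE_NAMES <- c("dz", "centerOffset", "logRadiusRatio",
                   "logIntensityRatio", "intervOffset", "logRadiusRatioInterv",
                   "logIntensityRatioInterv")

sliceRow <- function(slices, id) {
  info <- sliceInfo(slices)
  i <- match(id, info$id)
  if (is.na(i)) stop("unknown slice id: ", id)
  info[i, ]
}

#' Feature vector of a candidate slice relative to a nuclear center
#'
#' Describes a candidate slice's position, size and intensity relative to the
#' center slice of a nucleus and to the closest intervening slice (the member
#' slice on the plane between candidate and center; when the candidate is on
#' a plane adjacent to the center, the intervening slice is the center
#' itself). The 7 dimensions are: signed z offset in planes; in-plane center
#' offset normalized by the center's equivalent radius; log radius ratio
#' candidate/center; log mean-intensity ratio candidate/center; and the
#' offset/radius/intensity triple measured against the intervening slice.
#' Ratios make the features invariant to global intensity rescaling; the z
#' offset is signed because depth fading makes above and below asymmetric.
#'
#' @param candidate,center,intervening slices, each a list or one-row
#'   data.frame with fields \code{y, x, z, radius, meanIntensity}. Candidate
#'   and center must lie on distinct planes.
#' @return named numeric of length 7; log ratios clamp their arguments at
#'   1e-6 to stay finite.
#' @export
computeFeatures <- function(candidate, center, intervening = center) {
  eps <- 1e-6
  if (center$radius <= 0) stop("center slice radius must be > 0")
  if (candidate$z == center$z)
    stop("candidate and center must lie on distinct planes")
  lograt <- function(a, b) log(max(a, eps) / max(b, eps))
  off <- function(a, b) sqrt((a$y - b$y)^2 + (a$x - b$x)^2)
  f <- c(candidate$z - center$z,
         off(candidate, center) / center$radius,
         lograt(candidate$radius, center$radius),
         lograt(candidate$meanIntensity, center$meanIntensity),
         off(candidate, intervening) / max(intervening$radius, eps),
         lograt(candidate$radius, intervening$radius),
         lograt(candidate$meanIntensity, intervening$meanIntensity))
  names(f) <- FEATURE_NAMES
  f
}

#' Train the two-class Gaussian shape model
#'
#' Maximum-likelihood fit of a 7-D Gaussian to each class: sample means and
#' sample covariances (1/(n-1)), with a ridge of
#' \code{regularization * mean(diag(cov))} added to each covariance diagonal
#' so that small training sets never yield singular models. Priors default to
#' the empirical class frequencies.
#'
#' @param features numeric matrix, one row per labeled example, 7 columns.
#' @param labels character/factor vector of \code{"member"} /
#'   \code{"distractor"} parallel to the rows.
#' @param regularization ridge fraction (default 1e-4).
#' @param priors optional length-2 override (member, distractor), normalized
#'   to sum to 1.
#' @param minPerClass minimum examples per class (default 10).
#' @return a [ShapeModel-class].
#' @seealso [classifySlice()], [sceneTrainingLabels()]
#' @export
trainShapeModel <- function(features, labels, regularization = 1e-4,
                            priors = NULL, minPerClass = 10L) {
  features <- as.matrix(features)
  if (ncol(features) != 7L) stop("feature matrix must have 7 columns")
  labels <- as.character(labels)
  if (!all(labels %in% c("member", "distractor")))
    stop("labels must be 'member' or 'distractor'")
  fitClass <- function(cls) {
    rows <- features[labels == cls, , drop = FALSE]
    if (nrow(rows) < minPerClass)
      stop(sprintf("class '%s' has %d examples; need at least %d",
                   cls, nrow(rows), minPerClass))
    cv <- if (nrow(rows) > 1) stats::cov(rows) else matrix(0, 7, 7)
    ridge <- regularization * max(mean(diag(cv)), 1)
    list(mean = colMeans(rows), cov = cv + diag(ridge, 7),
         n = nrow(rows))
  }
  m <- fitClass("member")
  d <- fitClass("distractor")
  p <- if (is.null(priors)) c(m$n, d$n) / (m$n + d$n) else priors / sum(priors)
  names(p) <- c("member", "distractor")
  new("ShapeModel",
      memberMean = unname(m$mean), memberCov = unname(m$cov),
      distractorMean = unname(d$mean), distractorCov = unname(d$cov),
      priors = p,
      nTraining = c(member = as.integer(m$n), distractor = as.integer(d$n)),
      regularization = regularization)
}

logdmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * sum(d^2) - sum(log(diag(ch))) - 0.5 * length(mu) * log(2 * pi)
}

#' Classify a candidate slice as nuclear member or distractor
#'
#' Maximum-likelihood two-class decision: the log odds are
#' \code{log N(f; member) + log p_member - log N(f; distractor) -
#' log p_distractor}; the label is \code{member} iff the log odds are
#' strictly positive (ties resolve to distractor, which keeps claiming
#' conservative). The log odds double as the claim strength used by the
#' extraction and conflict-resolution stages.
#'
#' @param feature numeric length-7 feature vector from [computeFeatures()].
#' @param model a trained [ShapeModel-class].
#' @return list with \code{label} (\code{"member"}/\code{"distractor"}) and
#'   \code{logOdds}.
#' @export
classifySlice <- function(feature, model) {
  stopifnot(is(model, "ShapeModel"))
  f <- as.numeric(feature)
  if (length(f) != 7L) stop("feature must have length 7")
  lo <- logdmvnorm(f, model@memberMean, model@memberCov) +
    log(model@priors["member"]) -
    logdmvnorm(f, model@distractorMean, model@distractorCov) -
    log(model@priors["distractor"])
  lo <- unname(lo)
  list(label = if (lo > 0) "member" else "distractor", logOdds = lo)
}

# Intervening slice for a candidate at plane cz relative to a center slice:
# the nearest-in-plane slice of `pool` on the adjacent plane toward the
# center (searching farther intervening planes on a gap); the center itself
# when the candidate is adjacent.
findIntervening <- function(candidate, center, pool) {
  dir <- sign(candidate$z - center$z)
  planes <- candidate$z - dir * seq_len(abs(candidate$z - center$z) - 1L)
  for (p in planes) {
    onPlane <- pool[pool$z == p, , drop = FALSE]
    if (nrow(onPlane)) {
      d2 <- (onPlane$y - candidate$y)^2 + (onPlane$x - candidate$x)^2
      return(onPlane[which.min(d2), ])
    }
  }
  center
}

#' Generate the candidate worksheet for shape-model training
#'
#' For every seed (candidate nuclear center), lists all slices within a
#' z window and an in-plane radius of the seed's slice: the superset of
#' slices that might belong to that nucleus. The worksheet carries the
#' 7 features of each (center, candidate) pairing plus an empty \code{label}
#' column which a human (or synthetic ground truth) fills with
#' \code{member} / \code{distractor}; [worksheetFeatures()] then converts the
#' corrected worksheet into training data.
#'
#' @param slices a [SliceSet-class].
#' @param seeds data.frame from [find3dMaxima()].
#' @param config a [detectionConfig()]; the z window is
#'   \code{ceiling(nuclearDiameter/2 * xy spacing / z spacing) + 1} planes
#'   and the in-plane gate is the sum of candidate and center radii.
#' @return data.frame: \code{seedIndex, centerSliceId, candidateSliceId},
#'   the 7 feature columns, and \code{label} (NA).
#' @export
trainingCandidates <- function(slices, seeds, config = detectionConfig()) {
  info <- sliceInfo(slices)
  sp <- voxelSpacing(slices)
  zWindow <- ceiling((config$nuclearDiameter / 2) *
                       mean(sp[c("x", "y")]) / sp["z"]) + 1L
  out <- list()
  for (s in seq_len(nrow(seeds))) {
    ctrIdx <- which(info$z == seeds$z[s] & info$y == seeds$y[s] &
                      info$x == seeds$x[s])
    if (!length(ctrIdx)) next
    ctr <- info[ctrIdx[1], ]
    near <- info[info$z != ctr$z & abs(info$z - ctr$z) <= zWindow, ,
                 drop = FALSE]
    if (!nrow(near)) next
    dist <- sqrt((near$y - ctr$y)^2 + (near$x - ctr$x)^2)
    near <- near[dist < near$radius + ctr$radius, , drop = FALSE]
    for (i in seq_len(nrow(near))) {
      cand <- near[i, ]
      interv <- findIntervening(cand, ctr, near)
      f <- computeFeatures(cand, ctr, interv)
      out[[length(out) + 1L]] <- data.frame(
        seedIndex = s, centerSliceId = ctr$id, candidateSliceId = cand$id,
        as.list(f), label = NA_character_)
    }
  }
  if (!length(out)) {
    cols <- stats::setNames(rep(list(numeric()), 7), FEATURE_NAMES)
    return(cbind(data.frame(seedIndex = integer(), centerSliceId = integer(),
                            candidateSliceId = integer()),
                 as.data.frame(cols),
                 data.frame(label = character())))
  }
  do.call(rbind, out)
}

#' Convert a labeled worksheet into training features
#'
#' @param worksheet data.frame from [trainingCandidates()] with the
#'   \code{label} column filled; rows with missing labels are dropped.
#' @return list with \code{features} (matrix) and \code{labels} (character).
#' @rdname trainingCandidates
#' @export
worksheetFeatures <- function(worksheet) {
  keep <- !is.na(worksheet$label) & worksheet$label %in%
    c("member", "distractor")
  ws <- worksheet[keep, , drop = FALSE]
  list(features = as.matrix(ws[, FEATURE_NAMES, drop = FALSE]),
       labels = as.character(ws$label))
}

#' @param worksheet data.frame from [trainingCandidates()].
#' @param path CSV file path.
#' @rdname trainingCandidates
#' @export
writeWorksheet <- function(worksheet, path) {
  utils::write.csv(worksheet, path, row.names = FALSE)
  invisible(path)
}

#' @rdname trainingCandidates
#' @export
readWorksheet <- function(path) {
  if (!file.exists(path)) stop("worksheet not found: ", path)
  ws <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("seedIndex", "centerSliceId", "candidateSliceId", FEATURE_NAMES,
            "label")
  if (!all(need %in% names(ws)))
    stop("worksheet is missing columns: ",
         paste(setdiff(need, names(ws)), collapse = ", "))
  ws$label <- as.character(ws$label)
  ws
}
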