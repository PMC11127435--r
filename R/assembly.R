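# Skeleton assembly from rendered fields: peak detection on confidence
# maps, affinity line-integral scoring, greedy limb matching, and the
# masked field-loss metrics.

#' Detect joint candidates in a confidence map
#'
#' Finds local maxima at or above \code{threshold} and applies greedy
#' non-maximum suppression within a Euclidean radius. Candidates are
#' returned sorted by descending score, ties broken by (row, column)
#' order, so the result is fully deterministic.
#'
#' @param confMap numeric matrix \code{[y, x]}.
#' @param threshold minimum score, in (0, 1).
#' @param nmsRadius suppression radius in pixels.
#' @return data frame with columns \code{x}, \code{y}, \code{score};
#'   zero rows when nothing clears the threshold.
#' @export
detectPeaks <- function(confMap, threshold = 0.1, nmsRadius = 6) {
  if (threshold <= 0 || threshold >= 1) .stopf("threshold must be in (0, 1)")
  h <- nrow(confMap)
  w <- ncol(confMap)
  # restrict the 8-neighbour maximum test to cells above threshold
  above <- which(confMap >= threshold)
  if (length(above) == 0L)
    return(data.frame(x = numeric(), y = numeric(), score = numeric()))
  ay <- (above - 1L) %% h + 1L
  ax <- (above - 1L) %/% h + 1L
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- confMap
  v <- confMap[above]
  isMax <- rep(TRUE, length(above))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    isMax <- isMax & v >= pad[cbind(ay + 1L + dy, ax + 1L + dx)]
  }
  cx <- ax[isMax]; cy <- ay[isMax]; cs <- v[isMax]
  o <- order(-cs, cy, cx)
  cx <- cx[o]; cy <- cy[o]; cs <- cs[o]
  n <- length(cx)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0L ||
        all((kx - cx[i])^2 + (ky - cy[i])^2 > nmsRadius^2)) {
      keep[i] <- TRUE
      kx <- c(kx, cx[i]); ky <- c(ky, cy[i])
    }
  }
  data.frame(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
             score = cs[keep])
}

#' Affinity reliability of a candidate joint pair
#'
#' Discretized line integral of the affinity field projected onto the
#' candidate segment: with q(u) = (1 - u) a + u b, the field is sampled
#' at the nearest grid point of \code{nSamples} uniformly spaced u in
#' [0, 1] and dotted with the unit vector from \code{a} to \code{b}. The
#' mean (not the raw sum) is returned, so a perfectly aligned field
#' scores exactly 1 regardless of \code{nSamples}.
#'
#' @param field numeric array \code{[y, x, 2]}: one limb's two-channel
#'   affinity field.
#' @param a,b candidate positions \code{(x, y)}; the projection direction
#'   runs from \code{a} to \code{b}.
#' @param nSamples number of integration samples (at least 2).
#' @return scalar reliability E.
#' @export
affinityScore <- function(field, a, b, nSamples = 10L) {
  a <- as.numeric(a)[1:2]
  b <- as.numeric(b)[1:2]
  if (nSamples < 2L) .stopf("nSamples must be >= 2")
  d <- b - a
  len <- sqrt(sum(d^2))
  if (len < 1e-9) .stopf("zero-length candidate pair")
  dhat <- d / len
  u <- seq(0, 1, length.out = nSamples)
  qx <- pmin(pmax(round((1 - u) * a[1L] + u * b[1L]), 1L), ncol(field))
  qy <- pmin(pmax(round((1 - u) * a[2L] + u * b[2L]), 1L), nrow(field))
  lx <- field[cbind(qy, qx, 1L)]
  ly <- field[cbind(qy, qx, 2L)]
  mean(lx * dhat[1L] + ly * dhat[2L])
}

#' Assemble skeletons by greedy limb matching
#'
#' For each limb type, all cross pairs of endpoint candidates are scored
#' with \code{\link{affinityScore}}, sorted by descending reliability
#' (ties broken by candidate indices), and greedily accepted while both
#' endpoints are unused and E is at least \code{eMin}. Accepted limbs
#' sharing a candidate are then merged into per-person skeletons.
#'
#' Orientation: the rendered field of limb (j1, j2) points from j2
#' towards j1, so pairs are scored from the j2 candidate towards the j1
#' candidate and a correct connection scores close to +1.
#'
#' @param candidates list of candidate data frames (as returned by
#'   \code{\link{detectPeaks}}), one per joint, in joint-index order.
#' @param fields affinity array \code{[y, x, 2, limb]}.
#' @param jointModel the \linkS4class{JointModel}.
#' @param eMin minimum reliability for accepting a connection.
#' @param nSamples integration samples per pair.
#' @param singles keep unmatched candidates as single-joint skeletons.
#' @return list of \linkS4class{AssembledSkeleton}.
#' @export
matchLimbs <- function(candidates, fields, jointModel = JointModel(),
                       eMin = 0.5, nSamples = 10L, singles = FALSE) {
  limbs <- jointModel@limbs
  nJ <- length(jointModel@jointNames)
  nCand <- vapply(candidates, nrow, integer(1L))
  off <- cumsum(c(0L, nCand))[seq_len(nJ)]  # global candidate numbering
  nNodes <- sum(nCand)
  parent <- seq_len(max(nNodes, 1L))
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  # accepted connections: limb0, i1, i2, E (candidate indices per joint)
  cLimb <- integer(0); cI1 <- integer(0); cI2 <- integer(0); cE <- numeric(0)
  for (ci in seq_len(nrow(limbs))) {
    j1 <- limbs[ci, 1L] + 1L
    j2 <- limbs[ci, 2L] + 1L
    cA <- candidates[[j1]]
    cB <- candidates[[j2]]
    nA <- nCand[j1]; nB <- nCand[j2]
    if (nA == 0L || nB == 0L) next
    ia <- rep(seq_len(nA), times = nB)
    ib <- rep(seq_len(nB), each = nA)
    fld <- fields[, , , ci]
    E <- vapply(seq_along(ia), function(k) {
      a <- c(cB$x[ib[k]], cB$y[ib[k]])
      b <- c(cA$x[ia[k]], cA$y[ia[k]])
      if (sum((a - b)^2) < 1e-18) return(-Inf)
      affinityScore(fld, a, b, nSamples)
    }, numeric(1L))
    usedA <- logical(nA)
    usedB <- logical(nB)
    for (k in order(-E, ia, ib)) {
      if (E[k] < eMin) break
      if (usedA[ia[k]] || usedB[ib[k]]) next
      usedA[ia[k]] <- TRUE
      usedB[ib[k]] <- TRUE
      cLimb <- c(cLimb, ci - 1L); cI1 <- c(cI1, ia[k])
      cI2 <- c(cI2, ib[k]); cE <- c(cE, E[k])
      ra <- findRoot(off[j1] + ia[k])
      rb <- findRoot(off[j2] + ib[k])
      if (ra != rb) parent[ra] <- rb
    }
  }

  if (nNodes == 0L) return(list())
  roots <- vapply(seq_len(nNodes), findRoot, integer(1L))
  nodeJoint <- rep(seq_len(nJ), nCand)
  nodeIdx <- unlist(lapply(nCand, seq_len), use.names = FALSE)
  connRoot <- if (length(cLimb))
    vapply(seq_along(cLimb), function(k)
      findRoot(off[limbs[cLimb[k] + 1L, 1L] + 1L] + cI1[k]), integer(1L))
  else integer(0)

  skels <- list()
  for (root in sort(unique(roots))) {
    mem <- which(roots == root)
    if (length(mem) < 2L && !singles) next
    co <- matrix(NA_real_, nJ, 2L,
                 dimnames = list(jointNames(jointModel), c("x", "y")))
    sc <- rep(NA_real_, nJ)
    for (nd in mem) {
      j <- nodeJoint[nd]; i <- nodeIdx[nd]
      co[j, 1L] <- candidates[[j]]$x[i]
      co[j, 2L] <- candidates[[j]]$y[i]
      sc[j] <- candidates[[j]]$score[i]
    }
    inC <- which(connRoot == root)
    limbDf <- data.frame(limb = cLimb[inC], candA = cI1[inC],
                         candB = cI2[inC], E = cE[inC])
    skels[[length(skels) + 1L]] <-
      new("AssembledSkeleton", coords = co, scores = sc, limbs = limbDf)
  }
  # deterministic order: by leftmost recovered joint, then topmost
  if (length(skels) > 1L) {
    kx <- vapply(skels, function(s) min(s@coords[, 1L], na.rm = TRUE), numeric(1L))
    ky <- vapply(skels, function(s) min(s@coords[, 2L], na.rm = TRUE), numeric(1L))
    skels <- skels[order(kx, ky)]
  }
  skels
}

setMethod("show", "AssembledSkeleton", function(object) {
  cat(sprintf("AssembledSkeleton: %d/%d joints, %d limbs, mean E %.3f\n",
              sum(!is.na(object@scores)), length(object@scores),
              nrow(object@limbs),
              if (nrow(object@limbs)) mean(object@limbs$E) else NA_real_))
})

#' Assemble the skeletons of a rendered scene
#'
#' Runs peak detection on every joint map of a \linkS4class{FieldScene}
#' and matches the candidates through the scene's affinity fields.
#'
#' @param scene a \linkS4class{FieldScene}.
#' @param threshold,nmsRadius peak detection settings;
#'   \code{nmsRadius = NULL} defaults to the scene's sigma.
#' @param eMin,nSamples,singles passed to \code{\link{matchLimbs}}.
#' @param jointModel the \linkS4class{JointModel}.
#' @return list of \linkS4class{AssembledSkeleton}.
#' @export
assembleScene <- function(scene, threshold = 0.1, nmsRadius = NULL,
                          eMin = 0.5, nSamples = 10L, singles = FALSE,
                          jointModel = JointModel()) {
  if (is.null(nmsRadius)) nmsRadius <- scene@params@sigma
  nJ <- dim(scene@confMaps)[3L]
  cands <- lapply(seq_len(nJ), function(j)
    detectPeaks(scene@confMaps[, , j], threshold, nmsRadius))
  matchLimbs(cands, scene@pafFields, jointModel, eMin, nSamples, singles)
}

#' Re-detect a whole motion through rendered fields
#'
#' For every frame of a single-person motion: render the scene, detect
#' peaks, and assemble; the recovered joint positions form a new
#' sequence. This exercises the full detection path (grid quantization
#' included) instead of passing generator truth downstream. Occasional
#' missing joints are filled by carrying the previous frame's position
#' (leading gaps are back-filled).
#'
#' @param motion a \linkS4class{MotionSequence}.
#' @param params \linkS4class{SceneParams} for rendering.
#' @param jointModel the \linkS4class{JointModel}.
#' @param ... passed to \code{\link{assembleScene}}.
#' @return a \linkS4class{MotionSequence} of assembled coordinates,
#'   carrying the input's label.
#' @export
assembleMotion <- function(motion, params = SceneParams(),
                           jointModel = JointModel(), ...) {
  nT <- nFrames(motion)
  nJ <- nJoints(motion)
  out <- array(NA_real_, dim = c(nT, nJ, 2L))
  for (tIdx in seq_len(nT)) {
    scene <- makeScene(list(motion), tIdx, params, jointModel)
    sk <- assembleScene(scene, jointModel = jointModel, ...)
    if (length(sk) == 0L) next
    nRec <- vapply(sk, function(s) sum(!is.na(s@scores)), integer(1L))
    out[tIdx, , ] <- sk[[which.max(nRec)]]@coords
  }
  # fill gaps along time, then back-fill leading gaps
  for (j in seq_len(nJ)) for (ax in 1:2) {
    v <- out[, j, ax]
    if (all(is.na(v))) .stopf("joint %d never recovered", j - 1L)
    for (k in seq_len(nT)) if (is.na(v[k]) && k > 1L) v[k] <- v[k - 1L]
    for (k in rev(seq_len(nT))) if (is.na(v[k]) && k < nT) v[k] <- v[k + 1L]
    out[, j, ax] <- v
  }
  MotionSequence(out, t = motion@t, personId = motion@personId,
                 label = motion@label, fps = motion@fps)
}

#' Masked squared-error field losses
#'
#' Computes the annotation-masked squared L2 losses between predicted and
#' true fields: \code{fR} sums \code{w(q) ||pred - true||^2} over joint
#' confidence maps, \code{fM} the analogous vector norm over limb
#' affinity fields, and \code{f = fR + fM}. Points with mask 0
#' (unannotated) contribute nothing, so a positive sample is never
#' penalized for missing labels.
#'
#' @param predMaps,trueMaps confidence arrays \code{[y, x, joint]}.
#' @param predFields,trueFields affinity arrays \code{[y, x, 2, limb]}.
#' @param mask per-joint 0/1 array \code{[y, x, joint]} or a single
#'   \code{[y, x]} matrix recycled over joints.
#' @param fieldMask optional per-limb mask \code{[y, x, limb]} or
#'   \code{[y, x]}; by default the product of the two endpoint joint
#'   masks of each limb (requires \code{jointModel}).
#' @param jointModel used only to derive the default \code{fieldMask}.
#' @return list with components \code{fR}, \code{fM}, \code{f}.
#' @export
fieldLoss <- function(predMaps, trueMaps, predFields, trueFields, mask,
                      fieldMask = NULL, jointModel = JointModel()) {
  if (!all(dim(predMaps) == dim(trueMaps)) ||
      !all(dim(predFields) == dim(trueFields)))
    .stopf("prediction and truth shapes disagree")
  nJ <- dim(predMaps)[3L]
  nC <- dim(predFields)[4L]
  if (length(dim(mask)) == 2L)
    mask <- array(mask, dim = c(dim(mask), nJ))
  if (!all(dim(mask) == dim(predMaps)))
    .stopf("mask shape disagrees with the maps")
  fR <- sum(mask * (predMaps - trueMaps)^2)
  if (is.null(fieldMask)) {
    limbs <- jointModel@limbs
    fieldMask <- array(0, dim = c(dim(mask)[1:2], nC))
    for (ci in seq_len(nC))
      fieldMask[, , ci] <- mask[, , limbs[ci, 1L] + 1L] *
                           mask[, , limbs[ci, 2L] + 1L]
  } else if (length(dim(fieldMask)) == 2L) {
    fieldMask <- array(fieldMask, dim = c(dim(fieldMask), nC))
  }
  dF <- (predFields - trueFields)^2
  dSum <- array(dF[, , 1L, , drop = FALSE] + dF[, , 2L, , drop = FALSE],
                dim = c(dim(dF)[1:2], nC))
  fM <- sum(fieldMask * dSum)
  list(fR = fR, fM = fM, f = fR + fM)
}

#' Total loss over refinement stages
#'
#' Sums \code{fR + fM} over a list of per-stage losses (each an output
#' of \code{\link{fieldLoss}}); with a single stage it degenerates to
#' \code{fR + fM}.
#'
#' @param stageLosses list of \code{\link{fieldLoss}} results.
#' @return scalar total loss.
#' @export
fieldLossTotal <- function(stageLosses) {
  sum(vapply(stageLosses, function(s) s$fR + s$fM, numeric(1L)))
}
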