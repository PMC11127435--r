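# Ground-truth field rendering.
#
# Confidence model: s*_{j,n}(q) = exp(-||q - x_{j,n}||^2 / sigma^2) per
# person, fused over persons by the pointwise maximum. Affinity model:
# on the support band of limb c of person n (within limbWidth of the
# segment, between the endpoints) the field holds the unit vector along
# the limb, oriented from the limb's second endpoint towards its first
# (V = (x_j1 - x_j2)/||.||); overlapping persons are averaged over the
# nonzero contributions.

#' Render per-joint confidence maps
#'
#' Each joint's map is a Gaussian bump \code{exp(-d^2 / sigma^2)} around
#' the true position of every person, fused across persons by the
#' pointwise maximum, so values lie in (0, 1] with the exact value 1 at
#' a true joint position. Invisible joints contribute nothing.
#'
#' @param truthFrames list of \linkS4class{SkeletonFrame} (one per
#'   person).
#' @param params \linkS4class{SceneParams} or a named list with at least
#'   \code{gridW}, \code{gridH}, \code{sigma}.
#' @return numeric array \code{[y, x, joint]}.
#' @export
renderConfidence <- function(truthFrames, params = SceneParams()) {
  p <- .paramsList(params)
  if (p$sigma <= 0) .stopf("sigma must be > 0")
  nJ <- nrow(truthFrames[[1L]]@coords)
  out <- array(0, dim = c(p$gridH, p$gridW, nJ))
  xs <- seq_len(p$gridW)
  ys <- seq_len(p$gridH)
  for (fr in truthFrames) {
    for (j in seq_len(nJ)) {
      if (!fr@visible[j]) next
      # the squared distance is separable, so the Gaussian is an outer
      # product of two 1-D profiles
      ex <- exp(-(xs - fr@coords[j, 1L])^2 / p$sigma^2)
      ey <- exp(-(ys - fr@coords[j, 2L])^2 / p$sigma^2)
      out[, , j] <- pmax(out[, , j], outer(ey, ex))
    }
  }
  out
}

#' Render per-limb part affinity fields
#'
#' A grid point q lies on limb c of person n when its projection onto the
#' segment falls between the endpoints and its perpendicular distance is
#' at most \code{limbWidth}. There the person's field is the unit vector
#' along the limb; where several persons' bands overlap, vectors are
#' averaged over the number of nonzero contributions, so single-person
#' support carries exactly unit norm and overlaps never exceed it.
#'
#' @inheritParams renderConfidence
#' @param jointModel the \linkS4class{JointModel} supplying the limb
#'   list.
#' @return numeric array \code{[y, x, channel, limb]}; channel 1 is the
#'   x component, channel 2 the y component.
#' @export
renderPAF <- function(truthFrames, params = SceneParams(),
                      jointModel = JointModel()) {
  p <- .paramsList(params)
  limbs <- jointModel@limbs
  nC <- nrow(limbs)
  sumF <- array(0, dim = c(p$gridH, p$gridW, 2L, nC))
  cnt <- array(0L, dim = c(p$gridH, p$gridW, nC))
  for (fr in truthFrames) {
    for (ci in seq_len(nC)) {
      p1 <- fr@coords[limbs[ci, 1L] + 1L, ]
      p2 <- fr@coords[limbs[ci, 2L] + 1L, ]
      dvec <- p1 - p2
      len <- sqrt(sum(dvec^2))
      if (len < 1e-9) {
        warning(sprintf("limb %d of person %d has coincident endpoints; skipped",
                        ci - 1L, fr@personId))
        next
      }
      v <- dvec / len
      x0 <- max(1L, floor(min(p1[1L], p2[1L]) - p$limbWidth))
      x1 <- min(p$gridW, ceiling(max(p1[1L], p2[1L]) + p$limbWidth))
      y0 <- max(1L, floor(min(p1[2L], p2[2L]) - p$limbWidth))
      y1 <- min(p$gridH, ceiling(max(p1[2L], p2[2L]) + p$limbWidth))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1
      ys <- y0:y1
      qx <- matrix(xs - p2[1L], length(ys), length(xs), byrow = TRUE)
      qy <- matrix(ys - p2[2L], length(ys), length(xs))
      along <- v[1L] * qx + v[2L] * qy
      perp <- abs(-v[2L] * qx + v[1L] * qy)
      on <- along >= 0 & along <= len & perp <= p$limbWidth
      if (!any(on)) next
      sumF[ys, xs, 1L, ci] <- sumF[ys, xs, 1L, ci] + v[1L] * on
      sumF[ys, xs, 2L, ci] <- sumF[ys, xs, 2L, ci] + v[2L] * on
      cnt[ys, xs, ci] <- cnt[ys, xs, ci] + on
    }
  }
  # cnt == 1 already holds the plain vector and cnt == 0 holds zero, so
  # only overlap cells need the average
  for (ci in seq_len(nC)) {
    cc <- cnt[, , ci]
    over <- which(cc > 1L)
    if (length(over)) {
      for (ch in 1:2) {
        sl <- sumF[, , ch, ci]
        sl[over] <- sl[over] / cc[over]
        sumF[, , ch, ci] <- sl
      }
    }
  }
  sumF
}

#' Compose a rendered scene at one frame index
#'
#' Bundles the confidence maps, affinity fields, annotation mask and the
#' ground-truth skeletons of one frame of one or more motions into a
#' \linkS4class{FieldScene}. The mask of a joint map is all ones when the
#' joint is marked visible for every person and all zeros otherwise.
#'
#' @param motions list of \linkS4class{MotionSequence}.
#' @param frameIdx 1-based frame position, present in every motion.
#' @param params \linkS4class{SceneParams}.
#' @param jointModel limb layout for the affinity fields.
#' @return a \linkS4class{FieldScene}.
#' @export
makeScene <- function(motions, frameIdx, params = SceneParams(),
                      jointModel = JointModel()) {
  if (length(motions) == 0L) .stopf("empty motion list")
  bad <- vapply(motions, function(m) frameIdx > nFrames(m), logical(1L))
  if (any(bad)) .stopf("frame %d missing from %d motion(s)", frameIdx, sum(bad))
  frames <- lapply(motions, getFrame, frameIdx = frameIdx)
  p <- .paramsList(params)
  nJ <- nrow(frames[[1L]]@coords)
  conf <- renderConfidence(frames, params)
  paf <- renderPAF(frames, params, jointModel)
  mask <- array(0, dim = c(p$gridH, p$gridW, nJ))
  for (j in seq_len(nJ)) {
    allVisible <- all(vapply(frames, function(f) f@visible[j], logical(1L)))
    if (allVisible) mask[, , j] <- 1
  }
  if (!is(params, "SceneParams"))
    params <- SceneParams(p$gridW, p$gridH, p$sigma, p$limbWidth,
                          p$nPersons, p$noiseSd, p$seed)
  new("FieldScene", confMaps = conf, pafFields = paf, mask = mask,
      truth = frames, params = params)
}

#' @rdname FieldScene-class
#' @aliases confMaps pafFields sceneMask truthFrames sceneParams
#' @export
setMethod("confMaps", "FieldScene", function(x) x@confMaps)

#' @rdname FieldScene-class
#' @export
setMethod("pafFields", "FieldScene", function(x) x@pafFields)

#' @rdname FieldScene-class
#' @export
setMethod("sceneMask", "FieldScene", function(x) x@mask)

#' @rdname FieldScene-class
#' @export
setMethod("truthFrames", "FieldScene", function(x) x@truth)

#' @rdname FieldScene-class
#' @export
setMethod("sceneParams", "FieldScene", function(x) x@params)

setMethod("show", "FieldScene", function(object) {
  d <- dim(object@confMaps)
  cat(sprintf("FieldScene: %dx%d grid, %d joint maps, %d limb fields, %d person(s)\n",
              d[2L], d[1L], d[3L], dim(object@pafFields)[4L],
              length(object@truth)))
})
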