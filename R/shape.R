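# Range normalization and Procrustes calibration.
#
# Keypoint sequences are standardized in two steps: an affine range
# normalization mapping x into [-200, 200] and y into [-800, 800]
# (matching the ~1:4 shoulder-width-to-height proportion of a standing
# body), and a per-frame similarity alignment -- translation to the
# centroid, anisotropic per-axis RMS scaling, and the least-squares
# optimal rotation against a model frame. The per-axis scaling is
# deliberately anisotropic and therefore applied before rotation; the
# two do not commute, and the fixed order translate -> scale -> rotate
# is part of the method.

#' Range-normalize a frame
#'
#' Affine, order-preserving per-axis map sending the given extrema to
#' exactly -200/200 on x and -800/800 on y:
#' \code{x = 400 (x_o - x_min)/(x_max - x_min) - 200},
#' \code{y = 1600 (y_o - y_min)/(y_max - y_min) - 800}.
#'
#' @param coords J x 2 coordinate matrix (or a
#'   \linkS4class{SkeletonFrame}).
#' @param xMin,xMax,yMin,yMax the defining extrema; default the frame's
#'   own ranges. For sequences use \code{\link{normalizeSequence}}, which
#'   shares extrema across frames so temporal amplitude survives.
#' @return list with \code{coords} (normalized matrix) and
#'   \code{provenance} (the extrema used).
#' @export
normalizeFrame <- function(coords, xMin = NULL, xMax = NULL,
                           yMin = NULL, yMax = NULL) {
  if (is(coords, "SkeletonFrame")) coords <- coords@coords
  if (is.null(xMin)) xMin <- min(coords[, 1L])
  if (is.null(xMax)) xMax <- max(coords[, 1L])
  if (is.null(yMin)) yMin <- min(coords[, 2L])
  if (is.null(yMax)) yMax <- max(coords[, 2L])
  if (xMax <= xMin) .stopf("degenerate range on the x axis (max <= min)")
  if (yMax <= yMin) .stopf("degenerate range on the y axis (max <= min)")
  out <- coords
  out[, 1L] <- 400 * (coords[, 1L] - xMin) / (xMax - xMin) - 200
  out[, 2L] <- 1600 * (coords[, 2L] - yMin) / (yMax - yMin) - 800
  list(coords = out,
       provenance = c(xMin = xMin, xMax = xMax, yMin = yMin, yMax = yMax))
}

#' Range-normalize a whole motion
#'
#' Applies \code{\link{normalizeFrame}} to every frame using the
#' sequence-wide coordinate extrema of the person (not per-frame
#' extrema, which would erase temporal amplitude).
#'
#' @param motion a \linkS4class{MotionSequence}.
#' @param perFrame use per-frame extrema instead (not recommended;
#'   provided for comparison).
#' @return a \linkS4class{MotionSequence} in normalized coordinates.
#' @export
normalizeSequence <- function(motion, perFrame = FALSE) {
  co <- motion@coords
  out <- co
  if (perFrame) {
    for (i in seq_len(dim(co)[1L]))
      out[i, , ] <- normalizeFrame(co[i, , ])$coords
  } else {
    xr <- range(co[, , 1L])
    yr <- range(co[, , 2L])
    for (i in seq_len(dim(co)[1L]))
      out[i, , ] <- normalizeFrame(co[i, , ], xr[1L], xr[2L],
                                   yr[1L], yr[2L])$coords
  }
  MotionSequence(out, t = motion@t, visible = motion@visible,
                 personId = motion@personId, label = motion@label,
                 fps = motion@fps)
}

#' Centre a point set on its centroid
#'
#' @param points N x 2 matrix.
#' @return list with \code{centered} points and the \code{centroid}
#'   (per-axis mean).
#' @export
centerPoints <- function(points) {
  if (is.null(dim(points)) || nrow(points) < 1L) .stopf("empty point set")
  centroid <- colMeans(points)
  list(centered = sweep(points, 2L, centroid), centroid = centroid)
}

#' Scale a centred point set to unit per-axis RMS
#'
#' Divides each axis by its root-mean-square norm
#' \code{S_F = sqrt(mean(coord^2))}, so the output has RMS exactly 1 per
#' axis. The scaling is anisotropic (x and y scaled independently).
#'
#' @param centered N x 2 matrix of centred points.
#' @return list with \code{scaled} points, \code{sFx} and \code{sFy}.
#' @export
scalePoints <- function(centered) {
  sFx <- sqrt(mean(centered[, 1L]^2))
  sFy <- sqrt(mean(centered[, 2L]^2))
  if (sFx < 1e-12) .stopf("zero variance on the x axis; cannot scale")
  if (sFy < 1e-12) .stopf("zero variance on the y axis; cannot scale")
  list(scaled = cbind(centered[, 1L] / sFx, centered[, 2L] / sFy),
       sFx = sFx, sFy = sFy)
}

#' Least-squares optimal rotation between centred point sets
#'
#' Finds the pure rotation (no reflection, so left/right anatomy is
#' preserved) minimizing the squared Procrustes distance
#' \code{sum((x_s - x_m)^2 + (y_s - y_m)^2)} between the rotated sample
#' and the model. The minimizer is closed-form:
#' \code{theta = atan2(sum(x_s y_m - y_s x_m), sum(x_s x_m + y_s y_m))}.
#' Positive theta is counter-clockwise in a y-up frame (image
#' coordinates are y-down, where it appears clockwise).
#'
#' @param sample,model N x 2 centred point matrices with matching rows.
#' @return list with \code{theta} (radians), \code{rotated} sample and
#'   the residual \code{pd2}.
#' @export
optimalRotation <- function(sample, model) {
  if (nrow(sample) != nrow(model)) .stopf("point counts differ")
  A <- sum(sample[, 1L] * model[, 1L] + sample[, 2L] * model[, 2L])
  B <- sum(sample[, 1L] * model[, 2L] - sample[, 2L] * model[, 1L])
  theta <- atan2(B, A)
  rot <- .rotate(sample, theta)
  pd2 <- sum((rot - model)^2)
  list(theta = theta, rotated = rot, pd2 = pd2)
}

.rotate <- function(points, theta) {
  cs <- cos(theta); sn <- sin(theta)
  cbind(points[, 1L] * cs - points[, 2L] * sn,
        points[, 1L] * sn + points[, 2L] * cs)
}

#' Procrustes-calibrate a motion against a model frame
#'
#' Per frame: translate to the centroid, scale each axis to unit RMS,
#' and rotate to the least-squares optimum against the model frame
#' (itself centred and scaled internally). The full transform of each
#' frame is recorded for audit and invertibility.
#'
#' @param motion a \linkS4class{MotionSequence} (typically
#'   range-normalized first).
#' @param modelFrame J x 2 matrix: the reference pose, e.g. the mean
#'   normalized frame of a training set (see \code{\link{meanFrame}}).
#' @return list with \code{motion} (calibrated sequence) and
#'   \code{transforms} (list of \linkS4class{ProcrustesTransform}).
#' @export
procrustesCalibrate <- function(motion, modelFrame) {
  mdl <- scalePoints(centerPoints(modelFrame)$centered)$scaled
  co <- motion@coords
  out <- co
  tr <- vector("list", dim(co)[1L])
  for (i in seq_len(dim(co)[1L])) {
    cc <- centerPoints(co[i, , ])
    sc <- scalePoints(cc$centered)
    rt <- optimalRotation(sc$scaled, mdl)
    out[i, , ] <- rt$rotated
    tr[[i]] <- new("ProcrustesTransform",
                   translation = unname(cc$centroid),
                   scales = c(sc$sFx, sc$sFy),
                   theta = rt$theta, pd2 = rt$pd2)
  }
  list(motion = MotionSequence(out, t = motion@t, visible = motion@visible,
                               personId = motion@personId,
                               label = motion@label, fps = motion@fps),
       transforms = tr)
}

#' Mean frame of a set of motions
#'
#' Joint-wise mean over all frames of all supplied motions; the default
#' Procrustes model pose.
#'
#' @param motions list of \linkS4class{MotionSequence} with equal joint
#'   counts.
#' @return J x 2 matrix.
#' @export
meanFrame <- function(motions) {
  acc <- NULL
  n <- 0L
  for (m in motions) {
    s <- apply(m@coords, c(2L, 3L), sum)
    acc <- if (is.null(acc)) s else acc + s
    n <- n + nFrames(m)
  }
  acc / n
}

setMethod("show", "ProcrustesTransform", function(object) {
  cat(sprintf(
    "ProcrustesTransform: translation (%.3g, %.3g), scales (%.3g, %.3g), theta %.4f rad, pd2 %.3g\n",
    object@translation[1L], object@translation[2L], object@scales[1L],
    object@scales[2L], object@theta, object@pd2))
})
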