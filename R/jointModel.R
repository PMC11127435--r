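#' Construct the skeleton joint model
#'
#' Builds the 15-position joint model used throughout the pipeline. The
#' layout follows the common monitoring skeleton: a hip centre (index 0,
#' derived as the midpoint of the two femur heads), spine and neck on the
#' trunk, and symmetric arm and leg chains. Fourteen of the positions are
#' measured points; the hip centre is derived, so
#' \code{selectedJoints(model)} has length 14.
#'
#' The body is partitioned into three overlapping segments for feature
#' extraction: the base body \code{BB} (joints 0, 1, 2), the upper body
#' \code{UB} (5, 4, 3, 2, 6, 7, 8) and the lower body \code{LB}
#' (11, 10, 9, 0, 12, 13, 14). Joints 0 and 2 are shared between
#' segments.
#'
#' @param jointNames,segments,limbs,measured override the shipped layout;
#'   all indices are 0-based. Defaults give the standard 15-position,
#'   14-measured-point model.
#' @return a \linkS4class{JointModel}.
#' @examples
#' m <- JointModel()
#' length(selectedJoints(m))       # 14 measured points
#' lengths(segmentPartition(m))    # BB 3, UB 7, LB 7
#' @export
JointModel <- function(jointNames = NULL, segments = NULL, limbs = NULL,
                       measured = NULL) {
  if (is.null(jointNames))
    jointNames <- c("hip_center", "spine", "neck",
                    "l_shoulder", "l_elbow", "l_wrist",
                    "r_shoulder", "r_elbow", "r_wrist",
                    "l_hip", "l_knee", "l_ankle",
                    "r_hip", "r_knee", "r_ankle")
  if (is.null(segments))
    segments <- list(BB = c(0L, 1L, 2L),
                     UB = c(5L, 4L, 3L, 2L, 6L, 7L, 8L),
                     LB = c(11L, 10L, 9L, 0L, 12L, 13L, 14L))
  if (is.null(limbs))
    limbs <- rbind(c(0L, 1L), c(1L, 2L),
                   c(2L, 3L), c(3L, 4L), c(4L, 5L),
                   c(2L, 6L), c(6L, 7L), c(7L, 8L),
                   c(0L, 9L), c(9L, 10L), c(10L, 11L),
                   c(0L, 12L), c(12L, 13L), c(13L, 14L))
  if (is.null(measured)) measured <- 1:14
  new("JointModel",
      jointNames = jointNames,
      segments = lapply(segments, as.integer),
      limbs = matrix(as.integer(limbs), ncol = 2L),
      measured = as.integer(measured))
}

#' @rdname JointModel-class
#' @aliases jointNames limbList segmentPartition selectedJoints
#' @export
setMethod("jointNames", "JointModel", function(x) x@jointNames)

#' @rdname JointModel-class
#' @export
setMethod("limbList", "JointModel", function(x) x@limbs)

#' @rdname JointModel-class
#' @export
setMethod("segmentPartition", "JointModel", function(x) x@segments)

#' @rdname JointModel-class
#' @export
setMethod("selectedJoints", "JointModel", function(x) x@measured)

setMethod("show", "JointModel", function(object) {
  cat("JointModel:", length(object@jointNames), "indexed joints,",
      length(object@measured), "measured,",
      nrow(object@limbs), "limbs\n")
  cat("  segments:",
      paste(sprintf("%s(%d)", names(object@segments),
                    lengths(object@segments)), collapse = " "), "\n")
})

# Neutral standing pose in unit-height coordinates, hip centre at the
# origin, y downward (image convention). The hip centre equals the
# femur-head midpoint exactly.
.basePoseTable <- function() {
  p <- rbind(
    hip_center = c( 0.00,  0.00),
    spine      = c( 0.00, -0.18),
    neck       = c( 0.00, -0.36),
    l_shoulder = c(-0.11, -0.34),
    l_elbow    = c(-0.16, -0.18),
    l_wrist    = c(-0.18, -0.02),
    r_shoulder = c( 0.11, -0.34),
    r_elbow    = c( 0.16, -0.18),
    r_wrist    = c( 0.18, -0.02),
    l_hip      = c(-0.08,  0.00),
    l_knee     = c(-0.09,  0.25),
    l_ankle    = c(-0.10,  0.48),
    r_hip      = c( 0.08,  0.00),
    r_knee     = c( 0.09,  0.25),
    r_ankle    = c( 0.10,  0.48))
  colnames(p) <- c("x", "y")
  p
}

#' Neutral base pose
#'
#' The standing reference pose every synthetic motion oscillates around,
#' in unit-height coordinates with the hip centre at the origin and y
#' pointing down (image convention).
#'
#' @return a 15 x 2 matrix with columns \code{x}, \code{y} and joint
#'   names as row names.
#' @export
basePose <- function() .basePoseTable()
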