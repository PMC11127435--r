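# Central S4 containers.
#
# Coordinate convention used throughout: pixel units with the origin at the
# top-left of the grid, x increasing rightward and y increasing downward.
# Grids are stored as R matrices indexed [y, x] (row-major when flattened
# by row). Joint indices follow the field's 0-based numbering (0..14).

#' @import methods
NULL

#' Skeleton joint model
#'
#' Describes the joint layout used by the whole pipeline: 15 indexed joint
#' positions (0--14) of which 14 are measured and joint 0 (the hip centre,
#' i.e. the midpoint of the two femur heads) is derived; the three-way
#' body-segment partition BB/UB/LB; and the limb tree connecting the
#' joints.
#'
#' @slot jointNames ordered character vector of 15 joint labels; position
#'   \code{k} holds the name of joint index \code{k - 1}.
#' @slot segments named list \code{BB}, \code{UB}, \code{LB} of 0-based
#'   joint indices (sizes 3, 7 and 7; joints 0 and 2 are shared between
#'   segments).
#' @slot limbs integer matrix with two columns, one row per limb, holding
#'   0-based endpoint indices; the rows span the skeleton as a single
#'   connected tree.
#' @slot measured 0-based indices of the measured joints (the derived hip
#'   centre is excluded).
#' @export
setClass("JointModel",
  representation(
    jointNames = "character",
    segments   = "list",
    limbs      = "matrix",
    measured   = "integer"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@jointNames)
    seg <- object@segments
    if (!identical(sort(names(seg)), sort(c("BB", "UB", "LB"))))
      msg <- c(msg, "segments must be named BB, UB, LB")
    else {
      if (length(seg$BB) != 3L) msg <- c(msg, "BB must contain exactly 3 joints")
      if (length(seg$UB) != 7L) msg <- c(msg, "UB must contain exactly 7 joints")
      if (length(seg$LB) != 7L) msg <- c(msg, "LB must contain exactly 7 joints")
      idx <- unlist(seg, use.names = FALSE)
      if (any(idx < 0L | idx >= n))
        msg <- c(msg, "segment joint indices out of range")
      if (!all((seq_len(n) - 1L) %in% idx))
        msg <- c(msg, "every joint index must appear in at least one segment")
    }
    lb <- object@limbs
    if (ncol(lb) != 2L) msg <- c(msg, "limbs must have two columns")
    else {
      if (any(lb < 0L | lb >= n)) msg <- c(msg, "limb endpoints out of range")
      if (any(lb[, 1L] == lb[, 2L])) msg <- c(msg, "limb endpoints must differ")
      if (!.graphConnected(n, lb))
        msg <- c(msg, "limbs must connect all joints into one connected graph")
    }
    if (any(object@measured < 0L | object@measured >= n))
      msg <- c(msg, "measured indices out of range")
    if (length(msg)) msg else TRUE
  }
)

#' One person's skeleton at one time step
#'
#' @slot personId integer person identifier.
#' @slot t frame index.
#' @slot coords numeric matrix, one row per joint, columns \code{x},
#'   \code{y}, in pixel units.
#' @slot visible logical flag per joint; invisible joints carry no
#'   annotation weight downstream.
#' @export
setClass("SkeletonFrame",
  representation(
    personId = "integer",
    t        = "integer",
    coords   = "matrix",
    visible  = "logical"
  ),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have columns x, y")
    if (length(object@visible) != nrow(object@coords))
      msg <- c(msg, "visible must have one flag per joint")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (sum(object@visible) < 3L)
      msg <- c(msg, "at least 3 joints must be visible")
    if (length(msg)) msg else TRUE
  }
)

#' Time-ordered skeleton motion of one person
#'
#' Stores all frames of one person as a dense array for fast access, plus
#' the activity label used by the classifier stages.
#'
#' @slot coords numeric array \code{[frame, joint, axis]} with axes x, y.
#' @slot visible logical matrix \code{[frame, joint]}.
#' @slot t integer vector of strictly increasing frame indices.
#' @slot personId integer person identifier, constant over frames.
#' @slot label activity class token (may be \code{NA}).
#' @slot fps frames per second.
#' @export
setClass("MotionSequence",
  representation(
    coords   = "array",
    visible  = "matrix",
    t        = "integer",
    personId = "integer",
    label    = "character",
    fps      = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[3L] != 2L)
      msg <- c(msg, "coords must be a [frame, joint, 2] array")
    if (length(object@t) != d[1L])
      msg <- c(msg, "t must have one entry per frame")
    if (length(object@t) > 1L && any(diff(object@t) <= 0L))
      msg <- c(msg, "frame indices must be strictly increasing")
    if (!all(dim(object@visible) == d[1:2]))
      msg <- c(msg, "visible must be a [frame, joint] matrix")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Scene rendering parameters
#'
#' @slot gridW,gridH grid size in pixels (at least 32).
#' @slot sigma Gaussian spread of the joint confidence model, pixels.
#' @slot limbWidth half-width of the limb support band, pixels.
#' @slot nPersons number of persons composed into a scene.
#' @slot noiseSd additive coordinate noise, pixels.
#' @slot seed integer random seed.
#' @export
setClass("SceneParams",
  representation(
    gridW     = "integer",
    gridH     = "integer",
    sigma     = "numeric",
    limbWidth = "numeric",
    nPersons  = "integer",
    noiseSd   = "numeric",
    seed      = "integer"
  ),
  prototype(
    gridW = 128L, gridH = 128L, sigma = 6, limbWidth = 4,
    nPersons = 1L, noiseSd = 1, seed = 1L
  ),
  validity = function(object) {
    msg <- character()
    if (object@sigma <= 0) msg <- c(msg, "sigma must be > 0")
    if (object@limbWidth <= 0) msg <- c(msg, "limbWidth must be > 0")
    if (object@gridW < 32L || object@gridH < 32L)
      msg <- c(msg, "grid dimensions must be >= 32")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Rendered ground-truth scene
#'
#' Gridded per-joint confidence maps and per-limb two-channel affinity
#' fields for one frame, together with the skeletons that produced them
#' and the annotation mask.
#'
#' @slot confMaps numeric array \code{[y, x, joint]}, values in [0, 1].
#' @slot pafFields numeric array \code{[y, x, channel, limb]} with
#'   channel 1 = x component, channel 2 = y component; vector norms are
#'   at most 1.
#' @slot mask numeric array \code{[y, x, joint]} of 0/1 annotation
#'   weights.
#' @slot truth list of \linkS4class{SkeletonFrame} objects.
#' @slot params the \linkS4class{SceneParams} used for rendering.
#' @export
setClass("FieldScene",
  representation(
    confMaps  = "array",
    pafFields = "array",
    mask      = "array",
    truth     = "list",
    params    = "SceneParams"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@confMaps < 0 | object@confMaps > 1))
      msg <- c(msg, "confidence values must lie in [0, 1]")
    nrm2 <- object@pafFields[, , 1L, , drop = FALSE]^2 +
            object@pafFields[, , 2L, , drop = FALSE]^2
    if (any(nrm2 > 1 + 1e-9))
      msg <- c(msg, "affinity vectors must have norm <= 1")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask values must be 0 or 1")
    if (length(msg)) msg else TRUE
  }
)

#' Per-person skeleton recovered by limb matching
#'
#' @slot coords numeric matrix \code{[joint, 2]}; \code{NA} rows mark
#'   joints not recovered.
#' @slot scores per-joint peak confidence (\code{NA} where missing).
#' @slot limbs data frame of accepted connections with columns
#'   \code{limb} (0-based limb index), \code{candA}, \code{candB}
#'   (candidate indices at the limb's two endpoint types) and \code{E}
#'   (affinity reliability).
#' @export
setClass("AssembledSkeleton",
  representation(
    coords = "matrix",
    scores = "numeric",
    limbs  = "data.frame"
  )
)

#' Similarity-alignment record of one frame
#'
#' The translation, per-axis scaling and rotation applied during
#' Procrustes calibration, plus the residual squared Procrustes distance
#' to the model frame.
#'
#' @slot translation centroid \code{(x, y)} removed from the frame.
#' @slot scales per-axis root-mean-square norms \code{(S_Fx, S_Fy)}
#'   divided out after centring.
#' @slot theta rotation angle in radians; positive is counter-clockwise
#'   in a y-up frame (clockwise on image coordinates, which are y-down).
#' @slot pd2 residual squared Procrustes distance after alignment.
#' @export
setClass("ProcrustesTransform",
  representation(
    translation = "numeric",
    scales      = "numeric",
    theta       = "numeric",
    pd2         = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@scales <= 0)) msg <- c(msg, "scales must be > 0")
    if (object@pd2 < -1e-12) msg <- c(msg, "pd2 must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Fitted principal-component model
#'
#' @slot center training-set mean vector.
#' @slot eigvals eigenvalues of the training scatter matrix, descending,
#'   clipped at zero.
#' @slot eigvecs orthonormal eigenvector columns, sign-fixed so the
#'   largest-magnitude entry of each column is positive.
#' @slot selected indices of the retained components.
#' @slot reduction projection matrix actually applied by
#'   \code{\link{pcaTransform}} (depends on \code{mode}).
#' @slot precision cumulative-variance threshold used for selection.
#' @slot mode \code{"standard"} (project on eigenvectors) or
#'   \code{"eigenscaled"} (additionally scale components by their eigenvalues).
#' @export
setClass("PCAModel",
  representation(
    center    = "numeric",
    eigvals   = "numeric",
    eigvecs   = "matrix",
    selected  = "integer",
    reduction = "matrix",
    precision = "numeric",
    mode      = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(rev(object@eigvals))) msg <- c(msg, "eigenvalues must be sorted descending")
    if (any(object@eigvals < -1e-9)) msg <- c(msg, "eigenvalues must be >= 0 (after clipping)")
    if (length(object@selected) == 0L) msg <- c(msg, "at least one component must be selected")
    vtv <- crossprod(object@eigvecs)
    if (max(abs(vtv - diag(ncol(object@eigvecs)))) > 1e-6)
      msg <- c(msg, "eigenvectors must be orthonormal")
    if (length(msg)) msg else TRUE
  }
)

#' One-vs-rest support vector machine ensemble
#'
#' One binary max-margin machine per class; prediction takes the class
#' with the largest decision value. Features are standardized with
#' training-set statistics stored in the model.
#'
#' @slot models list of fitted \pkg{e1071} binary machines, one per class.
#' @slot classes class tokens in training order.
#' @slot center,scale feature standardization vectors.
#' @slot kernel,cost,gamma kernel settings shared by the binary machines.
#' @export
setClass("SVMEnsemble",
  representation(
    models  = "list",
    classes = "character",
    center  = "numeric",
    scale   = "numeric",
    kernel  = "character",
    cost    = "numeric",
    gamma   = "numeric"
  )
)

#' Single-hidden-layer network baseline
#'
#' A small ReLU + softmax network trained by plain stochastic gradient
#' descent; provided as a secondary baseline next to the SVM.
#'
#' @slot W1,b1,W2,b2 network weights.
#' @slot classes class tokens.
#' @slot center,scale feature standardization vectors.
#' @export
setClass("MLPModel",
  representation(
    W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
    classes = "character", center = "numeric", scale = "numeric"
  )
)

#' Classifier evaluation report
#'
#' @slot confusion class-by-class count matrix; rows are true classes,
#'   columns predicted classes.
#' @slot perClass data frame with one row per class: counts \code{tp},
#'   \code{fp}, \code{fn}, \code{tn} from the one-vs-rest reading of the
#'   confusion matrix and the derived \code{precision},
#'   \code{sensitivity}, \code{specificity} in percent.
#' @slot macro macro-averaged precision/sensitivity/specificity (percent;
#'   classes with an undefined metric are dropped from the average).
#' @slot accuracy overall accuracy in percent.
#' @export
setClass("ClassifierReport",
  representation(
    confusion = "matrix",
    perClass  = "data.frame",
    macro     = "numeric",
    accuracy  = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    m <- c(object@perClass$precision, object@perClass$sensitivity,
           object@perClass$specificity)
    m <- m[!is.na(m)]
    if (any(m < 0 | m > 100)) msg <- c(msg, "metrics must lie in [0, 100] percent")
    if (length(msg)) msg else TRUE
  }
)

#' Fixed-length kinematic feature vector
#'
#' Concatenated polynomial coefficients and goodness-of-fit values for
#' the three body segments and two axes, in the documented fixed order.
#'
#' @slot values named numeric vector of length 6 * (degree + 2).
#' @slot label optional activity class token.
#' @slot degree polynomial degree used for the fits.
#' @export
setClass("FeatureVector",
  representation(values = "numeric", label = "character", degree = "integer"),
  validity = function(object) {
    if (length(object@values) != 6L * (object@degree + 2L))
      "values must have length 6 * (degree + 2)" else TRUE
  }
)

# breadth-first connectivity over 0-based limb rows
.graphConnected <- function(nJoints, limbs0) {
  if (nJoints == 0L) return(TRUE)
  a <- limbs0[, 1L] + 1L
  b <- limbs0[, 2L] + 1L
  seen <- logical(nJoints)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- c(b[a %in% frontier], a[b %in% frontier])
    nb <- unique(nb[!seen[nb]])
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}
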