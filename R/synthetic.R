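# Synthetic skeleton motions.
#
# Each activity class is a set of per-joint sinusoidal offsets around the
# neutral base pose; the generator emulates smooth periodic whole-body
# movement (gait cycles, exercise repetitions, racket strokes) with
# additive Gaussian coordinate noise standing in for detector jitter.

#' @rdname SceneParams-class
#' @param gridW,gridH,sigma,limbWidth,nPersons,noiseSd,seed see slots.
#' @export
SceneParams <- function(gridW = 128L, gridH = 128L, sigma = 6,
                        limbWidth = 4, nPersons = 1L, noiseSd = 1,
                        seed = 1L) {
  new("SceneParams", gridW = as.integer(gridW), gridH = as.integer(gridH),
      sigma = sigma, limbWidth = limbWidth, nPersons = as.integer(nPersons),
      noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "SceneParams", function(object) {
  cat(sprintf(
    "SceneParams: %dx%d grid, sigma %.3g px, limb half-width %.3g px, %d person(s), noise sd %.3g px, seed %d\n",
    object@gridW, object@gridH, object@sigma, object@limbWidth,
    object@nPersons, object@noiseSd, object@seed))
})

#' @rdname SkeletonFrame-class
#' @param coords J x 2 coordinate matrix
#' @param personId,t identifiers
#' @param visible logical per-joint flags
#' @export
SkeletonFrame <- function(coords, personId = 1L, t = 1L,
                          visible = rep(TRUE, nrow(coords))) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y")
  new("SkeletonFrame", personId = as.integer(personId), t = as.integer(t),
      coords = coords, visible = visible)
}

#' @rdname MotionSequence-class
#' @param coords \code{[frame, joint, 2]} array
#' @param t frame indices (default 1..n)
#' @param visible \code{[frame, joint]} logical matrix
#' @param personId,label,fps identifiers and sampling rate
#' @export
MotionSequence <- function(coords, t = seq_len(dim(coords)[1L]),
                           visible = NULL, personId = 1L,
                           label = NA_character_, fps = 20) {
  if (is.null(visible))
    visible <- matrix(TRUE, dim(coords)[1L], dim(coords)[2L])
  new("MotionSequence", coords = coords, visible = visible,
      t = as.integer(t), personId = as.integer(personId),
      label = as.character(label), fps = fps)
}

#' @rdname MotionSequence-class
#' @aliases coords visibility activityLabel nFrames nJoints
#' @param x,object a \code{MotionSequence} or \code{SkeletonFrame}
#' @param ... unused
#' @export
setMethod("coords", "MotionSequence", function(x, ...) x@coords)

#' @rdname MotionSequence-class
#' @export
setMethod("coords", "SkeletonFrame", function(x, ...) x@coords)

#' @rdname MotionSequence-class
#' @export
setMethod("visibility", "MotionSequence", function(x) x@visible)

#' @rdname MotionSequence-class
#' @export
setMethod("visibility", "SkeletonFrame", function(x) x@visible)

#' @rdname MotionSequence-class
#' @export
setMethod("activityLabel", "MotionSequence", function(x) x@label)

#' @rdname MotionSequence-class
#' @export
setMethod("nFrames", "MotionSequence", function(x) dim(x@coords)[1L])

#' @rdname MotionSequence-class
#' @export
setMethod("nJoints", "MotionSequence", function(x) dim(x@coords)[2L])

setMethod("show", "MotionSequence", function(object) {
  cat(sprintf("MotionSequence: person %d, %d frames x %d joints, label %s, %g fps\n",
              object@personId, dim(object@coords)[1L], dim(object@coords)[2L],
              object@label, object@fps))
})

setMethod("show", "SkeletonFrame", function(object) {
  cat(sprintf("SkeletonFrame: person %d, t %d, %d joints (%d visible)\n",
              object@personId, object@t, nrow(object@coords),
              sum(object@visible)))
})

#' Load the activity class table
#'
#' Reads the sinusoidal trajectory archetypes (frequency, per-joint
#' amplitudes and phases) that define each activity class. The shipped
#' table covers \code{running}, \code{aerobics} and \code{table_tennis}.
#'
#' @param path YAML file; default the table shipped with the package.
#' @return named list of class definitions.
#' @export
activityClasses <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "activity_classes.yaml",
                        package = "kinepose", mustWork = TRUE)
  yaml::read_yaml(path)$classes
}

# Closed-form noiseless trajectory: [frame, joint, 2] array for frames
# `tIdx` (integer indices), given the class definition. Exported logic is
# makeMotion(); this core is separate so tests can check the zero-noise
# case against an independent reconstruction.
.motionTruth <- function(classDef, tIdx, fps, heightPx, center) {
  base <- .basePoseTable()
  nJ <- nrow(base)
  nT <- length(tIdx)
  tt <- (tIdx - 1L) / fps
  out <- array(0, dim = c(nT, nJ, 2L))
  offx <- matrix(0, nT, nJ)
  offy <- matrix(0, nT, nJ)
  w <- 2 * pi * classDef$freq_hz
  for (cmp in classDef$components) {
    ph <- 2 * pi * cmp$phase
    s <- sin(w * tt + ph)
    for (j0 in cmp$joints) {
      offx[, j0 + 1L] <- offx[, j0 + 1L] + cmp$amp_x * s
      offy[, j0 + 1L] <- offy[, j0 + 1L] + cmp$amp_y * s
    }
  }
  out[, , 1L] <- center[1L] + heightPx *
    (matrix(base[, 1L], nT, nJ, byrow = TRUE) + offx)
  out[, , 2L] <- center[2L] + heightPx *
    (matrix(base[, 2L], nT, nJ, byrow = TRUE) + offy)
  # hip centre is a derived point: femur-head midpoint
  out[, 1L, ] <- (out[, 10L, ] + out[, 13L, ]) / 2
  out
}

#' Generate a labelled synthetic skeleton motion
#'
#' Produces one person's smooth periodic joint trajectories for an
#' activity class: base pose plus class-specific sinusoidal offsets,
#' scaled to the scene grid, with additive Gaussian coordinate noise.
#' The hip centre (joint 0) is derived per frame as the midpoint of the
#' femur heads, so the sequence carries 14 independently measured points.
#' Output is deterministic for a fixed \code{seed}.
#'
#' @param classToken activity class name; must appear in \code{classes}.
#' @param nFrames number of frames (at least 2).
#' @param seed integer seed for the coordinate noise.
#' @param params \linkS4class{SceneParams} (grid size sets the body
#'   scale: height = 0.55 * gridH; noise sd in pixels).
#' @param classes class table, default \code{\link{activityClasses}()}.
#' @param fps sampling rate, frames per second.
#' @param personId person identifier stored in the sequence.
#' @param center body centre on the grid; default the grid centre.
#' @param heightPx body height in pixels; default 0.55 * gridH.
#' @return a \linkS4class{MotionSequence} labelled with
#'   \code{classToken}.
#' @examples
#' m <- makeMotion("running", nFrames = 10, seed = 1)
#' dim(coords(m))
#' @export
makeMotion <- function(classToken, nFrames, seed = 1L,
                       params = SceneParams(), classes = activityClasses(),
                       fps = 20, personId = 1L, center = NULL,
                       heightPx = NULL) {
  if (!classToken %in% names(classes))
    .stopf("unknown activity class '%s'; valid tokens: %s",
           classToken, paste(names(classes), collapse = ", "))
  if (nFrames < 2L) .stopf("nFrames must be >= 2")
  p <- .paramsList(params)
  if (is.null(center)) center <- c(p$gridW / 2, p$gridH / 2)
  if (is.null(heightPx)) heightPx <- 0.55 * p$gridH
  truth <- .motionTruth(classes[[classToken]], seq_len(nFrames), fps,
                        heightPx, center)
  if (p$noiseSd > 0) {
    nJ <- dim(truth)[2L]
    noise <- .withSeed(seed,
      array(stats::rnorm(nFrames * nJ * 2L, sd = p$noiseSd),
            dim = dim(truth)))
    # noise enters through the measured points; the derived hip centre
    # inherits the femur average
    noise[, 1L, ] <- 0
    truth <- truth + noise
    truth[, 1L, ] <- (truth[, 10L, ] + truth[, 13L, ]) / 2
  }
  MotionSequence(truth, personId = personId, label = classToken, fps = fps)
}

#' Generate several persons side by side
#'
#' Convenience wrapper around \code{\link{makeMotion}} placing one person
#' per class token at evenly spaced horizontal positions, so scenes with
#' several non-overlapping people can be rendered directly.
#'
#' @param classTokens one activity token per person.
#' @param nFrames,seed,params,classes,fps as in \code{\link{makeMotion}};
#'   each person uses \code{seed + personId - 1}.
#' @param heightPx body height in pixels, default 0.35 * gridH (smaller
#'   than the single-person default so several bodies fit the grid).
#' @return list of \linkS4class{MotionSequence}, person ids 1..n.
#' @export
makeMultiMotion <- function(classTokens, nFrames, seed = 1L,
                            params = SceneParams(), classes = activityClasses(),
                            fps = 20, heightPx = NULL) {
  p <- .paramsList(params)
  n <- length(classTokens)
  if (is.null(heightPx)) heightPx <- 0.35 * p$gridH
  cx <- p$gridW * seq_len(n) / (n + 1)
  lapply(seq_len(n), function(i)
    makeMotion(classTokens[i], nFrames, seed = seed + i - 1L, params = params,
               classes = classes, fps = fps, personId = i,
               center = c(cx[i], p$gridH / 2), heightPx = heightPx))
}

#' Extract one frame of a motion
#'
#' @param motion a \linkS4class{MotionSequence}.
#' @param frameIdx position in the sequence (1-based).
#' @return a \linkS4class{SkeletonFrame}.
#' @export
getFrame <- function(motion, frameIdx) {
  if (frameIdx < 1L || frameIdx > nFrames(motion))
    .stopf("frameIdx %d outside 1..%d", frameIdx, nFrames(motion))
  SkeletonFrame(motion@coords[frameIdx, , ], personId = motion@personId,
                t = motion@t[frameIdx], visible = motion@visible[frameIdx, ])
}
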