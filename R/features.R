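# Segment-wise polynomial trajectory features.
#
# A calibrated sequence is summarized by fitting, for each body segment
# (BB, UB, LB) and each axis (x, y), a polynomial to the segment's
# centroid coordinate against normalized time in [0, 1]. Coefficients
# plus the goodness of fit give a fixed-length vector per sequence.

#' Partition a frame's joints into body segments
#'
#' Returns the BB/UB/LB point sets (sizes 3, 7 and 7). Shared joints
#' (the hip centre and the neck) are duplicated into both owning
#' segments.
#'
#' @param coords J x 2 matrix or \linkS4class{SkeletonFrame}.
#' @param jointModel the \linkS4class{JointModel}.
#' @return named list of coordinate matrices \code{BB}, \code{UB},
#'   \code{LB}.
#' @export
partitionJoints <- function(coords, jointModel = JointModel()) {
  if (is(coords, "SkeletonFrame")) coords <- coords@coords
  seg <- jointModel@segments
  need <- sort(unique(unlist(seg, use.names = FALSE)))
  bad <- need[need + 1L > nrow(coords)]
  missing <- need[vapply(need, function(j)
    any(!is.finite(coords[j + 1L, ])), logical(1L))]
  if (length(bad) || length(missing))
    .stopf("missing joint(s): %s",
           paste(sort(unique(c(bad, missing))), collapse = ", "))
  lapply(seg, function(idx) coords[idx + 1L, , drop = FALSE])
}

#' Goodness of fit of a fitted curve
#'
#' \code{R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)}. A constant
#' target with identically zero residuals returns 1 (limit convention);
#' a constant target with nonzero residuals is an error, since the ratio
#' is undefined.
#'
#' @param yTrue,yFit numeric vectors of equal length (at least 2).
#' @return scalar R-squared (at most 1; can be negative for fits worse
#'   than the mean).
#' @export
goodnessOfFit <- function(yTrue, yFit) {
  if (length(yTrue) != length(yFit)) .stopf("lengths differ")
  if (length(yTrue) < 2L) .stopf("need at least 2 points")
  ssRes <- sum((yTrue - yFit)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  if (ssTot < 1e-24) {
    if (ssRes < 1e-24) return(1)
    .stopf("zero total variance with nonzero residuals; R^2 undefined")
  }
  1 - ssRes / ssTot
}

#' Least-squares polynomial fit of a sampled series
#'
#' Fits \code{p(u) = c0 + c1 u + ... + cn u^n} by ordinary least squares
#' on the (by default normalized) abscissa and scores it with
#' \code{\link{goodnessOfFit}}.
#'
#' @param samples numeric response values.
#' @param degree polynomial degree n.
#' @param u abscissa; default equally spaced on [0, 1] (normalizing time
#'   keeps the Vandermonde system well conditioned and makes features
#'   invariant to uniform temporal shift).
#' @return list with \code{coeffs} (c0..cn), \code{r2}, \code{fitted}
#'   and \code{nPoints}.
#' @export
polyfitSeries <- function(samples, degree, u = NULL) {
  n <- length(samples)
  if (n < degree + 1L)
    .stopf("underdetermined fit: degree %d needs at least %d points, got %d",
           degree, degree + 1L, n)
  if (is.null(u)) u <- if (n == 1L) 0 else (seq_len(n) - 1L) / (n - 1L)
  X <- outer(u, 0:degree, `^`)
  fit <- stats::lm.fit(X, samples)
  coeffs <- unname(fit$coefficients)
  coeffs[is.na(coeffs)] <- 0
  fitted <- as.numeric(X %*% coeffs)
  list(coeffs = coeffs, r2 = goodnessOfFit(samples, fitted),
       fitted = fitted, nPoints = n)
}

#' Extract the kinematic feature vector of a sequence
#'
#' For each segment (BB, UB, LB) and axis (x, y), the segment centroid's
#' trajectory over normalized time is fitted with
#' \code{\link{polyfitSeries}}; the coefficients and the goodness of fit
#' are concatenated in the fixed order BB.x, BB.y, UB.x, UB.y, LB.x,
#' LB.y, each block being (c0, ..., cn, r2). Total length
#' \code{6 * (degree + 2)}.
#'
#' @param motion a calibrated \linkS4class{MotionSequence}.
#' @param jointModel the \linkS4class{JointModel}.
#' @param degree polynomial degree (default 5).
#' @return a \linkS4class{FeatureVector} carrying the motion's label.
#' @export
extractFeatures <- function(motion, jointModel = JointModel(), degree = 5L) {
  if (nFrames(motion) < degree + 1L)
    .stopf("need at least %d frames for a degree-%d fit", degree + 1L, degree)
  seg <- jointModel@segments
  vals <- numeric(0)
  nms <- character(0)
  for (sName in c("BB", "UB", "LB")) {
    idx <- seg[[sName]] + 1L
    for (ax in 1:2) {
      series <- rowMeans(motion@coords[, idx, ax, drop = FALSE], dims = 1L)
      fit <- polyfitSeries(series, degree)
      vals <- c(vals, fit$coeffs, fit$r2)
      nms <- c(nms,
               paste0(sName, "_", c("x", "y")[ax], "_c", 0:degree),
               paste0(sName, "_", c("x", "y")[ax], "_r2"))
    }
  }
  names(vals) <- nms
  new("FeatureVector", values = vals, label = motion@label,
      degree = as.integer(degree))
}

#' @rdname FeatureVector-class
#' @aliases featureValues
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: %d values (degree %d), label %s\n",
              length(object@values), object@degree, object@label))
})

#' Stack feature vectors into a labelled table
#'
#' @param featureList list of \linkS4class{FeatureVector}.
#' @return list with \code{x} (numeric matrix, one row per vector) and
#'   \code{labels} (character).
#' @export
featureTable <- function(featureList) {
  x <- do.call(rbind, lapply(featureList, function(f) f@values))
  labels <- vapply(featureList, function(f) f@label, character(1L))
  list(x = x, labels = labels)
}
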