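# Generics and accessors. Slots are never reached into by user code;
# these accessors are the supported surface.

#' @rdname JointModel-class
#' @param x,object an object of the documented class
#' @export
setGeneric("jointNames", function(x) standardGeneric("jointNames"))

#' @rdname JointModel-class
#' @export
setGeneric("limbList", function(x) standardGeneric("limbList"))

#' @rdname JointModel-class
#' @export
setGeneric("segmentPartition", function(x) standardGeneric("segmentPartition"))

#' @rdname JointModel-class
#' @export
setGeneric("selectedJoints", function(x) standardGeneric("selectedJoints"))

#' @rdname MotionSequence-class
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname MotionSequence-class
#' @export
setGeneric("visibility", function(x) standardGeneric("visibility"))

#' @rdname MotionSequence-class
#' @export
setGeneric("activityLabel", function(x) standardGeneric("activityLabel"))

#' @rdname MotionSequence-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname MotionSequence-class
#' @export
setGeneric("nJoints", function(x) standardGeneric("nJoints"))

#' @rdname FieldScene-class
#' @export
setGeneric("confMaps", function(x) standardGeneric("confMaps"))

#' @rdname FieldScene-class
#' @export
setGeneric("pafFields", function(x) standardGeneric("pafFields"))

#' @rdname FieldScene-class
#' @export
setGeneric("sceneMask", function(x) standardGeneric("sceneMask"))

#' @rdname FieldScene-class
#' @export
setGeneric("truthFrames", function(x) standardGeneric("truthFrames"))

#' @rdname FieldScene-class
#' @export
setGeneric("sceneParams", function(x) standardGeneric("sceneParams"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))

#' @rdname ClassifierReport-class
#' @export
setGeneric("overallAccuracy", function(x) standardGeneric("overallAccuracy"))

#' @rdname FeatureVector-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
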