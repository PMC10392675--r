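#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Standard accessors for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return The slot contents (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tensors", function(x, ...) standardGeneric("tensors"))

#' @rdname accessors
#' @export
setGeneric("trajectoryInfo", function(x, ...) standardGeneric("trajectoryInfo"))

#' @rdname accessors
#' @export
setGeneric("descriptors", function(x, ...) standardGeneric("descriptors"))

#' @rdname accessors
#' @export
setGeneric("descriptorNames", function(x, ...) standardGeneric("descriptorNames"))

#' @rdname accessors
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("ligandIds", function(x) standardGeneric("ligandIds"))

#' @rdname accessors
#' @export
setGeneric("trainIndices", function(x) standardGeneric("trainIndices"))

#' @rdname accessors
#' @export
setGeneric("validationIndices", function(x) standardGeneric("validationIndices"))

#' @rdname accessors
#' @export
setGeneric("normalizer", function(x) standardGeneric("normalizer"))

#' @rdname accessors
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setGeneric("modelParameters", function(x) standardGeneric("modelParameters"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("rocAUC", function(x) standardGeneric("rocAUC"))

#' @rdname accessors
#' @export
setGeneric("perLigandErrors", function(x) standardGeneric("perLigandErrors"))

#' @rdname accessors
#' @export
setGeneric("saliency", function(x, ...) standardGeneric("saliency"))

#' @rdname accessors
#' @export
setGeneric("ablationTable", function(x) standardGeneric("ablationTable"))

#' @rdname accessors
#' @export
setGeneric("forecastTargets", function(x) standardGeneric("forecastTargets"))

#' @rdname accessors
#' @export
setGeneric("forecastInputs", function(x) standardGeneric("forecastInputs"))
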