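#' @rdname accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))

#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("templateId", function(x) standardGeneric("templateId"))

#' @rdname template-accessors
#' @export
setGeneric("nPointsMarkup", function(x) standardGeneric("nPointsMarkup"))

#' @rdname template-accessors
#' @export
setGeneric("nPointsModel", function(x) standardGeneric("nPointsModel"))

#' @rdname template-accessors
#' @export
setGeneric("excludedIndices", function(x) standardGeneric("excludedIndices"))

#' @rdname template-accessors
#' @export
setGeneric("retainedIndices", function(x) standardGeneric("retainedIndices"))

#' @rdname template-accessors
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @rdname model-accessors
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))

#' @rdname model-accessors
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname model-accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname model-accessors
#' @export
setGeneric("scoreSds", function(x) standardGeneric("scoreSds"))

#' @rdname model-accessors
#' @export
setGeneric("varianceFractions", function(x) standardGeneric("varianceFractions"))

#' @rdname model-accessors
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' @rdname model-accessors
#' @export
setGeneric("nTraining", function(x) standardGeneric("nTraining"))

#' @rdname gpa
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))

#' @rdname gpa
#' @export
setGeneric("procrustesResiduals", function(x) standardGeneric("procrustesResiduals"))

#' @rdname gpa
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname effectiveTests
#' @export
setGeneric("veff", function(x) standardGeneric("veff"))

#' @rdname effectiveTests
#' @export
setGeneric("lossFraction", function(x) standardGeneric("lossFraction"))
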