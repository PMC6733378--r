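#' Accessors for landmark sets and shape objects
#'
#' @param x a \linkS4class{LandmarkSet}, \linkS4class{ProcrustesFit},
#'   \linkS4class{ShapeTemplate} or \linkS4class{ShapeModel}.
#' @return the corresponding component: image identifiers, counts of
#'   images or points, or the template identifier.
#' @name accessors
#' @aliases imageIds nImages nPoints templateId
NULL

#' @rdname accessors
#' @export
setMethod("imageIds", "LandmarkSet", function(x) x@imageIds)

#' @rdname accessors
#' @export
setMethod("imageIds", "ProcrustesFit", function(x) x@imageIds)

#' @rdname accessors
#' @export
setMethod("nImages", "LandmarkSet", function(x) dim(x@coords)[3])

#' @rdname accessors
#' @export
setMethod("nImages", "ProcrustesFit", function(x) nrow(x@aligned))

#' @rdname accessors
#' @export
setMethod("nPoints", "LandmarkSet", function(x) dim(x@coords)[1])

#' @rdname accessors
#' @export
setMethod("nPoints", "ShapeModel", function(x) length(x@mean) %/% 2L)

#' @rdname accessors
#' @export
setMethod("templateId", "LandmarkSet", function(x) x@templateId)

#' @rdname accessors
#' @export
setMethod("templateId", "ShapeTemplate", function(x) x@templateId)

#' @rdname accessors
#' @export
setMethod("templateId", "ShapeModel", function(x) x@templateId)

#' @rdname accessors
#' @export
setMethod("templateId", "ProcrustesFit", function(x) x@templateId)

#' Extract one configuration from a LandmarkSet
#'
#' Returns the k x 2 coordinate matrix of a single image, selected by
#' position or image id.
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param i integer position or character image id.
#' @return a k x 2 numeric matrix (columns \code{x}, \code{y}).
#' @export
setMethod("[[", "LandmarkSet", function(x, i) {
    if (is.character(i)) {
        j <- match(i, x@imageIds)
        if (is.na(j)) stop("unknown image id: ", i)
        i <- j
    }
    m <- x@coords[, , i, drop = TRUE]
    dimnames(m) <- list(NULL, c("x", "y"))
    m
})

#' Subset a LandmarkSet by image
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param i integer positions or character image ids.
#' @param j,...,drop ignored.
#' @return a \linkS4class{LandmarkSet} with the selected images.
#' @export
setMethod("[", "LandmarkSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        idx <- match(i, x@imageIds)
        if (anyNA(idx)) stop("unknown image ids: ",
                             paste(i[is.na(idx)], collapse = ", "))
        i <- idx
    }
    new("LandmarkSet",
        coords = x@coords[, , i, drop = FALSE],
        imageIds = x@imageIds[i], templateId = x@templateId)
})

#' @rdname template-accessors
#' @export
setMethod("nPointsMarkup", "ShapeTemplate", function(x) x@nPointsMarkup)

#' Template accessors
#'
#' @param x a \linkS4class{ShapeTemplate}.
#' @return markup point count, model point count after exclusions, the
#'   0-based excluded or retained indices, or the named label vector.
#' @name template-accessors
NULL

#' @rdname template-accessors
#' @export
setMethod("nPointsModel", "ShapeTemplate",
    function(x) x@nPointsMarkup - length(x@excludedIndices))

#' @rdname template-accessors
#' @export
setMethod("excludedIndices", "ShapeTemplate", function(x) x@excludedIndices)

#' @rdname template-accessors
#' @export
setMethod("retainedIndices", "ShapeTemplate",
    function(x) setdiff(seq_len(x@nPointsMarkup) - 1L, x@excludedIndices))

#' @rdname template-accessors
#' @export
setMethod("pointLabels", "ShapeTemplate", function(x) x@labels)

#' Shape model accessors
#'
#' @param x a \linkS4class{ShapeModel} or \linkS4class{GroundTruthModel}.
#' @return mean coordinate vector, eigenvector matrix (2k x M),
#'   eigenvalues, per-mode training score SDs, per-mode variance
#'   fractions, the number of modes, or the training-set size.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setMethod("meanShape", "ShapeModel", function(x) x@mean)

#' @rdname model-accessors
#' @export
setMethod("meanShape", "ProcrustesFit", function(x) x@meanShape)

#' @rdname model-accessors
#' @export
setMethod("eigenVectors", "ShapeModel", function(x) x@eigenvectors)

#' @rdname model-accessors
#' @export
setMethod("eigenValues", "ShapeModel", function(x) x@eigenvalues)

#' @rdname model-accessors
#' @export
setMethod("eigenValues", "EffectiveTestsResult", function(x) x@eigenvalues)

#' @rdname model-accessors
#' @export
setMethod("scoreSds", "ShapeModel", function(x) x@scoreSds)

#' @rdname model-accessors
#' @export
setMethod("varianceFractions", "ShapeModel", function(x) x@varianceFraction)

#' @rdname model-accessors
#' @export
setMethod("nModes", "ShapeModel", function(x) length(x@eigenvalues))

#' @rdname model-accessors
#' @export
setMethod("nModes", "GroundTruthModel", function(x) ncol(x@trueModes))

#' @rdname model-accessors
#' @export
setMethod("nTraining", "ShapeModel", function(x) x@nTraining)

#' @rdname gpa
#' @export
setMethod("alignedCoords", "ProcrustesFit", function(x) x@aligned)

#' @rdname gpa
#' @export
setMethod("procrustesResiduals", "ProcrustesFit", function(x) {
    stats::setNames(x@residuals, x@imageIds)
})

#' @rdname gpa
#' @export
setMethod("converged", "ProcrustesFit", function(x) x@converged)

#' @rdname effectiveTests
#' @export
setMethod("veff", "EffectiveTestsResult", function(x) x@veffNyholt)

#' @rdname effectiveTests
#' @export
setMethod("lossFraction", "EffectiveTestsResult", function(x) x@lossFraction)

setMethod("show", "ShapeTemplate", function(object) {
    cat("ShapeTemplate '", object@templateId, "': ",
        object@nPointsMarkup, " markup points, ",
        nPointsModel(object), " in model (",
        length(object@excludedIndices), " excluded",
        if (length(object@excludedIndices))
            paste0(": ", paste(object@excludedIndices, collapse = ", ")),
        ")\n", sep = "")
    if (length(object@labels))
        cat("  ", length(object@labels), "labelled key points\n")
})

setMethod("show", "LandmarkSet", function(object) {
    cat("LandmarkSet: ", nImages(object), " image(s) x ",
        nPoints(object), " points (template '", object@templateId,
        "')\n", sep = "")
})

setMethod("show", "ProcrustesFit", function(object) {
    cat("ProcrustesFit: ", nImages(object), " shapes, ",
        ncol(object@aligned) %/% 2L, " points\n",
        "  iterations: ", object@iterations,
        ", converged: ", object@converged, "\n",
        "  mean Procrustes residual: ",
        format(mean(object@residuals), digits = 4), "\n", sep = "")
})

setMethod("show", "ShapeModel", function(object) {
    M <- nModes(object)
    cat("ShapeModel (template '", object@templateId, "'): ",
        nPoints(object), " points, ", M, " modes, trained on n = ",
        object@nTraining, "\n", sep = "")
    if (M) {
        top <- utils::head(object@varianceFraction, 5)
        cat("  variance explained by leading modes: ",
            paste(sprintf("%.1f%%", 100 * top), collapse = ", "),
            if (M > 5) ", ...", "\n", sep = "")
    }
})

setMethod("show", "ExclusionLedger", function(object) {
    labels <- c("Total images", paste0("- ", object@stageNames), "Final")
    counts <- c(object@initialCount, object@countsRemoved,
                object@finalCount)
    w <- max(nchar(labels)) + 2L
    for (i in seq_along(labels))
        cat(formatC(labels[i], width = -w),
            format(counts[i], big.mark = ","), "\n", sep = "")
})

setMethod("show", "EffectiveTestsResult", function(object) {
    cat("Effective number of independent variables (spectral decomposition)\n",
        "  M = ", object@M,
        ", Veff (Nyholt) = ", sprintf("%.1f", object@veffNyholt),
        ", Meff (Li-Ji) = ", sprintf("%.1f", object@meffLiJi), "\n",
        "  loss of independence: ",
        sprintf("%.0f%%", 100 * object@lossFraction), "\n", sep = "")
})

setMethod("show", "GroundTruthModel", function(object) {
    cat("GroundTruthModel: ", nrow(object@baseShape), " points, ",
        ncol(object@trueModes), " true modes (score SDs: ",
        paste(format(object@trueModeSds, digits = 3), collapse = ", "),
        ")\n", sep = "")
})

setMethod("show", "ReliabilityReport", function(object) {
    cat("ReliabilityReport over ", object@nImages, " images\n",
        "  point-to-point: mean ",
        format(object@meanPointToPoint, digits = 4), " px, median ",
        format(object@medianPointToPoint, digits = 4), " px\n", sep = "")
    cat("  images above ", object@accuracyCutoff, " px median cut-off: ",
        length(object@flaggedImages), "\n", sep = "")
    if (nrow(object@iccPerMode))
        cat("  mean ICC across ", nrow(object@iccPerMode), " modes: ",
            format(object@meanIcc, digits = 3), "\n", sep = "")
})
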