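#' @import methods
NULL

# Single landmark configurations are plain k x 2 numeric matrices
# (columns x, y, raster convention: x rightward, y downward, pixels).
# Collections are held in LandmarkSet; per-mode score tables are plain
# n x M matrices with image ids as rownames.

#' Shape template: point roster, labels, and model exclusions
#'
#' A \code{ShapeTemplate} describes a landmark markup scheme: how many
#' points an image is marked with, anatomical labels for key points,
#' which point indices are dropped before modelling (e.g. the 58-point
#' femur markup reduced to a 53-point model), and label aliases for
#' points that can coincide anatomically. Point indices are 0-based
#' throughout, matching the numbering convention of femur markup
#' protocols.
#'
#' @slot templateId character(1) identifier.
#' @slot nPointsMarkup integer(1), points placed per image.
#' @slot labels named character, anatomical descriptions; names are
#'   0-based point indices.
#' @slot excludedIndices integer, 0-based indices dropped from the model.
#' @slot aliases named integer, metadata recording that one point often
#'   coincides with another (no coordinates are merged).
#'
#' @export
setClass("ShapeTemplate",
    representation(
        templateId      = "character",
        nPointsMarkup   = "integer",
        labels          = "character",
        excludedIndices = "integer",
        aliases         = "integer"
    ),
    prototype(
        templateId      = "template",
        nPointsMarkup   = 0L,
        labels          = character(0),
        excludedIndices = integer(0),
        aliases         = integer(0)
    )
)

setValidity("ShapeTemplate", function(object) {
    msg <- character(0)
    n <- object@nPointsMarkup
    if (length(n) != 1L || is.na(n) || n < 1L)
        msg <- c(msg, "nPointsMarkup must be a single positive integer")
    ex <- object@excludedIndices
    if (anyDuplicated(ex))
        msg <- c(msg, "excludedIndices must be unique")
    if (length(ex) && (any(ex < 0L) || any(ex >= n)))
        msg <- c(msg, sprintf("excludedIndices must lie in [0, %d)", n))
    if (length(object@labels)) {
        idx <- suppressWarnings(as.integer(names(object@labels)))
        if (anyNA(idx) || any(idx < 0L) || any(idx >= n))
            msg <- c(msg, "label names must be valid 0-based point indices")
    }
    if (length(msg)) msg else TRUE
})

#' Set of landmark configurations sharing one template
#'
#' Ordered 2D point sets for a collection of images, stored as a
#' k x 2 x n array (points x xy x images) in pixel coordinates.
#'
#' @slot coords numeric array, dim k x 2 x n.
#' @slot imageIds character(n), unique.
#' @slot templateId character(1).
#'
#' @export
setClass("LandmarkSet",
    representation(
        coords     = "array",
        imageIds   = "character",
        templateId = "character"
    )
)

setValidity("LandmarkSet", function(object) {
    msg <- character(0)
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 2L)
        msg <- c(msg, "coords must be a k x 2 x n array")
    else {
        if (d[3] != length(object@imageIds))
            msg <- c(msg, "length(imageIds) must equal number of images")
        if (!all(is.finite(object@coords)))
            msg <- c(msg, "all coordinates must be finite")
    }
    if (anyDuplicated(object@imageIds))
        msg <- c(msg, "imageIds must be unique")
    if (length(msg)) msg else TRUE
})

#' Result of generalized Procrustes alignment
#'
#' Holds the aligned shapes (each centered at the origin, scaled to unit
#' centroid size and rotated into the mean's frame), the unit-size mean
#' shape, per-image Procrustes residuals, and convergence information.
#' Aligned coordinates are stored as an n x 2k matrix with rows
#' (x1, y1, ..., xk, yk).
#'
#' @slot aligned numeric matrix, n x 2k.
#' @slot meanShape numeric(2k), unit centroid size, centroid at origin.
#' @slot residuals numeric(n), per-image root-sum-square distance to the mean.
#' @slot imageIds character(n).
#' @slot iterations integer(1).
#' @slot converged logical(1).
#' @slot templateId character(1).
#'
#' @export
setClass("ProcrustesFit",
    representation(
        aligned    = "matrix",
        meanShape  = "numeric",
        residuals  = "numeric",
        imageIds   = "character",
        iterations = "integer",
        converged  = "logical",
        templateId = "character"
    )
)

setValidity("ProcrustesFit", function(object) {
    msg <- character(0)
    if (nrow(object@aligned) != length(object@imageIds))
        msg <- c(msg, "one aligned row per image id required")
    if (ncol(object@aligned) != length(object@meanShape))
        msg <- c(msg, "meanShape length must match aligned dimension")
    if (length(object@residuals) != nrow(object@aligned))
        msg <- c(msg, "one residual per image required")
    if (length(msg)) msg else TRUE
})

#' Point distribution shape model (hip shape modes)
#'
#' A frozen linear shape model: mean coordinate vector, orthonormal
#' eigenvectors (modes of variation), eigenvalues in descending order,
#' per-mode training-score standard deviations (the square roots of the
#' eigenvalues) and the fraction of total shape variance carried by each
#' mode. Modes whose eigenvalue is numerically zero (the directions
#' removed exactly by centering) are not retained.
#'
#' @slot mean numeric(2k), mean of the aligned training coordinates.
#' @slot eigenvectors numeric matrix 2k x M, orthonormal columns.
#' @slot eigenvalues numeric(M), non-negative, descending.
#' @slot scoreSds numeric(M), sqrt(eigenvalues).
#' @slot varianceFraction numeric(M), eigenvalue / total variance.
#' @slot nTraining integer(1), training-set size.
#' @slot templateId character(1).
#'
#' @export
setClass("ShapeModel",
    representation(
        mean             = "numeric",
        eigenvectors     = "matrix",
        eigenvalues      = "numeric",
        scoreSds         = "numeric",
        varianceFraction = "numeric",
        nTraining        = "integer",
        templateId       = "character"
    )
)

setValidity("ShapeModel", function(object) {
    msg <- character(0)
    M <- length(object@eigenvalues)
    V <- object@eigenvectors
    if (ncol(V) != M)
        msg <- c(msg, "one eigenvector per eigenvalue required")
    if (nrow(V) != length(object@mean))
        msg <- c(msg, "eigenvector length must match mean length")
    if (M > 0) {
        if (any(object@eigenvalues < 0))
            msg <- c(msg, "eigenvalues must be non-negative")
        if (is.unsorted(rev(object@eigenvalues)))
            msg <- c(msg, "eigenvalues must be in descending order")
        G <- crossprod(V)
        if (max(abs(G - diag(M))) > 1e-8)
            msg <- c(msg, "eigenvectors must be orthonormal (tol 1e-8)")
        if (max(abs(object@scoreSds^2 - object@eigenvalues)) >
                1e-8 * max(object@eigenvalues, 1))
            msg <- c(msg, "scoreSds^2 must equal eigenvalues")
        if (length(object@varianceFraction) != M)
            msg <- c(msg, "one variance fraction per mode required")
    }
    if (length(msg)) msg else TRUE
})

#' Exclusion ledger for staged sample filtering
#'
#' Accounting of how an initial image count is reduced through named
#' exclusion stages down to the count entering the shape model.
#'
#' @slot initialCount integer(1).
#' @slot stageNames character.
#' @slot countsRemoved integer, same length as stageNames.
#' @slot finalCount integer(1), equals initial minus total removed.
#'
#' @export
setClass("ExclusionLedger",
    representation(
        initialCount  = "integer",
        stageNames    = "character",
        countsRemoved = "integer",
        finalCount    = "integer"
    )
)

setValidity("ExclusionLedger", function(object) {
    msg <- character(0)
    if (length(object@stageNames) != length(object@countsRemoved))
        msg <- c(msg, "one removed count per stage required")
    if (any(object@countsRemoved < 0L) || object@initialCount < 0L)
        msg <- c(msg, "counts must be non-negative")
    if (object@finalCount !=
            object@initialCount - sum(object@countsRemoved))
        msg <- c(msg, "finalCount must equal initialCount - sum(countsRemoved)")
    if (any(object@initialCount - cumsum(object@countsRemoved) < 0L))
        msg <- c(msg, "running total must never go negative")
    if (length(msg)) msg else TRUE
})

#' Effective number of independent tests from a correlation matrix
#'
#' Spectral-decomposition summary of a score correlation matrix:
#' eigenvalues, their sample variance, the Nyholt effective number of
#' independent variables, the Li-Ji companion estimate, and the
#' fractional loss of independence.
#'
#' @slot M integer(1), number of variables.
#' @slot eigenvalues numeric(M), descending, summing to M.
#' @slot varLambda numeric(1), sample variance of the eigenvalues
#'   (divisor M - 1).
#' @slot veffNyholt numeric(1).
#' @slot meffLiJi numeric(1).
#' @slot lossFraction numeric(1), (M - veffNyholt) / M.
#'
#' @export
setClass("EffectiveTestsResult",
    representation(
        M            = "integer",
        eigenvalues  = "numeric",
        varLambda    = "numeric",
        veffNyholt   = "numeric",
        meffLiJi     = "numeric",
        lossFraction = "numeric"
    )
)

setValidity("EffectiveTestsResult", function(object) {
    msg <- character(0)
    M <- object@M
    if (length(object@eigenvalues) != M)
        msg <- c(msg, "M eigenvalues required")
    if (abs(sum(object@eigenvalues) - M) > 1e-8)
        msg <- c(msg, "eigenvalues must sum to M (trace of a correlation matrix)")
    if (any(object@eigenvalues < -1e-10))
        msg <- c(msg, "eigenvalues must be non-negative up to round-off")
    if (object@veffNyholt < 1 - 1e-12 || object@veffNyholt > M + 1e-12)
        msg <- c(msg, "veffNyholt must lie in [1, M]")
    if (length(msg)) msg else TRUE
})

#' Ground-truth population model for synthetic landmark data
#'
#' The generative model behind a synthetic femur-landmark population:
#' a base shape plus orthonormal displacement modes with known per-mode
#' score scales. Used to validate mode recovery by the fitted shape model.
#'
#' @slot baseShape numeric matrix k x 2, pixel coordinates.
#' @slot trueModes numeric matrix 2k x m, orthonormal columns.
#' @slot trueModeSds numeric(m), per-mode score scale in pixels.
#' @slot template ShapeTemplate.
#'
#' @export
setClass("GroundTruthModel",
    representation(
        baseShape   = "matrix",
        trueModes   = "matrix",
        trueModeSds = "numeric",
        template    = "ShapeTemplate"
    )
)

setValidity("GroundTruthModel", function(object) {
    msg <- character(0)
    k <- nrow(object@baseShape)
    if (ncol(object@baseShape) != 2L)
        msg <- c(msg, "baseShape must be a k x 2 matrix")
    m <- ncol(object@trueModes)
    if (m > 0) {
        if (nrow(object@trueModes) != 2L * k)
            msg <- c(msg, "trueModes rows must equal 2 * nrow(baseShape)")
        G <- crossprod(object@trueModes)
        if (max(abs(G - diag(m))) > 1e-8)
            msg <- c(msg, "trueModes must be mutually orthonormal (tol 1e-8)")
        if (m > 2L * k - 4L)
            msg <- c(msg, "at most 2k - 4 modes are identifiable after similarity alignment")
    }
    if (length(object@trueModeSds) != m)
        msg <- c(msg, "one score SD per mode required")
    if (length(msg)) msg else TRUE
})

#' Reproducibility report for repeated point placement
#'
#' Summary of agreement between two marking sessions of the same images:
#' pixel point-to-point distances (with the conventional accuracy flag at
#' a median of 3 pixels) and, when a shape model is supplied, per-mode
#' intraclass correlation coefficients of the resulting scores.
#'
#' @slot meanPointToPoint numeric(1), pixels.
#' @slot medianPointToPoint numeric(1), pixels.
#' @slot perImageMeans named numeric, per-image mean distance.
#' @slot flaggedImages character, images whose median distance exceeds
#'   the accuracy cut-off.
#' @slot accuracyCutoff numeric(1), pixels (default 3).
#' @slot iccPerMode data.frame with columns mode, icc, belowThreshold
#'   (zero rows when no model was supplied).
#' @slot meanIcc numeric(1), NA when no model was supplied.
#' @slot nImages integer(1).
#'
#' @export
setClass("ReliabilityReport",
    representation(
        meanPointToPoint   = "numeric",
        medianPointToPoint = "numeric",
        perImageMeans      = "numeric",
        flaggedImages      = "character",
        accuracyCutoff     = "numeric",
        iccPerMode         = "data.frame",
        meanIcc            = "numeric",
        nImages            = "integer"
    )
)

setValidity("ReliabilityReport", function(object) {
    msg <- character(0)
    if (length(object@perImageMeans) != object@nImages)
        msg <- c(msg, "one per-image mean per image required")
    if (any(object@perImageMeans < 0))
        msg <- c(msg, "distances must be non-negative")
    if (nrow(object@iccPerMode) &&
        any(stats::na.omit(object@iccPerMode$icc) > 1 + 1e-12 |
            stats::na.omit(object@iccPerMode$icc) < -1 - 1e-12))
        msg <- c(msg, "ICC values must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})
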