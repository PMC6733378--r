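#' Repeatability of repeated point placement
#'
#' Compares two markings of the same image set in raw pixel coordinates:
#' per-image mean point-to-point distances, their overall mean and
#' median, and a flag for images whose median distance exceeds the
#' conventional 3-pixel accuracy cut-off. When a shape model is
#' supplied, both sessions are scored against it (one fixed model for
#' both) and per-mode intraclass correlation coefficients are added.
#'
#' @param setA,setB \linkS4class{LandmarkSet}s covering the same image
#'   ids (matched by id, order-independent).
#' @param model optional \linkS4class{ShapeModel} for mode-score ICCs;
#'   when its point count is the template's reduced count, the
#'   template's exclusions are applied before scoring.
#' @param template optional \linkS4class{ShapeTemplate} used for the
#'   reduction when scoring against \code{model}.
#' @param accuracyCutoff pixels; median cut-off for the accuracy flag.
#' @param iccThreshold modes with ICC below this are marked
#'   (conventionally 0.70).
#' @return a \linkS4class{ReliabilityReport}.
#' @export
repeatabilitySummary <- function(setA, setB, model = NULL, template = NULL,
                                 accuracyCutoff = 3, iccThreshold = 0.70) {
    stopifnot(is(setA, "LandmarkSet"), is(setB, "LandmarkSet"))
    missing <- setdiff(imageIds(setA), imageIds(setB))
    extra <- setdiff(imageIds(setB), imageIds(setA))
    if (length(missing) || length(extra))
        stop("image sets do not match; missing from one session: ",
             paste(c(missing, extra), collapse = ", "))
    setB <- setB[imageIds(setA)]
    if (nPoints(setA) != nPoints(setB))
        stop("template mismatch between the two sessions")
    n <- nImages(setA)
    perImage <- numeric(n)
    medians <- numeric(n)
    for (i in seq_len(n)) {
        pp <- pointToPoint(setA[[i]], setB[[i]])
        perImage[i] <- pp$mean
        medians[i] <- pp$median
    }
    names(perImage) <- imageIds(setA)
    iccTab <- data.frame(mode = integer(0), icc = numeric(0),
                         belowThreshold = logical(0))
    meanIcc <- NA_real_
    if (!is.null(model)) {
        reduce <- function(s) {
            if (!is.null(template) && nPoints(s) == nPointsMarkup(template) &&
                nPoints(model) == nPointsModel(template))
                applyTemplateExclusions(s, template) else s
        }
        iccTab <- iccPerMode(projectShapes(model, reduce(setA)),
                             projectShapes(model, reduce(setB)),
                             threshold = iccThreshold)
        meanIcc <- mean(iccTab$icc)
    }
    new("ReliabilityReport",
        meanPointToPoint = mean(perImage),
        medianPointToPoint = stats::median(medians),
        perImageMeans = perImage,
        flaggedImages = imageIds(setA)[medians > accuracyCutoff],
        accuracyCutoff = accuracyCutoff,
        iccPerMode = iccTab, meanIcc = meanIcc, nImages = as.integer(n))
}

#' Intraclass correlation coefficient
#'
#' Single-measurement ICC from a complete subjects x raters matrix,
#' computed from the two-way ANOVA mean squares. The default
#' \code{"agreement"} form is the two-way random-effects,
#' absolute-agreement ICC
#' \deqn{\frac{MS_S - MS_E}{MS_S + (k-1) MS_E + (k/n)(MS_R - MS_E)},}
#' the conservative standard for test-retest of continuous scores; the
#' \code{"consistency"} form drops the rater variance term.
#'
#' @param ratings numeric matrix, subjects in rows, raters in columns.
#' @param type \code{"agreement"} (default) or \code{"consistency"}.
#' @return a scalar in [-1, 1].
#' @export
icc <- function(ratings, type = c("agreement", "consistency")) {
    type <- match.arg(type)
    ratings <- as.matrix(ratings)
    n <- nrow(ratings); k <- ncol(ratings)
    if (n < 2L || k < 2L)
        stop("at least 2 subjects and 2 raters are required")
    if (anyNA(ratings)) stop("ratings matrix must be complete")
    grand <- mean(ratings)
    rowM <- rowMeans(ratings)
    colM <- colMeans(ratings)
    ssS <- k * sum((rowM - grand)^2)
    ssR <- n * sum((colM - grand)^2)
    ssT <- sum((ratings - grand)^2)
    ssE <- ssT - ssS - ssR
    msS <- ssS / (n - 1)
    msR <- ssR / (k - 1)
    msE <- ssE / ((n - 1) * (k - 1))
    if (msS <= .Machine$double.eps * max(abs(ratings), 1)^2)
        warning("degenerate ratings: no between-subject variance")
    den <- switch(type,
        agreement   = msS + (k - 1) * msE + (k / n) * (msR - msE),
        consistency = msS + (k - 1) * msE)
    if (den == 0) return(if (msS == 0) 0 else 1)
    (msS - msE) / den
}

#' Per-mode ICC between two score tables
#'
#' Computes the ICC of each mode's scores between two sessions (two
#' markings or two markers) scored against one fixed model, plus their
#' mean, marking modes below the reliability threshold.
#'
#' @param scoresA,scoresB n x M score matrices over the same images
#'   (matched by row name when present).
#' @param type passed to \code{\link{icc}}.
#' @param threshold reliability threshold (default 0.70).
#' @return a data.frame with columns \code{mode}, \code{icc},
#'   \code{belowThreshold}; the mean ICC is attached as attribute
#'   \code{"meanIcc"}.
#' @export
iccPerMode <- function(scoresA, scoresB, type = "agreement",
                       threshold = 0.70) {
    scoresA <- as.matrix(scoresA); scoresB <- as.matrix(scoresB)
    if (!is.null(rownames(scoresA)) && !is.null(rownames(scoresB))) {
        if (!setequal(rownames(scoresA), rownames(scoresB)))
            stop("mismatched images between score tables")
        scoresB <- scoresB[rownames(scoresA), , drop = FALSE]
    }
    if (!all(dim(scoresA) == dim(scoresB)))
        stop("score tables must have matching dimensions")
    vals <- vapply(seq_len(ncol(scoresA)), function(m)
        icc(cbind(scoresA[, m], scoresB[, m]), type = type), 0)
    out <- data.frame(mode = seq_len(ncol(scoresA)), icc = vals,
                      belowThreshold = vals < threshold)
    attr(out, "meanIcc") <- mean(vals)
    out
}
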