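#' Build a point distribution model from aligned shapes
#'
#' Performs principal component analysis of the aligned coordinate
#' vectors: eigen-decomposition of their sample covariance matrix
#' (divisor n - 1), centered at the arithmetic mean of the aligned
#' shapes. Modes are sorted by descending eigenvalue; a deterministic
#' sign convention (each eigenvector's largest-magnitude entry is
#' positive) makes saved models reproducible across platforms. Modes
#' whose eigenvalue is numerically zero relative to the leading one
#' (below \code{rankTol} times the largest) are dropped; variance
#' fractions are taken against the total variance, so the retained
#' fractions sum to 1 up to that negligible remainder.
#'
#' @param x a \linkS4class{ProcrustesFit} from \code{\link{gpa}}, or an
#'   n x 2k matrix of aligned coordinate rows.
#' @param rankTol relative eigenvalue threshold below which a mode is
#'   treated as numerically zero.
#' @return a \linkS4class{ShapeModel}.
#' @export
buildShapeModel <- function(x, rankTol = 1e-10) {
    X <- if (is(x, "ProcrustesFit")) alignedCoords(x) else as.matrix(x)
    n <- nrow(X)
    if (n < 2L) stop("at least two shapes are required")
    mu <- colMeans(X)
    S <- stats::cov(X)
    e <- eigen(S, symmetric = TRUE)
    lambda <- e$values
    total <- sum(pmax(lambda, 0))
    if (total <= 0) stop("zero total variance: all shapes identical")
    keep <- which(lambda > rankTol * lambda[1])
    lambda <- lambda[keep]
    V <- e$vectors[, keep, drop = FALSE]
    # sign convention: largest-magnitude entry of each mode positive
    for (j in seq_along(keep)) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    new("ShapeModel", mean = unname(mu), eigenvectors = unname(V),
        eigenvalues = lambda, scoreSds = sqrt(lambda),
        varianceFraction = lambda / total, nTraining = n,
        templateId = if (is(x, "ProcrustesFit")) templateId(x) else "unknown")
}

scoresFromRows <- function(model, X, ids) {
    D <- sweep(X, 2L, model@mean)
    sc <- D %*% model@eigenvectors
    if (nModes(model) > 0L) sc <- sweep(sc, 2L, model@scoreSds, `/`)
    dimnames(sc) <- list(ids, modeNames(model))
    sc
}

modeNames <- function(model) {
    if (nModes(model) > 0L) sprintf("HSM%d", seq_len(nModes(model))) else
        character(0)
}

#' Standardized training scores of a shape model
#'
#' Scores the shapes a model was built from:
#' \eqn{s_{im} = \langle x_i - \bar{x}, e_m \rangle / \sigma_m} with
#' \eqn{\sigma_m} the training SD of mode m (the square root of its
#' eigenvalue). Across the training set each mode's scores have mean 0
#' and standard deviation 1 (divisor n - 1) to machine precision — each
#' individual's score is its number of SDs from the mean shape.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param x the \linkS4class{ProcrustesFit} (or aligned coordinate
#'   matrix) the model was built from.
#' @return an n x M score matrix with image ids as row names.
#' @export
scoreTraining <- function(model, x) {
    X <- if (is(x, "ProcrustesFit")) alignedCoords(x) else as.matrix(x)
    if (ncol(X) != length(model@mean))
        stop("dimension mismatch between shapes and model")
    ids <- if (is(x, "ProcrustesFit")) imageIds(x) else rownames(X)
    scoresFromRows(model, X, ids)
}

#' Project new shapes onto a frozen reference model
#'
#' Scores configurations against a saved reference model without
#' refitting it: each configuration is centered and scaled to unit
#' centroid size, rotated onto the model mean by the orthogonal
#' Procrustes solution, and the residual from the mean is projected onto
#' the saved eigenvectors and divided by the reference training SDs. The
#' model is not modified. Projected scores of an external population
#' may legitimately have nonzero means and SDs different from 1 — that
#' displacement is the comparison the frozen reference enables.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param x a \linkS4class{LandmarkSet} (already reduced to the model's
#'   point count), a single k x 2 configuration, or a ProcrustesFit.
#' @return an n x M score matrix in reference SD units.
#' @export
projectShapes <- function(model, x) {
    if (is(x, "ProcrustesFit")) {
        configs <- lapply(seq_len(nImages(x)),
                          function(i) unflattenXY(x@aligned[i, ]))
        ids <- imageIds(x)
    } else if (is(x, "LandmarkSet")) {
        configs <- lapply(seq_len(nImages(x)), function(i) x[[i]])
        ids <- imageIds(x)
    } else {
        configs <- list(asConfig(x))
        ids <- NULL
    }
    k <- nPoints(model)
    muM <- unflattenXY(model@mean)
    X <- t(vapply(configs, function(p) {
        if (nrow(p) != k)
            stop("template mismatch: configuration has ", nrow(p),
                 " points, model expects ", k)
        q <- normalizeShape(p)
        flattenXY(q %*% optimalRotation(q, muM))
    }, numeric(2L * k)))
    scoresFromRows(model, X, ids)
}

#' Reconstruct the shape at a chosen score along one mode
#'
#' Returns \eqn{\bar{x} + s \,\sigma_m e_m} as a k x 2 point set — the
#' conventional way to visualize what a mode encodes, e.g. at +2 and -2
#' SD, which are reflections of each other about the mean shape.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param mode 1-based mode index.
#' @param kSd score in SD units (0 returns the mean shape).
#' @return a k x 2 matrix.
#' @export
reconstructShape <- function(model, mode, kSd = 2) {
    mode <- as.integer(mode)
    if (mode < 1L || mode > nModes(model))
        stop("mode index out of range [1, ", nModes(model), "]")
    v <- model@mean + kSd * model@scoreSds[mode] * model@eigenvectors[, mode]
    unflattenXY(v)
}

#' Cumulative variance explained by the leading modes
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param nModes number of leading modes (defaults to all).
#' @return the cumulative fraction of total shape variance in [0, 1].
#' @export
varianceExplained <- function(model, nModes = length(model@eigenvalues)) {
    nModes <- as.integer(nModes)
    if (nModes < 0L || nModes > length(model@eigenvalues))
        stop("nModes out of range")
    if (nModes == 0L) return(0)
    sum(model@varianceFraction[seq_len(nModes)])
}

#' Restrict a model to its leading modes
#'
#' Higher modes typically carry noise-level variance and are discarded;
#' variance fractions are retained as-is (not renormalized), so the
#' cumulative variance explained by the kept modes is unchanged.
#'
#' @param model a \linkS4class{ShapeModel}.
#' @param nModes number of leading modes to keep (>= 1).
#' @return a \linkS4class{ShapeModel} with \code{nModes} modes.
#' @export
truncateModel <- function(model, nModes) {
    nModes <- as.integer(nModes)
    if (nModes < 1L || nModes > length(model@eigenvalues))
        stop("nModes must lie in [1, ", length(model@eigenvalues), "]")
    idx <- seq_len(nModes)
    new("ShapeModel", mean = model@mean,
        eigenvectors = model@eigenvectors[, idx, drop = FALSE],
        eigenvalues = model@eigenvalues[idx],
        scoreSds = model@scoreSds[idx],
        varianceFraction = model@varianceFraction[idx],
        nTraining = model@nTraining, templateId = model@templateId)
}
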