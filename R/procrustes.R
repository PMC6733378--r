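#' Centroid of a landmark configuration
#'
#' @param points k x 2 numeric matrix of landmark coordinates.
#' @return numeric(2), the arithmetic mean of the x and y coordinates.
#' @export
centroid <- function(points) {
    points <- asConfig(points)
    if (nrow(points) < 1L) stop("at least one point is required")
    colMeans(points)
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of all landmarks from
#' their centroid -- the standard size measure of geometric
#' morphometrics, removed before shape analysis.
#'
#' @param points k x 2 numeric matrix.
#' @return a positive scalar.
#' @export
centroidSize <- function(points) {
    points <- asConfig(points)
    if (nrow(points) < 2L) stop("at least two points are required")
    ctr <- colMeans(points)
    s <- sqrt(sum(sweep(points, 2, ctr)^2))
    if (s <= 0) stop("degenerate configuration: all points coincide")
    s
}

#' Center and scale a configuration to unit centroid size
#'
#' Removes translation (centroid moved to the origin) and size (scaled
#' to unit centroid size). Idempotent.
#'
#' @param points k x 2 numeric matrix.
#' @return k x 2 matrix with centroid (0, 0) and centroid size 1.
#' @export
normalizeShape <- function(points) {
    points <- asConfig(points)
    ctr <- centroid(points)
    centered <- sweep(points, 2, ctr)
    centered / centroidSize(points)
}

#' Optimal rotation between two centered configurations
#'
#' Solves the orthogonal Procrustes problem: the proper rotation R
#' (determinant +1) minimizing \eqn{\sum_i \| A_i R - B_i \|^2} for
#' centered point sets A and B, via singular value decomposition of the
#' cross-covariance matrix. Reflections are suppressed by a sign
#' correction on the smallest singular value.
#'
#' @param A,B k x 2 centered numeric matrices with matching rows.
#' @return a 2 x 2 rotation matrix to be applied as \code{A \%*\% R}.
#' @export
optimalRotation <- function(A, B) {
    A <- asConfig(A); B <- asConfig(B)
    if (nrow(A) != nrow(B)) stop("configurations must have the same point count")
    C <- crossprod(A, B)            # 2 x 2 cross-covariance
    if (max(abs(C)) == 0) stop("degenerate cross-covariance (rank 0)")
    sv <- svd(C)
    d <- sign(det(sv$u %*% t(sv$v)))
    if (d == 0) stop("degenerate cross-covariance")
    sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Removes translation, scale and rotation from a set of landmark
#' configurations and estimates their mean shape. Each configuration is
#' centered and scaled to unit centroid size, then iteratively rotated
#' onto the current mean estimate; the mean is recomputed as the
#' coordinate-wise average and renormalized, until it moves by less than
#' \code{tol} (Euclidean norm) or \code{maxIter} is reached. A final
#' rotation pass aligns every shape to the converged mean.
#'
#' @param x a \linkS4class{LandmarkSet} (or list of k x 2 matrices).
#' @param tol convergence tolerance on the mean displacement.
#' @param maxIter maximum number of iterations.
#' @return a \linkS4class{ProcrustesFit}; non-convergence raises a
#'   warning and is recorded in the \code{converged} flag, never an error.
#' @name gpa
#' @export
gpa <- function(x, tol = 1e-10, maxIter = 100L) {
    configs <- asConfigList(x)
    n <- length(configs)
    if (n < 2L) stop("at least two configurations are required")
    k <- nrow(configs[[1]])
    if (any(vapply(configs, nrow, 0L) != k))
        stop("all configurations must share one template (equal point counts)")

    # rows of X hold normalized, flattened (x1, y1, ..., xk, yk) shapes
    X <- t(vapply(configs, function(p) flattenXY(normalizeShape(p)),
                  numeric(2L * k)))
    mu <- X[1L, ]
    iter <- 0L
    conv <- FALSE
    rotateAll <- function(X, mu) {
        muM <- unflattenXY(mu)
        t(apply(X, 1L, function(row) {
            flattenXY(unflattenXY(row) %*% optimalRotation(unflattenXY(row), muM))
        }))
    }
    while (iter < maxIter) {
        iter <- iter + 1L
        X <- rotateAll(X, mu)
        avg <- colMeans(X)
        muNew <- flattenXY(normalizeShape(unflattenXY(avg)))
        delta <- sqrt(sum((muNew - mu)^2))
        mu <- muNew
        if (delta < tol) { conv <- TRUE; break }
    }
    if (!conv)
        warning("generalized Procrustes analysis did not converge in ",
                maxIter, " iterations")
    X <- rotateAll(X, mu)
    res <- sqrt(rowSums(sweep(X, 2L, mu)^2))
    ids <- if (is(x, "LandmarkSet")) imageIds(x) else
        (names(configs) %||% paste0("shape", seq_len(n)))
    new("ProcrustesFit",
        aligned = X, meanShape = mu, residuals = unname(res),
        imageIds = ids, iterations = iter, converged = conv,
        templateId = if (is(x, "LandmarkSet")) templateId(x) else "unknown")
}

#' Point-to-point distances between two markings of one image
#'
#' Euclidean distance per landmark between two configurations in raw
#' pixel coordinates (not Procrustes-aligned), the scale in which
#' point-placement repeatability is conventionally reported.
#'
#' @param A,B k x 2 matrices of the same template.
#' @return a list with \code{distances} (numeric(k)), \code{mean} and
#'   \code{median}.
#' @export
pointToPoint <- function(A, B) {
    A <- asConfig(A); B <- asConfig(B)
    if (nrow(A) != nrow(B))
        stop("configurations must have the same point count")
    d <- sqrt(rowSums((A - B)^2))
    list(distances = d, mean = mean(d), median = stats::median(d))
}

# ---- internal helpers -------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce to a k x 2 numeric matrix, accepting flattened length-2k vectors
asConfig <- function(p) {
    if (is.numeric(p) && is.null(dim(p))) p <- unflattenXY(p)
    if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
        stop("a configuration must be a k x 2 numeric matrix")
    if (!all(is.finite(p))) stop("coordinates must be finite")
    unname(p)
}

asConfigList <- function(x) {
    if (is(x, "LandmarkSet"))
        lapply(seq_len(nImages(x)), function(i) x[[i]])
    else if (is.list(x)) lapply(x, asConfig)
    else stop("expected a LandmarkSet or a list of configurations")
}

# (x1, y1, ..., xk, yk) flattening used for model vectors
flattenXY <- function(p) as.vector(t(p))

unflattenXY <- function(v) matrix(v, ncol = 2L, byrow = TRUE)
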