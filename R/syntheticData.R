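#' Construct a LandmarkSet
#'
#' @param coords a list of k x 2 matrices, or a k x 2 x n array.
#' @param imageIds character vector of unique image identifiers.
#' @param templateId template identifier string.
#' @return a \linkS4class{LandmarkSet}.
#' @export
LandmarkSet <- function(coords, imageIds = NULL, templateId = "template") {
    if (is.list(coords)) {
        mats <- lapply(coords, asConfig)
        k <- nrow(mats[[1]])
        arr <- array(unlist(mats), dim = c(k, 2L, length(mats)))
        if (is.null(imageIds))
            imageIds <- names(coords) %||% sprintf("img%04d", seq_along(mats))
    } else {
        arr <- coords
        if (is.null(imageIds)) imageIds <- sprintf("img%04d", seq_len(dim(arr)[3]))
    }
    new("LandmarkSet", coords = arr, imageIds = as.character(imageIds),
        templateId = templateId)
}

# 58-point schematic proximal femur in a nominal 250 x 180 pixel frame
# (x rightward, y downward). Indices 0-45 trace the main outline from
# the distal medial shaft up over the lesser trochanter, medial neck,
# femoral head arc and greater trochanter, down the lateral shaft;
# 46-50 retrace the inferior lesser trochanter; 51-56 are the detached
# two-segment acetabular eyebrow; 57 is an extra point beyond its
# lateral end. Points 0, 1, 44, 45 and 57 are excluded from the model.
femur58Coords <- function() {
    headC <- c(80, 60); headR <- 32
    arcA <- seq(-50, -320, length.out = 17)   # degrees, head arc 9..25
    arc <- cbind(headC[1] + headR * cospi(arcA / 180),
                 headC[2] - headR * sinpi(arcA / 180))
    pts <- rbind(
        c(151, 176), c(150, 168), c(150, 152), c(143, 144), c(149, 130),  # 0-4
        c(146, 122), c(136, 114), c(124, 106), c(112, 97),                # 5-8
        arc,                                                              # 9-25
        c(118, 50), c(135, 58), c(152, 66),                               # 26-28
        c(165, 72), c(174, 66), c(181, 62), c(188, 62), c(193, 68),       # 29-33
        c(195, 78), c(194, 90), c(192, 102), c(189, 114),                 # 34-37
        c(187, 124), c(186, 132), c(185, 140), c(185, 148), c(184, 156),  # 38-42
        c(184, 163), c(183, 170), c(183, 176),                            # 43-45
        c(150, 153), c(145, 148), c(141, 143), c(143, 137), c(147, 133),  # 46-50
        c(52, 30), c(65, 24), c(78, 20), c(92, 19), c(105, 21), c(118, 25), # 51-56
        c(130, 30))                                                       # 57
    colnames(pts) <- c("x", "y")
    pts
}

femur58Labels <- function() {
    c("2"  = "Medial femoral shaft meets inferior lesser trochanter",
      "4"  = "Medial femoral shaft meets superior lesser trochanter",
      "9"  = "Lateral inferior curvature of femoral head where it meets femoral neck",
      "10" = "Medial inferior curvature of the femoral head",
      "23" = "Superior lateral femoral head curvature",
      "25" = "Inferior lateral femoral head where it meets the superior femoral neck",
      "29" = "Inferior greater trochanter slope where it meets superior femoral neck",
      "31" = "Medial superior greater trochanter",
      "38" = "Inferior lateral greater trochanter",
      "43" = "Lateral femoral shaft",
      "46" = "Inferior lesser trochanter",
      "51" = "Acetabular eyebrow medial end",
      "56" = "Acetabular eyebrow lateral end")
}

# resample an open polyline to m points equally spaced by arc length
resamplePolyline <- function(pts, m) {
    seg <- sqrt(rowSums(diff(pts)^2))
    s <- c(0, cumsum(seg))
    target <- seq(0, s[length(s)], length.out = m)
    cbind(stats::approx(s, pts[, 1], xout = target)$y,
          stats::approx(s, pts[, 2], xout = target)$y)
}

#' Schematic proximal-femur landmark template
#'
#' Builds the parametric base shape used by the synthetic-data
#' generator: a schematic proximal femur outline (femoral head arc,
#' neck, greater and lesser trochanter bumps, medial and lateral shaft
#' segments) plus a detached two-segment acetabular "eyebrow" polyline,
#' in a nominal 250 x 180 pixel frame with the raster convention
#' (x rightward, y downward).
#'
#' The default 58-point markup carries anatomical labels for its 13 key
#' landmarks and excludes points \{0, 1, 44, 45, 57\} from the model,
#' yielding the standard 53-point shape model. For any other even point
#' count (at least 12), the main outline is resampled by arc length and
#' no points are excluded.
#'
#' @param nPoints even integer, number of markup points (default 58).
#' @return a list with elements \code{template}
#'   (\linkS4class{ShapeTemplate}) and \code{baseShape} (k x 2 matrix).
#' @examples
#' tpl <- makeBaseTemplate()
#' nPointsModel(tpl$template)   # 53
#' @export
makeBaseTemplate <- function(nPoints = 58L) {
    nPoints <- as.integer(nPoints)
    if (is.na(nPoints) || nPoints < 12L || nPoints %% 2L != 0L)
        stop("invalid template: nPoints must be an even integer >= 12")
    full <- femur58Coords()
    if (nPoints == 58L) {
        template <- new("ShapeTemplate", templateId = "femur58",
                        nPointsMarkup = 58L, labels = femur58Labels(),
                        excludedIndices = c(0L, 1L, 44L, 45L, 57L),
                        aliases = c("2" = 46L))
        return(list(template = template, baseShape = unname(full)))
    }
    outline <- resamplePolyline(full[1:46, ], nPoints - 6L)
    eyebrow <- full[52:57, ]
    base <- rbind(outline, eyebrow)
    template <- new("ShapeTemplate",
                    templateId = sprintf("femur%d", nPoints),
                    nPointsMarkup = nPoints, labels = character(0),
                    excludedIndices = integer(0), aliases = integer(0))
    list(template = template, baseShape = unname(base))
}

#' Ground-truth modes of variation for a synthetic population
#'
#' Builds \code{nModes} orthonormal displacement fields over the base
#' shape by orthonormalizing smooth low-frequency random fields
#' (truncated Fourier series in the point index). Candidate fields are
#' first projected out of the four-dimensional similarity tangent space
#' at the base shape (two translations, scaling and infinitesimal
#' rotation) so that the planted variation survives Procrustes
#' alignment, then Gram-Schmidt orthonormalized among themselves.
#'
#' @param baseShape k x 2 matrix, typically from
#'   \code{\link{makeBaseTemplate}}.
#' @param nModes number of true modes (at most 2k - 4).
#' @param modeSds numeric(nModes), per-mode score SD in pixels.
#' @param template the matching \linkS4class{ShapeTemplate}.
#' @param seed integer seed for the random fields.
#' @return a \linkS4class{GroundTruthModel}.
#' @export
makeGroundTruthModes <- function(baseShape, nModes, modeSds,
                                 template = makeBaseTemplate(nrow(baseShape))$template,
                                 seed = 1L) {
    baseShape <- asConfig(baseShape)
    k <- nrow(baseShape)
    nModes <- as.integer(nModes)
    if (nModes < 0L || nModes > 2L * k - 4L)
        stop("nModes must lie in [0, 2k - 4]")
    if (length(modeSds) != nModes)
        stop("one score SD per mode is required")
    ctr <- sweep(baseShape, 2, colMeans(baseShape))
    sim <- cbind(flattenXY(cbind(rep(1, k), 0)),
                 flattenXY(cbind(0, rep(1, k))),
                 flattenXY(ctr),
                 flattenXY(cbind(-ctr[, 2], ctr[, 1])))
    sim <- qr.Q(qr(sim))
    modes <- matrix(0, 2L * k, nModes)
    if (nModes > 0L) withSeed(seed, {
        t <- (seq_len(k) - 1) / k
        freqs <- 1:4
        basis <- do.call(cbind, lapply(freqs, function(f)
            cbind(cospi(2 * f * t), sinpi(2 * f * t)) / f))
        j <- 0L
        while (j < nModes) {
            d <- cbind(basis %*% stats::rnorm(ncol(basis)),
                       basis %*% stats::rnorm(ncol(basis)))
            v <- flattenXY(d)
            v <- v - sim %*% crossprod(sim, v)
            if (j > 0L) {
                prev <- modes[, seq_len(j), drop = FALSE]
                v <- v - prev %*% crossprod(prev, v)
            }
            nv <- sqrt(sum(v^2))
            if (nv < 1e-6) next  # degenerate draw, try again
            j <- j + 1L
            modes[, j] <- v / nv
        }
    })
    new("GroundTruthModel", baseShape = baseShape, trueModes = modes,
        trueModeSds = as.numeric(modeSds), template = template)
}

#' Simulate a femur-like landmark population
#'
#' Draws \code{nImages} configurations from a ground-truth linear shape
#' model: image i is
#' \deqn{T_i(\mathrm{base} + \textstyle\sum_m s_{im}\,\sigma_m e_m) + \epsilon,}
#' with standard-normal true scores \eqn{s_{im}}, a similarity nuisance
#' transform \eqn{T_i} (rotation about the centroid, scaling, and
#' translation, each drawn uniformly from the given ranges), and i.i.d.
#' normal per-coordinate marking noise \eqn{\epsilon}. Fully
#' reproducible from the seed.
#'
#' Defaults emulate plausible DXA positioning variation: rotation within
#' +/-15 degrees, scale 0.9-1.1, translation within +/-20 px.
#'
#' @param gt a \linkS4class{GroundTruthModel}.
#' @param nImages number of images (>= 2).
#' @param rotationRange radians, c(min, max).
#' @param scaleRange positive c(min, max).
#' @param translationRange pixels, c(min, max), applied per axis.
#' @param markingNoiseSd pixels, per-coordinate noise SD (>= 0).
#' @param aspectRatioScale optional x-axis scale factor emulating
#'   anisotropic pixel spacing between scanners (default 1, isotropic).
#' @param seed integer seed.
#' @return list with \code{landmarks} (a \linkS4class{LandmarkSet}) and
#'   \code{trueScores} (nImages x nModes matrix of the planted scores).
#' @export
simulatePopulation <- function(gt, nImages,
                               rotationRange = c(-15, 15) * pi / 180,
                               scaleRange = c(0.9, 1.1),
                               translationRange = c(-20, 20),
                               markingNoiseSd = 1,
                               aspectRatioScale = 1,
                               seed = 1L) {
    stopifnot(is(gt, "GroundTruthModel"))
    nImages <- as.integer(nImages)
    if (nImages < 2L) stop("nImages must be at least 2")
    if (markingNoiseSd < 0) stop("markingNoiseSd must be non-negative")
    if (any(scaleRange <= 0)) stop("scaleRange bounds must be positive")
    k <- nrow(gt@baseShape)
    m <- ncol(gt@trueModes)
    base <- flattenXY(gt@baseShape)
    withSeed(seed, {
        scores <- matrix(stats::rnorm(nImages * m), nImages, m)
        theta <- stats::runif(nImages, rotationRange[1], rotationRange[2])
        scl <- stats::runif(nImages, scaleRange[1], scaleRange[2])
        tx <- stats::runif(nImages, translationRange[1], translationRange[2])
        ty <- stats::runif(nImages, translationRange[1], translationRange[2])
        configs <- vector("list", nImages)
        for (i in seq_len(nImages)) {
            v <- base
            if (m > 0L)
                v <- v + gt@trueModes %*% (scores[i, ] * gt@trueModeSds)
            p <- unflattenXY(v)
            p[, 1] <- p[, 1] * aspectRatioScale
            ctr <- colMeans(p)
            R <- rot2(theta[i])
            p <- sweep(sweep(p, 2, ctr) %*% t(R) * scl[i], 2,
                       ctr + c(tx[i], ty[i]), `+`)
            p <- p + matrix(stats::rnorm(2L * k, 0, markingNoiseSd), k, 2L)
            configs[[i]] <- p
        }
    })
    lm <- LandmarkSet(configs, imageIds = sprintf("sim%04d", seq_len(nImages)),
                      templateId = templateId(gt@template))
    colnames(scores) <- if (m > 0L) sprintf("mode%d", seq_len(m)) else NULL
    rownames(scores) <- imageIds(lm)
    list(landmarks = lm, trueScores = scores)
}

#' Simulate a second marking session
#'
#' Returns a copy of each configuration with fresh i.i.d. per-coordinate
#' normal noise of scale \code{noiseSd}, emulating a repeat manual
#' marking of the same images.
#'
#' @param x a \linkS4class{LandmarkSet}.
#' @param noiseSd pixels, >= 0.
#' @param seed integer seed.
#' @return a \linkS4class{LandmarkSet} with the same image ids.
#' @export
simulateRemarking <- function(x, noiseSd, seed = 1L) {
    stopifnot(is(x, "LandmarkSet"))
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    arr <- x@coords
    withSeed(seed, {
        arr <- arr + array(stats::rnorm(length(arr), 0, noiseSd), dim(arr))
    })
    new("LandmarkSet", coords = arr, imageIds = x@imageIds,
        templateId = x@templateId)
}

#' Simulate mode scores with a target correlation structure
#'
#' Rows are i.i.d. draws of a zero-mean vector whose population
#' correlation matrix is \code{R}, obtained by transforming independent
#' standard normals with the symmetric square root of \code{R}. The
#' sample correlation converges to \code{R} as \code{n} grows.
#'
#' @param R symmetric positive semi-definite matrix with unit diagonal.
#' @param n number of rows to draw (>= 2).
#' @param seed integer seed.
#' @return an n x M numeric matrix (column names taken from \code{R}).
#' @export
simulateCorrelatedScores <- function(R, n, seed = 1L) {
    R <- as.matrix(R)
    M <- nrow(R)
    if (ncol(R) != M || max(abs(R - t(R))) > 1e-8)
        stop("R must be a symmetric matrix")
    if (max(abs(diag(R) - 1)) > 1e-8)
        stop("R must have a unit diagonal")
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) < -1e-8)
        stop("R is not positive semi-definite: eigenvalue ",
             format(min(e$values)))
    sqrtR <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
    X <- withSeed(seed, matrix(stats::rnorm(n * M), n, M)) %*% sqrtR
    colnames(X) <- colnames(R)
    X
}

# ---- internal ---------------------------------------------------------

rot2 <- function(theta)
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)

# evaluate expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(eval.parent(substitute(expr)))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    eval.parent(substitute(expr))
}
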