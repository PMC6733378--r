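#' Pearson correlation matrix of a score table
#'
#' @param scores n x M numeric matrix, n >= 3 observations of M >= 2
#'   variables with nonzero variance.
#' @return a symmetric M x M correlation matrix with unit diagonal.
#' @export
scoreCorrelation <- function(scores) {
    scores <- as.matrix(scores)
    if (nrow(scores) < 3L || ncol(scores) < 2L)
        stop("need at least 3 observations of at least 2 variables")
    sds <- apply(scores, 2L, stats::sd)
    if (any(sds == 0)) {
        nm <- colnames(scores) %||% as.character(seq_along(sds))
        stop("constant column: ", nm[which(sds == 0)[1]])
    }
    R <- stats::cor(scores)
    (R + t(R)) / 2
}

checkCorrelationMatrix <- function(R) {
    R <- as.matrix(R)
    M <- nrow(R)
    if (ncol(R) != M || M < 2L) stop("R must be a square matrix (M >= 2)")
    if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("R must have a unit diagonal")
    R
}

#' Effective number of independent variables (Nyholt's Veff)
#'
#' Matrix spectral decomposition of a correlation matrix among M
#' correlated scores: the eigenvalues are extracted and the effective
#' number of independent variables is
#' \deqn{V_{eff} = 1 + (M - 1)\left(1 - \frac{Var(\lambda)}{M}\right),}
#' with the eigenvalue sample variance using divisor M - 1 (the matSpD
#' convention). The fractional loss of independence is
#' \eqn{(M - V_{eff})/M}. Values are kept at full precision; rounding to
#' one decimal happens only in the show method.
#'
#' @param R symmetric correlation matrix (unit diagonal), e.g. from
#'   \code{\link{scoreCorrelation}}.
#' @return an \linkS4class{EffectiveTestsResult}, which also carries the
#'   Li-Ji companion estimate (see \code{\link{lijiMeff}}).
#' @examples
#' f <- system.file("extdata", "hsm_cor_age14.csv", package = "hipSSM")
#' R <- as.matrix(read.csv(f, row.names = 1))
#' nyholtVeff(R)   # Veff 9.6, 4% loss of independence
#' @name effectiveTests
#' @export
nyholtVeff <- function(R) {
    R <- checkCorrelationMatrix(R)
    M <- nrow(R)
    lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    varLambda <- stats::var(lambda)
    v <- 1 + (M - 1) * (1 - varLambda / M)
    new("EffectiveTestsResult", M = M, eigenvalues = lambda,
        varLambda = varLambda, veffNyholt = v,
        meffLiJi = lijiMeff(R), lossFraction = (M - v) / M)
}

#' Effective number of independent tests (Li and Ji's Meff)
#'
#' The companion spectral estimator: each eigenvalue contributes its
#' integer part's indicator plus its fractional part,
#' \eqn{M_{eff} = \sum_i [ I(\lambda_i \ge 1) + (\lambda_i - \lfloor \lambda_i \rfloor) ]}.
#' Reported alongside Veff for sensitivity; the two can differ
#' appreciably on weakly correlated scores.
#'
#' @param R symmetric correlation matrix (unit diagonal).
#' @return a scalar.
#' @export
lijiMeff <- function(R) {
    R <- checkCorrelationMatrix(R)
    lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    lambda <- pmax(lambda, 0)
    sum((lambda >= 1) + (lambda - floor(lambda)))
}
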