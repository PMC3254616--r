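#' Drop genes with too many missing samples
#'
#' Removes every gene whose number of missing time points exceeds
#' \code{maxMissing} (default 3, the customary cutoff for an 18-sample
#' yeast time course). Survivor order is preserved.
#'
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @param maxMissing maximum tolerated number of missing samples per gene.
#' @return the filtered \linkS4class{ExpressionTimeSeries}.
#' @export
filterMissing <- function(x, maxMissing = 3) {
    if (maxMissing < 0) stop("maxMissing must be non-negative")
    keep <- rowSums(missingMask(x)) <= maxMissing
    if (!any(keep))
        stop("all genes removed: every gene has more than ", maxMissing,
             " missing samples")
    x[keep, ]
}

#' Impute missing values by iterative low-rank SVD completion
#'
#' Missing entries are initialized with the row mean of the observed values
#' and then refined by alternating a rank-\code{rank} truncated SVD with
#' overwriting the missing entries by the low-rank reconstruction, until the
#' relative Frobenius-norm change of the imputed entries drops below
#' \code{tol} or \code{maxIter} iterations are reached (non-convergence is
#' reported as a warning with the iteration count; the last iterate is still
#' returned). Observed entries are never modified.
#'
#' @param x an \linkS4class{ExpressionTimeSeries}; every row must retain at
#'   least one observed value.
#' @param rank rank of the SVD reconstruction (default 5, matching the
#'   eigengene rank typically used downstream).
#' @param tol relative-change convergence threshold.
#' @param maxIter iteration cap.
#' @return an \linkS4class{ExpressionTimeSeries} with no missing values;
#'   \code{metadata()} gains \code{imputeIterations} and
#'   \code{imputeConverged}.
#' @export
imputeMissingSVD <- function(x, rank = 5, tol = 1e-6, maxIter = 100) {
    if (rank < 1) stop("rank must be at least 1")
    X <- exprs(x)
    mask <- is.na(X)
    if (!any(mask)) return(x)
    allmiss <- rowSums(!mask) == 0
    if (any(allmiss))
        stop("gene(s) with all samples missing cannot be imputed: ",
             paste(utils::head(rownames(X)[allmiss], 3), collapse = ", "))
    if (rank > min(dim(X))) stop("rank exceeds matrix dimensions")

    rm <- rowMeans(X, na.rm = TRUE)
    X[mask] <- rm[row(X)[mask]]
    converged <- FALSE
    iter <- 0L
    while (iter < maxIter) {
        iter <- iter + 1L
        sv <- svd(X, nu = rank, nv = rank)
        recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
        newvals <- recon[mask]
        delta <- sqrt(sum((newvals - X[mask])^2))
        scale <- sqrt(sum(newvals^2))
        X[mask] <- newvals
        if (delta <= tol * max(scale, .Machine$double.eps)) {
            converged <- TRUE
            break
        }
    }
    if (!converged)
        warning("SVD imputation did not converge after ", iter,
                " iterations; returning last iterate")
    out <- ExpressionTimeSeries(X, times = timePoints(x))
    metadata(out)$imputeIterations <- iter
    metadata(out)$imputeConverged <- converged
    out
}

#' Scale each gene's time series to unit Euclidean norm
#'
#' After normalization every gene contributes equally to the SVD regardless
#' of its absolute expression level; amplitudes downstream are then
#' comparable across genes. Requires a complete matrix (impute first).
#'
#' @param x an \linkS4class{ExpressionTimeSeries} with no missing values.
#' @return the row-normalized \linkS4class{ExpressionTimeSeries}.
#' @export
normalizeRows <- function(x) {
    X <- exprs(x)
    if (anyNA(X))
        stop("missing values present; impute before normalizing")
    nrm <- sqrt(rowSums(X^2))
    zero <- nrm == 0
    if (any(zero))
        stop("zero expression row(s), norm undefined: ",
             paste(utils::head(rownames(X)[zero], 3), collapse = ", "))
    ExpressionTimeSeries(X / nrm, times = timePoints(x))
}

#' Filter, impute and normalize in the standard order
#'
#' Convenience composition \code{filterMissing} then
#' \code{\link{imputeMissingSVD}} (skipped when nothing is missing) then
#' optionally \code{\link{normalizeRows}}.
#'
#' @param x an \linkS4class{ExpressionTimeSeries}.
#' @param maxMissing see \code{\link{filterMissing}}.
#' @param imputeRank,imputeTol,imputeMaxIter see
#'   \code{\link{imputeMissingSVD}}.
#' @param normalize scale rows to unit norm (recommended for real
#'   measurements; simulated data are typically analyzed unnormalized).
#' @return the preprocessed \linkS4class{ExpressionTimeSeries}.
#' @export
preprocessExpression <- function(x, maxMissing = 3, imputeRank = 5,
                                 imputeTol = 1e-6, imputeMaxIter = 100,
                                 normalize = TRUE) {
    x <- filterMissing(x, maxMissing)
    if (any(missingMask(x)))
        x <- imputeMissingSVD(x, rank = imputeRank, tol = imputeTol,
                              maxIter = imputeMaxIter)
    if (normalize) x <- normalizeRows(x)
    x
}
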