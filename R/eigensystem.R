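#' Build the eigen-genomic system by truncated SVD
#'
#' Decomposes the complete expression matrix X (N genes x M time points) as
#' X = U D V' and keeps the first r right singular vectors as
#' \emph{eigengenes} (characteristic temporal profiles) with gene loadings
#' W = U D restricted to those components, so X ~ W V_r. With
#' \code{rank = "auto"} r is the smallest rank whose squared singular values
#' capture at least \code{varThreshold} of the total (default 0.98).
#'
#' Singular-vector orientation is intrinsically arbitrary; for
#' reproducibility each component is flipped so that the largest-magnitude
#' entry of its eigengene is positive. This affects only the coherent signs
#' of (W, V_r), never any downstream amplitude.
#'
#' @param x an \linkS4class{ExpressionTimeSeries} with no missing values.
#' @param rank \code{"auto"} or a fixed integer rank (at most min(N, M)).
#' @param varThreshold covariance fraction for automatic rank selection.
#' @return an \linkS4class{EigenSystem}.
#' @examples
#' sim <- simulateExpression(nGenes = 100, seed = 1)
#' es <- computeEigensystem(sim$expression, rank = 5)
#' covarianceCaptured(es)
#' @export
computeEigensystem <- function(x, rank = "auto", varThreshold = 0.98) {
    X <- exprs(x)
    if (anyNA(X))
        stop("missing values present; impute before computing the eigensystem")
    if (all(X == 0))
        stop("all-zero expression matrix has no eigensystem")
    if (!identical(rank, "auto")) {
        if (rank < 1 || rank > min(dim(X)))
            stop("rank must lie in [1, min(N, M)]")
    } else {
        if (varThreshold <= 0 || varThreshold > 1)
            stop("varThreshold must lie in (0, 1]")
    }
    sv <- svd(X)
    frac <- cumsum(sv$d^2) / sum(sv$d^2)
    r <- if (identical(rank, "auto"))
        which(frac >= varThreshold - 1e-12)[1] else as.integer(rank)
    # deterministic orientation: dominant eigengene entry positive
    for (i in seq_len(r)) {
        j <- which.max(abs(sv$v[, i]))
        if (sv$v[j, i] < 0) {
            sv$v[, i] <- -sv$v[, i]
            sv$u[, i] <- -sv$u[, i]
        }
    }
    V <- t(sv$v[, seq_len(r), drop = FALSE])
    W <- sv$u[, seq_len(r), drop = FALSE] %*%
        diag(sv$d[seq_len(r)], r, r)
    rownames(W) <- rownames(X)
    new("EigenSystem", singularValues = sv$d, eigengenes = V, loadings = W,
        rank = as.integer(r), covarianceCaptured = frac[r],
        times = timePoints(x), geneIds = rownames(X))
}

#' @describeIn computeEigensystem eigengene matrix V_r (r x M).
#' @param object an \linkS4class{EigenSystem}.
#' @export
setMethod("eigengenes", "EigenSystem", function(object) object@eigengenes)

#' Gene-loading matrix of an EigenSystem
#' @name loadings-EigenSystem
#' @param object an \linkS4class{EigenSystem}.
#' @return the N x r loading matrix W with X ~ W \%*\% eigengenes.
#' @export
setMethod("loadings", "EigenSystem", function(object) object@loadings)

#' Singular values of the decomposed expression matrix
#' @name singularValues
#' @param object an \linkS4class{EigenSystem}.
#' @return all singular values, non-increasing.
#' @export
setMethod("singularValues", "EigenSystem", function(object) object@singularValues)

#' Covariance fraction captured by the retained eigengenes
#' @name covarianceCaptured
#' @param object an \linkS4class{EigenSystem}.
#' @return sum of the first r squared singular values over the total.
#' @export
setMethod("covarianceCaptured", "EigenSystem", function(object) object@covarianceCaptured)

#' @export
setMethod("eigenRank", "EigenSystem", function(x) x@rank)

#' @export
setMethod("show", "EigenSystem", function(object) {
    cat(sprintf("EigenSystem: rank %d over %d genes x %d time points\n",
                object@rank, length(object@geneIds), length(object@times)))
    cat(sprintf("  covariance captured: %.4f\n", object@covarianceCaptured))
    cat("  singular values:",
        paste(signif(utils::head(object@singularValues, 6), 4), collapse = ", "),
        if (length(object@singularValues) > 6) "..." else "", "\n")
})

#' Relative reconstruction error of a truncated eigensystem
#'
#' Computes ||X - W V_r||_F^2 / ||X||_F^2, which by the SVD identity equals
#' 1 - \code{covarianceCaptured(es)} up to numerical round-off.
#'
#' @param es an \linkS4class{EigenSystem} computed from \code{x}.
#' @param x the matching \linkS4class{ExpressionTimeSeries}.
#' @return the relative squared Frobenius reconstruction error.
#' @export
reconstructionError <- function(es, x) {
    X <- exprs(x)
    if (!identical(dim(X), c(nrow(loadings(es)), ncol(eigengenes(es)))))
        stop("shape mismatch between eigensystem and expression matrix")
    R <- X - loadings(es) %*% eigengenes(es)
    sum(R^2) / sum(X^2)
}
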