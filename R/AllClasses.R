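#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.almost_equal <- function(a, b, tol = 1e-8) abs(a - b) <= tol * pmax(1, abs(a), abs(b))

#' ExpressionTimeSeries: gene-by-time expression matrix
#'
#' A \linkS4class{SummarizedExperiment} subclass holding a gene x time-point
#' expression matrix sampled on an equally spaced time grid (minutes).
#' Missing values are stored as \code{NA} in the single \code{"exprs"} assay;
#' row names are the gene identifiers and \code{colData(x)$time} carries the
#' sampling times. The equal-spacing requirement is structural: propagator
#' estimation maps each snapshot to the next, which is only meaningful on a
#' uniform grid.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso \code{\link{ExpressionTimeSeries}} (constructor),
#'   \code{\link{timePoints}}, \code{\link{missingMask}}
#' @exportClass ExpressionTimeSeries
setClass("ExpressionTimeSeries", contains = "SummarizedExperiment")

setValidity("ExpressionTimeSeries", function(object) {
    msg <- character()
    if (!"exprs" %in% assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    ids <- rownames(object)
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "all genes must have non-empty identifiers (rownames)")
    else if (anyDuplicated(ids))
        msg <- c(msg, "duplicate gene identifiers")
    tm <- object$time
    if (is.null(tm) || !is.numeric(tm))
        msg <- c(msg, "colData(x)$time must hold numeric time points")
    else if (length(tm) >= 2) {
        dt <- diff(tm)
        if (any(dt <= 0))
            msg <- c(msg, "time points must be strictly increasing")
        else if (any(!.almost_equal(dt, dt[1], tol = 1e-6)))
            msg <- c(msg, "time points must be equally spaced")
    }
    if (length(msg)) msg else TRUE
})

#' EigenSystem: SVD eigengenes and gene loadings
#'
#' Result of the singular value decomposition X = U D V' of an expression
#' matrix, truncated to the first r components. The rows of
#' \code{eigengenes(es)} (r x M) are the first r right singular vectors --
#' characteristic temporal profiles; \code{loadings(es)} (N x r) is
#' U D restricted to those components, so X is approximated by
#' \code{loadings \%*\% eigengenes}.
#'
#' @slot singularValues non-negative, non-increasing singular values (all of
#'   them, not only the first r).
#' @slot eigengenes r x M matrix, orthonormal rows.
#' @slot loadings N x r gene-loading matrix W.
#' @slot rank integer r.
#' @slot covarianceCaptured fraction of squared singular values captured by
#'   the first r components.
#' @slot times sampling times (minutes) inherited from the input.
#' @slot geneIds gene identifiers, in input row order.
#' @exportClass EigenSystem
setClass("EigenSystem",
    representation(singularValues = "numeric", eigengenes = "matrix",
                   loadings = "matrix", rank = "integer",
                   covarianceCaptured = "numeric", times = "numeric",
                   geneIds = "character"))

setValidity("EigenSystem", function(object) {
    msg <- character()
    d <- object@singularValues
    if (any(d < 0) || is.unsorted(rev(d)))
        msg <- c(msg, "singular values must be non-negative and non-increasing")
    r <- object@rank
    V <- object@eigengenes
    W <- object@loadings
    if (nrow(V) != r || ncol(W) != r)
        msg <- c(msg, "rank inconsistent with eigengene/loading dimensions")
    if (ncol(V) != length(object@times))
        msg <- c(msg, "eigengene columns must match time points")
    if (nrow(W) != length(object@geneIds))
        msg <- c(msg, "loading rows must match gene identifiers")
    G <- tcrossprod(V)
    if (nrow(V) > 0 && max(abs(G - diag(nrow(V)))) > 1e-6)
        msg <- c(msg, "eigengene rows must be orthonormal")
    cc <- object@covarianceCaptured
    if (length(cc) != 1 || cc < 0 || cc > 1 + 1e-12)
        msg <- c(msg, "covarianceCaptured must be a fraction in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Propagator: one-step linear map between eigengene snapshots
#'
#' The r x r matrix Phi advancing the eigengene state by one sampling
#' interval tau: V(t_{k+1}) ~ Phi V(t_k). Estimated by least squares over all
#' consecutive snapshot pairs.
#'
#' @slot Phi r x r real matrix.
#' @slot tau sampling interval (minutes).
#' @slot fitResidual Frobenius norm of the one-step prediction error.
#' @exportClass Propagator
setClass("Propagator",
    representation(Phi = "matrix", tau = "numeric", fitResidual = "numeric"))

setValidity("Propagator", function(object) {
    msg <- character()
    if (!all(is.finite(object@Phi)))
        msg <- c(msg, "Phi must have finite entries")
    if (length(object@tau) != 1 || object@tau <= 0)
        msg <- c(msg, "tau must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' SystemMatrix: continuous-time eigen-genomic system matrix
#'
#' The r x r matrix B of the state equation dV/dt = B V governing the top
#' eigengenes, obtained from the propagator either through the principal
#' matrix logarithm (exact for linear dynamics) or a first-order Euler
#' difference. The full N x N genomic system matrix W B W^+ is never
#' materialized.
#'
#' @slot B r x r real matrix (units 1/min).
#' @slot method \code{"matrix-log"} or \code{"euler"}.
#' @slot tau sampling interval used in the conversion.
#' @exportClass SystemMatrix
setClass("SystemMatrix",
    representation(B = "matrix", method = "character", tau = "numeric"))

setValidity("SystemMatrix", function(object) {
    msg <- character()
    if (!all(is.finite(object@B)))
        msg <- c(msg, "B must have finite entries")
    if (!object@method %in% c("matrix-log", "euler"))
        msg <- c(msg, "method must be 'matrix-log' or 'euler'")
    if (length(msg)) msg else TRUE
})

#' PopPair: one principal oscillation pattern pair
#'
#' A complex conjugate eigenvalue pair sigma + i omega (omega > 0) of the
#' system matrix together with the oscillation-pattern vectors derived from
#' its eigenvector e: p1 = Re(e), p2 = -Im(e) in eigengene space, and their
#' gene-space images W p1, W p2. The dynamics rotate through
#' p1 -> p2 -> -p1 -> -p2 with period 2 pi / omega.
#'
#' @slot eigenvalue complex sigma + i omega, omega > 0.
#' @slot period minutes, 2 pi / omega.
#' @slot p1,p2 r-vectors (eigengene space).
#' @slot geneP1,geneP2 N-vectors (gene space).
#' @slot rankIndex 1-based position after ordering pairs by explained
#'   variance.
#' @slot explainedVariance temporal variance of the pair's contribution to
#'   the eigengene trajectories.
#' @slot nyquistReliable FALSE when period <= 2 tau, i.e. the oscillation is
#'   at or beyond the Nyquist limit of the sampling grid.
#' @exportClass PopPair
setClass("PopPair",
    representation(eigenvalue = "complex", period = "numeric",
                   p1 = "numeric", p2 = "numeric",
                   geneP1 = "numeric", geneP2 = "numeric",
                   rankIndex = "integer", explainedVariance = "numeric",
                   nyquistReliable = "logical"))

setValidity("PopPair", function(object) {
    msg <- character()
    w <- Im(object@eigenvalue)
    if (w <= 0)
        msg <- c(msg, "the representative eigenvalue must have positive imaginary part")
    else if (!.almost_equal(object@period, 2 * pi / w, tol = 1e-9))
        msg <- c(msg, "period must equal 2*pi/Im(eigenvalue)")
    if (length(object@p1) != length(object@p2))
        msg <- c(msg, "p1 and p2 must have equal length")
    if (length(object@geneP1) != length(object@geneP2))
        msg <- c(msg, "geneP1 and geneP2 must have equal length")
    if (length(msg)) msg else TRUE
})

#' GenePopTable: per-gene oscillation amplitude and phase
#'
#' A \code{DataFrame} subclass with one row per gene and columns \code{gene},
#' \code{c1}, \code{c2} (coefficients on the orthonormalized pattern pair),
#' \code{amplitude} = sqrt(c1^2 + c2^2), \code{phase} in degrees [0, 360),
#' and \code{phaseDefined} (FALSE where amplitude is exactly zero, in which
#' case the phase is reported as 0 by convention). \code{metadata()} records
#' the oscillation period and the coefficient-extraction method.
#'
#' @exportClass GenePopTable
setClass("GenePopTable", contains = "DFrame")

setValidity("GenePopTable", function(object) {
    req <- c("gene", "c1", "c2", "amplitude", "phase", "phaseDefined")
    if (!all(req %in% colnames(object)))
        return(paste("required columns:", paste(req, collapse = ", ")))
    msg <- character()
    if (nrow(object)) {
        if (any(object$amplitude < 0))
            msg <- c(msg, "amplitudes must be non-negative")
        if (any(object$phase < 0 | object$phase >= 360))
            msg <- c(msg, "phases must lie in [0, 360)")
        th <- object$phase * pi / 180
        if (max(abs(object$amplitude * cos(th) - object$c1),
                abs(object$amplitude * sin(th) - object$c2)) > 1e-9 *
                max(1, max(object$amplitude)))
            msg <- c(msg, "polar and Cartesian coefficients disagree")
    }
    if (length(msg)) msg else TRUE
})

#' PopAnalysis: full result of a POP analysis run
#'
#' Container returned by \code{\link{runPopAnalysis}}: the eigensystem, the
#' estimated propagator and continuous-time system matrix, all extracted
#' oscillation pairs (ordered by explained variance), the real eigenvalues
#' (non-oscillatory decay modes, slowest first), and the per-gene
#' amplitude/phase table for the leading pair.
#'
#' @exportClass PopAnalysis
setClass("PopAnalysis",
    representation(eigenSystem = "EigenSystem", propagator = "Propagator",
                   systemMatrix = "SystemMatrix", pairs = "list",
                   decayModes = "numeric", geneTable = "GenePopTable"))

#' ThresholdReport: amplitude-threshold selection by survival-curve gap
#'
#' Survival curves P(amplitude > a) for all genes and for all genes excluding
#' a reference set, on a common amplitude grid, plus the smallest amplitude
#' at which the curves separate persistently (NA when they never do).
#'
#' @exportClass ThresholdReport
setClass("ThresholdReport",
    representation(grid = "numeric", survivalAll = "numeric",
                   survivalExcluded = "numeric", threshold = "numeric",
                   nAbove = "integer", minGap = "numeric"))

setValidity("ThresholdReport", function(object) {
    msg <- character()
    if (length(object@grid) != length(object@survivalAll) ||
        length(object@grid) != length(object@survivalExcluded))
        msg <- c(msg, "grid and survival curves must have equal length")
    for (s in list(object@survivalAll, object@survivalExcluded)) {
        if (any(s < -1e-12 | s > 1 + 1e-12))
            msg <- c(msg, "survival values must lie in [0, 1]")
        if (is.unsorted(rev(s), strictly = FALSE))
            msg <- c(msg, "survival curves must be non-increasing")
    }
    if (length(msg)) unique(msg) else TRUE
})
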