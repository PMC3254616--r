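#' Estimate the one-step propagator of the eigengene dynamics
#'
#' Fits the linear map Phi advancing the eigengene state by one sampling
#' interval, by ordinary least squares over all consecutive snapshot pairs:
#' Phi = argmin sum_k || V(t_{k+1}) - Phi V(t_k) ||^2, solved through the
#' Moore-Penrose pseudo-inverse of the past-snapshot matrix. For data
#' generated by a linear system V(t_{k+1}) = exp(B tau) V(t_k) with at least
#' r independent snapshots this recovers exp(B tau) exactly.
#'
#' @param object an \linkS4class{EigenSystem}, or a numeric r x M matrix of
#'   state snapshots (columns = consecutive, equally spaced time points).
#' @param tau sampling interval in minutes (taken from the eigensystem when
#'   one is supplied).
#' @param ... unused.
#' @return a \linkS4class{Propagator}.
#' @examples
#' th <- pi / 6
#' R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
#' V <- matrix(0, 2, 10); V[, 1] <- c(1, 0)
#' for (k in 2:10) V[, k] <- R %*% V[, k - 1]
#' estimatePropagator(V, tau = 7)
#' @rdname estimatePropagator
#' @export
setMethod("estimatePropagator", "matrix", function(object, tau, ...) {
    V <- object
    r <- nrow(V)
    M <- ncol(V)
    if (M < r + 1)
        warning("fewer snapshots (", M, ") than states + 1 (", r + 1,
                "); propagator under-determined")
    past <- V[, -M, drop = FALSE]
    future <- V[, -1, drop = FALSE]
    sv <- svd(past)
    if (min(sv$d) < 1e-10 * max(sv$d))
        warning("rank-deficient snapshot matrix; using minimum-norm solution")
    Phi <- future %*% pracma::pinv(past)
    res <- sqrt(sum((future - Phi %*% past)^2))
    new("Propagator", Phi = Phi, tau = as.numeric(tau), fitResidual = res)
})

#' @rdname estimatePropagator
#' @export
setMethod("estimatePropagator", "EigenSystem", function(object, ...) {
    tm <- object@times
    estimatePropagator(eigengenes(object), tau = diff(tm)[1])
})

#' @export
setMethod("show", "Propagator", function(object) {
    cat(sprintf("Propagator: %d x %d, tau = %g min, fit residual %.3g\n",
                nrow(object@Phi), ncol(object@Phi), object@tau,
                object@fitResidual))
})

#' Convert the propagator to the continuous-time system matrix
#'
#' Recovers B from Phi ~ exp(B tau). \code{"matrix-log"} (default) takes the
#' principal matrix logarithm B = logm(Phi)/tau, exact for linear dynamics;
#' it requires that no eigenvalue of Phi lies on the closed negative real
#' axis (where the principal branch is undefined). \code{"euler"} uses the
#' first-order difference B = (Phi - I)/tau, always defined but biased for
#' large tau. The two give identical oscillation periods whenever periods
#' are computed from arg(eigenvalue)/tau through the logarithm.
#'
#' @param p a \linkS4class{Propagator}.
#' @param method \code{"matrix-log"} or \code{"euler"}.
#' @return a \linkS4class{SystemMatrix}.
#' @export
propagatorToSystem <- function(p, method = c("matrix-log", "euler")) {
    method <- match.arg(method)
    Phi <- p@Phi
    tau <- p@tau
    if (method == "euler") {
        B <- (Phi - diag(nrow(Phi))) / tau
    } else {
        mu <- eigen(Phi, only.values = TRUE)$values
        onbranch <- Re(mu) <= 0 & abs(Im(mu)) <= 1e-12 * pmax(1, abs(mu))
        if (any(onbranch))
            stop("propagator has an eigenvalue on the closed negative real ",
                 "axis; the principal matrix logarithm is undefined. ",
                 "Use method = 'euler'.")
        L <- pracma::logm(Phi)
        if (is.complex(L)) {
            if (max(abs(Im(L))) > 1e-8 * max(1, abs(Re(L))))
                stop("matrix logarithm is not real; use method = 'euler'")
            L <- Re(L)
        }
        B <- L / tau
    }
    new("SystemMatrix", B = B, method = method, tau = tau)
}

#' System matrix of a \linkS4class{SystemMatrix}
#' @param x a \linkS4class{SystemMatrix}.
#' @return the r x r matrix B.
#' @export
systemMatrix <- function(x) x@B

#' @export
setMethod("show", "SystemMatrix", function(object) {
    ev <- eigen(object@B, only.values = TRUE)$values
    cat(sprintf("SystemMatrix (%s): %d x %d, tau = %g min\n", object@method,
                nrow(object@B), ncol(object@B), object@tau))
    cat("  eigenvalues:", paste(format(signif(ev, 4)), collapse = ", "), "\n")
})

.complex_tol <- function(lambda) 1e-9 * max(1, max(abs(lambda)))

#' Extract principal oscillation patterns from the system matrix
#'
#' Eigendecomposes the real matrix B. Complex eigenvalues come in conjugate
#' pairs sigma +/- i omega; each pair (represented by omega > 0) is an
#' oscillatory mode with period 2 pi / omega whose eigenvector e yields the
#' oscillation patterns p1 = Re(e), p2 = -Im(e): the state rotates through
#' p1 -> p2 -> -p1 -> -p2 over one period. Real eigenvalues are
#' non-oscillatory decay modes and are reported separately. Gene-space
#' patterns are the loadings images W p1, W p2.
#'
#' The eigenvector gauge (an arbitrary complex scalar) is fixed by scaling e
#' to unit norm and rotating its phase so that the mode's coefficient at the
#' first snapshot is real and non-negative; amplitudes downstream are
#' invariant to this choice, phases are defined up to the global rotation it
#' pins down.
#'
#' Pairs are ordered by the temporal variance of their contribution to the
#' reconstructed gene-expression trajectories (descending; ties broken by
#' larger omega), so a mode that moves a lot of expression ranks above one
#' that merely stirs low-energy eigengenes. A pair
#' whose period does not exceed twice the sampling interval is flagged
#' unreliable (\code{nyquistReliable = FALSE}): its frequency is at or
#' beyond the Nyquist limit of the grid.
#'
#' @param b a \linkS4class{SystemMatrix}.
#' @param es the \linkS4class{EigenSystem} the system was estimated from.
#' @param which \code{"all"} (default), \code{"leading"}, or a pair index.
#' @return list with elements \code{pairs} (list of \linkS4class{PopPair},
#'   possibly empty) and \code{decayModes} (real eigenvalues, slowest decay
#'   first).
#' @export
extractPops <- function(b, es, which = "all") {
    B <- b@B
    eg <- eigen(B)
    lambda <- eg$values
    E <- eg$vectors
    tol <- .complex_tol(lambda)
    iscplx <- abs(Im(lambda)) > tol
    decay <- sort(Re(lambda[!iscplx]), decreasing = TRUE)

    V <- eigengenes(es)
    W <- loadings(es)
    Z <- tryCatch(solve(E, V), error = function(e)
        stop("defective system matrix: eigenvector basis is singular"))
    tau <- diff(es@times)[1]

    idx <- which(Im(lambda) > tol)
    pairs <- lapply(idx, function(j) {
        e0 <- E[, j]
        z0 <- Z[j, ]
        alpha <- 1 / sqrt(sum(Mod(e0)^2))
        if (Mod(z0[1]) > 0)
            alpha <- alpha * exp(1i * Arg(z0[1]))
        e <- e0 * alpha
        z <- z0 / alpha
        # explained variance of the pair's gene-space contribution
        # 2*Re((W e) z(t)): summed temporal variance over genes, computed
        # without materializing the N x M contribution matrix
        g <- W %*% e
        zc <- z - mean(z)
        a <- Re(g); bb <- Im(g); u <- Re(zc); v <- Im(zc)
        ev <- 4 * (sum(a^2) * sum(u^2) + sum(bb^2) * sum(v^2) -
                   2 * sum(a * bb) * sum(u * v)) / (length(z) - 1)
        omega <- Im(lambda[j])
        new("PopPair", eigenvalue = lambda[j], period = 2 * pi / omega,
            p1 = Re(e), p2 = -Im(e),
            geneP1 = as.numeric(W %*% Re(e)),
            geneP2 = as.numeric(W %*% -Im(e)),
            rankIndex = NA_integer_, explainedVariance = ev,
            nyquistReliable = (2 * pi / omega) > 2 * tau)
    })
    if (length(pairs)) {
        ord <- order(-vapply(pairs, function(p) p@explainedVariance, 0),
                     -vapply(pairs, function(p) Im(p@eigenvalue), 0))
        pairs <- pairs[ord]
        for (i in seq_along(pairs)) pairs[[i]]@rankIndex <- i
    }
    if (identical(which, "leading"))
        pairs <- pairs[seq_len(min(1, length(pairs)))]
    else if (is.numeric(which))
        pairs <- pairs[which]
    list(pairs = pairs, decayModes = decay)
}

#' Oscillation period of a POP pair
#' @param pair a \linkS4class{PopPair}.
#' @return period in minutes.
#' @export
popPeriod <- function(pair) pair@period

#' @export
setMethod("show", "PopPair", function(object) {
    cat(sprintf("PopPair #%s: eigenvalue %.4g %+.4gi, period %.2f min%s\n",
                ifelse(is.na(object@rankIndex), "?", object@rankIndex),
                Re(object@eigenvalue), Im(object@eigenvalue), object@period,
                if (!object@nyquistReliable) " [beyond Nyquist limit]" else ""))
})

#' Per-gene oscillation amplitude and phase from a POP pair
#'
#' Expresses every gene's loading vector on the oscillation plane spanned by
#' the pattern pair and converts the coefficient pair (c1, c2) to polar
#' coordinates: amplitude r = sqrt(c1^2 + c2^2), phase
#' theta = atan2(c2, c1) in degrees mapped to [0, 360). The amplitude
#' measures how strongly the gene oscillates at the pair's frequency; the
#' phase marks where in the cycle the gene peaks.
#'
#' Because p1 and p2 need not be orthogonal, the default
#' (\code{method = "orthogonal"}) projects onto a Gram-Schmidt
#' orthonormalization of the pair (p1 first); amplitudes are then invariant
#' to the eigenvector gauge. \code{method = "oblique"} instead solves for
#' the raw coordinates in the (p1, p2) basis by least squares.
#'
#' @param pair a \linkS4class{PopPair}.
#' @param es the matching \linkS4class{EigenSystem}.
#' @param method \code{"orthogonal"} (default) or \code{"oblique"}.
#' @return a \linkS4class{GenePopTable}; genes with exactly zero amplitude
#'   carry \code{phaseDefined = FALSE} and phase 0 by convention.
#' @export
amplitudePhase <- function(pair, es, method = c("orthogonal", "oblique")) {
    method <- match.arg(method)
    W <- loadings(es)
    p1 <- pair@p1
    p2 <- pair@p2
    if (method == "orthogonal") {
        n1 <- sqrt(sum(p1^2))
        if (n1 == 0) stop("degenerate pattern: p1 is zero")
        q1 <- p1 / n1
        u2 <- p2 - sum(q1 * p2) * q1
        n2 <- sqrt(sum(u2^2))
        if (n2 < 1e-12 * max(1, sqrt(sum(p2^2))))
            stop("degenerate pattern pair: p1 and p2 are collinear")
        q2 <- u2 / n2
        c1 <- as.numeric(W %*% q1)
        c2 <- as.numeric(W %*% q2)
    } else {
        cf <- W %*% t(pracma::pinv(cbind(p1, p2)))
        c1 <- cf[, 1]
        c2 <- cf[, 2]
    }
    amp <- sqrt(c1^2 + c2^2)
    theta <- atan2(c2, c1) * 180 / pi
    theta <- theta %% 360
    defined <- amp > 0
    theta[!defined] <- 0
    tab <- DataFrame(gene = es@geneIds, c1 = c1, c2 = c2, amplitude = amp,
                     phase = theta, phaseDefined = defined)
    out <- new("GenePopTable", tab)
    metadata(out) <- list(period = pair@period,
                          eigenvalue = pair@eigenvalue, method = method)
    out
}

#' @export
setMethod("show", "GenePopTable", function(object) {
    cat(sprintf("GenePopTable: %d genes, oscillation period %.2f min (%s projection)\n",
                nrow(object),
                if (is.null(metadata(object)$period)) NA else metadata(object)$period,
                if (is.null(metadata(object)$method)) "?" else metadata(object)$method))
    callNextMethod()
})

.emptyGenePopTable <- function() {
    new("GenePopTable",
        DataFrame(gene = character(), c1 = numeric(), c2 = numeric(),
                  amplitude = numeric(), phase = numeric(),
                  phaseDefined = logical()))
}

#' Run the full principal-oscillation-pattern analysis
#'
#' Composes the pipeline: truncated SVD eigensystem, least-squares
#' propagator, continuous-time system matrix, POP extraction, and the
#' per-gene amplitude/phase table for the leading oscillation pair. When the
#' system spectrum is entirely real (no oscillatory mode), the pair list is
#' empty and the gene table has zero rows.
#'
#' @param x a preprocessed \linkS4class{ExpressionTimeSeries} (complete
#'   matrix; normalize rows beforehand for real measurements).
#' @param rank,varThreshold see \code{\link{computeEigensystem}}.
#' @param discretization see \code{\link{propagatorToSystem}}.
#' @param coefMethod see \code{\link{amplitudePhase}}.
#' @return a \linkS4class{PopAnalysis}.
#' @examples
#' sim <- simulateExpression(nGenes = 200, seed = 1)
#' res <- runPopAnalysis(sim$expression, rank = 5)
#' res
#' @export
runPopAnalysis <- function(x, rank = "auto", varThreshold = 0.98,
                           discretization = c("matrix-log", "euler"),
                           coefMethod = c("orthogonal", "oblique")) {
    discretization <- match.arg(discretization)
    coefMethod <- match.arg(coefMethod)
    es <- computeEigensystem(x, rank = rank, varThreshold = varThreshold)
    prop <- estimatePropagator(es)
    b <- propagatorToSystem(prop, method = discretization)
    pops <- extractPops(b, es)
    tab <- if (length(pops$pairs))
        amplitudePhase(pops$pairs[[1]], es, method = coefMethod)
    else .emptyGenePopTable()
    new("PopAnalysis", eigenSystem = es, propagator = prop, systemMatrix = b,
        pairs = pops$pairs, decayModes = pops$decayModes, geneTable = tab)
}

#' POP pairs of an analysis, ordered by explained variance
#' @param x a \linkS4class{PopAnalysis}.
#' @return list of \linkS4class{PopPair}.
#' @export
popPairs <- function(x) x@pairs

#' Non-oscillatory decay modes (real eigenvalues), slowest decay first
#' @param x a \linkS4class{PopAnalysis}.
#' @return numeric vector of real eigenvalues of the system matrix.
#' @export
decayModes <- function(x) x@decayModes

#' Per-gene amplitude/phase table of the leading oscillation pair
#' @param x a \linkS4class{PopAnalysis}.
#' @return a \linkS4class{GenePopTable}.
#' @export
geneTable <- function(x) x@geneTable

#' Eigensystem underlying an analysis
#' @param x a \linkS4class{PopAnalysis}.
#' @return the \linkS4class{EigenSystem}.
#' @export
eigenSystem <- function(x) x@eigenSystem

#' Period of the leading oscillation pair
#' @param x a \linkS4class{PopAnalysis}.
#' @return period in minutes, or NA when no oscillatory mode exists.
#' @export
leadingPeriod <- function(x) {
    if (!length(x@pairs)) return(NA_real_)
    x@pairs[[1]]@period
}

#' @export
setMethod("show", "PopAnalysis", function(object) {
    es <- object@eigenSystem
    cat(sprintf("PopAnalysis: %d genes, rank %d (%.1f%% covariance), %s discretization\n",
                length(es@geneIds), es@rank, 100 * es@covarianceCaptured,
                object@systemMatrix@method))
    if (length(object@pairs)) {
        cat(sprintf("  %d oscillation pair(s); leading period %.2f min\n",
                    length(object@pairs), leadingPeriod(object)))
    } else {
        cat("  no oscillatory mode (all eigenvalues real)\n")
    }
    cat(sprintf("  %d decay mode(s): %s\n", length(object@decayModes),
                paste(signif(object@decayModes, 3), collapse = ", ")))
})
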