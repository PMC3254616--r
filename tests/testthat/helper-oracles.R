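# Independent oracles and small fixture builders used across the suite.

# Fine-step RK4 integration of dx/dt = P(t) - lambda * x; reference for the
# simulator's closed-form trajectories.
rk4Trajectory <- function(prodFun, lambda, x0, times, stepsPerUnit = 200) {
    x <- x0
    out <- numeric(length(times))
    out[1] <- x0
    for (k in seq_len(length(times) - 1)) {
        t0 <- times[k]
        t1 <- times[k + 1]
        nstep <- ceiling((t1 - t0) * stepsPerUnit)
        h <- (t1 - t0) / nstep
        tt <- t0
        f <- function(t, x) prodFun(t) - lambda * x
        for (s in seq_len(nstep)) {
            k1 <- f(tt, x)
            k2 <- f(tt + h / 2, x + h / 2 * k1)
            k3 <- f(tt + h / 2, x + h / 2 * k2)
            k4 <- f(tt + h, x + h * k3)
            x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
            tt <- tt + h
        }
        out[k + 1] <- x
    }
    out
}

# closed-form steady-state response of the production-degradation ODE to
# sinusoidal forcing b*(1 + A*cos(omega*t + phi))
steadyStateSinusoid <- function(times, lambda, A, phi, omega, b = 1) {
    b / lambda + b * A / sqrt(lambda^2 + omega^2) *
        cos(omega * times + phi - atan2(omega, lambda))
}

# planar rotation matrix
rotationMatrix <- function(theta) {
    matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
}

# random orthonormal-row matrix (r x M), deterministic in the RNG state
orthonormalRows <- function(r, M) {
    t(qr.Q(qr(matrix(stats::rnorm(M * r), M, r))))
}

# EigenSystem with prescribed eigengenes/loadings, bypassing the SVD; rows
# of V must be orthonormal
makeEigenSystem <- function(V, W, times) {
    new("EigenSystem",
        singularValues = rev(sort(sqrt(colSums(W^2)))),
        eigengenes = V, loadings = W, rank = nrow(V),
        covarianceCaptured = 1.0, times = times,
        geneIds = if (is.null(rownames(W)))
            sprintf("g%03d", seq_len(nrow(W))) else rownames(W))
}

writeToyTsv <- function(lines, path = tempfile(fileext = ".tsv")) {
    writeLines(lines, path)
    path
}
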