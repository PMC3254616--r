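test_that("a constant eigengene gives the identity propagator", {
    V <- matrix(1, 1, 10)
    p <- estimatePropagator(V, tau = 7)
    expect_equal(p@Phi, matrix(1, 1, 1), tolerance = 1e-12)
    expect_lt(p@fitResidual, 1e-12)
})

test_that("least squares recovers a planar rotation propagator exactly", {
    R <- rotationMatrix(pi / 6)
    V <- matrix(0, 2, 12)
    V[, 1] <- c(1, 0.2)
    for (k in 2:12) V[, k] <- R %*% V[, k - 1]
    p <- estimatePropagator(V, tau = 7)
    expect_equal(p@Phi, R, tolerance = 1e-10)

    # rotation-log closed form: B = [[0, -w], [w, 0]], w = (pi/6)/7
    b <- propagatorToSystem(p, method = "matrix-log")
    w <- (pi / 6) / 7
    expect_equal(systemMatrix(b), matrix(c(0, w, -w, 0), 2), tolerance = 1e-9)
    ev <- eigen(systemMatrix(b), only.values = TRUE)$values
    expect_equal(sort(Im(ev)), c(-w, w), tolerance = 1e-10)
})

test_that("identity propagator maps to the zero system matrix under both methods", {
    p <- new("Propagator", Phi = diag(3), tau = 7, fitResidual = 0)
    for (m in c("matrix-log", "euler"))
        expect_equal(systemMatrix(propagatorToSystem(p, m)), matrix(0, 3, 3),
                     tolerance = 1e-12)
})

test_that("matrix-log refuses eigenvalues on the negative real axis", {
    p <- new("Propagator", Phi = diag(c(1, -0.5)), tau = 7, fitResidual = 0)
    expect_error(propagatorToSystem(p, "matrix-log"), "euler")
    expect_silent(propagatorToSystem(p, "euler"))
})

test_that("an all-real spectrum yields decay modes and no POP pairs", {
    set.seed(5)
    V <- orthonormalRows(2, 10)
    W <- matrix(rnorm(12 * 2), 12, 2)
    es <- makeEigenSystem(V, W, times = seq(0, 63, 7))
    b <- new("SystemMatrix", B = diag(c(-1, -2)), method = "matrix-log",
             tau = 7)
    pops <- extractPops(b, es)
    expect_length(pops$pairs, 0)
    expect_equal(pops$decayModes, c(-1, -2))   # slow first
})

test_that("a pure rotation block yields one orthogonal, equal-norm pattern pair", {
    omega <- 2 * pi / 30
    set.seed(6)
    V <- orthonormalRows(2, 10)
    W <- matrix(rnorm(20 * 2), 20, 2)
    es <- makeEigenSystem(V, W, times = seq(0, 63, 7))
    b <- new("SystemMatrix", B = matrix(c(0, omega, -omega, 0), 2),
             method = "matrix-log", tau = 7)
    pops <- extractPops(b, es)
    expect_length(pops$pairs, 1)
    pair <- pops$pairs[[1]]
    expect_equal(pair@period, 30, tolerance = 1e-10)
    # analytic eigenvectors (1, -+i)/sqrt(2): orthogonal, equal norms
    expect_lt(abs(sum(pair@p1 * pair@p2)), 1e-10)
    expect_equal(sum(pair@p1^2), sum(pair@p2^2), tolerance = 1e-10)
    expect_equal(sum(pair@p1^2) + sum(pair@p2^2), 1, tolerance = 1e-10)
    expect_equal(pair@geneP1, as.numeric(W %*% pair@p1), tolerance = 1e-12)
    expect_true(pair@nyquistReliable)
})

test_that("periods at or beyond the Nyquist limit are flagged unreliable", {
    omega <- 2 * pi / 10                   # 10-min period, tau = 7
    set.seed(7)
    es <- makeEigenSystem(orthonormalRows(2, 10),
                          matrix(rnorm(10 * 2), 10, 2), seq(0, 63, 7))
    b <- new("SystemMatrix", B = matrix(c(0, omega, -omega, 0), 2),
             method = "matrix-log", tau = 7)
    pair <- extractPops(b, es)$pairs[[1]]
    expect_false(pair@nyquistReliable)
})

test_that("complex eigenvalues always come in closed conjugate pairs", {
    set.seed(8)
    for (i in 1:10) {
        r <- sample(2:5, 1)
        B <- matrix(rnorm(r * r, sd = 0.1), r)
        es <- makeEigenSystem(orthonormalRows(r, 12),
                              matrix(rnorm(15 * r), 15, r), seq(0, 77, 7))
        pops <- extractPops(new("SystemMatrix", B = B, method = "euler",
                                tau = 7), es)
        ev <- eigen(B, only.values = TRUE)$values
        nComplex <- sum(abs(Im(ev)) > 1e-9 * max(1, abs(ev)))
        expect_identical(length(pops$pairs) * 2L + length(pops$decayModes),
                         as.integer(r))
        expect_identical(length(pops$pairs), as.integer(nComplex / 2))
    }
})

test_that("amplitude and phase follow the polar convention on axis cases", {
    # loadings aligned with the first then the second pattern
    V <- diag(2)
    omega <- 2 * pi / 30
    # eigenvector (1, -i)/sqrt(2) of the rotation generator gives
    # p1 = e1/sqrt(2), p2 = e2/sqrt(2)
    es <- makeEigenSystem(orthonormalRows2 <- diag(2),
                          W <- rbind(c(1, 0), c(0, 1), c(0, 0)),
                          times = c(0, 7))
    b <- new("SystemMatrix", B = matrix(c(0, omega, -omega, 0), 2),
             method = "matrix-log", tau = 7)
    pair <- extractPops(b, es)$pairs[[1]]
    # force the canonical gauge for the axis check
    pair@p1 <- c(1, 0) / sqrt(2)
    pair@p2 <- c(0, 1) / sqrt(2)
    tab <- amplitudePhase(pair, es)
    expect_equal(tab$amplitude, c(1, 1, 0), tolerance = 1e-12)
    expect_equal(tab$phase, c(0, 90, 0), tolerance = 1e-9)
    expect_identical(tab$phaseDefined, c(TRUE, TRUE, FALSE))
    # envelope identity r*cos(theta) = c1, r*sin(theta) = c2
    expect_equal(tab$amplitude * cos(tab$phase * pi / 180), tab$c1,
                 tolerance = 1e-9)
    expect_equal(tab$amplitude * sin(tab$phase * pi / 180), tab$c2,
                 tolerance = 1e-9)
})

test_that("identity loadings make gene-space POPs equal eigen-space POPs", {
    omega <- 2 * pi / 40
    es <- makeEigenSystem(diag(2), diag(2), times = c(0, 7))
    b <- new("SystemMatrix", B = matrix(c(-0.01, omega, -omega, -0.01), 2),
             method = "matrix-log", tau = 7)
    pair <- extractPops(b, es)$pairs[[1]]
    expect_equal(pair@geneP1, pair@p1, tolerance = 1e-12)
    expect_equal(pair@geneP2, pair@p2, tolerance = 1e-12)
})

test_that("full pipeline recovers a planted linear system exactly", {
    # planted continuous-time system: rotation block (25-min period, slow
    # damping) plus one decay mode
    omega <- 2 * pi / 25
    B <- matrix(0, 3, 3)
    B[1:2, 1:2] <- matrix(c(-0.005, omega, -omega, -0.005), 2)
    B[3, 3] <- -0.04
    tau <- 7
    M <- 18
    Phi <- pracma::expm(B * tau)
    V <- matrix(0, 3, M)
    V[, 1] <- c(1, 0.3, 0.8)
    for (k in 2:M) V[, k] <- Phi %*% V[, k - 1]

    # propagator oracle on the raw snapshots
    p <- estimatePropagator(V, tau = tau)
    expect_lt(sqrt(sum((p@Phi - Phi)^2)), 1e-8)

    # full pipeline on gene-space data X = W V
    set.seed(9)
    W <- matrix(rnorm(60 * 3), 60, 3)
    x <- ExpressionTimeSeries(W %*% V, times = seq(0, by = tau, length.out = M),
                              geneIds = sprintf("g%02d", 1:60))
    res <- runPopAnalysis(x, rank = 3)
    expect_length(popPairs(res), 1)
    expect_equal(leadingPeriod(res), 25, tolerance = 1e-6)
    expect_equal(sort(decayModes(res)), -0.04, tolerance = 1e-6)
    ev <- eigen(systemMatrix(res@systemMatrix), only.values = TRUE)$values
    expect_equal(sort(Re(ev)), sort(Re(eigen(B)$values)), tolerance = 1e-6)
})

test_that("gauge rotation leaves amplitudes unchanged and shifts phases uniformly", {
    sim <- simulateExpression(nGenes = 80, seed = 17)
    res <- runPopAnalysis(sim$expression, rank = 5)
    pair <- popPairs(res)[[1]]
    es <- eigenSystem(res)
    tab <- geneTable(res)

    alpha <- 0.7
    rot <- pair
    rot@p1 <- pair@p1 * cos(alpha) + pair@p2 * sin(alpha)
    rot@p2 <- -pair@p1 * sin(alpha) + pair@p2 * cos(alpha)
    rot@geneP1 <- as.numeric(loadings(es) %*% rot@p1)
    rot@geneP2 <- as.numeric(loadings(es) %*% rot@p2)
    tabRot <- amplitudePhase(rot, es)

    expect_equal(tabRot$amplitude, tab$amplitude, tolerance = 1e-9)
    dphi <- (tabRot$phase - tab$phase) %% 360
    keep <- tab$amplitude > 1e-6
    expect_lt(max(dphi[keep]) - min(dphi[keep]), 1e-6)
})

test_that("orthogonal and oblique coefficient extraction agree for orthogonal pairs", {
    omega <- 2 * pi / 30
    set.seed(11)
    es <- makeEigenSystem(orthonormalRows(2, 10),
                          matrix(rnorm(30 * 2), 30, 2), seq(0, 63, 7))
    b <- new("SystemMatrix", B = matrix(c(0, omega, -omega, 0), 2),
             method = "matrix-log", tau = 7)
    pair <- extractPops(b, es)$pairs[[1]]
    orth <- amplitudePhase(pair, es, method = "orthogonal")
    obl <- amplitudePhase(pair, es, method = "oblique")
    # p1 and p2 are orthogonal with equal norms here, so the two
    # parameterizations differ only by the common scale factor ||p1||
    scale <- sqrt(sum(pair@p1^2))
    expect_equal(obl$amplitude * scale, orth$amplitude, tolerance = 1e-9)
    expect_equal(obl$phase, orth$phase, tolerance = 1e-6)
})
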