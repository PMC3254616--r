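# popgex

Principal oscillation pattern (POP) analysis for genome-wide
gene-expression time series.

## What it does

Synchronized cell populations (e.g. budding yeast released from
alpha-factor arrest) express cell-cycle genes periodically. Given a gene
× time expression matrix on an equally spaced grid, popgex

1. builds the **eigen-genomic system**: SVD eigengenes V_r (characteristic
   temporal profiles) with gene loadings W, X ≈ W V_r, keeping the rank
   that captures ≥ 98% of the covariance (r = 5 for the classic 18-sample
   yeast course);
2. models the eigengene state by the linear state equation dv/dt = B v,
   estimating the one-step propagator Φ ≈ exp(Bτ) by least squares over
   consecutive snapshots and recovering B = logm(Φ)/τ;
3. extracts **principal oscillation patterns** from each complex conjugate
   eigenvalue pair σ ± iω of B: the eigenvector e = p1 − i p2 spans a plane
   on which the state rotates p1 → p2 → −p1 → −p2 with period 2π/ω, while
   real eigenvalues are non-oscillatory decay modes;
4. assigns every gene polar coordinates on the leading pattern plane —
   **POP amplitude** r_n = √(c1² + c2²) and **POP phase**
   θ_n = atan2(c2, c1) ∈ [0°, 360°) — measuring oscillation strength and
   peak timing;
5. supports calling periodic genes: Welch/F/permutation tests of a
   reference set's amplitudes, survival-curve threshold selection, circular
   phase medians per annotated cluster, and recovery scoring against
   simulation ground truth.

An ODE-based simulator of periodic transcription with lognormal mRNA decay
(`simulateExpression`) provides ground-truthed data, so the complete
pipeline is testable with no download. SVD-based missing-value imputation
and row normalization cover real-measurement preprocessing.

## Worked example

```r
library(popgex)

sim <- simulateExpression(nGenes = 1000, seed = 1)   # 1000 genes, 18 samples,
res <- runPopAnalysis(sim$expression, rank = 5)      # 30-min forcing period
res
#> PopAnalysis: 1000 genes, rank 5 (100.0% covariance), matrix-log discretization
#>   2 oscillation pair(s); leading period 30.01 min
#>   1 decay mode(s): -9.79e-07

head(as.data.frame(geneTable(res)), 3)
#>       gene         c1         c2 amplitude    phase phaseDefined
#> 1 gene0001 -0.1631826 -0.2410942 0.2911270 235.9082         TRUE
#> 2 gene0002 -0.5190029 -0.2275280 0.5666860 203.6724         TRUE
#> 3 gene0003  0.3966191 -0.7782917 0.8735243 297.0035         TRUE

unlist(evaluateRecovery(geneTable(res), sim$truth))
#>        amplitudePearson     phaseSinePearsonRaw phaseSinePearsonAligned
#>               0.9885038              -0.1981808               0.9477180
#>               offsetDeg                  nGenes
#>             101.6243444            1000.0000000
```

Reading this: the estimated system has one dominant oscillatory mode with a
30.01-minute period (the simulator's true period is 30); each gene's
amplitude/phase sit in `geneTable(res)`. Recovered amplitudes correlate
with the generator's true amplitudes at 0.989. The raw phase-sine
correlation is low only because phases are defined up to a global rotation
(eigenvector gauge plus the common kinetic lag atan2(ω, λ) of the
production–degradation response); after a single global offset (≈ 102°
here) the sine correlation is 0.948.

For real measurements, preprocess first:

```r
x <- readExpression("alpha_factor.tsv")      # gene<TAB>t0<TAB>t7...
x <- preprocessExpression(x, maxMissing = 3, imputeRank = 5, normalize = TRUE)
res <- runPopAnalysis(x, rank = 5)
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `preprocess`, `analyze`, `evaluate`, `threshold`, `report`;
every run writes a reproducibility manifest) is installed at:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","popgex.R",package="popgex"))')" \
    simulate --n-genes 4000 --seed 1 --out expr.tsv --truth truth.tsv
```

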