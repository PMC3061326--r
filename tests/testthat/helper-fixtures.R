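## Shared fixtures, built in code. The full benchmark geometry (dense grid
## plus 204-gradiometer lead field) is expensive, so it is built lazily once
## per test session and cached.

.fixtureEnv <- new.env(parent = emptyenv())

## Small desk geometry for unit tests: 48-channel helmet, coarse grid.
smallGeometry <- function() {
    if (!is.null(.fixtureEnv$small)) return(.fixtureEnv$small)
    cond <- SphereConductor(c(0, 0, 0), 8)
    helm <- fibonacciHelmet(nLocations = 16, helmetRadius = 10,
        conductor = cond)
    grid <- buildSourceGrid(cond, spacing = 2, shellFraction = 0.8)
    grid <- neighborMatrix(grid, radius = 2)
    lf <- assembleLeadField(grid, helm)
    .fixtureEnv$small <- list(cond = cond, helm = helm, grid = grid, lf = lf)
    .fixtureEnv$small
}

## Full benchmark geometry: the study conditions of the six-source
## simulation (204 planar gradiometers, 0.5 cm volumetric grid, 1 cm
## neighbor radius).
benchGeometry <- function() {
    if (!is.null(.fixtureEnv$bench)) return(.fixtureEnv$bench)
    cond <- SphereConductor()
    helm <- fibonacciHelmet(conductor = cond)
    grads <- selectChannels(helm, channelKinds(helm) == "GRAD")
    grid <- buildSourceGrid(cond, spacing = 0.5, shellFraction = 0.85)
    grid <- neighborMatrix(grid, radius = 1)
    lf <- assembleLeadField(grid, grads)
    .fixtureEnv$bench <- list(cond = cond, helm = helm, grads = grads,
        grid = grid, lf = lf)
    .fixtureEnv$bench
}

## One full benchmark filtering run at the study conditions.
runBenchmark <- function(seed, discrepancy = 1, nParticles = 10000,
                         sigma = 3) {
    geo <- benchGeometry()
    sim <- simulateBenchmark(benchmarkSources(), geo$helm, sigma = sigma,
        seed = seed)
    noise <- estimateNoiseFromPrestim(sim$measurements,
        discrepancy = discrepancy)
    cfg <- FilterConfig(nParticles = nParticles, discrepancy = discrepancy,
        seed = seed)
    res <- runFilter(sim$measurements, geo$lf, geo$grid, noise, cfg)
    list(result = res, sim = sim, geo = geo)
}

## Tiny three-point source space with mutual visibility, for the exhaustive
## filter comparison.
tinySpace <- function() {
    if (!is.null(.fixtureEnv$tiny)) return(.fixtureEnv$tiny)
    cond <- SphereConductor(c(0, 0, 0), 8)
    helm <- fibonacciHelmet(nLocations = 10, helmetRadius = 10,
        conductor = cond)
    pts <- rbind(c(-3, 0, 3), c(3, 0, 3), c(0, 3, -2))
    space <- new("SourceSpace", points = pts, orientations = NULL,
        spacing = NA_real_, neighbors = list())
    space <- neighborMatrix(space, radius = 20)  # fully connected
    lf <- assembleLeadField(space, helm)
    .fixtureEnv$tiny <- list(cond = cond, helm = helm, space = space, lf = lf)
    .fixtureEnv$tiny
}

## Memoized benchmark runs shared across acceptance blocks (the discrepancy
## sweep reuses the discrepancy-1 runs).
acceptRun <- function(seed, discrepancy, nParticles = 10000) {
    key <- sprintf("run_%d_%g_%d", seed, discrepancy, nParticles)
    if (is.null(.fixtureEnv[[key]]))
        .fixtureEnv[[key]] <- runBenchmark(seed, discrepancy, nParticles)
    .fixtureEnv[[key]]
}
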