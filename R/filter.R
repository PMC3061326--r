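## R-level surface of the random-finite-set particle filter. The hot loop
## lives in src/filter.cpp; these wrappers expose each algorithmic step for
## scripting and testing and assemble the full filtering pass.

#' Particle-filter configuration constructor
#'
#' @param nParticles number of particles N_p. Larger values buy stability at
#'   linearly increasing cost.
#' @param maxDipoles upper bound on simultaneously active dipoles.
#' @param discrepancy multiplier on the noise estimate; below 1 demands a
#'   tighter data fit (more, less stable sources), above 1 a looser fit
#'   (fewer, more stable sources).
#' @param pBirth,pDeath,pMove dipole birth probability (per particle per
#'   sample), death probability (per dipole), jump probability (per dipole).
#'   The default `pBirth < pDeath` encodes a parsimony prior: the stationary
#'   dipole-count distribution of the birth/death chain decays like
#'   `(pBirth/pDeath)^k / k!`, so the empty model is the resting state and a
#'   dipole survives only while the data keep paying for it.
#' @param momentPriorStd std (nA*m) of the Gaussian moment prior in the
#'   ridge fit.
#' @param resampleESS effective-sample-size fraction triggering resampling;
#'   the default 1 resamples at every sample.
#' @param seed integer RNG seed.
#' @return A [FilterConfig-class].
#' @examples
#' FilterConfig(nParticles = 2000, discrepancy = 0.7, seed = 7)
#' @export
FilterConfig <- function(nParticles = 10000, maxDipoles = 5, discrepancy = 1,
                         pBirth = 1 / 30, pDeath = 1 / 10, pMove = 1 / 2,
                         momentPriorStd = 10, resampleESS = 1, seed = 1) {
    new("FilterConfig", nParticles = as.integer(nParticles),
        maxDipoles = as.integer(maxDipoles), discrepancy = discrepancy,
        pBirth = pBirth, pDeath = pDeath, pMove = pMove,
        momentPriorStd = momentPriorStd, resampleESS = resampleESS,
        seed = as.integer(seed))
}

#' Noise model constructor
#'
#' @param sigma per-channel noise std (fT/cm) for the white model.
#' @param covariance optional channels x channels covariance matrix; when
#'   supplied the mode is "covariance".
#' @param discrepancy unitless multiplier on the noise estimate.
#' @return A [NoiseModel-class].
#' @export
NoiseModel <- function(sigma = 1, covariance = NULL, discrepancy = 1) {
    if (is.null(covariance))
        new("NoiseModel", mode = "white", sigma = sigma,
            covariance = matrix(0, 0, 0), discrepancy = discrepancy)
    else
        new("NoiseModel", mode = "covariance",
            sigma = sqrt(mean(diag(covariance))), covariance = covariance,
            discrepancy = discrepancy)
}

.restoreRNG <- function() {
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    function() if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
}

#' Draw the initial particle set
#'
#' Dipole counts are uniform on `{0, ..., maxDipoles}`, locations uniform
#' without replacement over the grid, weights uniform. Deterministic given
#' the configuration seed.
#'
#' @param config a [FilterConfig-class].
#' @param sourceSpace a [SourceSpace-class].
#' @return A [ParticleSet-class] at time index 0.
#' @export
initializeParticles <- function(config, sourceSpace) {
    n <- nrow(sourceSpace@points)
    if (config@maxDipoles > n)
        stop("configuration error: maxDipoles exceeds the source-space size")
    on.exit(.restoreRNG()())
    set.seed(config@seed)
    parts <- cpp_initialize_particles(config@nParticles, config@maxDipoles, n)
    new("ParticleSet", particles = parts,
        weights = rep(1 / config@nParticles, config@nParticles),
        timeIndex = 0L)
}

#' Ridge least-squares moment fit for a dipole configuration
#'
#' Fits the moments of dipoles at the given grid locations to one data
#' column under a zero-mean Gaussian moment prior (ridge regularization
#' `lambda = (sigma / priorStd)^2`), and returns the residual. The
#' regularization keeps the system solvable even for nearby grid columns.
#'
#' @param locations integer vector of distinct grid indices (may be empty).
#' @param dataColumn numeric vector, one sample of sensor data.
#' @param leadField a [LeadField-class].
#' @param noise a [NoiseModel-class] (its sigma sets the ridge scale).
#' @param priorStd moment prior std (nA*m).
#' @return list with `moments` (dofPerPoint x k matrix, nA*m), `residual`
#'   (data minus predicted field) and `rss` (residual sum of squares).
#' @export
fitMoments <- function(locations, dataColumn, leadField, noise,
                       priorStd = 10) {
    if (anyDuplicated(locations)) stop("'locations' must be distinct")
    lambda <- (noise@sigma / priorStd)^2
    fit <- cpp_fit_moments(leadField@matrix, dataColumn,
        as.integer(locations), leadField@dofPerPoint, lambda)
    pred <- 0
    if (length(locations)) {
        d <- leadField@dofPerPoint
        cols <- as.vector(vapply(as.integer(locations),
            function(i) (d * (i - 1) + 1):(d * i), integer(d)))
        pred <- leadField@matrix[, cols, drop = FALSE] %*% as.vector(fit$moments)
    }
    list(moments = fit$moments, residual = as.numeric(dataColumn - pred),
        rss = fit$rss)
}

#' Unnormalized likelihood weight of a particle
#'
#' Gaussian likelihood of the ridge-fit residual, with the residual energy
#' measured against the expected total noise energy of the measurement
#' vector: `exp(-||r||^2 / (2 n_ch sigma_eff^2))` with `sigma_eff =
#' discrepancy * sigma`. A particle whose predicted field matches the data
#' exactly has weight 1; the empty particle's residual is the data column
#' itself. Increasing the discrepancy increases every weight with nonzero
#' residual (a looser fit is demanded).
#'
#' @param particle integer vector of grid indices (possibly empty).
#' @param dataColumn numeric vector, one data sample.
#' @param leadField a [LeadField-class].
#' @param noise a [NoiseModel-class]; `sigma * discrepancy` must be positive.
#' @param priorStd moment prior std (nA*m).
#' @return unnormalized weight in (0, 1].
#' @export
likelihoodWeight <- function(particle, dataColumn, leadField, noise,
                             priorStd = 10) {
    sEff <- noise@discrepancy * noise@sigma
    if (sEff <= 0) stop("effective noise level is zero")
    fit <- fitMoments(particle, dataColumn, leadField, noise, priorStd)
    exp(-fit$rss / (2 * length(dataColumn) * sEff^2))
}

#' Systematic resampling of a particle set
#'
#' Discards low-weight particles and multiplies high-weight ones while
#' preserving the particle count: the expected copy count of particle i is
#' `nParticles * w_i`, uniform weights map to the identity multiset, and the
#' output weights are uniform. Deterministic given the RNG state.
#'
#' @param particleSet a [ParticleSet-class] with normalized weights.
#' @return A resampled [ParticleSet-class] with uniform weights.
#' @export
resampleParticles <- function(particleSet) {
    idx <- cpp_systematic_resample(particleSet@weights)
    n <- length(idx)
    new("ParticleSet", particles = particleSet@particles[idx],
        weights = rep(1 / n, n), timeIndex = particleSet@timeIndex)
}

#' Random evolution of the dipole configurations
#'
#' Independently per particle: every dipole dies with probability `pDeath`;
#' every survivor jumps with probability `pMove` to a uniformly chosen entry
#' of its neighbor list (jumps onto an occupied point are rejected); with
#' probability `pBirth`, and if the particle is not full, a new dipole is
#' born at a uniform grid point (rejected if occupied). Weights are
#' unchanged.
#'
#' @param particleSet a [ParticleSet-class].
#' @param sourceSpace a [SourceSpace-class] with neighbor lists computed.
#' @param config a [FilterConfig-class].
#' @return The evolved [ParticleSet-class].
#' @export
evolveParticles <- function(particleSet, sourceSpace, config) {
    if (!length(sourceSpace@neighbors))
        stop("neighbor lists not computed; run neighborMatrix() first")
    parts <- cpp_evolve(particleSet@particles, sourceSpace@neighbors,
        nrow(sourceSpace@points), config@pBirth, config@pDeath,
        config@pMove, config@maxDipoles)
    new("ParticleSet", particles = parts, weights = particleSet@weights,
        timeIndex = particleSet@timeIndex)
}

#' Run the random-finite-set particle filter
#'
#' Sequential pass over the measurement samples. At each sample the filter
#' (1) weights every dipole configuration by the Gaussian likelihood of its
#' ridge-fit residual, (2) summarizes the weighted cloud into the
#' model-order posterior, its mode and conditional dipole estimates,
#' (3) resamples systematically, and (4) lets the configurations evolve
#' randomly with dipole birth, death and grid jumps. In covariance mode data
#' and lead field are prewhitened once up front; an optional signal-space
#' projection is applied to both before filtering.
#'
#' @param measurements a [Measurements-class].
#' @param leadField a [LeadField-class]; rows must match the measurement
#'   channels, columns the source space.
#' @param sourceSpace a [SourceSpace-class] with neighbor lists.
#' @param noise a [NoiseModel-class] (typically from
#'   [estimateNoiseFromPrestim()]). Its discrepancy slot is overridden by
#'   the configuration's.
#' @param config a [FilterConfig-class].
#' @param projection optional idempotent signal-space projection matrix.
#' @param snapshotAt integer sample indices at which to keep the full
#'   weighted particle set (attached as attribute "snapshots").
#' @param verbose logical, emit per-50-sample progress.
#' @return A [FilterResult-class].
#' @examples
#' ## a tiny end-to-end run on a coarse grid
#' cond <- SphereConductor(c(0, 0, 0), 8)
#' helm <- fibonacciHelmet(20, 10, conductor = cond)
#' grid <- neighborMatrix(buildSourceGrid(cond, 2, 0.8), 2)
#' lf <- assembleLeadField(grid, helm)
#' sim <- simulateBenchmark(benchmarkSources()[3, ], helm, sigma = 3,
#'     seed = 2, times = seq(-20, 80, by = 2), sfreq = 500, prestim = c(-20, 0))
#' fit <- runFilter(sim$measurements, lf, grid,
#'     NoiseModel(sigma = 3), FilterConfig(nParticles = 200, seed = 2))
#' @export
runFilter <- function(measurements, leadField, sourceSpace, noise, config,
                      projection = NULL, snapshotAt = integer(0),
                      verbose = FALSE) {
    G <- leadField@matrix
    Y <- measurements@data
    if (nrow(G) != nrow(Y))
        stop(sprintf("dimension mismatch: lead field has %d rows, data %d channels",
            nrow(G), nrow(Y)))
    n <- nrow(sourceSpace@points)
    if (ncol(G) != leadField@dofPerPoint * n)
        stop(sprintf("dimension mismatch: lead field has %d columns, source space needs %d",
            ncol(G), leadField@dofPerPoint * n))
    if (anyNA(Y)) stop("NaN/NA in measurement data")
    if (!length(sourceSpace@neighbors))
        stop("neighbor lists not computed; run neighborMatrix() first")
    if (!is.null(projection)) {
        if (max(abs(projection %*% projection - projection)) > 1e-6)
            stop("projection matrix is not idempotent")
        G <- projection %*% G
        Y <- projection %*% Y
    }
    if (noise@mode == "covariance") {
        W <- whiteningOperator(noise)
        G <- W %*% G
        Y <- W %*% Y
        sigma <- 1
    } else {
        sigma <- noise@sigma
        if (sigma <= 0) stop("white noise model with zero sigma")
    }
    lambda <- (sigma / config@momentPriorStd)^2
    noiseScale2 <- nrow(Y) * (config@discrepancy * sigma)^2

    on.exit(.restoreRNG()())
    set.seed(config@seed)
    raw <- cpp_run_filter(G, Y, sourceSpace@neighbors,
        leadField@dofPerPoint, config@nParticles, config@maxDipoles,
        config@pBirth, config@pDeath, config@pMove, lambda, noiseScale2,
        config@resampleESS, NULL, as.integer(snapshotAt), verbose)

    dip <- .assembleDipoleTable(raw, measurements@times, sourceSpace)
    res <- new("FilterResult", times = measurements@times,
        orderPosterior = raw$orderPosterior, nHat = as.integer(raw$nHat),
        dipoles = dip, config = config)
    if (length(snapshotAt)) attr(res, "snapshots") <- raw$snapshots
    res
}

## Turn the per-sample pooled tables of the C++ pass into the estimated
## dipole table via weighted k-means grouping (see conditionalDipoleEstimates).
.assembleDipoleTable <- function(raw, times, sourceSpace) {
    rows <- vector("list", length(times))
    for (t in seq_along(times)) {
        k <- raw$nHat[t]
        if (k == 0L) next
        est <- .groupPooledDipoles(raw$pooled[[t]], k, sourceSpace)
        est$sample <- t
        est$time <- times[t]
        rows[[t]] <- est
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(sample = integer(0), time = numeric(0),
            gridIndex = integer(0), x = numeric(0), y = numeric(0),
            z = numeric(0), mx = numeric(0), my = numeric(0), mz = numeric(0),
            qx = numeric(0), qy = numeric(0), qz = numeric(0),
            amplitude = numeric(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("sample", "time", "gridIndex", "x", "y", "z", "mx", "my", "mz",
        "qx", "qy", "qz", "amplitude")]
}
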