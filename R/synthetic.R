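## Six-source synthetic evoked-field benchmark: calibrated Gaussian-bump
## activations, white sensor noise, the Frobenius SNR statistic and
## prestimulus noise estimation.

#' The six-source benchmark configuration
#'
#' Source parameters of the synthetic evoked-field benchmark: locations (cm,
#' head frame), peak latencies (ms), peak planar-gradiometer amplitudes
#' (fT/cm) and activation durations (full width at half maximum, ms).
#' Sources 1 and 6 share a location (the same patch active twice); sources 2
#' and 3 peak together but differ in duration; sources 4 and 5 carry exactly
#' the same waveform (time-correlated pair).
#'
#' @return A data.frame with columns `x`, `y`, `z`, `latency`, `peakAmp`,
#'   `fwhm`, `label`.
#' @examples
#' benchmarkSources()
#' @export
benchmarkSources <- function() {
    data.frame(
        x = c(-1.37, 3.74, -2.04, 2.96, -3.43, -1.37),
        y = c(-5.43, 4.54, 3.73, 2.11, -2.71, -5.43),
        z = c(7.34, 5.66, 9.56, 9.42, 4.07, 7.34),
        latency = c(20, 40, 40, 110, 110, 220),
        peakAmp = c(51, 57, 130, 100, 110, 51),
        fwhm = c(30, 20, 50, 30, 30, 30),
        label = c("red", "blue", "green", "magenta", "cyan", "yellow"),
        stringsAsFactors = FALSE)
}

#' Unit-peak Gaussian activation waveform
#'
#' Gaussian bump with the requested full width at half maximum, renormalized
#' so its maximum is exactly 1 at the sample nearest the peak latency.
#'
#' @param peakLatency numeric, peak time (ms).
#' @param fwhm numeric, full width at half maximum (ms), positive.
#' @param times numeric vector of sample times (ms).
#' @return numeric vector of amplitudes in `[0, 1]`, same length as `times`.
#' @examples
#' w <- sourceWaveform(110, 30, seq(-100, 300))
#' max(w)
#' @export
sourceWaveform <- function(peakLatency, fwhm, times) {
    if (fwhm <= 0) stop("'fwhm' must be positive")
    g <- exp(-4 * log(2) * (times - peakLatency)^2 / fwhm^2)
    g / g[which.min(abs(times - peakLatency))]
}

#' Simulate the calibrated multi-source benchmark
#'
#' Generates an averaged evoked MEG data set from point sources at exact
#' (off-grid) locations inside the conductor. Each source receives a fixed
#' tangential moment direction (drawn once from the seed) and a moment
#' magnitude calibrated so that, with all other sources silenced, its
#' maximum absolute planar-gradiometer reading at its peak latency equals
#' `peakAmp`. White Gaussian noise of standard deviation `sigma` is added to
#' every channel and sample.
#'
#' @param sources data.frame as returned by [benchmarkSources()].
#' @param sensors a [SensorArray-class].
#' @param sigma numeric, noise std (fT/cm).
#' @param seed integer seed; the simulation is bit-reproducible given
#'   (sources, sensors, sigma, seed).
#' @param times numeric vector of sample times (ms).
#' @param sfreq numeric, sampling frequency (Hz).
#' @param prestim numeric(2), prestimulus interval (ms).
#' @param gradiometersOnly logical; keep only the planar-gradiometer
#'   channels (the benchmark convention).
#' @return list with `measurements` (a [Measurements-class]) and `truth`, a
#'   list holding the source table, moment directions and magnitudes
#'   (nA*m), waveforms, per-source channel patterns, the noiseless data
#'   matrix `signal` and the realized noise matrix `noise`.
#' @examples
#' helm <- fibonacciHelmet(nLocations = 12)
#' sim <- simulateBenchmark(benchmarkSources(), helm, sigma = 3, seed = 1,
#'     times = seq(-20, 60, by = 5), sfreq = 200)
#' @export
simulateBenchmark <- function(sources, sensors, sigma = 3, seed = 1,
                              times = seq(-100, 300), sfreq = 1000,
                              prestim = c(-100, 0), gradiometersOnly = TRUE) {
    cond <- sensors@conductor
    locs <- as.matrix(sources[, c("x", "y", "z")])
    depth <- sqrt(rowSums(sweep(locs, 2, cond@center)^2))
    if (any(depth >= cond@radius))
        stop("invalid geometry: source outside the conductor sphere")
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
    }
    nS <- nrow(sources)
    grad <- sensors@kinds == "GRAD"
    ## fixed tangential directions, one angle per source, from the seed;
    ## co-located sources model the same neural patch active twice and
    ## share one direction
    angles <- stats::runif(nS, 0, 2 * pi)
    firstAt <- match(interaction(locs[, 1], locs[, 2], locs[, 3]),
        interaction(locs[, 1], locs[, 2], locs[, 3]))
    angles <- angles[firstAt]
    dirs <- matrix(0, nS, 3L)
    patterns <- matrix(0, nrow(sensors@positions), nS)
    q <- numeric(nS)
    for (i in seq_len(nS)) {
        rhat <- (locs[i, ] - cond@center) / depth[i]
        ref <- if (abs(rhat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        u <- ref - sum(ref * rhat) * rhat
        u <- u / sqrt(sum(u^2))
        v <- c(rhat[2] * u[3] - rhat[3] * u[2],
               rhat[3] * u[1] - rhat[1] * u[3],
               rhat[1] * u[2] - rhat[2] * u[1])
        dirs[i, ] <- cos(angles[i]) * u + sin(angles[i]) * v
        g <- .dipoleChannelResponses(locs[i, ], dirs[i, ], sensors)
        q[i] <- sources$peakAmp[i] / max(abs(g[grad]))
        patterns[, i] <- q[i] * g
    }
    waveforms <- t(vapply(seq_len(nS), function(i)
        sourceWaveform(sources$latency[i], sources$fwhm[i], times),
        numeric(length(times))))
    signal <- patterns %*% waveforms
    keep <- if (gradiometersOnly) grad else rep(TRUE, nrow(signal))
    signal <- signal[keep, , drop = FALSE]
    noise <- matrix(stats::rnorm(sum(keep) * length(times), sd = sigma),
        sum(keep), length(times))
    meas <- new("Measurements", data = signal + noise, times = times,
        sfreq = sfreq, prestim = prestim, kinds = sensors@kinds[keep])
    list(measurements = meas,
         truth = list(sources = sources, directions = dirs, magnitudes = q,
             waveforms = waveforms, patterns = patterns[keep, , drop = FALSE],
             signal = signal, noise = noise, channelMask = which(keep)))
}

#' Frobenius signal-to-noise ratio in dB
#'
#' `10 log10(||D||_F^2 / ||N||_F^2)` for a signal matrix `D` and a noise
#' matrix `N` of the same shape. An all-zero noise matrix yields `Inf` (the
#' documented infinite-SNR sentinel).
#'
#' @param signal,noise numeric matrices of identical dimensions.
#' @return numeric, the SNR in dB.
#' @examples
#' snrDb(diag(2), diag(2))  # 0 dB
#' @export
snrDb <- function(signal, noise) {
    if (!all(dim(signal) == dim(noise)))
        stop("'signal' and 'noise' must have the same shape")
    n2 <- sum(noise^2)
    if (n2 == 0) return(Inf)
    10 * log10(sum(signal^2) / n2)
}

#' Estimate the noise model from the prestimulus interval
#'
#' White mode pools the per-channel variance over the prestimulus samples
#' (channel means removed) and averages across channels into a single
#' standard deviation. Covariance mode returns the empirical channel
#' covariance over the prestimulus samples, later used to prewhiten data and
#' lead field.
#'
#' @param measurements a [Measurements-class]; the prestimulus window
#'   (samples with `prestim[1] <= t < prestim[2]`) must hold at least 2
#'   samples.
#' @param mode "white" or "covariance".
#' @param discrepancy numeric multiplier stored in the returned model.
#' @return A [NoiseModel-class]. A flat-zero prestimulus yields sigma 0 with
#'   a warning (degenerate model).
#' @export
estimateNoiseFromPrestim <- function(measurements, mode = c("white", "covariance"),
                                     discrepancy = 1) {
    mode <- match.arg(mode)
    t <- measurements@times
    sel <- t >= measurements@prestim[1] - 1e-9 & t < measurements@prestim[2] - 1e-9
    if (sum(sel) < 2L)
        stop("prestimulus interval too short: need at least 2 samples")
    X <- measurements@data[, sel, drop = FALSE]
    if (mode == "white") {
        v <- apply(X, 1, stats::var)
        sigma <- sqrt(mean(v))
        if (sigma == 0)
            warning("degenerate noise estimate: prestimulus data are constant")
        new("NoiseModel", mode = "white", sigma = sigma,
            covariance = matrix(0, 0, 0), discrepancy = discrepancy)
    } else {
        cv <- stats::cov(t(X))
        new("NoiseModel", mode = "covariance", sigma = sqrt(mean(diag(cv))),
            covariance = cv, discrepancy = discrepancy)
    }
}

#' Prewhitening operator of a noise model
#'
#' Inverse symmetric square root of the channel covariance; applying it to
#' data and lead field turns the noise into unit-variance white noise. For a
#' white model this is `1/sigma` times the identity.
#'
#' @param noise a [NoiseModel-class].
#' @param nChannels integer, number of channels (needed in white mode).
#' @return numeric matrix, channels x channels.
#' @export
whiteningOperator <- function(noise, nChannels = nrow(noise@covariance)) {
    if (noise@mode == "white") {
        if (noise@sigma <= 0) stop("white noise model with zero sigma")
        return(diag(1 / noise@sigma, nChannels))
    }
    e <- eigen(noise@covariance, symmetric = TRUE)
    if (min(e$values) <= 0) stop("covariance is not positive definite")
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
}
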