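## S4 classes for the dipole-tracking pipeline.
##
## Conventions used throughout the package:
##   positions        cm, head frame
##   dipole moments   nA*m
##   gradiometer data fT/cm, magnetometer data fT
##   times            ms

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Single-sphere conductor model
#'
#' Geometry of the spherically symmetric volume conductor used by the
#' closed-form forward model: the center of the sphere in head coordinates
#' and its radius. All candidate sources must lie inside the sphere and all
#' sensors strictly outside it.
#'
#' @slot center numeric(3), sphere center in head coordinates (cm).
#' @slot radius numeric(1), conductor radius (cm).
#'
#' @seealso [SphereConductor()], [dipoleFieldSphere()]
#' @export
setClass("SphereConductor",
    representation(center = "numeric", radius = "numeric"))

setValidity("SphereConductor", function(object) {
    if (length(object@center) != 3L || !all(is.finite(object@center)))
        return("'center' must be a finite 3-vector")
    if (length(object@radius) != 1L || !is.finite(object@radius) ||
        object@radius <= 0)
        return("'radius' must be a single positive number")
    TRUE
})

#' Discretized source space
#'
#' A finite set of candidate dipole locations (a regular volumetric grid in
#' practice), optional fixed unit orientations (one per point, for the
#' orientation-constrained mode), the nominal grid spacing, and per-point
#' neighbor lists (all points within a user-selected radius, self included)
#' along which dipoles are allowed to jump between consecutive samples.
#'
#' @slot points numeric matrix, n x 3, candidate locations (cm).
#' @slot orientations numeric matrix n x 3 of unit vectors, or `NULL` when the
#'   source space is unconstrained.
#' @slot spacing numeric(1), nominal grid spacing (cm).
#' @slot neighbors list of integer vectors; `neighbors[[i]]` holds the indices
#'   of all points within the neighbor radius of point `i` (including `i`).
#'   Empty list until [neighborMatrix()] has been applied.
#'
#' @seealso [buildSourceGrid()], [neighborMatrix()]
#' @export
setClass("SourceSpace",
    representation(points = "matrix", orientations = "matrixOrNULL",
        spacing = "numeric", neighbors = "list"))

setValidity("SourceSpace", function(object) {
    p <- object@points
    if (ncol(p) != 3L || nrow(p) < 1L) return("'points' must be an n x 3 matrix")
    if (!is.null(object@orientations)) {
        o <- object@orientations
        if (!all(dim(o) == dim(p)))
            return("'orientations' must match the dimensions of 'points'")
        nrm <- sqrt(rowSums(o^2))
        if (any(abs(nrm - 1) > 1e-9))
            return("orientation vectors must have unit norm (tol 1e-9)")
    }
    if (length(object@neighbors)) {
        if (length(object@neighbors) != nrow(p))
            return("'neighbors' must have one entry per point")
        for (i in seq_along(object@neighbors))
            if (!(i %in% object@neighbors[[i]]))
                return("every point must appear in its own neighbor list")
    }
    TRUE
})

#' MEG sensor array
#'
#' Channel geometry: one row per channel. Magnetometer channels ("MAG")
#' measure the radial field component at their position; planar gradiometer
#' channels ("GRAD") measure a symmetric finite difference of the radial
#' component along their tangential axis, divided by the baseline.
#'
#' @slot positions numeric matrix n x 3, channel positions (cm), all strictly
#'   outside the conductor sphere.
#' @slot kinds character vector, "MAG" or "GRAD" per channel.
#' @slot axes numeric matrix n x 3; for gradiometers, the tangential unit
#'   vector of differentiation (rows for magnetometers are zero).
#' @slot baseline numeric(1), finite-difference arm length (cm).
#' @slot conductor the [SphereConductor-class] the array is placed around.
#'
#' @seealso [fibonacciHelmet()], [gradiometerSignal()]
#' @export
setClass("SensorArray",
    representation(positions = "matrix", kinds = "character",
        axes = "matrix", baseline = "numeric", conductor = "SphereConductor"))

setValidity("SensorArray", function(object) {
    n <- nrow(object@positions)
    if (ncol(object@positions) != 3L) return("'positions' must be n x 3")
    if (length(object@kinds) != n || !all(object@kinds %in% c("MAG", "GRAD")))
        return("'kinds' must be 'MAG'/'GRAD', one per channel")
    if (!all(dim(object@axes) == c(n, 3L))) return("'axes' must be n x 3")
    cen <- object@conductor@center
    d <- sqrt(rowSums(sweep(object@positions, 2, cen)^2))
    if (any(d <= object@conductor@radius))
        return("all channel positions must lie strictly outside the conductor")
    grad <- object@kinds == "GRAD"
    if (any(grad)) {
        ax <- object@axes[grad, , drop = FALSE]
        nrm <- sqrt(rowSums(ax^2))
        if (any(abs(nrm - 1) > 1e-6))
            return("gradiometer axes must be unit vectors (tol 1e-6)")
        rad <- sweep(object@positions[grad, , drop = FALSE], 2, cen)
        rad <- rad / sqrt(rowSums(rad^2))
        if (any(abs(rowSums(ax * rad)) > 1e-6))
            return("gradiometer axes must be orthogonal to the radial direction")
    }
    if (length(object@baseline) != 1L || object@baseline <= 0)
        return("'baseline' must be a single positive length (cm)")
    TRUE
})

#' Lead field
#'
#' Linear map from dipole moments at the source-space points to sensor
#' readings. In free-orientation mode each point contributes three columns
#' (unit moments along x, y, z); in orientation-constrained mode one column
#' (unit moment along the fixed orientation). Gradiometer rows are in fT/cm
#' per nA*m, magnetometer rows in fT per nA*m.
#'
#' @slot matrix numeric matrix, channels x (dofPerPoint * nPoints).
#' @slot dofPerPoint integer, 3 (free) or 1 (constrained).
#' @slot kinds character vector, channel kind per row ("MAG"/"GRAD").
#'
#' @seealso [assembleLeadField()]
#' @export
setClass("LeadField",
    representation(matrix = "matrix", dofPerPoint = "integer",
        kinds = "character"))

setValidity("LeadField", function(object) {
    if (!object@dofPerPoint %in% c(1L, 3L))
        return("'dofPerPoint' must be 1 or 3")
    if (ncol(object@matrix) %% object@dofPerPoint != 0L)
        return("column count must be a multiple of 'dofPerPoint'")
    if (length(object@kinds) != nrow(object@matrix))
        return("'kinds' must have one entry per row")
    TRUE
})

#' Evoked measurement matrix
#'
#' Sensor data for one (averaged) evoked sequence: channels x samples, the
#' time axis, the sampling frequency and the prestimulus window used for
#' noise estimation.
#'
#' @slot data numeric matrix, channels x samples (fT/cm and/or fT).
#' @slot times numeric, sample times (ms), first entry is the start time t0.
#' @slot sfreq numeric(1), sampling frequency (Hz).
#' @slot prestim numeric(2), prestimulus interval (ms) within the time axis.
#' @slot kinds character vector, channel kind per row.
#'
#' @seealso [simulateBenchmark()], [readMeasurements()]
#' @export
setClass("Measurements",
    representation(data = "matrix", times = "numeric", sfreq = "numeric",
        prestim = "numeric", kinds = "character"))

setValidity("Measurements", function(object) {
    if (ncol(object@data) != length(object@times))
        return("'times' must have one entry per data column")
    if (length(object@prestim) != 2L)
        return("'prestim' must be an interval [start, end] in ms")
    if (object@prestim[1] < min(object@times) - 1e-9 ||
        object@prestim[2] > max(object@times) + 1e-9)
        return("prestimulus interval must lie within the recorded time axis")
    if (length(object@kinds) != nrow(object@data))
        return("'kinds' must have one entry per channel")
    TRUE
})

#' Noise model
#'
#' Either white noise with a common per-channel standard deviation, or a full
#' channel covariance (used to prewhiten data and lead field). The
#' discrepancy parameter multiplies the noise estimate in the particle-filter
#' likelihood: values below 1 demand a tighter fit (more, less stable
#' sources), values above 1 a looser fit (fewer, more stable sources).
#'
#' @slot mode character, "white" or "covariance".
#' @slot sigma numeric(1), per-channel noise std (fT/cm) in white mode.
#' @slot covariance channels x channels covariance matrix (or 0 x 0).
#' @slot discrepancy numeric(1), unitless multiplier on the noise estimate.
#'
#' @seealso [estimateNoiseFromPrestim()], [likelihoodWeight()]
#' @export
setClass("NoiseModel",
    representation(mode = "character", sigma = "numeric",
        covariance = "matrix", discrepancy = "numeric"))

setValidity("NoiseModel", function(object) {
    if (!object@mode %in% c("white", "covariance"))
        return("'mode' must be 'white' or 'covariance'")
    if (object@sigma < 0) return("'sigma' must be nonnegative")
    if (object@discrepancy <= 0) return("'discrepancy' must be positive")
    if (object@mode == "covariance") {
        cv <- object@covariance
        if (nrow(cv) == 0L) return("covariance mode requires a covariance matrix")
        if (!isSymmetric(unname(cv), tol = 1e-8))
            return("covariance must be symmetric")
        ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) <= 0) return("covariance must be positive definite")
    }
    TRUE
})

#' Particle-filter configuration
#'
#' Run-time parameters of the random-finite-set particle filter. None of the
#' dynamics rates are dictated by the tracking model itself; the defaults are
#' chosen so that the dipole-count birth/death chain mixes within tens of
#' samples, and every one of them can be overridden.
#'
#' @slot nParticles integer, number of particles N_p.
#' @slot maxDipoles integer, upper bound on simultaneous dipoles per particle.
#' @slot discrepancy numeric, multiplier on the noise estimate (see
#'   [NoiseModel-class]).
#' @slot pBirth,pDeath,pMove numeric probabilities of dipole birth (per
#'   particle and sample), death (per dipole) and grid jump (per dipole).
#' @slot momentPriorStd numeric, std (nA*m) of the zero-mean Gaussian prior
#'   used in the ridge moment fit.
#' @slot resampleESS numeric in (0, 1]; resample when the effective sample
#'   size falls below `resampleESS * nParticles`. The default 1 resamples at
#'   every sample.
#' @slot seed integer RNG seed controlling the full run.
#'
#' @seealso [FilterConfig()], [runFilter()]
#' @export
setClass("FilterConfig",
    representation(nParticles = "integer", maxDipoles = "integer",
        discrepancy = "numeric", pBirth = "numeric", pDeath = "numeric",
        pMove = "numeric", momentPriorStd = "numeric",
        resampleESS = "numeric", seed = "integer"))

setValidity("FilterConfig", function(object) {
    p <- c(object@pBirth, object@pDeath, object@pMove)
    if (any(p < 0) || any(p > 1)) return("probabilities must lie in [0, 1]")
    if (object@pBirth + object@pDeath > 1)
        return("pBirth + pDeath must not exceed 1")
    if (object@nParticles < 1L) return("'nParticles' must be at least 1")
    if (object@maxDipoles < 0L) return("'maxDipoles' must be nonnegative")
    if (object@discrepancy <= 0) return("'discrepancy' must be positive")
    if (object@momentPriorStd <= 0) return("'momentPriorStd' must be positive")
    if (object@resampleESS <= 0 || object@resampleESS > 1)
        return("'resampleESS' must lie in (0, 1]")
    TRUE
})

#' Weighted set of dipole configurations
#'
#' The particle-filter state at one time sample: `nParticles` dipole
#' configurations ("particles"), each a finite set of 0..maxDipoles grid
#' indices, with normalized importance weights. Moments are not part of the
#' state; they are refit from the data at every sample.
#'
#' @slot particles list of integer vectors of distinct grid indices (possibly
#'   length 0: the empty configuration).
#' @slot weights numeric, nonnegative, summing to 1.
#' @slot timeIndex integer sample index the weights refer to (0 = prior).
#'
#' @seealso [initializeParticles()], [resampleParticles()], [evolveParticles()]
#' @export
setClass("ParticleSet",
    representation(particles = "list", weights = "numeric",
        timeIndex = "integer"))

setValidity("ParticleSet", function(object) {
    if (length(object@particles) != length(object@weights))
        return("one weight per particle required")
    if (any(object@weights < 0)) return("weights must be nonnegative")
    if (abs(sum(object@weights) - 1) > 1e-9)
        return("weights must sum to 1 (tol 1e-9)")
    for (p in object@particles)
        if (anyDuplicated(p)) return("a particle must not repeat a grid index")
    TRUE
})

#' Particle-filter result
#'
#' Per-sample output of [runFilter()]: the model-order posterior (probability
#' that 0, 1, ..., maxDipoles dipoles are active), its mode `nHat`, and the
#' conditional estimates of the `nHat[t]` dipoles at each sample, stacked
#' into one table.
#'
#' @slot times numeric, sample times (ms).
#' @slot orderPosterior numeric matrix, samples x (maxDipoles + 1); row t is
#'   the posterior over the number of active dipoles at `times[t]`.
#' @slot nHat integer, posterior mode per sample (ties toward the smaller
#'   order).
#' @slot dipoles data.frame with one row per estimated dipole: `sample`,
#'   `time`, `gridIndex`, grid-snapped location `x,y,z`, unsnapped weighted
#'   mean location `mx,my,mz`, moment `qx,qy,qz` (nA*m) and `amplitude`
#'   (moment norm, nA*m).
#' @slot config the [FilterConfig-class] used.
#'
#' @seealso [runFilter()], [clusterDipoles()]
#' @export
setClass("FilterResult",
    representation(times = "numeric", orderPosterior = "matrix",
        nHat = "integer", dipoles = "data.frame", config = "FilterConfig"))

setValidity("FilterResult", function(object) {
    if (nrow(object@orderPosterior) != length(object@times))
        return("one posterior row per sample required")
    if (length(object@nHat) != length(object@times))
        return("one nHat per sample required")
    s <- rowSums(object@orderPosterior)
    if (any(abs(s - 1) > 1e-9))
        return("each order-posterior row must sum to 1 (tol 1e-9)")
    cnt <- tabulate(object@dipoles$sample, nbins = length(object@times))
    if (!all(cnt == object@nHat))
        return("dipole rows per sample must match nHat")
    TRUE
})

#' Clustered neural sources
#'
#' Result of binding per-sample dipole estimates across time into stable
#' neural sources. Each cluster carries its members, a mean location
#' (optionally a mean orientation) and an amplitude waveform over the
#' analyzed samples.
#'
#' @slot dipoles data.frame of the clustered dipoles (as in
#'   [FilterResult-class]) with an added `cluster` column.
#' @slot meanLocations numeric matrix, clusters x 3 (cm).
#' @slot meanOrientations clusters x 3 unit vectors, or `NULL` in
#'   location-only mode.
#' @slot waveforms numeric matrix, clusters x samples; amplitude (nA*m) per
#'   sample, zero where a cluster has no member (member mode) or the refit
#'   amplitude at the frozen mean location (refit mode).
#' @slot times numeric, sample times (ms) the waveforms refer to.
#' @slot mode character, "location" or "location+orientation".
#'
#' @seealso [clusterDipoles()], [clusterWaveforms()]
#' @export
setClass("ClusterSet",
    representation(dipoles = "data.frame", meanLocations = "matrix",
        meanOrientations = "matrixOrNULL", waveforms = "matrix",
        times = "numeric", mode = "character"))

setValidity("ClusterSet", function(object) {
    k <- nrow(object@meanLocations)
    if (k < 1L) return("at least one cluster required")
    if (!"cluster" %in% names(object@dipoles))
        return("'dipoles' must carry a cluster column")
    cl <- object@dipoles$cluster
    if (any(is.na(cl)) || any(cl < 1L) || any(cl > k))
        return("every dipole must belong to exactly one cluster")
    if (nrow(object@waveforms) && nrow(object@waveforms) != k)
        return("one waveform row per cluster required")
    if (nrow(object@waveforms) && ncol(object@waveforms) != length(object@times))
        return("waveform length must equal the number of analyzed samples")
    TRUE
})
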