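## Binding per-sample dipole estimates into stable neural sources: recursive
## k-medoids partitioning with a center-separation significance test, mean
## locations, and member/refit amplitude waveforms.

## Pairwise dissimilarity under the clustering metric. Location mode is
## plain Euclidean distance (cm); the orientation-aware mode adds
## lambda * (1 - |cos angle|) cm-equivalents, so antiparallel moments (same
## neural patch, opposite phase) are not split apart.
.clusterDist <- function(loc, ori, mode, lambda) {
    d <- as.matrix(stats::dist(loc))
    if (mode == "location+orientation") {
        cosang <- abs(tcrossprod(ori))
        cosang[cosang > 1] <- 1
        d <- d + lambda * (1 - cosang)
    }
    stats::as.dist(d)
}

.rowUnit <- function(q) {
    n <- sqrt(rowSums(q^2))
    n[n == 0] <- 1
    q / n
}

#' Are two dipole clusters significantly different?
#'
#' Separation test used by the recursive cluster reduction: the clusters are
#' significantly different when the distance between their centers (under
#' the clustering metric) strictly exceeds `cFactor` times the pooled
#' within-cluster RMS spread. Point clusters at distinct locations are
#' always different; identical clusters never are.
#'
#' @param clusterA,clusterB data.frames of member dipoles with columns
#'   `x,y,z` (and `qx,qy,qz` for the orientation-aware mode).
#' @param mode "location" or "location+orientation".
#' @param cFactor separation factor (default 2).
#' @param lambda orientation weight (cm per unit of `1 - |cos|`).
#' @return logical.
#' @export
clustersSignificantlyDifferent <- function(clusterA, clusterB,
                                           mode = c("location", "location+orientation"),
                                           cFactor = 2, lambda = 1) {
    mode <- match.arg(mode)
    locA <- as.matrix(clusterA[, c("x", "y", "z")])
    locB <- as.matrix(clusterB[, c("x", "y", "z")])
    cA <- colMeans(locA)
    cB <- colMeans(locB)
    dCenter <- sqrt(sum((cA - cB)^2))
    dA <- sqrt(rowSums(sweep(locA, 2, cA)^2))
    dB <- sqrt(rowSums(sweep(locB, 2, cB)^2))
    if (mode == "location+orientation") {
        oA <- .rowUnit(as.matrix(clusterA[, c("qx", "qy", "qz")]))
        oB <- .rowUnit(as.matrix(clusterB[, c("qx", "qy", "qz")]))
        mA <- .meanOrientation(oA)
        mB <- .meanOrientation(oB)
        dCenter <- dCenter + lambda * (1 - min(1, abs(sum(mA * mB))))
        dA <- dA + lambda * (1 - pmin(1, abs(oA %*% mA)))
        dB <- dB + lambda * (1 - pmin(1, abs(oB %*% mB)))
    }
    pooled <- sqrt(mean(c(dA, dB)^2))
    dCenter > cFactor * pooled
}

## Mean axis of a set of unit vectors, sign-invariant (principal eigenvector
## of the orientation scatter).
.meanOrientation <- function(o) {
    e <- eigen(crossprod(o), symmetric = TRUE)
    v <- e$vectors[, 1]
    v / sqrt(sum(v^2))
}

#' Bind per-sample dipoles into clusters of stable neural sources
#'
#' Dipoles estimated at different time samples that plausibly represent the
#' same neural source are grouped by k-medoids partitioning under either a
#' location metric or a combined location+orientation metric. The procedure
#' starts from the user-defined maximum number of clusters and recursively
#' decreases it until every pair of clusters passes the separation test of
#' [clustersSignificantlyDifferent()].
#'
#' @param x a [FilterResult-class], or a data.frame of estimated dipoles
#'   (columns `sample,time,x,y,z,qx,qy,qz,amplitude`) with `times` supplied.
#' @param maxClusters starting (maximum) number of clusters, >= 1.
#' @param mode "location" (default) or "location+orientation".
#' @param cFactor,lambda separation-test parameters, see
#'   [clustersSignificantlyDifferent()].
#' @param times sample times (ms); taken from `x` when it is a
#'   [FilterResult-class].
#' @return A [ClusterSet-class] with member-amplitude waveforms (zero at
#'   samples where a cluster has no member); see [clusterWaveforms()] for
#'   continuous refit waveforms.
#' @export
clusterDipoles <- function(x, maxClusters, mode = c("location", "location+orientation"),
                           cFactor = 2, lambda = 1, times = NULL) {
    mode <- match.arg(mode)
    if (is(x, "FilterResult")) {
        dip <- x@dipoles
        times <- x@times
    } else {
        dip <- x
        if (is.null(times)) stop("'times' required for a raw dipole table")
    }
    if (!nrow(dip)) stop("empty dipole list: nothing to cluster")
    if (maxClusters < 1) stop("'maxClusters' must be at least 1")
    loc <- as.matrix(dip[, c("x", "y", "z")])
    ori <- .rowUnit(as.matrix(dip[, c("qx", "qy", "qz")]))
    D <- .clusterDist(loc, ori, mode, lambda)
    k <- min(maxClusters, nrow(unique(loc)))
    repeat {
        if (k == 1L) {
            assign <- rep(1L, nrow(dip))
            break
        }
        assign <- cluster::pam(D, k, diss = TRUE, pamonce = 5,
            cluster.only = TRUE)
        members <- split(seq_len(nrow(dip)), assign)
        ok <- TRUE
        for (a in seq_len(k - 1L)) {
            for (b in (a + 1L):k) {
                if (!clustersSignificantlyDifferent(dip[members[[a]], ],
                        dip[members[[b]], ], mode, cFactor, lambda)) {
                    ok <- FALSE
                    break
                }
            }
            if (!ok) break
        }
        if (ok) break
        k <- k - 1L
    }
    dip$cluster <- as.integer(assign)
    kfin <- max(assign)
    meanLoc <- t(vapply(seq_len(kfin), function(j)
        colMeans(loc[assign == j, , drop = FALSE]), numeric(3)))
    meanOri <- if (mode == "location+orientation")
        t(vapply(seq_len(kfin), function(j)
            .meanOrientation(ori[assign == j, , drop = FALSE]), numeric(3)))
    else NULL
    wf <- .memberWaveforms(dip, kfin, times)
    new("ClusterSet", dipoles = dip, meanLocations = meanLoc,
        meanOrientations = meanOri, waveforms = wf, times = times,
        mode = mode)
}

## Member-amplitude waveforms: amplitude of a cluster's member dipole at
## each sample, zero where the cluster is silent (discontinuous by nature).
.memberWaveforms <- function(dip, k, times) {
    wf <- matrix(0, k, length(times))
    for (r in seq_len(nrow(dip)))
        wf[dip$cluster[r], dip$sample[r]] <-
            wf[dip$cluster[r], dip$sample[r]] + dip$amplitude[r]
    wf
}

#' Summary of one cluster
#'
#' Unweighted mean location of the member dipoles and the member-amplitude
#' waveform over the analyzed samples (zero at samples without a member).
#'
#' @param cluster data.frame of member dipoles (columns
#'   `sample,x,y,z,amplitude`).
#' @param nSamples total number of analyzed samples.
#' @return list with `meanLocation` (numeric(3), cm) and `waveform`
#'   (numeric(nSamples), nA*m).
#' @export
clusterSummary <- function(cluster, nSamples) {
    wf <- numeric(nSamples)
    for (r in seq_len(nrow(cluster)))
        wf[cluster$sample[r]] <- wf[cluster$sample[r]] + cluster$amplitude[r]
    list(meanLocation = colMeans(as.matrix(cluster[, c("x", "y", "z")])),
        waveform = wf)
}

## Free-orientation gain of a single (off-grid) location: channels x 3.
.pointGain <- function(location, sensors) {
    vapply(1:3, function(j) {
        m <- c(0, 0, 0)
        m[j] <- 1
        .dipoleChannelResponses(location, m, sensors)
    }, numeric(nrow(sensors@positions)))
}

#' Continuous cluster waveforms by moment refitting
#'
#' Recomputes each cluster's amplitude waveform by ridge-refitting a dipole
#' moment at the cluster's frozen mean location against the data at every
#' sample. Unlike the member waveforms (which inherit discontinuities from
#' the jumping per-sample locations), these waveforms are continuous in
#' time.
#'
#' @param clusterSet a [ClusterSet-class].
#' @param measurements a [Measurements-class].
#' @param sensors a [SensorArray-class] whose channels match the
#'   measurement rows (subset with [selectChannels()] if needed).
#' @param noise a [NoiseModel-class] (sets the ridge scale).
#' @param priorStd moment prior std (nA*m).
#' @return The [ClusterSet-class] with its waveforms replaced by the refit
#'   (continuous) ones.
#' @export
clusterWaveforms <- function(clusterSet, measurements, sensors,
                             noise = NoiseModel(sigma = 1), priorStd = 10) {
    if (nrow(sensors@positions) != nrow(measurements@data))
        stop("sensor array does not match the measurement channels")
    k <- nrow(clusterSet@meanLocations)
    lambda <- (noise@sigma / priorStd)^2
    wf <- matrix(0, k, ncol(measurements@data))
    for (j in seq_len(k)) {
        g <- .pointGain(clusterSet@meanLocations[j, ], sensors)
        A <- crossprod(g)
        M <- solve(A + diag(lambda, 3), t(g) %*% measurements@data)
        wf[j, ] <- sqrt(colSums(M^2))
    }
    clusterSet@waveforms <- wf
    clusterSet
}

#' Subset the channels of a sensor array
#'
#' @param sensors a [SensorArray-class].
#' @param which logical or integer channel selector.
#' @return A [SensorArray-class] with the selected channels.
#' @export
selectChannels <- function(sensors, which) {
    new("SensorArray", positions = sensors@positions[which, , drop = FALSE],
        kinds = sensors@kinds[which],
        axes = sensors@axes[which, , drop = FALSE],
        baseline = sensors@baseline, conductor = sensors@conductor)
}
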