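## Evaluation of a benchmark run against its ground truth: localization
## errors, cluster errors, per-source recovery, detection onset.

#' Distance of every estimated dipole to its nearest true source
#'
#' @param result a [FilterResult-class] (or its dipole table).
#' @param truth ground-truth list from [simulateBenchmark()] (or a matrix of
#'   true locations).
#' @return numeric vector (cm), one entry per estimated dipole.
#' @export
dipoleLocalizationErrors <- function(result, truth) {
    dip <- if (is(result, "FilterResult")) result@dipoles else result
    trueLoc <- .truthLocations(truth)
    if (!nrow(dip)) return(numeric(0))
    est <- as.matrix(dip[, c("x", "y", "z")])
    apply(est, 1, function(p) sqrt(min(colSums((t(trueLoc) - p)^2))))
}

.truthLocations <- function(truth) {
    if (is.matrix(truth)) return(truth)
    as.matrix(truth$sources[, c("x", "y", "z")])
}

#' Cluster-mean localization errors
#'
#' Distance of each cluster's mean location to its matched (nearest) true
#' source.
#'
#' @param clusterSet a [ClusterSet-class].
#' @param truth ground truth as in [dipoleLocalizationErrors()].
#' @return numeric vector (cm), one entry per cluster.
#' @export
clusterLocationErrors <- function(clusterSet, truth) {
    trueLoc <- .truthLocations(truth)
    apply(clusterSet@meanLocations, 1, function(p)
        sqrt(min(colSums((t(trueLoc) - p)^2))))
}

#' Which true sources were recovered?
#'
#' A true source counts as recovered when at least `minSamples` estimated
#' dipoles fall within `maxDist` of its location during its activation
#' window (peak latency +/- one FWHM). Co-located sources active at
#' different times (the red/yellow benchmark pair) are told apart by their
#' windows.
#'
#' @param result a [FilterResult-class].
#' @param truth ground-truth list from [simulateBenchmark()].
#' @param maxDist recovery radius (cm).
#' @param minSamples minimum number of matching dipole estimates.
#' @return logical vector, one entry per true source.
#' @export
recoveredSources <- function(result, truth, maxDist = 1.5, minSamples = 3) {
    dip <- result@dipoles
    src <- truth$sources
    vapply(seq_len(nrow(src)), function(i) {
        if (!nrow(dip)) return(FALSE)
        inWin <- dip$time >= src$latency[i] - src$fwhm[i] &
                 dip$time <= src$latency[i] + src$fwhm[i]
        d <- sqrt((dip$x - src$x[i])^2 + (dip$y - src$y[i])^2 +
                  (dip$z - src$z[i])^2)
        sum(inWin & d <= maxDist) >= minSamples
    }, logical(1))
}

#' Onset of detected activity
#'
#' First post-stimulus time at which the one-dipole (or larger) model
#' overtakes the zero-dipole model as the mode of the model-order
#' posterior.
#'
#' @param result a [FilterResult-class].
#' @return time (ms), or `NA` if the mode never leaves 0 after the stimulus.
#' @export
detectionOnset <- function(result) {
    post <- result@times > 0
    hit <- post & result@nHat >= 1L
    if (!any(hit)) return(NA_real_)
    result@times[which(hit)[1]]
}
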