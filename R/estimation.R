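## Per-sample summaries of the weighted particle cloud: model-order
## posterior, its mode, and conditional location/moment estimates.

#' Model-order posterior of a particle set
#'
#' Probability that exactly k dipoles are active, `P(k) =` sum of the
#' weights of the particles carrying exactly k dipoles.
#'
#' @param particleSet a [ParticleSet-class] with normalized weights.
#' @param maxDipoles length of the returned vector minus one; defaults to
#'   the largest dipole count present.
#' @return numeric vector of probabilities for k = 0..maxDipoles (sums to 1).
#' @examples
#' ps <- new("ParticleSet", particles = list(integer(0), 1L, c(1L, 2L), 2L),
#'     weights = rep(0.25, 4), timeIndex = 1L)
#' modelOrderPosterior(ps)
#' @export
modelOrderPosterior <- function(particleSet, maxDipoles = NULL) {
    k <- lengths(particleSet@particles)
    if (is.null(maxDipoles)) maxDipoles <- max(k)
    p <- vapply(0:maxDipoles, function(i)
        sum(particleSet@weights[k == i]), numeric(1))
    names(p) <- 0:maxDipoles
    p
}

#' Point estimate of the number of active dipoles
#'
#' Mode of the model-order posterior; ties are broken toward the smaller
#' order (a uniform posterior yields 0).
#'
#' @param posterior numeric probability vector over k = 0, 1, 2, ...
#' @return integer, the estimated dipole count.
#' @examples
#' estimateNHat(c(0.2, 0.5, 0.3))  # 1
#' estimateNHat(c(0.5, 0.5))       # 0 (tie toward smaller)
#' @export
estimateNHat <- function(posterior) {
    which.max(posterior) - 1L
}

## Deterministic weighted k-means on 3-D locations. Seeding: the
## highest-weight point first, then greedily the point maximizing
## weight x squared distance to its nearest chosen center. Ties break
## toward the lower row index throughout, so the grouping is reproducible
## and permutation-invariant given the aggregated input table.
.weightedKMeans <- function(X, w, k, maxIter = 100L) {
    m <- nrow(X)
    if (k >= m)
        return(list(assignment = seq_len(m), centers = X[seq_len(m), , drop = FALSE]))
    centers <- matrix(0, k, ncol(X))
    centers[1, ] <- X[which.max(w), ]
    d2near <- rowSums(sweep(X, 2, centers[1, ])^2)
    if (k > 1) for (j in 2:k) {
        centers[j, ] <- X[which.max(w * d2near), ]
        d2 <- rowSums(sweep(X, 2, centers[j, ])^2)
        d2near <- pmin(d2near, d2)
    }
    assign <- integer(m)
    for (iter in seq_len(maxIter)) {
        D <- vapply(seq_len(k), function(j)
            rowSums(sweep(X, 2, centers[j, ])^2), numeric(m))
        newAssign <- max.col(-D, ties.method = "first")
        for (j in seq_len(k)) {
            sel <- newAssign == j
            if (!any(sel)) {
                ## dead center: reseed at the point worst-served by the rest
                far <- which.max(w * D[cbind(seq_len(m), newAssign)])
                newAssign[far] <- j
                sel <- newAssign == j
            }
            ww <- w[sel]
            centers[j, ] <- colSums(X[sel, , drop = FALSE] * ww) / sum(ww)
        }
        if (identical(newAssign, assign)) break
        assign <- newAssign
    }
    list(assignment = assign, centers = centers)
}

## Group an aggregated pooled-dipole table (columns: gridIndex, weight,
## moment components) into nHat estimated dipoles.
.groupPooledDipoles <- function(pooled, nHat, sourceSpace) {
    pts <- sourceSpace@points
    idx <- as.integer(pooled[, 1])
    w <- pooled[, 2]
    dof <- ncol(pooled) - 2L
    if (dof == 3L) {
        Q <- pooled[, 3:5, drop = FALSE]
    } else {
        Q <- sourceSpace@orientations[idx, , drop = FALSE] * pooled[, 3]
    }
    X <- pts[idx, , drop = FALSE]
    km <- .weightedKMeans(X, w, nHat)
    out <- data.frame(gridIndex = integer(nHat), x = numeric(nHat),
        y = numeric(nHat), z = numeric(nHat), mx = numeric(nHat),
        my = numeric(nHat), mz = numeric(nHat), qx = numeric(nHat),
        qy = numeric(nHat), qz = numeric(nHat), amplitude = numeric(nHat))
    for (j in seq_len(nHat)) {
        sel <- km$assignment == j
        ww <- w[sel]
        mloc <- colSums(X[sel, , drop = FALSE] * ww) / sum(ww)
        snap <- which.min(colSums((t(pts) - mloc)^2))
        q <- colSums(Q[sel, , drop = FALSE] * ww) / sum(ww)
        out$gridIndex[j] <- snap
        out[j, c("x", "y", "z")] <- pts[snap, ]
        out[j, c("mx", "my", "mz")] <- mloc
        out[j, c("qx", "qy", "qz")] <- q
        out$amplitude[j] <- sqrt(sum(q^2))
    }
    out[order(-vapply(split(w, km$assignment)[as.character(seq_len(nHat))],
        sum, numeric(1))), , drop = FALSE]
}

#' Conditional dipole estimates from a particle cloud
#'
#' Restricts the cloud to the particles carrying exactly `nHat` dipoles,
#' pools their (weighted) dipoles, partitions the pool into `nHat` groups by
#' deterministic weighted k-means on location, and reports each group's
#' weighted-mean location (also snapped to the nearest grid point) and
#' weighted-mean moment. Moments are refit from the supplied data column;
#' without data the moments are zero and only locations are estimated.
#'
#' @param particleSet a [ParticleSet-class].
#' @param nHat number of dipoles to estimate (>= 1); at least one particle
#'   must carry exactly `nHat` dipoles.
#' @param sourceSpace a [SourceSpace-class].
#' @param dataColumn,leadField,noise,priorStd optional; when given, moments
#'   are ridge-refit per configuration as in [fitMoments()].
#' @return data.frame with one row per estimated dipole: `gridIndex`,
#'   snapped location `x,y,z`, unsnapped mean `mx,my,mz`, moment `qx,qy,qz`
#'   and `amplitude` (nA*m), ordered by decreasing group weight.
#' @export
conditionalDipoleEstimates <- function(particleSet, nHat, sourceSpace,
                                       dataColumn = NULL, leadField = NULL,
                                       noise = NULL, priorStd = 10) {
    if (nHat < 1) stop("'nHat' must be at least 1")
    k <- lengths(particleSet@particles)
    sel <- which(k == nHat)
    if (!length(sel))
        stop("empty conditional: no particle carries exactly ", nHat,
            " dipoles; fall back to the posterior mode over represented counts")
    dof <- if (!is.null(leadField)) leadField@dofPerPoint else 3L
    acc <- new.env(parent = emptyenv())
    for (p in sel) {
        locs <- sort(particleSet@particles[[p]])
        wp <- particleSet@weights[p]
        if (wp == 0) next
        if (!is.null(dataColumn)) {
            M <- fitMoments(locs, dataColumn, leadField, noise, priorStd)$moments
        } else {
            M <- matrix(0, dof, nHat)
        }
        for (i in seq_len(nHat)) {
            key <- as.character(locs[i])
            cur <- if (!is.null(acc[[key]])) acc[[key]] else numeric(dof + 1)
            acc[[key]] <- cur + c(wp, wp * M[, i])
        }
    }
    keys <- as.integer(ls(acc))
    pooled <- matrix(0, length(keys), dof + 2L)
    for (i in seq_along(keys)) {
        a <- acc[[as.character(keys[i])]]
        pooled[i, ] <- c(keys[i], a[1], a[-1] / a[1])
    }
    .groupPooledDipoles(pooled, nHat, sourceSpace)
}
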