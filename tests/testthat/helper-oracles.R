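## Independent oracles used across the test suite. Each implements the
## quantity under test by a different route than the package code:
## numerical integration, brute-force enumeration, or direct linear algebra.

.crossv <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])

## Numerical forward oracle: Biot-Savart field of the primary (point-dipole)
## current plus the Geselowitz surface integral of the volume currents in
## the homogeneous sphere. The surface potential comes from the
## insulating-sphere Legendre series; its gradient with respect to the
## source position is taken by central differences. Entirely independent of
## the closed-form implementation path.
oracleDipoleField <- function(location, moment, sensorPoint,
                              center = c(0, 0, 0), radius = 9,
                              nTheta = 300, nPhi = 600, nTerms = 120) {
    r0 <- (location - center) * 1e-2
    r <- (sensorPoint - center) * 1e-2
    Q <- moment * 1e-9
    R <- radius * 1e-2
    mu0_4pi <- 1e-7
    a <- r - r0
    Bp <- mu0_4pi * .crossv(Q, a) / sqrt(sum(a^2))^3
    ## midpoint surface mesh in cos(theta) x phi
    u <- -1 + (seq_len(nTheta) - 0.5) * 2 / nTheta
    ph <- (seq_len(nPhi) - 0.5) * 2 * pi / nPhi
    gridu <- rep(u, times = nPhi)
    gridp <- rep(ph, each = nTheta)
    st <- sqrt(pmax(0, 1 - gridu^2))
    nrm <- cbind(st * cos(gridp), st * sin(gridp), gridu)
    surf <- R * nrm
    dS <- R^2 * (2 / nTheta) * (2 * pi / nPhi)
    seriesS <- function(r0v) {
        b <- sqrt(sum(r0v^2))
        if (b == 0) return(numeric(nrow(surf)))
        cg <- pmin(1, pmax(-1, as.vector(surf %*% r0v) / (R * b)))
        x <- b / R
        Pnm1 <- rep(1, length(cg))
        Pn <- cg
        tot <- 3 * (x / R) * Pn
        xn <- x
        for (n in 2:nTerms) {
            xn <- xn * x
            Pnp <- ((2 * n - 1) * cg * Pn - (n - 1) * Pnm1) / n
            Pnm1 <- Pn
            Pn <- Pnp
            tot <- tot + (2 * n + 1) / n * (xn / R) * Pn
            if (xn < 1e-15) break
        }
        tot
    }
    h <- 1e-6
    sigV <- numeric(nrow(surf))
    for (j in 1:3) {
        e <- c(0, 0, 0)
        e[j] <- h
        sigV <- sigV + Q[j] * (seriesS(r0 + e) - seriesS(r0 - e)) / (2 * h)
    }
    sigV <- sigV / (4 * pi)
    d <- sweep(-surf, 2, r, "+")                       # r - r'
    dn3 <- sqrt(rowSums(d^2))^3
    cr <- cbind(nrm[, 2] * d[, 3] - nrm[, 3] * d[, 2],
                nrm[, 3] * d[, 1] - nrm[, 1] * d[, 3],
                nrm[, 1] * d[, 2] - nrm[, 2] * d[, 1])
    Bv <- -mu0_4pi * colSums(cr * (sigV / dn3)) * dS
    (Bp + Bv) * 1e15
}

## Analytic tangential derivative of the radial field component at a point,
## for gradiometer-convergence checks: differentiates the closed-form field
## numerically at machine-tight step via Richardson extrapolation.
oracleRadialDerivative <- function(location, moment, point, axis, conductor) {
    rhat <- point - conductor@center
    rhat <- rhat / sqrt(sum(rhat^2))
    f <- function(h) {
        bp <- dipoleFieldSphere(location, moment, point + h * axis, conductor)
        bm <- dipoleFieldSphere(location, moment, point - h * axis, conductor)
        sum((bp - bm) * rhat) / (2 * h)
    }
    ## Richardson on the symmetric difference
    (4 * f(1e-3) - f(2e-3)) / 3
}

## Brute-force count of lattice points (spacing s) inside a ball.
oracleLatticeCount <- function(radius, spacing, shellFraction = 1) {
    rmax <- shellFraction * radius
    M <- floor(rmax / spacing + 1e-9)
    cnt <- 0L
    for (i in -M:M) for (j in -M:M) for (k in -M:M)
        if ((i^2 + j^2 + k^2) * spacing^2 <= rmax^2 + 1e-9) cnt <- cnt + 1L
    cnt
}

## O(n^2) neighbor lists by direct distance thresholding.
oracleNeighbors <- function(points, radius) {
    n <- nrow(points)
    lapply(seq_len(n), function(i) {
        d2 <- colSums((t(points) - points[i, ])^2)
        which(d2 <= radius^2 + 1e-12)
    })
}

## Direct normal-equations ridge solve (independent of the C++ path).
oracleRidgeFit <- function(G, y, locs, dof, lambda) {
    if (!length(locs)) return(list(m = numeric(0), rss = sum(y^2)))
    cols <- as.vector(vapply(as.integer(locs),
        function(i) (dof * (i - 1) + 1):(dof * i), integer(dof)))
    X <- G[, cols, drop = FALSE]
    m <- solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, y))
    r <- y - X %*% m
    list(m = as.numeric(m), rss = sum(r^2))
}

## --- exhaustive hidden-Markov filter over set-valued states ---------------

## All subsets of 1..n with size <= nmax, as sorted integer vectors.
oracleStates <- function(n, nmax) {
    states <- list(integer(0))
    for (k in seq_len(nmax)) {
        states <- c(states, utils::combn(n, k, simplify = FALSE))
    }
    states
}

.stateKey <- function(s)
    if (length(s)) paste(sort(s), collapse = ",") else "empty"

## Exact transition distribution of the evolution move, enumerating the
## same sequential death / move / birth process (including collision
## rejection) as the implementation, from the canonical sorted state.
oracleTransition <- function(state, neighbors, ngrid, pBirth, pDeath, pMove,
                             nmax) {
    out <- new.env(parent = emptyenv())
    add <- function(s, p) {
        key <- .stateKey(s)
        cur <- if (!is.null(out[[key]])) out[[key]] else 0
        out[[key]] <- cur + p
    }
    state <- sort(state)
    k <- length(state)
    ## enumerate death patterns
    for (pat in seq_len(2^k) - 1L) {
        alive <- if (k) as.logical(bitwAnd(pat, 2^(seq_len(k) - 1L))) else logical(0)
        pDeathPat <- prod(ifelse(alive, 1 - pDeath, pDeath))
        surv <- state[alive]
        .moveRec(surv, 1L, pDeathPat, neighbors, ngrid, pBirth, pMove, nmax, add)
    }
    keys <- ls(out)
    p <- vapply(keys, function(kk) out[[kk]], numeric(1))
    names(p) <- keys
    p
}

.moveRec <- function(surv, i, prob, neighbors, ngrid, pBirth, pMove, nmax, add) {
    if (i > length(surv)) {
        ## birth branch
        if (length(surv) < nmax && pBirth > 0) {
            for (g in seq_len(ngrid)) {
                s2 <- if (g %in% surv) surv else c(surv, g)
                add(s2, prob * pBirth / ngrid)
            }
            add(surv, prob * (1 - pBirth))
        } else {
            add(surv, prob)
        }
        return(invisible())
    }
    ## no-move branch
    .moveRec(surv, i + 1L, prob * (1 - pMove), neighbors, ngrid, pBirth,
        pMove, nmax, add)
    if (pMove > 0) {
        cand <- neighbors[[surv[i]]]
        for (tgt in cand) {
            s2 <- surv
            if (!(tgt %in% surv[-i])) s2[i] <- tgt
            .moveRec(s2, i + 1L, prob * pMove / length(cand), neighbors,
                ngrid, pBirth, pMove, nmax, add)
        }
    }
    invisible()
}

## Exhaustive Bayesian filter: exact forward recursion over the enumerated
## state space with the same ridge-residual Gaussian likelihood.
oracleExactFilter <- function(G, Y, neighbors, dof, nmax, pBirth, pDeath,
                              pMove, lambda, noiseScale2) {
    ngrid <- length(neighbors)
    states <- oracleStates(ngrid, nmax)
    keys <- vapply(states, .stateKey, character(1))
    S <- length(states)
    ## transition matrix
    M <- matrix(0, S, S, dimnames = list(keys, keys))
    for (s in seq_len(S)) {
        tr <- oracleTransition(states[[s]], neighbors, ngrid, pBirth,
            pDeath, pMove, nmax)
        M[names(tr), s] <- tr
    }
    ## initial prior: uniform count, uniform set given count
    p <- vapply(states, function(st)
        1 / (nmax + 1) / choose(ngrid, length(st)), numeric(1))
    T <- ncol(Y)
    post <- matrix(0, S, T, dimnames = list(keys, NULL))
    for (t in seq_len(T)) {
        y <- Y[, t]
        L <- vapply(states, function(st)
            exp(-oracleRidgeFit(G, y, st, dof, lambda)$rss /
                (2 * noiseScale2)), numeric(1))
        p <- p * L
        p <- p / sum(p)
        post[, t] <- p
        p <- as.vector(M %*% p)
    }
    list(states = states, keys = keys, posterior = post)
}

## Total-variation distance between two named probability vectors.
tvDist <- function(p, q) {
    keys <- union(names(p), names(q))
    pv <- ifelse(keys %in% names(p), p[keys], 0)
    qv <- ifelse(keys %in% names(q), q[keys], 0)
    0.5 * sum(abs(pv - qv))
}

## Aggregate a particle snapshot (list with $particles, $weights) into a
## named state-probability vector.
snapshotStateProbs <- function(snap) {
    keys <- vapply(snap$particles, .stateKey, character(1))
    tapply(snap$weights, keys, sum)
}

## Exhaustive weighted-partition oracle: best assignment of m points into k
## groups minimizing the weighted within-group sum of squares.
oracleBestPartition <- function(X, w, k) {
    m <- nrow(X)
    best <- NULL
    bestCost <- Inf
    assign <- integer(m)
    rec <- function(i, used) {
        if (i > m) {
            if (used < k) return(invisible())
            cost <- 0
            for (j in seq_len(k)) {
                sel <- assign == j
                ww <- w[sel]
                ctr <- colSums(X[sel, , drop = FALSE] * ww) / sum(ww)
                cost <- cost + sum(ww * rowSums(sweep(X[sel, , drop = FALSE],
                    2, ctr)^2))
            }
            if (cost < bestCost) {
                bestCost <<- cost
                best <<- assign
            }
            return(invisible())
        }
        for (j in seq_len(min(used + 1L, k))) {
            assign[i] <<- j
            rec(i + 1L, max(used, j))
        }
    }
    rec(1L, 0L)
    list(assignment = best, cost = bestCost)
}

## Cost of a given assignment under the same weighted within-group SS.
partitionCost <- function(X, w, assign) {
    cost <- 0
    for (j in unique(assign)) {
        sel <- assign == j
        ww <- w[sel]
        ctr <- colSums(X[sel, , drop = FALSE] * ww) / sum(ww)
        cost <- cost + sum(ww * rowSums(sweep(X[sel, , drop = FALSE], 2, ctr)^2))
    }
    cost
}
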