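## Particle-filter mechanics: initialization, moment fitting, weighting,
## systematic resampling, random evolution, and full filtering passes on
## constructed scenarios.

test_that("initialization draws uniform counts and distinct uniform locations", {
    geo <- smallGeometry()
    n <- nrow(sourcePoints(geo$grid))
    cfg <- FilterConfig(nParticles = 30000, maxDipoles = 4, seed = 13)
    ps <- initializeParticles(cfg, geo$grid)
    expect_length(particles(ps), 30000)
    expect_equal(sum(weights(ps)), 1, tolerance = 1e-12)
    k <- lengths(particles(ps))
    ## dipole counts uniform on 0..4 (chi-square, 99.9% level)
    tab <- tabulate(k + 1L, nbins = 5L)
    chi <- sum((tab - 6000)^2 / 6000)
    expect_lt(chi, qchisq(0.999, df = 4))
    ## no duplicated locations inside a particle
    expect_false(any(vapply(particles(ps), anyDuplicated, integer(1)) > 0))
    ## locations roughly uniform over the grid among single-dipole particles
    locs <- unlist(particles(ps)[k == 1])
    tabL <- tabulate(locs, nbins = n)
    expect_lt(sum((tabL - mean(tabL))^2 / mean(tabL)), qchisq(0.9999, n - 1))
    ## determinism
    ps2 <- initializeParticles(cfg, geo$grid)
    expect_identical(particles(ps), particles(ps2))
    ## maxDipoles = 0: all particles empty
    ps0 <- initializeParticles(FilterConfig(nParticles = 50, maxDipoles = 0,
        seed = 1), geo$grid)
    expect_true(all(lengths(particles(ps0)) == 0))
    expect_error(initializeParticles(FilterConfig(maxDipoles = 10000,
        seed = 1), geo$grid), "configuration error")
})

test_that("ridge moment fit recovers exact moments and matches the normal equations", {
    geo <- smallGeometry()
    G <- leadMatrix(geo$lf)
    nm <- NoiseModel(sigma = 1)
    ## noiseless single-dipole data, nearly flat prior: exact recovery of
    ## the observable (tangential) moment -- the radial direction is silent
    ## in a sphere, so only the tangential projection is identifiable
    m0 <- c(7, -3, 2)
    y <- as.numeric(G[, 10:12] %*% m0)
    fit <- fitMoments(4L, y, geo$lf, nm, priorStd = 1e7)
    expect_lt(max(abs(fit$residual)), 1e-6 * max(abs(y)))
    r <- sourcePoints(geo$grid)[4, ] - geo$cond@center
    Ptan <- diag(3) - tcrossprod(r) / sum(r^2)
    expect_equal(as.numeric(Ptan %*% as.numeric(fit$moments)),
        as.numeric(Ptan %*% m0), tolerance = 1e-6)
    ## zero data: moments shrink to the prior mean zero
    fit0 <- fitMoments(c(2L, 9L), numeric(nrow(G)), geo$lf, nm)
    expect_equal(as.numeric(fit0$moments), rep(0, 6))
    ## two-dipole fit agrees with a direct normal-equations solve
    set.seed(31)
    y2 <- rnorm(nrow(G))
    lam <- (1 / 10)^2
    fit2 <- fitMoments(c(5L, 40L), y2, geo$lf, nm, priorStd = 10)
    orac <- oracleRidgeFit(G, y2, c(5, 40), 3, lam)
    expect_equal(as.numeric(fit2$moments), orac$m, tolerance = 1e-10)
    expect_equal(fit2$rss, orac$rss, tolerance = 1e-10)
    expect_error(fitMoments(c(3L, 3L), y2, geo$lf, nm), "distinct")
})

test_that("likelihood weights follow the tempered Gaussian of the residual", {
    geo <- smallGeometry()
    G <- leadMatrix(geo$lf)
    nch <- nrow(G)
    nm <- NoiseModel(sigma = 2, discrepancy = 1)
    ## particle reproducing the data exactly: weight 1
    y <- as.numeric(G[, 28:30] %*% c(4, 4, -1))
    expect_equal(likelihoodWeight(10L, y, geo$lf, nm, priorStd = 1e7), 1,
        tolerance = 1e-6)
    ## the empty particle's residual is the data itself
    w0 <- likelihoodWeight(integer(0), y, geo$lf, nm)
    expect_equal(w0, exp(-sum(y^2) / (2 * nch * 4)))
    ## log-weight equals the independent quadratic-form computation
    set.seed(33)
    y2 <- rnorm(nch)
    for (locs in list(7L, c(3L, 50L))) {
        w <- likelihoodWeight(locs, y2, geo$lf, nm, priorStd = 10)
        rss <- oracleRidgeFit(G, y2, locs, 3, (2 / 10)^2)$rss
        SigmaEffInv <- diag(1 / (nch * (nm@discrepancy * nm@sigma)^2), nch)
        ## -1/2 r' Sigma_eff^-1 r with r the ridge residual
        expect_equal(log(w), -0.5 * rss * SigmaEffInv[1, 1], tolerance = 1e-10)
    }
    ## doubling the discrepancy strictly increases any imperfect weight
    nm2 <- NoiseModel(sigma = 2, discrepancy = 2)
    expect_gt(likelihoodWeight(7L, y2, geo$lf, nm2),
        likelihoodWeight(7L, y2, geo$lf, nm))
    nmz <- NoiseModel(sigma = 1)
    nmz@sigma <- 0
    expect_error(likelihoodWeight(7L, y2, geo$lf, nmz), "noise level")
})

test_that("systematic resampling preserves counts and expectations", {
    geo <- smallGeometry()
    mk <- function(parts, w) new("ParticleSet", particles = parts,
        weights = w / sum(w), timeIndex = 1L)
    ## single massive particle: all copies
    ps <- mk(list(1L, 2L, c(3L, 4L)), c(0, 1, 0))
    set.seed(1)
    rs <- resampleParticles(ps)
    expect_true(all(vapply(particles(rs), identical, logical(1), 2L)))
    expect_equal(weights(rs), rep(1 / 3, 3))
    ## uniform weights map to the identity multiset
    psU <- mk(as.list(1:8), rep(1, 8))
    set.seed(2)
    rsU <- resampleParticles(psU)
    expect_identical(sort(unlist(particles(rsU))), 1:8)
    ## copy counts stay within 1 of N w_i and match in expectation
    w <- c(0.45, 0.25, 0.2, 0.1)
    psW <- mk(as.list(1:4), w)
    N <- 4
    tot <- numeric(4)
    set.seed(3)
    for (trial in 1:4000) {
        cnt <- tabulate(unlist(particles(resampleParticles(psW))), nbins = 4)
        expect_true(all(abs(cnt - N * w) <= 1 + 1e-12))
        tot <- tot + cnt
    }
    expect_equal(tot / 4000, N * w, tolerance = 0.05)
    ## degenerate weights
    psz <- new("ParticleSet", particles = list(1L), weights = 1, timeIndex = 1L)
    psz@weights <- 0
    expect_error(resampleParticles(psz), "degenerate")
})

test_that("random evolution honors its probabilities and invariants", {
    geo <- smallGeometry()
    n <- nrow(sourcePoints(geo$grid))
    cfg0 <- FilterConfig(nParticles = 100, maxDipoles = 3, pBirth = 0,
        pDeath = 0, pMove = 0, seed = 7)
    ps <- initializeParticles(cfg0, geo$grid)
    ## all-zero rates: identity
    ev <- evolveParticles(ps, geo$grid, cfg0)
    expect_identical(particles(ev), particles(ps))
    ## certain death empties every particle
    cfgD <- FilterConfig(nParticles = 100, maxDipoles = 3, pBirth = 0,
        pDeath = 1, pMove = 0, seed = 7)
    evD <- evolveParticles(ps, geo$grid, cfgD)
    expect_true(all(lengths(particles(evD)) == 0))
    ## invariants under generic evolution: count preserved, no duplicates,
    ## never above maxDipoles, all indices valid
    cfgG <- FilterConfig(nParticles = 100, maxDipoles = 3, pBirth = 0.3,
        pDeath = 0.2, pMove = 0.8, seed = 8)
    cur <- ps
    set.seed(99)
    for (step in 1:30) {
        cur <- evolveParticles(cur, geo$grid, cfgG)
        expect_length(particles(cur), 100)
        k <- lengths(particles(cur))
        expect_true(all(k <= 3))
        expect_false(any(vapply(particles(cur), anyDuplicated, integer(1)) > 0))
        expect_true(all(unlist(particles(cur)) %in% seq_len(n)))
    }
})

test_that("birth/death chain reaches the exact stationary distribution", {
    ## three fully connected points, nmax 2: exhaustive 7-state chain
    tiny <- tinySpace()
    nb <- neighborLists(tiny$space)
    pB <- 0.2; pD <- 0.3; pM <- 0.5
    states <- oracleStates(3, 2)
    keys <- vapply(states, .stateKey, character(1))
    M <- matrix(0, 7, 7, dimnames = list(keys, keys))
    for (s in seq_along(states)) {
        tr <- oracleTransition(states[[s]], nb, 3, pB, pD, pM, 2)
        M[names(tr), s] <- tr
    }
    expect_equal(colSums(M), rep(1, 7), tolerance = 1e-12,
        ignore_attr = TRUE)
    ## exact stationary distribution by power iteration
    p <- rep(1 / 7, 7)
    for (i in 1:500) p <- as.vector(M %*% p)
    ## empirical distribution from the implementation
    cfg <- FilterConfig(nParticles = 20000, maxDipoles = 2, pBirth = pB,
        pDeath = pD, pMove = pM, seed = 17)
    ps <- initializeParticles(cfg, tiny$space)
    set.seed(55)
    for (i in 1:60) ps <- evolveParticles(ps, tiny$space, cfg)
    emp <- table(factor(vapply(particles(ps), .stateKey, character(1)),
        levels = keys)) / 20000
    expect_lt(0.5 * sum(abs(as.numeric(emp) - p)), 0.02)
})

test_that("the C++ filtering pass reproduces the R-level weighting step", {
    tiny <- tinySpace()
    G <- leadMatrix(tiny$lf)
    set.seed(41)
    y <- as.numeric(G[, 1:3] %*% c(6, -2, 3)) + rnorm(nrow(G))
    meas <- new("Measurements", data = cbind(y), times = 0, sfreq = 1000,
        prestim = c(0, 0), kinds = channelKinds(tiny$lf))
    meas@prestim <- c(0, 0)
    nm <- NoiseModel(sigma = 1, discrepancy = 1)
    cfg <- FilterConfig(nParticles = 500, maxDipoles = 2, seed = 23)
    res <- runFilter(meas, tiny$lf, tiny$space, nm, cfg, snapshotAt = 1L)
    snap <- attr(res, "snapshots")[[1]]
    ## the same initial particles, weighted through the R-level surface
    ps0 <- initializeParticles(cfg, tiny$space)
    wR <- vapply(particles(ps0), likelihoodWeight, numeric(1),
        dataColumn = y, leadField = tiny$lf, noise = nm, priorStd = 10)
    wR <- wR / sum(wR)
    keyze <- function(l) vapply(l, function(x) paste(sort(x), collapse = ","),
        character(1))
    expect_equal(unname(tapply(snap$weights, keyze(snap$particles), sum)),
        unname(tapply(wR, keyze(particles(ps0)), sum)), tolerance = 1e-12)
    ## model-order posterior consistency with the snapshot
    psSnap <- new("ParticleSet", particles = snap$particles,
        weights = snap$weights, timeIndex = 1L)
    expect_equal(as.numeric(orderPosterior(res)[1, ]),
        as.numeric(modelOrderPosterior(psSnap, maxDipoles = 2)),
        tolerance = 1e-12)
})

test_that("zero data settles on the empty model once the chain has relaxed", {
    tiny <- tinySpace()
    Tn <- 80
    meas <- new("Measurements", data = matrix(0, nrow(leadMatrix(tiny$lf)), Tn),
        times = seq_len(Tn), sfreq = 1000, prestim = c(1, 3),
        kinds = channelKinds(tiny$lf))
    nm <- NoiseModel(sigma = 5, discrepancy = 1)
    cfg <- FilterConfig(nParticles = 4000, maxDipoles = 2, seed = 3)
    res <- runFilter(meas, tiny$lf, tiny$space, nm, cfg)
    expect_true(all(nHat(res)[30:Tn] == 0L))
    expect_equal(rowSums(orderPosterior(res)), rep(1, Tn), tolerance = 1e-9)
})

test_that("a static high-SNR grid dipole is tracked at the right location", {
    geo <- smallGeometry()
    G <- leadMatrix(geo$lf)
    pts <- sourcePoints(geo$grid)
    truthIdx <- which.min(colSums((t(pts) - c(2, 0, 4))^2))
    Tn <- 60
    act <- ifelse(seq_len(Tn) >= 20 & seq_len(Tn) <= 45, 1, 0)
    moment <- c(0, 60, 30)   # large: high SNR
    set.seed(77)
    sig <- outer(as.numeric(G[, (3 * truthIdx - 2):(3 * truthIdx)] %*% moment),
        act)
    Y <- sig + matrix(rnorm(length(sig), sd = 1), nrow(sig))
    meas <- new("Measurements", data = Y, times = seq_len(Tn) - 10,
        sfreq = 1000, prestim = c(-9, 0), kinds = channelKinds(geo$lf))
    ## the scenario is unimodal: an exhaustive single-dipole scan at the
    ## activation peak picks the true grid point
    yPk <- Y[, 30]
    scan <- vapply(seq_len(nrow(pts)), function(i)
        oracleRidgeFit(G, yPk, i, 3, 1e-4)$rss, numeric(1))
    expect_equal(which.min(scan), truthIdx)
    nm <- NoiseModel(sigma = 1, discrepancy = 1)
    cfg <- FilterConfig(nParticles = 2000, maxDipoles = 3, seed = 5)
    res <- runFilter(meas, geo$lf, geo$grid, nm, cfg)
    ## modal order 1 through the activation (allowing a short onset lag)
    expect_true(all(nHat(res)[25:45] == 1L))
    dip <- estimatedDipoles(res)
    dip <- dip[dip$sample >= 25 & dip$sample <= 45, ]
    err <- sqrt((dip$x - pts[truthIdx, 1])^2 + (dip$y - pts[truthIdx, 2])^2 +
        (dip$z - pts[truthIdx, 3])^2)
    expect_lte(mean(err), gridSpacing(geo$grid))
    ## estimated moment direction at the peak aligns with the truth
    pk <- dip[dip$sample == 30, ]
    cosang <- sum(pk[, c("qx", "qy", "qz")] * moment) /
        sqrt(sum(pk[, c("qx", "qy", "qz")]^2) * sum(moment^2))
    expect_gt(abs(cosang), 0.9)
})

test_that("filtering runs are bit-reproducible and validate their inputs", {
    tiny <- tinySpace()
    G <- leadMatrix(tiny$lf)
    set.seed(9)
    Y <- matrix(rnorm(nrow(G) * 10), nrow(G))
    meas <- new("Measurements", data = Y, times = 1:10, sfreq = 1000,
        prestim = c(1, 4), kinds = channelKinds(tiny$lf))
    nm <- NoiseModel(sigma = 1)
    cfg <- FilterConfig(nParticles = 300, maxDipoles = 2, seed = 11)
    r1 <- runFilter(meas, tiny$lf, tiny$space, nm, cfg)
    r2 <- runFilter(meas, tiny$lf, tiny$space, nm, cfg)
    expect_identical(orderPosterior(r1), orderPosterior(r2))
    expect_identical(estimatedDipoles(r1), estimatedDipoles(r2))
    ## dimension mismatch reporting
    measBad <- new("Measurements", data = Y[-1, ], times = 1:10, sfreq = 1000,
        prestim = c(1, 4), kinds = channelKinds(tiny$lf)[-1])
    expect_error(runFilter(measBad, tiny$lf, tiny$space, nm, cfg),
        "dimension mismatch")
    measNA <- meas
    measNA@data[1, 1] <- NA
    expect_error(runFilter(measNA, tiny$lf, tiny$space, nm, cfg), "NaN|NA")
})
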