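## Spherical-conductor forward model: closed form vs numerical integration,
## channel models, grid and neighbor construction, lead-field assembly.

test_that("closed-form dipole field matches the Biot-Savart + volume-current oracle", {
    cond <- SphereConductor(c(0, 0, 0), 9)
    set.seed(11)
    for (i in 1:2) {
        loc <- rnorm(3)
        loc <- runif(1, 3.5, 6) * loc / sqrt(sum(loc^2))
        q <- rnorm(3)
        q <- 10 * q / sqrt(sum(q^2))
        sp <- rnorm(3)
        sp <- 10.5 * sp / sqrt(sum(sp^2))
        closed <- dipoleFieldSphere(loc, q, sp, cond)
        orac <- oracleDipoleField(loc, q, sp, c(0, 0, 0), 9,
            nTheta = 200, nPhi = 400, nTerms = 100)
        expect_lt(sqrt(sum((closed - orac)^2)) / sqrt(sum(closed^2)), 0.01)
    }
})

test_that("radial and central dipoles are externally silent; field is linear in the moment", {
    cond <- SphereConductor(c(0, 0, 4), 9)
    loc <- c(2, 1, 8)
    sp <- c(3, 2, 14)
    radialQ <- 10 * (loc - cond@center) / sqrt(sum((loc - cond@center)^2))
    expect_equal(dipoleFieldSphere(loc, radialQ, sp, cond), c(0, 0, 0),
        tolerance = 1e-12)
    expect_equal(dipoleFieldSphere(cond@center, c(5, 5, 0), sp, cond),
        c(0, 0, 0))
    q1 <- c(3, -1, 2)
    q2 <- c(-1, 4, 0.5)
    b12 <- dipoleFieldSphere(loc, 2 * q1 + 3 * q2, sp, cond)
    b1 <- dipoleFieldSphere(loc, q1, sp, cond)
    b2 <- dipoleFieldSphere(loc, q2, sp, cond)
    expect_equal(b12, 2 * b1 + 3 * b2, tolerance = 1e-12)
})

test_that("a sensor point inside the conductor is rejected", {
    cond <- SphereConductor(c(0, 0, 0), 9)
    expect_error(dipoleFieldSphere(c(0, 0, 5), c(1, 0, 0), c(0, 0, 8), cond),
        "invalid geometry")
})

test_that("gradiometer channel model: uniform and linear fields, baseline convergence", {
    cond <- SphereConductor(c(0, 0, 0), 8)
    helm <- fibonacciHelmet(nLocations = 4, helmetRadius = 10,
        conductor = cond)
    gradCh <- which(channelKinds(helm) == "GRAD")[1]
    magCh <- which(channelKinds(helm) == "MAG")[1]
    pos <- sensorPositions(helm)[gradCh, ]
    rhat <- pos / sqrt(sum(pos^2))
    ## spatially uniform field: zero gradiometer output, radial magnetometer
    uniform <- function(p) 7 * rhat
    expect_equal(gradiometerSignal(uniform, helm, gradCh), 0)
    expect_equal(gradiometerSignal(uniform, helm, magCh),
        sum(7 * rhat * sensorPositions(helm)[magCh, ]) /
            sqrt(sum(sensorPositions(helm)[magCh, ]^2)))
    ## field whose radial component is linear along the gradiometer axis
    e <- helm@axes[gradCh, ]
    s <- 0.37
    linear <- function(p) s * sum((p - pos) * e) * rhat
    expect_equal(gradiometerSignal(linear, helm, gradCh), s,
        tolerance = 1e-12)
    ## halving the baseline on a smooth (dipole) field: O(baseline^2) error
    loc <- c(1, 2, 4)
    q <- c(8, -3, 1)
    fld <- function(p) dipoleFieldSphere(loc, q, p, cond)
    exact <- oracleRadialDerivative(loc, q, pos, e, cond)
    err <- function(base) {
        h <- selectChannels(helm, seq_len(nrow(sensorPositions(helm))))
        h@baseline <- base
        abs(gradiometerSignal(fld, h, gradCh) - exact)
    }
    e1 <- err(1.68)
    e2 <- err(0.84)
    expect_lt(e2, e1 / 3)   # ~1/4 for a second-order scheme
})

test_that("source grid construction is deterministic and matches brute-force counts", {
    cond0 <- SphereConductor(c(0, 0, 0), 8)
    ## coarse limit: the origin-centered cross
    g <- buildSourceGrid(cond0, spacing = 8, shellFraction = 1)
    expect_lte(nrow(sourcePoints(g)), 7)
    expect_true(any(colSums(abs(t(sourcePoints(g)))) == 0))  # contains origin
    ## count equals an independent lattice-point count
    g5 <- buildSourceGrid(cond0, spacing = 0.5, shellFraction = 1)
    expect_equal(nrow(sourcePoints(g5)), oracleLatticeCount(8, 0.5))
    ## monotone nonincreasing in spacing
    counts <- vapply(c(0.8, 1, 1.5, 2, 3), function(s)
        nrow(sourcePoints(buildSourceGrid(cond0, s))), numeric(1))
    expect_true(all(diff(counts) <= 0))
    ## deterministic ordering, bit-exact
    expect_identical(sourcePoints(buildSourceGrid(cond0, 1, 0.9)),
        sourcePoints(buildSourceGrid(cond0, 1, 0.9)))
    ## z varies slowest (lexicographic z, y, x)
    z <- sourcePoints(g5)[, 3]
    expect_true(all(diff(z) >= 0))
    expect_error(buildSourceGrid(cond0, spacing = 16), "empty grid")
})

test_that("neighbor lists match brute-force distance thresholding and are symmetric", {
    cond0 <- SphereConductor(c(0, 0, 0), 6)
    g <- buildSourceGrid(cond0, spacing = 1)
    ## radius below spacing: singletons
    g1 <- neighborMatrix(g, radius = 0.5)
    expect_true(all(vapply(seq_len(nrow(sourcePoints(g1))), function(i)
        identical(neighborLists(g1)[[i]], i), logical(1))))
    ## radius equal to spacing at an interior point: self + 6 axis neighbors
    g2 <- neighborMatrix(g, radius = 1)
    origin <- which(rowSums(sourcePoints(g2)^2) == 0)
    expect_length(neighborLists(g2)[[origin]], 7L)
    ## full agreement with the O(n^2) oracle
    nb <- oracleNeighbors(sourcePoints(g2), 1)
    expect_identical(neighborLists(g2), nb)
    ## symmetry
    for (i in sample(length(nb), 25)) {
        for (j in neighborLists(g2)[[i]])
            expect_true(i %in% neighborLists(g2)[[j]])
    }
})

test_that("lead-field entries equal direct field + channel-model calls; map is linear", {
    geo <- smallGeometry()
    G <- leadMatrix(geo$lf)
    pts <- sourcePoints(geo$grid)
    set.seed(3)
    chans <- sample(nrow(G), 4)
    ptsIdx <- sample(nrow(pts), 4)
    for (ch in chans) for (i in ptsIdx) for (j in 1:3) {
        q <- c(0, 0, 0)
        q[j] <- 1
        fld <- function(p) dipoleFieldSphere(pts[i, ], q, p, geo$cond)
        expect_equal(G[ch, 3 * (i - 1) + j],
            gradiometerSignal(fld, geo$helm, ch), tolerance = 1e-10)
    }
    ## superposition: two dipoles vs summed scaled columns
    m1 <- c(5, 1, -2)
    m2 <- c(0, -3, 4)
    i1 <- ptsIdx[1]
    i2 <- ptsIdx[2]
    pred <- G[, (3 * i1 - 2):(3 * i1)] %*% m1 + G[, (3 * i2 - 2):(3 * i2)] %*% m2
    fld2 <- function(p) dipoleFieldSphere(pts[i1, ], m1, p, geo$cond) +
        dipoleFieldSphere(pts[i2, ], m2, p, geo$cond)
    both <- vapply(seq_len(nrow(G)), function(ch)
        gradiometerSignal(fld2, geo$helm, ch), numeric(1))
    expect_equal(as.numeric(pred), both, tolerance = 1e-9)
})

test_that("radial dipoles are silent through the whole lead field; constrained mode works", {
    geo <- smallGeometry()
    pts <- sourcePoints(geo$grid)
    G <- leadMatrix(geo$lf)
    ## radial unit moments at a sample of points: near-zero columns
    set.seed(4)
    idx <- sample(nrow(pts), 10)
    tangNorm <- median(sqrt(colSums(G^2)))
    for (i in idx) {
        r <- pts[i, ] - geo$cond@center
        nr <- sqrt(sum(r^2))
        if (nr < 1e-9) next
        col <- G[, (3 * i - 2):(3 * i)] %*% (r / nr)
        expect_lt(max(abs(col)), 1e-6 * tangNorm)
    }
    ## constrained assembly: orientation columns equal G %*% orientation
    ori <- t(apply(pts, 1, function(p) {
        v <- c(-p[2], p[1], 0.5)
        v / sqrt(sum(v^2))
    }))
    gridC <- new("SourceSpace", points = pts, orientations = ori,
        spacing = gridSpacing(geo$grid), neighbors = list())
    lfC <- assembleLeadField(gridC, geo$helm, constrained = TRUE)
    expect_equal(dofPerPoint(lfC), 1L)
    i <- idx[1]
    expect_equal(leadMatrix(lfC)[, i],
        as.numeric(G[, (3 * i - 2):(3 * i)] %*% ori[i, ]), tolerance = 1e-12)
    expect_error(assembleLeadField(geo$grid, geo$helm, constrained = TRUE),
        "configuration error")
})

test_that("sensor-array validity enforces geometry invariants", {
    cond <- SphereConductor(c(0, 0, 0), 9)
    helm <- fibonacciHelmet(nLocations = 6, conductor = cond)
    expect_true(validObject(helm))
    bad <- helm
    bad@positions[1, ] <- c(0, 0, 1)    # inside the conductor
    expect_error(validObject(bad), "outside the conductor")
    bad2 <- helm
    gr <- which(channelKinds(helm) == "GRAD")[1]
    bad2@axes[gr, ] <- bad2@positions[gr, ] / sqrt(sum(bad2@positions[gr, ]^2))
    expect_error(validObject(bad2), "orthogonal")
})
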