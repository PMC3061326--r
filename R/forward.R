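## Spherical-conductor MEG forward model: closed-form dipole field,
## magnetometer/planar-gradiometer channel responses, volumetric source grid,
## neighbor structure and lead-field assembly.

## Field of a unit-strength current dipole in a spherically symmetric
## conductor is linear in the moment; with positions in cm and moments in
## nA*m the closed-form expression returns fT after this prefactor
## (mu0/4pi = 1e-7 in SI; cm^-2 and nA*m and fT conversions give 1e3).
.kSarvas <- 1e3

#' Construct a single-sphere conductor
#'
#' @param center numeric(3), sphere center in head coordinates (cm).
#' @param radius numeric(1), conductor radius (cm).
#' @return A [SphereConductor-class] object.
#' @examples
#' SphereConductor(c(0, 0, 4), 9)
#' @export
SphereConductor <- function(center = c(0, 0, 4), radius = 9) {
    new("SphereConductor", center = as.numeric(center),
        radius = as.numeric(radius))
}

## 3 x 3 moment-to-field maps for many dipole locations and one field point.
## Returns an n x 9 matrix; columns (3*(j-1)+1):(3*j) hold the field (fT) of
## a unit moment (1 nA*m) along axis j for every location. All positions cm.
.sarvasMaps <- function(points, fieldPoint, center) {
    r <- fieldPoint - center
    rn <- sqrt(sum(r^2))
    r0 <- sweep(points, 2, center)               # n x 3
    av <- -sweep(r0, 2, r)                       # r - r0
    a <- sqrt(rowSums(av^2))
    r0r <- as.vector(r0 %*% r)
    avr <- as.vector(av %*% r)
    F <- a * (rn * a + rn^2 - r0r)
    c1 <- a^2 / rn + avr / a + 2 * a + 2 * rn
    c2 <- a + 2 * rn + avr / a
    gF <- outer(c1, r) - c2 * r0                 # n x 3
    out <- matrix(0, nrow(points), 9L)
    for (j in 1:3) {
        ## c_j = e_j x r0
        cj <- switch(j,
            cbind(0, -r0[, 3], r0[, 2]),
            cbind(r0[, 3], 0, -r0[, 1]),
            cbind(-r0[, 2], r0[, 1], 0))
        cjr <- as.vector(cj %*% r)
        B <- (.kSarvas / F^2) * (F * cj - cjr * gF)
        ## dipole exactly at the center: field vanishes by symmetry
        B[a == 0 | F == 0, ] <- 0
        out[, (3 * j - 2):(3 * j)] <- B
    }
    out
}

#' Magnetic field of a current dipole in a spherical conductor
#'
#' Closed-form field, outside a spherically symmetric conductor, of a current
#' dipole embedded in it. Volume currents are accounted for analytically;
#' radially oriented dipoles are externally silent and a dipole at the sphere
#' center produces no field.
#'
#' @param location numeric(3), dipole location (cm, head frame).
#' @param moment numeric(3), dipole moment (nA*m).
#' @param sensorPoint numeric(3), field point (cm), strictly outside the
#'   conductor.
#' @param conductor a [SphereConductor-class].
#' @return numeric(3), magnetic field at `sensorPoint` (fT).
#' @examples
#' cond <- SphereConductor(c(0, 0, 0), 9)
#' dipoleFieldSphere(c(2, 1, 5), c(10, 0, 0), c(3, 2, 10), cond)
#' @export
dipoleFieldSphere <- function(location, moment, sensorPoint,
                              conductor = SphereConductor()) {
    sensorPoint <- as.numeric(sensorPoint)
    d <- sqrt(sum((sensorPoint - conductor@center)^2))
    if (d <= conductor@radius)
        stop("invalid geometry: sensor point lies inside or on the conductor sphere")
    K <- .sarvasMaps(matrix(as.numeric(location), 1L, 3L), sensorPoint,
        conductor@center)
    as.numeric(matrix(K, 3L, 3L) %*% as.numeric(moment))
}

#' Channel response to a magnetic field
#'
#' Evaluates one channel of a [SensorArray-class] on an arbitrary field.
#' Magnetometers return the radial field component at the channel position
#' (fT); planar gradiometers return the symmetric finite difference of the
#' radial component along the channel's tangential axis divided by the
#' baseline (fT/cm).
#'
#' @param fieldFunction function taking a position (numeric(3), cm) and
#'   returning the field there (numeric(3), fT).
#' @param sensors a [SensorArray-class].
#' @param channel integer channel index.
#' @return scalar channel reading (fT or fT/cm).
#' @export
gradiometerSignal <- function(fieldFunction, sensors, channel) {
    pos <- sensors@positions[channel, ]
    rhat <- pos - sensors@conductor@center
    rhat <- rhat / sqrt(sum(rhat^2))
    radial <- function(p) sum(fieldFunction(p) * rhat)
    if (sensors@kinds[channel] == "MAG") {
        radial(pos)
    } else {
        e <- sensors@axes[channel, ]
        h <- sensors@baseline / 2
        (radial(pos + h * e) - radial(pos - h * e)) / sensors@baseline
    }
}

## All-channel response (fT or fT/cm per channel) to one dipole, vectorized
## over channels through the closed-form field. Backbone of simulation and
## of the lead-field assembly.
.dipoleChannelResponses <- function(location, moment, sensors) {
    loc <- matrix(as.numeric(location), 1L, 3L)
    cen <- sensors@conductor@center
    n <- nrow(sensors@positions)
    out <- numeric(n)
    for (i in seq_len(n)) {
        pos <- sensors@positions[i, ]
        rhat <- pos - cen
        rhat <- rhat / sqrt(sum(rhat^2))
        fld <- function(p)
            matrix(.sarvasMaps(loc, p, cen), 3L, 3L) %*% as.numeric(moment)
        if (sensors@kinds[i] == "MAG") {
            out[i] <- sum(fld(pos) * rhat)
        } else {
            e <- sensors@axes[i, ]
            h <- sensors@baseline / 2
            out[i] <- sum((fld(pos + h * e) - fld(pos - h * e)) * rhat) /
                sensors@baseline
        }
    }
    out
}

#' Quasi-uniform helmet sensor array
#'
#' Places sensor locations on a spherical cap by a deterministic
#' Fibonacci-lattice rule and equips each location with one magnetometer
#' (radial component) and two planar gradiometers with orthogonal tangential
#' axes, mimicking a 3-channels-per-location MEG helmet. Channel order is
#' GRAD, GRAD, MAG per location.
#'
#' @param nLocations integer, number of sensor locations.
#' @param helmetRadius numeric, distance of the locations from the conductor
#'   center (cm); must exceed the conductor radius.
#' @param capHalfAngle numeric, half-opening angle of the cap (degrees) about
#'   the +z axis.
#' @param baseline numeric, gradiometer finite-difference arm (cm).
#' @param conductor a [SphereConductor-class].
#' @return A [SensorArray-class] with `3 * nLocations` channels.
#' @examples
#' helm <- fibonacciHelmet(nLocations = 10)
#' table(channelKinds(helm))
#' @export
fibonacciHelmet <- function(nLocations = 102, helmetRadius = 10.5,
                            capHalfAngle = 110, baseline = 1.68,
                            conductor = SphereConductor()) {
    if (helmetRadius <= conductor@radius)
        stop("helmet radius must exceed the conductor radius")
    i <- seq_len(nLocations)
    umin <- cos(capHalfAngle * pi / 180)
    u <- 1 - (1 - umin) * (i - 0.5) / nLocations       # cos(theta)
    golden <- (1 + sqrt(5)) / 2
    phi <- 2 * pi * i / golden^2
    st <- sqrt(pmax(0, 1 - u^2))
    rhat <- cbind(st * cos(phi), st * sin(phi), u)
    pos1 <- sweep(helmetRadius * rhat, 2, conductor@center, "+")
    ## tangential frame per location
    zx <- cbind(-rhat[, 2], rhat[, 1], 0)              # z x rhat
    nz <- sqrt(rowSums(zx^2))
    pole <- nz < 1e-8
    e1 <- zx / ifelse(nz > 0, nz, 1)
    e1[pole, ] <- rep(c(1, 0, 0), each = sum(pole))
    e2 <- cbind(rhat[, 2] * e1[, 3] - rhat[, 3] * e1[, 2],
                rhat[, 3] * e1[, 1] - rhat[, 1] * e1[, 3],
                rhat[, 1] * e1[, 2] - rhat[, 2] * e1[, 1])
    idx <- rep(seq_len(nLocations), each = 3L)
    positions <- pos1[idx, , drop = FALSE]
    kinds <- rep(c("GRAD", "GRAD", "MAG"), nLocations)
    axes <- matrix(0, 3L * nLocations, 3L)
    axes[seq(1, by = 3, length.out = nLocations), ] <- e1
    axes[seq(2, by = 3, length.out = nLocations), ] <- e2
    new("SensorArray", positions = positions, kinds = kinds, axes = axes,
        baseline = baseline, conductor = conductor)
}

#' Build a regular volumetric source grid
#'
#' Regular Cartesian grid of candidate dipole locations restricted to a ball
#' concentric with the conductor. Points are ordered deterministically
#' (lexicographically by z, then y, then x).
#'
#' @param conductor a [SphereConductor-class].
#' @param spacing numeric, grid spacing (cm).
#' @param shellFraction numeric in (0, 1]; points are kept up to
#'   `shellFraction * radius` from the center.
#' @return A [SourceSpace-class] (neighbor lists not yet computed).
#' @examples
#' grid <- buildSourceGrid(SphereConductor(c(0, 0, 0), 8), spacing = 1)
#' nrow(sourcePoints(grid))
#' @export
buildSourceGrid <- function(conductor, spacing, shellFraction = 1) {
    R <- conductor@radius
    if (spacing <= 0) stop("'spacing' must be positive")
    if (shellFraction <= 0 || shellFraction > 1)
        stop("'shellFraction' must lie in (0, 1]")
    if (spacing >= 2 * R)
        stop("empty grid: spacing must be smaller than the sphere diameter")
    rmax <- shellFraction * R
    M <- floor(rmax / spacing + 1e-9)
    ax <- spacing * seq(-M, M)
    g <- expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE)
    keep <- g$x^2 + g$y^2 + g$z^2 <= rmax^2 + 1e-9
    g <- as.matrix(g[keep, , drop = FALSE])
    if (nrow(g) == 0L) stop("empty grid: no lattice point inside the shell")
    dimnames(g) <- NULL
    pts <- sweep(g, 2, conductor@center, "+")
    new("SourceSpace", points = pts, orientations = NULL,
        spacing = spacing, neighbors = list())
}

#' Compute neighbor lists within a radius
#'
#' For every source point, lists the indices of all points (itself included)
#' within Euclidean distance `radius`. The relation is symmetric; dipoles
#' are allowed to jump along these lists during the particle-filter
#' evolution.
#'
#' @param sourceSpace a [SourceSpace-class].
#' @param radius numeric, neighbor radius (cm).
#' @return The source space with its `neighbors` slot filled.
#' @examples
#' grid <- buildSourceGrid(SphereConductor(c(0, 0, 0), 4), spacing = 1)
#' grid <- neighborMatrix(grid, radius = 1)
#' @export
neighborMatrix <- function(sourceSpace, radius) {
    if (radius <= 0) stop("'radius' must be positive")
    p <- sourceSpace@points
    n <- nrow(p)
    r2 <- radius^2 + 1e-12
    nb <- vector("list", n)
    chunk <- max(1L, floor(2e7 / n))
    for (s in seq(1L, n, by = chunk)) {
        e <- min(n, s + chunk - 1L)
        idx <- s:e
        ## squared distances of chunk points to all points
        d2 <- outer(rowSums(p[idx, , drop = FALSE]^2), rowSums(p^2), "+") -
            2 * p[idx, , drop = FALSE] %*% t(p)
        for (k in seq_along(idx))
            nb[[idx[k]]] <- which(d2[k, ] <= r2)
    }
    sourceSpace@neighbors <- nb
    sourceSpace
}

#' Assemble the lead field
#'
#' Builds the channels x DOF gain matrix for all source-space points from the
#' closed-form sphere model. In free-orientation mode column
#' `3 * (i - 1) + j` is the array response to a unit moment (1 nA*m) along
#' axis j at point i; in constrained mode column i is the response to a unit
#' moment along the point's fixed orientation.
#'
#' @param sourceSpace a [SourceSpace-class].
#' @param sensors a [SensorArray-class].
#' @param constrained logical; use the source space's fixed orientations.
#' @return A [LeadField-class].
#' @export
assembleLeadField <- function(sourceSpace, sensors, constrained = FALSE) {
    if (constrained && is.null(sourceSpace@orientations))
        stop("configuration error: constrained mode requires orientations")
    pts <- sourceSpace@points
    n <- nrow(pts)
    nch <- nrow(sensors@positions)
    cen <- sensors@conductor@center
    G <- matrix(0, nch, 3L * n)
    jx <- seq(1L, 3L * n, by = 3L)
    radialPart <- function(fieldPoint, rhat) {
        K <- .sarvasMaps(pts, fieldPoint, cen)
        ## radial component of the field of each unit moment: n x 3
        cbind(K[, 1:3] %*% rhat, K[, 4:6] %*% rhat, K[, 7:9] %*% rhat)
    }
    for (i in seq_len(nch)) {
        pos <- sensors@positions[i, ]
        rhat <- pos - cen
        rhat <- rhat / sqrt(sum(rhat^2))
        if (sensors@kinds[i] == "MAG") {
            br <- radialPart(pos, rhat)
        } else {
            e <- sensors@axes[i, ]
            h <- sensors@baseline / 2
            br <- (radialPart(pos + h * e, rhat) -
                   radialPart(pos - h * e, rhat)) / sensors@baseline
        }
        G[i, jx] <- br[, 1]
        G[i, jx + 1L] <- br[, 2]
        G[i, jx + 2L] <- br[, 3]
    }
    if (constrained) {
        o <- sourceSpace@orientations
        Gc <- matrix(0, nch, n)
        for (i in seq_len(n))
            Gc[, i] <- G[, (3 * i - 2):(3 * i)] %*% o[i, ]
        return(new("LeadField", matrix = Gc, dofPerPoint = 1L,
            kinds = sensors@kinds))
    }
    new("LeadField", matrix = G, dofPerPoint = 3L, kinds = sensors@kinds)
}
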