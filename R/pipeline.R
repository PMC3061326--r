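## End-to-end pipeline: input reading/validation, noise estimation, filter,
## clustering, exports and run log. The command-line entry point
## (inst/scripts/dipoletrack.R) is a thin wrapper over runPipeline().

.defaultRunConfig <- function() {
    list(sourceSpace = NULL, leadField = NULL, measurements = NULL,
        covariance = NULL, projection = NULL, simulate = NULL,
        particles = 10000, maxDipoles = 5, discrepancy = 1,
        pBirth = 1 / 30, pDeath = 1 / 10, pMove = 1 / 2,
        momentPriorStd = 10, neighborRadius = 1, clustersMax = 6,
        clusterMode = "location", prestim = NULL, seed = 1, out = ".")
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Unknown keys are
#' rejected; numeric values are coerced. See [runPipeline()] for the known
#' keys and their defaults.
#'
#' @param path config file path.
#' @return named list of run parameters.
#' @export
readRunConfig <- function(path) {
    cfg <- .defaultRunConfig()
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2L) stop("malformed config line: ", ln)
        key <- trimws(kv[1])
        val <- trimws(kv[2])
        if (!key %in% names(cfg)) stop("unknown config key: ", key)
        num <- suppressWarnings(as.numeric(val))
        cfg[[key]] <- if (!is.na(num) &&
            !key %in% c("sourceSpace", "leadField", "measurements",
                "covariance", "projection", "out", "simulate",
                "clusterMode")) num else val
    }
    if (!is.null(cfg$prestim) && is.character(cfg$prestim))
        cfg$prestim <- as.numeric(strsplit(cfg$prestim, "[, ]+")[[1]])
    cfg
}

.validateRunConfig <- function(cfg) {
    if (cfg$discrepancy <= 0)
        stop("validation [config]: discrepancy must be positive")
    if (cfg$particles < 1)
        stop("validation [config]: particles must be at least 1")
    if (cfg$neighborRadius <= 0)
        stop("validation [config]: neighborRadius must be positive")
    if (cfg$clustersMax < 1)
        stop("validation [config]: clustersMax must be at least 1")
    if (!cfg$clusterMode %in% c("location", "location+orientation"))
        stop("validation [config]: unknown clusterMode ", cfg$clusterMode)
    if (is.null(cfg$simulate)) {
        for (key in c("sourceSpace", "leadField", "measurements"))
            if (is.null(cfg[[key]]))
                stop("validation [config]: mandatory input '", key,
                    "' missing")
    }
    invisible(cfg)
}

#' Run the full dipole-tracking pipeline
#'
#' Reads (or simulates) the inputs, computes the neighbor structure,
#' estimates the noise from the prestimulus interval (unless a covariance
#' file is supplied), runs the particle filter with per-sample estimation,
#' clusters the estimated dipoles, and writes all results plus a run log to
#' the output directory:
#' `dipoles.tsv`, `order_posterior.tsv`, `clusters.tsv`,
#' `cluster_waveforms.tsv`, `estimates.stc` and `run_log.txt`.
#'
#' Configuration keys (see [readRunConfig()]): input paths `sourceSpace`,
#' `leadField`, `measurements`, optional `covariance` and `projection`;
#' `simulate = benchmark` replaces the inputs by the six-source synthetic
#' benchmark; filter parameters `particles`, `maxDipoles`, `discrepancy`,
#' `pBirth`, `pDeath`, `pMove`, `momentPriorStd`; `neighborRadius` (cm);
#' `clustersMax` and `clusterMode`; `prestim` (ms, overrides the sidecar);
#' `seed`; output directory `out`.
#'
#' @param config named list (as from [readRunConfig()]) or a config file
#'   path.
#' @param verbose logical, log progress to the console as well.
#' @return invisibly, a list with the `filterResult` ([FilterResult-class]),
#'   `clusters` ([ClusterSet-class]) and the output directory.
#' @export
runPipeline <- function(config, verbose = TRUE) {
    if (is.character(config)) config <- readRunConfig(config)
    cfg <- utils::modifyList(.defaultRunConfig(), config)
    .validateRunConfig(cfg)
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    t0 <- proc.time()[3]
    logLines <- character(0)
    stamp <- function(stage, msg) {
        line <- sprintf("[%7.2fs] %-12s %s", proc.time()[3] - t0, stage, msg)
        logLines <<- c(logLines, line)
        if (verbose) message(line)
    }
    stamp("config", sprintf("seed=%d particles=%d discrepancy=%g maxDipoles=%d",
        as.integer(cfg$seed), as.integer(cfg$particles), cfg$discrepancy,
        as.integer(cfg$maxDipoles)))

    truth <- NULL
    sensors <- NULL
    if (!is.null(cfg$simulate)) {
        if (!cfg$simulate %in% c("benchmark", "table1"))
            stop("validation [inputs]: unknown simulation scenario ",
                cfg$simulate)
        stamp("inputs", "simulating the six-source benchmark")
        cond <- SphereConductor()
        sensors <- fibonacciHelmet(conductor = cond)
        sim <- simulateBenchmark(benchmarkSources(), sensors, sigma = 3,
            seed = as.integer(cfg$seed))
        meas <- sim$measurements
        truth <- sim$truth
        sensors <- selectChannels(sensors, truth$channelMask)
        space <- buildSourceGrid(cond, spacing = 0.5, shellFraction = 0.85)
        stamp("inputs", sprintf("source grid: %d points, spacing 0.5 cm",
            nrow(space@points)))
        lf <- assembleLeadField(space, sensors)
        noiseCov <- NULL
    } else {
        stamp("inputs", paste("reading", cfg$sourceSpace))
        space <- readSourceSpace(cfg$sourceSpace)
        lf <- readLeadField(cfg$leadField)
        meas <- readMeasurements(cfg$measurements)
        noiseCov <- if (!is.null(cfg$covariance))
            as.matrix(utils::read.table(cfg$covariance)) else NULL
        n <- nrow(space@points)
        if (ncol(lf@matrix) != lf@dofPerPoint * n)
            stop(sprintf(
                "validation [inputs]: lead field is %d x %d but the source space (%d points, %d DOF each) needs %d columns",
                nrow(lf@matrix), ncol(lf@matrix), n, lf@dofPerPoint,
                lf@dofPerPoint * n))
        if (nrow(lf@matrix) != nrow(meas@data))
            stop(sprintf(
                "validation [inputs]: lead field has %d rows but the measurements %d channels",
                nrow(lf@matrix), nrow(meas@data)))
    }
    if (!is.null(cfg$prestim)) meas@prestim <- as.numeric(cfg$prestim)

    proj <- NULL
    if (!is.null(cfg$projection)) {
        proj <- as.matrix(utils::read.table(cfg$projection))
        if (max(abs(proj %*% proj - proj)) > 1e-6)
            stop("validation [inputs]: projection matrix is not idempotent")
        meas@data <- proj %*% meas@data
        stamp("inputs", "applied signal-space projection")
    }

    stamp("neighbors", sprintf("radius %g cm", cfg$neighborRadius))
    space <- neighborMatrix(space, cfg$neighborRadius)

    if (is.null(noiseCov)) {
        noise <- estimateNoiseFromPrestim(meas, "white",
            discrepancy = cfg$discrepancy)
        stamp("noise", sprintf("prestimulus white-noise std %.4g", noise@sigma))
    } else {
        noise <- NoiseModel(covariance = noiseCov,
            discrepancy = cfg$discrepancy)
        stamp("noise", "using supplied covariance (prewhitening)")
    }

    fconf <- FilterConfig(nParticles = cfg$particles,
        maxDipoles = cfg$maxDipoles, discrepancy = cfg$discrepancy,
        pBirth = cfg$pBirth, pDeath = cfg$pDeath, pMove = cfg$pMove,
        momentPriorStd = cfg$momentPriorStd, seed = as.integer(cfg$seed))
    stamp("filter", sprintf("%d samples x %d particles",
        ncol(meas@data), fconf@nParticles))
    res <- runFilter(meas, lf, space, noise, fconf, projection = proj,
        verbose = verbose)
    stamp("filter", sprintf("%d dipole estimates, order range %d..%d",
        nrow(res@dipoles), min(res@nHat), max(res@nHat)))

    outputs <- list(filterResult = res, clusters = NULL, out = cfg$out)
    utils::write.table(
        data.frame(time = res@times, nHat = res@nHat, res@orderPosterior),
        file.path(cfg$out, "order_posterior.tsv"), row.names = FALSE,
        sep = "\t", quote = FALSE)
    exportDipoleTable(res, file.path(cfg$out, "dipoles.tsv"))
    exportSTC(res, space, file.path(cfg$out, "estimates.stc"))

    if (nrow(res@dipoles)) {
        cs <- clusterDipoles(res, maxClusters = cfg$clustersMax,
            mode = cfg$clusterMode)
        if (!is.null(sensors))
            cs <- clusterWaveforms(cs, meas, sensors, noise)
        stamp("clusters", sprintf("%d clusters from at most %d",
            nrow(cs@meanLocations), as.integer(cfg$clustersMax)))
        memb <- table(cs@dipoles$cluster)
        first <- vapply(split(cs@dipoles$time, cs@dipoles$cluster), min,
            numeric(1))
        last <- vapply(split(cs@dipoles$time, cs@dipoles$cluster), max,
            numeric(1))
        utils::write.table(data.frame(cluster = seq_along(memb),
            x = cs@meanLocations[, 1], y = cs@meanLocations[, 2],
            z = cs@meanLocations[, 3], members = as.integer(memb),
            firstMs = first, lastMs = last),
            file.path(cfg$out, "clusters.tsv"), row.names = FALSE,
            sep = "\t", quote = FALSE)
        utils::write.table(cs@waveforms,
            file.path(cfg$out, "cluster_waveforms.tsv"),
            row.names = FALSE, col.names = FALSE, sep = "\t")
        outputs$clusters <- cs
    } else {
        stamp("clusters", "no estimated dipoles; clustering skipped")
    }

    stamp("done", "all outputs written")
    writeLines(c(sprintf("dipoleTrack run, seed %d", as.integer(cfg$seed)),
        sprintf("parameters: %s", paste(names(cfg)[!vapply(cfg, is.null,
            logical(1))], vapply(cfg[!vapply(cfg, is.null, logical(1))],
            function(x) paste(x, collapse = ","), character(1)),
            sep = "=", collapse = " ")),
        logLines), file.path(cfg$out, "run_log.txt"))
    invisible(outputs)
}
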