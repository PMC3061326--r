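## Plain-text readers/writers for the pipeline's interchange formats and the
## binary STC source-estimate exporter. ASCII matrices are the canonical
## interchange; every writer round-trips bit-exactly through its reader.

#' Read / write a source space
#'
#' ASCII format: a header line `# spacing=<cm>`, then one point per row,
#' `x y z` or `x y z ox oy oz` (cm; orientations unit vectors). Neighbor
#' lists are always computed, never stored.
#'
#' @param path file path.
#' @param sourceSpace a [SourceSpace-class].
#' @return `readSourceSpace` returns a [SourceSpace-class];
#'   `writeSourceSpace` returns `path` invisibly.
#' @export
readSourceSpace <- function(path) {
    hdr <- readLines(path, n = 1L)
    spacing <- if (grepl("^#\\s*spacing=", hdr))
        as.numeric(sub("^#\\s*spacing=", "", hdr)) else NA_real_
    m <- as.matrix(utils::read.table(path, comment.char = "#"))
    dimnames(m) <- NULL
    if (!ncol(m) %in% c(3L, 6L))
        stop("source-space rows must have 3 or 6 columns, found ", ncol(m))
    ori <- if (ncol(m) == 6L) m[, 4:6, drop = FALSE] else NULL
    new("SourceSpace", points = m[, 1:3, drop = FALSE], orientations = ori,
        spacing = spacing, neighbors = list())
}

#' @rdname readSourceSpace
#' @export
writeSourceSpace <- function(sourceSpace, path) {
    m <- sourceSpace@points
    if (!is.null(sourceSpace@orientations))
        m <- cbind(m, sourceSpace@orientations)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spacing=%.17g", sourceSpace@spacing), con)
    utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read / write a lead field
#'
#' ASCII matrix (channels x DOF, whitespace-separated) plus a channel-kind
#' sidecar file (`<path>.kinds`) listing `MAG` or `GRAD` per row.
#'
#' @param path matrix file path; the sidecar lives at `<path>.kinds`.
#' @param leadField a [LeadField-class].
#' @param dofPerPoint 3 (free orientation) or 1 (constrained), used by the
#'   reader.
#' @return `readLeadField` returns a [LeadField-class].
#' @export
readLeadField <- function(path, dofPerPoint = 3) {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    kinds <- readLines(paste0(path, ".kinds"))
    if (length(kinds) != nrow(m))
        stop(sprintf("kind sidecar lists %d channels but the matrix has %d rows",
            length(kinds), nrow(m)))
    new("LeadField", matrix = m, dofPerPoint = as.integer(dofPerPoint),
        kinds = kinds)
}

#' @rdname readLeadField
#' @export
writeLeadField <- function(leadField, path) {
    utils::write.table(leadField@matrix, path, row.names = FALSE,
        col.names = FALSE)
    writeLines(leadField@kinds, paste0(path, ".kinds"))
    invisible(path)
}

#' Read / write measurements
#'
#' ASCII matrix (channels x samples) plus a JSON sidecar (`<path>.json`)
#' holding `t0` (ms), `sfreq` (Hz), `prestim` (ms) and the channel kinds.
#'
#' @param path matrix file path; the sidecar lives at `<path>.json`.
#' @param measurements a [Measurements-class].
#' @return `readMeasurements` returns a [Measurements-class].
#' @export
readMeasurements <- function(path) {
    m <- as.matrix(utils::read.table(path))
    dimnames(m) <- NULL
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    times <- meta$t0 + (seq_len(ncol(m)) - 1L) * 1000 / meta$sfreq
    new("Measurements", data = m, times = times, sfreq = meta$sfreq,
        prestim = meta$prestim, kinds = meta$kinds)
}

#' @rdname readMeasurements
#' @export
writeMeasurements <- function(measurements, path) {
    utils::write.table(format(measurements@data, digits = 17), path,
        row.names = FALSE, col.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(t0 = measurements@times[1],
        sfreq = measurements@sfreq, prestim = measurements@prestim,
        kinds = measurements@kinds), paste0(path, ".json"),
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Export estimated dipoles as an STC source-estimate file
#'
#' Binary big-endian layout: start time (ms, float32), sample period (ms,
#' float32), vertex count (uint32), vertex ids (uint32, 0-based grid
#' indices), sample count (uint32), then the data (float32), one block of
#' vertex amplitudes (nA*m) per sample. The very first exported sample
#' holds the superposition of all estimated dipoles (each vertex at its
#' maximum amplitude over time) so the overall picture of the estimated
#' activity is visible at a glance; the actual per-sample sequence follows.
#'
#' @param result a [FilterResult-class].
#' @param sourceSpace the [SourceSpace-class] of the run.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportSTC <- function(result, sourceSpace, path) {
    dip <- result@dipoles
    times <- result@times
    verts <- sort(unique(dip$gridIndex))
    nv <- length(verts)
    nt <- length(times)
    data <- matrix(0, nv, nt)
    if (nv) {
        vrow <- match(dip$gridIndex, verts)
        for (r in seq_len(nrow(dip)))
            data[vrow[r], dip$sample[r]] <-
                data[vrow[r], dip$sample[r]] + dip$amplitude[r]
    }
    super <- if (nv) apply(data, 1, max) else numeric(0)
    period <- if (nt > 1) times[2] - times[1] else 1
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(times[1] - period), con, size = 4, endian = "big")
    writeBin(as.numeric(period), con, size = 4, endian = "big")
    writeBin(as.integer(nv), con, size = 4, endian = "big")
    if (nv) writeBin(as.integer(verts - 1L), con, size = 4, endian = "big")
    writeBin(as.integer(nt + 1L), con, size = 4, endian = "big")
    writeBin(as.numeric(cbind(super, data)), con, size = 4, endian = "big")
    invisible(path)
}

#' Read back an STC file
#'
#' Parses the layout written by [exportSTC()].
#'
#' @param path file path.
#' @return list with `tmin` (ms), `tstep` (ms), `vertices` (0-based ids) and
#'   `data` (vertices x samples).
#' @export
readSTC <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    tmin <- readBin(con, numeric(), 1, size = 4, endian = "big")
    tstep <- readBin(con, numeric(), 1, size = 4, endian = "big")
    nv <- readBin(con, integer(), 1, size = 4, endian = "big")
    verts <- if (nv) readBin(con, integer(), nv, size = 4, endian = "big")
        else integer(0)
    nt <- readBin(con, integer(), 1, size = 4, endian = "big")
    data <- matrix(readBin(con, numeric(), nv * nt, size = 4, endian = "big"),
        nrow = nv)
    list(tmin = tmin, tstep = tstep, vertices = verts, data = data)
}

#' Tabular dipole export
#'
#' Writes the estimated dipole table (one row per estimated dipole and
#' sample) as tab-separated text.
#'
#' @param result a [FilterResult-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
exportDipoleTable <- function(result, path) {
    utils::write.table(result@dipoles, path, row.names = FALSE, sep = "\t",
        quote = FALSE)
    invisible(path)
}

#' Read / write simulation ground truth
#'
#' JSON record of a simulated benchmark: per-source location, moment
#' (direction x magnitude) and waveform samples.
#'
#' @param truth the `truth` list from [simulateBenchmark()].
#' @param path file path.
#' @return `readGroundTruth` returns a list with the source table, moments
#'   and waveforms.
#' @export
writeGroundTruth <- function(truth, path) {
    jsonlite::write_json(list(sources = truth$sources,
        directions = truth$directions, magnitudes = truth$magnitudes,
        waveforms = truth$waveforms), path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$sources <- as.data.frame(x$sources)
    x
}
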