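#' @import methods
NULL

#' @rdname accessors
#' @export
setGeneric("sourcePoints", function(x) standardGeneric("sourcePoints"))
#' @rdname accessors
#' @export
setGeneric("orientations", function(x) standardGeneric("orientations"))
#' @rdname accessors
#' @export
setGeneric("neighborLists", function(x) standardGeneric("neighborLists"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
#' @rdname accessors
#' @export
setGeneric("channelKinds", function(x) standardGeneric("channelKinds"))
#' @rdname accessors
#' @export
setGeneric("leadMatrix", function(x) standardGeneric("leadMatrix"))
#' @rdname accessors
#' @export
setGeneric("dofPerPoint", function(x) standardGeneric("dofPerPoint"))
#' @rdname accessors
#' @export
setGeneric("measData", function(x) standardGeneric("measData"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("particles", function(x) standardGeneric("particles"))
#' @rdname accessors
#' @export
setGeneric("weights", function(x) standardGeneric("weights"))
#' @rdname accessors
#' @export
setGeneric("orderPosterior", function(x) standardGeneric("orderPosterior"))
#' @rdname accessors
#' @export
setGeneric("nHat", function(x) standardGeneric("nHat"))
#' @rdname accessors
#' @export
setGeneric("estimatedDipoles", function(x) standardGeneric("estimatedDipoles"))
#' @rdname accessors
#' @export
setGeneric("clusterMeans", function(x) standardGeneric("clusterMeans"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Accessors for dipole-tracking objects
#'
#' Small read-only accessors for the package's S4 containers; use these
#' rather than reaching into slots.
#'
#' @param x a package S4 object.
#' @return The requested component: matrices for geometry and data, numeric
#'   vectors for times/weights, a data.frame for dipole tables.
#' @name accessors
#' @aliases sourcePoints orientations neighborLists gridSpacing
#'   sensorPositions channelKinds leadMatrix dofPerPoint measData sampleTimes
#'   particles weights orderPosterior nHat estimatedDipoles clusterMeans
#'   nClusters
NULL

setMethod("sourcePoints", "SourceSpace", function(x) x@points)
setMethod("orientations", "SourceSpace", function(x) x@orientations)
setMethod("neighborLists", "SourceSpace", function(x) x@neighbors)
setMethod("gridSpacing", "SourceSpace", function(x) x@spacing)
setMethod("sensorPositions", "SensorArray", function(x) x@positions)
setMethod("channelKinds", "SensorArray", function(x) x@kinds)
setMethod("channelKinds", "LeadField", function(x) x@kinds)
setMethod("channelKinds", "Measurements", function(x) x@kinds)
setMethod("leadMatrix", "LeadField", function(x) x@matrix)
setMethod("dofPerPoint", "LeadField", function(x) x@dofPerPoint)
setMethod("measData", "Measurements", function(x) x@data)
setMethod("sampleTimes", "Measurements", function(x) x@times)
setMethod("sampleTimes", "FilterResult", function(x) x@times)
setMethod("sampleTimes", "ClusterSet", function(x) x@times)
setMethod("particles", "ParticleSet", function(x) x@particles)
setMethod("weights", "ParticleSet", function(x) x@weights)
setMethod("orderPosterior", "FilterResult", function(x) x@orderPosterior)
setMethod("nHat", "FilterResult", function(x) x@nHat)
setMethod("estimatedDipoles", "FilterResult", function(x) x@dipoles)
setMethod("estimatedDipoles", "ClusterSet", function(x) x@dipoles)
setMethod("clusterMeans", "ClusterSet", function(x) x@meanLocations)
setMethod("nClusters", "ClusterSet", function(x) nrow(x@meanLocations))

setMethod("show", "SphereConductor", function(object) {
    cat("SphereConductor: center (", paste(format(object@center), collapse = ", "),
        ") cm, radius ", format(object@radius), " cm\n", sep = "")
})

setMethod("show", "SourceSpace", function(object) {
    cat("SourceSpace with", nrow(object@points), "points, spacing",
        format(object@spacing), "cm\n")
    cat("  orientation-constrained:", !is.null(object@orientations), "\n")
    if (length(object@neighbors)) {
        ns <- lengths(object@neighbors)
        cat("  neighbor lists: median size", stats::median(ns), "\n")
    } else cat("  neighbor lists: not computed\n")
})

setMethod("show", "SensorArray", function(object) {
    cat("SensorArray with", nrow(object@positions), "channels (",
        sum(object@kinds == "GRAD"), "GRAD,", sum(object@kinds == "MAG"),
        "MAG ), baseline", format(object@baseline), "cm\n")
})

setMethod("show", "LeadField", function(object) {
    cat("LeadField:", nrow(object@matrix), "channels x", ncol(object@matrix),
        "DOF (", object@dofPerPoint, "per point )\n")
})

setMethod("show", "Measurements", function(object) {
    cat("Measurements:", nrow(object@data), "channels x", ncol(object@data),
        "samples,", format(object@sfreq), "Hz\n")
    cat("  time", format(min(object@times)), "..", format(max(object@times)),
        "ms, prestimulus [", object@prestim[1], ",", object@prestim[2], "] ms\n")
})

setMethod("show", "NoiseModel", function(object) {
    cat("NoiseModel (", object@mode, "): sigma =", format(object@sigma),
        ", discrepancy =", format(object@discrepancy), "\n")
})

setMethod("show", "FilterConfig", function(object) {
    cat("FilterConfig: ", object@nParticles, " particles, <= ",
        object@maxDipoles, " dipoles, discrepancy ", object@discrepancy,
        "\n  pBirth ", object@pBirth, ", pDeath ", object@pDeath, ", pMove ",
        object@pMove, ", moment prior std ", object@momentPriorStd,
        " nA*m, seed ", object@seed, "\n", sep = "")
})

setMethod("show", "ParticleSet", function(object) {
    k <- lengths(object@particles)
    cat("ParticleSet:", length(k), "particles at sample", object@timeIndex, "\n")
    cat("  dipole counts:", paste(names(table(k)), table(k), sep = ":",
        collapse = " "), "\n")
})

setMethod("show", "FilterResult", function(object) {
    cat("FilterResult over", length(object@times), "samples (",
        format(min(object@times)), "..", format(max(object@times)), "ms )\n")
    cat("  model order range:", min(object@nHat), "..", max(object@nHat),
        "; estimated dipoles:", nrow(object@dipoles), "\n")
})

setMethod("show", "ClusterSet", function(object) {
    cat("ClusterSet with", nrow(object@meanLocations), "clusters (mode:",
        object@mode, ")\n")
    cnt <- table(object@dipoles$cluster)
    cat("  member counts:", paste(cnt, collapse = ", "), "\n")
})
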