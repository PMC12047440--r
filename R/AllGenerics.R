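#' Ground truth recorded by a synthetic-data generator
#'
#' Every generator stores the parameters it drew the data from; downstream
#' recovery tests read truth only from this record, never from the data.
#' Returns \code{NULL} for measured (non-synthetic) objects.
#'
#' @param object a generated data object.
#' @return a named list of ground-truth values, or \code{NULL}.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "MassEventSet", function(object) object@groundTruth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "BindingCurve", function(object) object@groundTruth)
#' @rdname groundTruth
#' @export
setMethod("groundTruth", "CurtainEventTable",
          function(object) object@groundTruth)

#' Event masses of a MassEventSet
#'
#' @param object a \code{MassEventSet}.
#' @return numeric vector of masses in kDa.
#' @export
setGeneric("eventMasses", function(object) standardGeneric("eventMasses"))

#' @rdname eventMasses
#' @export
setMethod("eventMasses", "MassEventSet", function(object) {
    if (length(object@mass)) return(object@mass)
    if (is.null(object@calibration))
        stop("event set is uncalibrated; run calibrateMass()/applyCalibration()")
    object@calibration$slope * object@contrast + object@calibration$intercept
})

#' Event table of a CurtainEventTable
#' @param object a \code{CurtainEventTable}.
#' @return the per-event data.frame.
#' @export
setGeneric("curtainEvents", function(object) standardGeneric("curtainEvents"))

#' @rdname curtainEvents
#' @export
setMethod("curtainEvents", "CurtainEventTable", function(object) object@events)

#' Spot table accessor
#' @param object a \code{SpotTable}.
#' @return the per-spot data.frame.
#' @export
setGeneric("spotData", function(object) standardGeneric("spotData"))

#' @rdname spotData
#' @export
setMethod("spotData", "SpotTable", function(object) object@spots)

#' Motif sites of a GenomeTrack
#' @param object a \code{GenomeTrack}.
#' @return data.frame of 1-based motif occurrences with strand.
#' @export
setGeneric("motifSites", function(object) standardGeneric("motifSites"))

#' @rdname motifSites
#' @export
setMethod("motifSites", "GenomeTrack", function(object) object@motifSites)

#' A/T-content track of a GenomeTrack
#' @param object a \code{GenomeTrack}.
#' @return data.frame with window centers (bp) and A/T fraction.
#' @export
setGeneric("atContent", function(object) standardGeneric("atContent"))

#' @rdname atContent
#' @export
setMethod("atContent", "GenomeTrack", function(object) object@atTrack)

setMethod("show", "MassEventSet", function(object) {
    n <- max(length(object@contrast), length(object@mass))
    cat("MassEventSet with", n, "events;",
        if (is.null(object@calibration) && !length(object@mass))
            "uncalibrated" else "calibrated", "\n")
    if (length(object@mass))
        cat("  mass range:", paste(signif(range(object@mass), 4),
                                   collapse = " - "), "kDa\n")
})

setMethod("show", "MassHistogram", function(object) {
    cat("MassHistogram:", length(object@counts), "bins of",
        diff(object@breaks)[1], "kDa from", object@breaks[1], "kDa;",
        sum(object@counts), "events in range,", object@outOfRange,
        "out of range;",
        if (length(object@smoothed)) "smoothed" else "raw", "\n")
})

setMethod("show", "BindingCurve", function(object) {
    cat("BindingCurve (replicate ", object@replicate, "): ",
        length(object@conc), " points, ",
        paste(signif(range(object@conc), 3), collapse = "-"), " nM; ",
        if (length(object@normalized)) "normalized" else "raw", "\n",
        sep = "")
})

setMethod("show", "CurtainEventTable", function(object) {
    ev <- object@events
    cat("CurtainEventTable:", nrow(ev), "events on",
        length(unique(ev$dna)), "DNA molecules;",
        sum(ev$censored), "censored; channels:",
        paste(unique(ev$channel), collapse = ","), "\n")
})

setMethod("show", "GenomeTrack", function(object) {
    cat("GenomeTrack:", length(object@sequence), "bp;",
        nrow(object@motifSites), "motif sites",
        if (!is.na(object@motif)) sprintf("(%s)", object@motif) else "",
        ";", nrow(object@atTrack), "A/T windows\n")
})

setMethod("show", "SurvivalCurve", function(object) {
    cat("SurvivalCurve:", object@nEvents, "events,", object@nCensored,
        "censored;", object@nBootstrap, "bootstrap resamples\n")
})

setMethod("show", "SpotTable", function(object) {
    sp <- object@spots
    cat("SpotTable:", sum(sp$origin == "detected"), "detected,",
        sum(sp$origin == "random"), "random spots\n")
})
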