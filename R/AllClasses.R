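#' @importClassesFrom Biostrings DNAString
NULL

setClassUnion("listOrNULL", c("list", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' MassEventSet: single-molecule mass-photometry landing events
#'
#' Contrast values of individual landing events from one mass-photometry
#' acquisition, optionally calibrated to masses (kDa). Synthetic sets carry
#' their generator ground truth.
#'
#' @slot contrast numeric, raw interferometric contrast per event.
#' @slot mass numeric, event masses in kDa (length 0 until calibrated,
#'   unless the set was generated directly in mass units).
#' @slot calibration list with elements \code{slope} (kDa per contrast
#'   unit), \code{intercept} (kDa) and \code{residuals}, or \code{NULL}.
#' @slot groundTruth list of generator parameters, or \code{NULL} for
#'   measured data.
#' @slot metadata free-form list (acquisition annotations).
#' @export
setClass("MassEventSet",
    slots = c(contrast = "numeric", mass = "numeric",
              calibration = "listOrNULL", groundTruth = "listOrNULL",
              metadata = "list"),
    prototype = list(mass = numeric(0), calibration = NULL,
                     groundTruth = NULL, metadata = list()))

setValidity("MassEventSet", function(object) {
    if (length(object@contrast) == 0L && length(object@mass) == 0L)
        return("empty event set: no contrasts and no masses")
    if (length(object@mass) && length(object@contrast) &&
        length(object@mass) != length(object@contrast))
        return("mass and contrast lengths differ")
    if (!is.null(object@calibration)) {
        cal <- object@calibration
        if (!all(c("slope", "intercept") %in% names(cal)))
            return("calibration must contain 'slope' and 'intercept'")
        if (cal$slope == 0) return("calibration slope must be non-zero")
    }
    TRUE
})

#' MassHistogram: fixed-width mass histogram
#'
#' Mass histogram with 100 uniform bins of exactly 8 kDa, the standard
#' binning for mass-photometry deconvolution. Out-of-range events are
#' counted but excluded from the bins.
#'
#' @slot breaks numeric, 101 bin edges in kDa (uniform 8-kDa width).
#' @slot counts numeric, events per bin.
#' @slot smoothed numeric, Savitzky-Golay smoothed counts (length 0 until
#'   \code{\link{smoothMassHistogram}} is applied).
#' @slot outOfRange integer, number of events outside the bin range.
#' @export
setClass("MassHistogram",
    slots = c(breaks = "numeric", counts = "numeric",
              smoothed = "numeric", outOfRange = "integer"),
    prototype = list(smoothed = numeric(0), outOfRange = 0L))

setValidity("MassHistogram", function(object) {
    if (length(object@breaks) != length(object@counts) + 1L)
        return("breaks must have one more element than counts")
    w <- diff(object@breaks)
    if (any(abs(w - w[1]) > 1e-9))
        return("bins must be uniform")
    if (length(object@smoothed) &&
        length(object@smoothed) != length(object@counts))
        return("smoothed counts length mismatch")
    if (any(object@counts < 0)) return("negative counts")
    TRUE
})

#' BindingCurve: a fluorescence-anisotropy titration
#'
#' One titration of labelled nucleic acid with increasing protein
#' concentration. The normalized signal is defined only after
#' \code{\link{normalizeAnisotropy}}: the protein-free blank is subtracted
#' and the result min-max scaled to [0, 1].
#'
#' @slot conc numeric, protein concentrations (nM), strictly increasing.
#' @slot raw numeric, raw anisotropy per point.
#' @slot blank numeric(1), protein-free control anisotropy.
#' @slot normalized numeric, normalized signal (length 0 until normalized).
#' @slot replicate character(1), replicate identifier.
#' @slot groundTruth list of generator parameters or \code{NULL}.
#' @export
setClass("BindingCurve",
    slots = c(conc = "numeric", raw = "numeric", blank = "numeric",
              normalized = "numeric", replicate = "character",
              groundTruth = "listOrNULL"),
    prototype = list(normalized = numeric(0), replicate = "r1",
                     groundTruth = NULL))

setValidity("BindingCurve", function(object) {
    if (length(object@conc) != length(object@raw))
        return("conc and raw lengths differ")
    if (any(object@conc < 0)) return("concentrations must be nonnegative")
    if (any(diff(object@conc) <= 0))
        return("concentrations must be strictly increasing")
    if (length(object@blank) != 1L) return("blank must be a single value")
    if (length(object@normalized) &&
        length(object@normalized) != length(object@conc))
        return("normalized length mismatch")
    TRUE
})

#' CurtainEventTable: DNA-curtains binding events
#'
#' Per-event records of condensate binding on stretched curtain DNA.
#' Positions are kbp from the barrier; times in seconds. Events persisting
#' at movie end are right-censored (\code{censored} flag, \code{t_end}
#' equals the movie length).
#'
#' @slot events data.frame with columns \code{experiment}, \code{fov},
#'   \code{dna}, \code{position_kbp}, \code{t_start_s}, \code{t_end_s},
#'   \code{censored}, \code{channel}, \code{amplitude} and optional
#'   \code{partner_event}.
#' @slot movieLength numeric(1), movie length in seconds.
#' @slot genomeLengthKbp numeric(1), DNA substrate length in kbp.
#' @slot groundTruth list of generator parameters or \code{NULL}.
#' @export
setClass("CurtainEventTable",
    slots = c(events = "data.frame", movieLength = "numeric",
              genomeLengthKbp = "numeric", groundTruth = "listOrNULL"),
    prototype = list(groundTruth = NULL))

.curtainRequiredCols <- c("experiment", "fov", "dna", "position_kbp",
                          "t_start_s", "t_end_s", "censored", "channel",
                          "amplitude")

setValidity("CurtainEventTable", function(object) {
    ev <- object@events
    miss <- setdiff(.curtainRequiredCols, names(ev))
    if (length(miss))
        return(paste("missing event columns:", paste(miss, collapse = ", ")))
    if (nrow(ev)) {
        if (any(ev$position_kbp < 0 | ev$position_kbp > object@genomeLengthKbp))
            return("positions outside [0, genome length]")
        if (any(ev$t_start_s >= ev$t_end_s))
            return("t_start must be < t_end")
        if (any(ev$t_end_s > object@movieLength + 1e-9))
            return("t_end beyond movie length")
        if (any(ev$censored & abs(ev$t_end_s - object@movieLength) > 1e-9))
            return("censored events must end at movie length")
    }
    TRUE
})

#' GenomeTrack: a DNA substrate with motif and A/T-content annotations
#'
#' A DNA sequence annotated with exact motif occurrences (both strands by
#' default) and a sliding-window A/T-content track, used to relate
#' curtain binding positions to sequence features.
#'
#' @slot sequence a \code{\link[Biostrings]{DNAString}}.
#' @slot motif character(1), the scanned motif (e.g. the L1 target site
#'   \code{TTTTTAA}), or \code{NA} if not scanned.
#' @slot motifSites data.frame with 1-based \code{start}, \code{end},
#'   \code{strand}.
#' @slot atWindow,atStep integer, A/T-content window and step (bp).
#' @slot atTrack data.frame with window \code{center_bp} and \code{at}
#'   fraction in [0, 1].
#' @export
setClass("GenomeTrack",
    slots = c(sequence = "DNAString", motif = "character",
              motifSites = "data.frame", atWindow = "integer",
              atStep = "integer", atTrack = "data.frame"),
    prototype = list(motif = NA_character_,
                     motifSites = data.frame(start = integer(0),
                                             end = integer(0),
                                             strand = character(0)),
                     atWindow = NA_integer_, atStep = NA_integer_,
                     atTrack = data.frame(center_bp = numeric(0),
                                          at = numeric(0))))

setValidity("GenomeTrack", function(object) {
    if (length(object@sequence) == 0L) return("empty sequence")
    if (nrow(object@atTrack) &&
        any(object@atTrack$at < 0 | object@atTrack$at > 1))
        return("at_content must lie in [0, 1]")
    TRUE
})

#' SurvivalCurve: Kaplan-Meier dwell-time survival with bootstrap band
#'
#' Product-limit survival estimate of binding-event lifetimes under right
#' censoring, with a percentile-bootstrap confidence band.
#'
#' @slot time numeric, event-time grid (s), starting at 0.
#' @slot surv numeric, survival probability, non-increasing, S(0) = 1.
#' @slot lower,upper numeric, bootstrap band.
#' @slot nEvents,nCensored integer.
#' @slot nBootstrap integer, number of bootstrap resamples.
#' @export
setClass("SurvivalCurve",
    slots = c(time = "numeric", surv = "numeric", lower = "numeric",
              upper = "numeric", nEvents = "integer",
              nCensored = "integer", nBootstrap = "integer"))

setValidity("SurvivalCurve", function(object) {
    if (length(object@time) != length(object@surv))
        return("time and surv lengths differ")
    if (any(diff(object@surv) > 1e-12)) return("surv must be non-increasing")
    if (abs(object@surv[1] - 1) > 1e-12 || object@time[1] != 0)
        return("curve must start at S(0) = 1")
    if (length(object@lower) &&
        any(object@lower > object@surv + 1e-9 |
            object@upper < object@surv - 1e-9))
        return("bootstrap band must cover the point estimate")
    TRUE
})

#' SpotTable: detected or randomized 3D spots
#'
#' Spots from 3D Laplacian-of-Gaussian detection (or the count-matched
#' randomized null), with ROI membership, compartment label and
#' per-channel aperture intensities.
#'
#' @slot spots data.frame with columns \code{x}, \code{y}, \code{z}
#'   (voxel coordinates), \code{sigma}, \code{response}, \code{roi},
#'   \code{compartment}, \code{origin} plus per-channel intensity columns
#'   added by measurement steps.
#' @slot metadata list (detection parameters, image shape, etc.).
#' @export
setClass("SpotTable",
    slots = c(spots = "data.frame", metadata = "list"),
    prototype = list(metadata = list()))

setValidity("SpotTable", function(object) {
    sp <- object@spots
    need <- c("x", "y", "z", "origin")
    miss <- setdiff(need, names(sp))
    if (length(miss))
        return(paste("missing spot columns:", paste(miss, collapse = ", ")))
    if (nrow(sp) && !all(sp$origin %in% c("detected", "random")))
        return("origin must be 'detected' or 'random'")
    TRUE
})
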