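# DNA-curtains analysis: events per DNA, two-colour colocalization,
# position histograms against sequence tracks, dwell-time survival with
# bootstrap, amplitudes and kymograms.

#' PositionHistogram: binding positions along the curtain DNA
#'
#' Fixed binning of binding positions: 24 bins of exactly 2 kbp from the
#' barrier (position 0), half-open \code{[lo, hi)}.
#'
#' @slot breaks numeric bin edges, kbp.
#' @slot counts events per bin.
#' @slot outOfRange events outside the binned range.
#' @slot normalization \code{"counts"} or \code{"density"}.
#' @export
setClass("PositionHistogram",
    slots = c(breaks = "numeric", counts = "numeric",
              outOfRange = "integer", normalization = "character"))

setValidity("PositionHistogram", function(object) {
    if (length(object@breaks) != length(object@counts) + 1L)
        return("breaks/counts length mismatch")
    w <- diff(object@breaks)
    if (any(abs(w - w[1]) > 1e-9)) return("bins must be uniform")
    TRUE
})

setMethod("show", "PositionHistogram", function(object) {
    cat("PositionHistogram:", length(object@counts), "bins of",
        diff(object@breaks)[1], "kbp;", sum(object@counts),
        "events in range,", object@outOfRange, "out of range\n")
})

#' Annotate a DNA substrate with motif sites and an A/T-content track
#'
#' @param sequence a \code{\link[Biostrings]{DNAString}} or character
#'   DNA sequence.
#' @param motif motif to scan (default the L1 endonuclease target site
#'   \code{TTTTTAA}); \code{NULL} to skip.
#' @param strand_policy \code{"both"} (default; curtains cannot
#'   distinguish strands) or \code{"forward"}.
#' @param at_window,at_step A/T-content sliding-window size and step, bp.
#' @return a \code{\linkS4class{GenomeTrack}}.
#' @export
genomeTrack <- function(sequence, motif = "TTTTTAA",
                        strand_policy = c("both", "forward"),
                        at_window = 500, at_step = 100) {
    strand_policy <- match.arg(strand_policy)
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    sites <- if (is.null(motif))
        data.frame(start = integer(0), end = integer(0),
                   strand = character(0))
    else findMotifSites(sequence, motif, strand_policy)
    at <- atContentTrack(sequence, window = min(at_window, length(sequence)),
                         step = at_step)
    new("GenomeTrack", sequence = sequence,
        motif = if (is.null(motif)) NA_character_ else motif,
        motifSites = sites, atWindow = as.integer(min(at_window,
                                                      length(sequence))),
        atStep = as.integer(at_step), atTrack = at)
}

#' Find exact motif occurrences in a DNA sequence
#'
#' All exact, possibly overlapping occurrences of the motif. Under the
#' \code{"both"} policy, occurrences of the reverse complement on the
#' given strand are also reported (annotated strand \code{"-"}); this is
#' the default because the curtain assay cannot distinguish strands.
#' Coordinates are 1-based on the given strand.
#'
#' @param sequence \code{DNAString} or character.
#' @param motif non-empty uppercase ACGT string.
#' @param strand_policy \code{"both"} or \code{"forward"}.
#' @return data.frame with \code{start}, \code{end}, \code{strand}.
#' @examples
#' findMotifSites("TTTTTAATTTTTAA", "TTTTTAA", "forward")
#' @export
findMotifSites <- function(sequence, motif,
                           strand_policy = c("both", "forward")) {
    strand_policy <- match.arg(strand_policy)
    if (!nzchar(motif)) stop("motif must be non-empty")
    if (grepl("[^ACGT]", motif))
        stop("motif must contain only uppercase A, C, G, T")
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    fwd <- Biostrings::matchPattern(motif, sequence)
    out <- data.frame(start = Biostrings::start(fwd),
                      end = Biostrings::end(fwd),
                      strand = rep("+", length(fwd)))
    if (strand_policy == "both") {
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(motif)))
        rev <- Biostrings::matchPattern(rc, sequence)
        out <- rbind(out,
                     data.frame(start = Biostrings::start(rev),
                                end = Biostrings::end(rev),
                                strand = rep("-", length(rev))))
    }
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Sliding-window A/T content
#'
#' Fraction of A or T per window of \code{window} bp advancing by
#' \code{step} bp; the window center coordinate is reported.
#'
#' @param sequence \code{DNAString} or character.
#' @param window window size, bp (> 0, <= sequence length).
#' @param step step size, bp.
#' @return data.frame with \code{start}, \code{center_bp}, \code{at}.
#' @export
atContentTrack <- function(sequence, window, step = window) {
    if (is.character(sequence))
        sequence <- Biostrings::DNAString(toupper(sequence))
    if (window <= 0) stop("window must be > 0")
    if (window > length(sequence))
        stop("window exceeds sequence length")
    freq <- Biostrings::letterFrequencyInSlidingView(
        sequence, window, c("A", "T"), as.prob = TRUE)
    at <- rowSums(freq)
    starts <- seq(1L, length(at), by = step)
    data.frame(start = starts,
               center_bp = starts + (window - 1) / 2,
               at = at[starts])
}

# condensate count: dual-labelled pairs (linked via partner_event) count
# once
#' @noRd
.condensateCount <- function(ev) {
    if (!"partner_event" %in% names(ev) || !nrow(ev))
        return(nrow(ev))
    paired <- !is.na(ev$partner_event)
    nrow(ev) - sum(paired) / 2
}

#' Binding events per DNA molecule, averaged across experiments
#'
#' Per experiment, the total number of condensate binding events divided
#' by the total number of DNA strands observed in its fields of view;
#' the mean and SEM are taken across experiments. Dual-labelled events
#' (two colours of one condensate) count once.
#'
#' @param table a \code{\linkS4class{CurtainEventTable}}.
#' @param dna_counts data.frame with \code{experiment}, \code{fov},
#'   \code{n_dna} (> 0) covering every fov present in the events.
#' @return list with \code{per_experiment} (data.frame), \code{mean} and
#'   \code{sem}.
#' @export
eventsPerDNA <- function(table, dna_counts) {
    ev <- curtainEvents(table)
    stopifnot(all(c("experiment", "fov", "n_dna") %in% names(dna_counts)))
    if (any(dna_counts$n_dna <= 0)) stop("n_dna must be > 0")
    have <- unique(ev[c("experiment", "fov")])
    key <- function(d) paste(d$experiment, d$fov)
    miss <- setdiff(key(have), key(dna_counts))
    if (length(miss))
        stop("missing dna_counts for fov(s): ", paste(miss, collapse = ", "))
    exps <- unique(dna_counts$experiment)
    per <- vapply(exps, function(e) {
        sube <- ev[ev$experiment == e, , drop = FALSE]
        nd <- sum(dna_counts$n_dna[dna_counts$experiment == e])
        .condensateCount(sube) / nd
    }, numeric(1))
    ms <- .meanSem(per)
    list(per_experiment = data.frame(experiment = exps,
                                     events_per_dna = unname(per)),
         mean = unname(ms["mean"]), sem = unname(ms["sem"]))
}

#' Normalize events per DNA by RNA concentration
#'
#' @param events_per_dna events per DNA strand.
#' @param rna_conc RNA concentration in nM (> 0).
#' @return events per DNA per nM RNA.
#' @export
normalizePerRNA <- function(events_per_dna, rna_conc) {
    if (any(rna_conc <= 0)) stop("rna_conc must be > 0")
    events_per_dna / rna_conc
}

#' Weighted average
#'
#' Weighted average with weights proportional to the number of DNA
#' strands observed per experiment (precision scales with observation
#' count).
#'
#' @param values numeric values.
#' @param weights nonnegative weights, same length.
#' @return weighted mean.
#' @export
weightedAverage <- function(values, weights) {
    stopifnot(length(values) == length(weights), all(weights >= 0),
              sum(weights) > 0)
    sum(values * weights) / sum(weights)
}

#' Two-colour colocalization fraction of curtain condensates
#'
#' Greedily pairs nearest cross-channel events on the same DNA molecule
#' within a position and a start-time threshold; the fraction is paired
#' condensates over all condensates, a matched pair counting as one
#' condensate. The pairing is symmetric under channel swap.
#'
#' @param table a \code{\linkS4class{CurtainEventTable}} with two
#'   channels.
#' @param max_distance maximal position offset, kbp.
#' @param max_time_offset maximal start-time offset, s (default one
#'   frame at the 500-ms illumination rate).
#' @return list with pooled \code{fraction}, \code{sem} (across
#'   experiments, or binomial for a single experiment) and
#'   \code{per_experiment}.
#' @export
colocalizationFraction <- function(table, max_distance = 1,
                                   max_time_offset = 0.5) {
    ev <- curtainEvents(table)
    chans <- unique(ev$channel)
    if (length(chans) < 2)
        stop("colocalization requires events in two channels")
    perExp <- function(sub) {
        paired <- 0L
        for (d in unique(sub$dna)) {
            a <- sub[sub$dna == d & sub$channel == chans[1], , drop = FALSE]
            b <- sub[sub$dna == d & sub$channel == chans[2], , drop = FALSE]
            if (!nrow(a) || !nrow(b)) next
            dpos <- abs(outer(a$position_kbp, b$position_kbp, "-"))
            dt <- abs(outer(a$t_start_s, b$t_start_s, "-"))
            ok <- dpos <= max_distance & dt <= max_time_offset
            dpos[!ok] <- Inf
            while (any(is.finite(dpos))) {
                ij <- arrayInd(which.min(dpos), dim(dpos))
                paired <- paired + 1L
                dpos[ij[1], ] <- Inf
                dpos[, ij[2]] <- Inf
            }
        }
        total <- nrow(sub) - paired   # a paired pair counts once
        c(paired = paired, total = total)
    }
    exps <- unique(ev$experiment)
    res <- t(vapply(exps, function(e)
        perExp(ev[ev$experiment == e, , drop = FALSE]), numeric(2)))
    frac <- res[, "paired"] / res[, "total"]
    pooled <- sum(res[, "paired"]) / sum(res[, "total"])
    sem <- if (length(exps) > 1) .meanSem(frac)["sem"] else
        sqrt(pooled * (1 - pooled) / sum(res[, "total"]))
    list(fraction = pooled, sem = unname(sem),
         per_experiment = data.frame(experiment = exps,
                                     fraction = unname(frac)))
}

#' Position histogram of binding events along the DNA
#'
#' Fixed 24 x 2-kbp binning from the barrier (position 0), half-open
#' bins \code{[lo, hi)}. Out-of-range events are counted, reported and
#' excluded.
#'
#' @param table a \code{\linkS4class{CurtainEventTable}} or a numeric
#'   vector of positions in kbp.
#' @param bin_kbp bin width, kbp.
#' @param n_bins number of bins.
#' @return a \code{\linkS4class{PositionHistogram}}.
#' @export
positionHistogram <- function(table, bin_kbp = 2, n_bins = 24) {
    pos <- if (is(table, "CurtainEventTable"))
        curtainEvents(table)$position_kbp else table
    breaks <- bin_kbp * (0:n_bins)
    idx <- findInterval(pos, breaks)
    inr <- idx >= 1L & idx <= n_bins & pos < breaks[n_bins + 1L]
    new("PositionHistogram", breaks = breaks,
        counts = as.numeric(tabulate(idx[inr], nbins = n_bins)),
        outOfRange = sum(!inr), normalization = "counts")
}

#' Permutation test of A/T-content enrichment at binding positions
#'
#' Score: mean A/T content (from the genome track) at the observed
#' binding positions. Null: the same statistic at positions resampled
#' uniformly along the substrate. One-sided permutation p-value
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}.
#'
#' @param positions_kbp observed binding positions, kbp (non-empty).
#' @param track a \code{\linkS4class{GenomeTrack}} with an A/T track.
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with \code{score}, \code{null_mean} and \code{p_value}.
#' @export
positionEnrichmentTest <- function(positions_kbp, track,
                                   n_permutations = 1000, seed = 1) {
    if (!length(positions_kbp)) stop("no positions supplied")
    if (n_permutations < 100) stop("n_permutations must be >= 100")
    at <- track@atTrack
    glen_kbp <- length(track@sequence) / 1000
    lookup <- function(pos_kbp) {
        i <- findInterval(pos_kbp * 1000, at$start)
        i[i < 1L] <- 1L
        mean(at$at[i])
    }
    obs <- lookup(positions_kbp)
    set.seed(.subSeed(seed, 7L))
    null <- vapply(seq_len(n_permutations), function(...)
        lookup(runif(length(positions_kbp), 0, glen_kbp)), numeric(1))
    list(score = obs, null_mean = mean(null),
         p_value = (1 + sum(null >= obs)) / (1 + n_permutations))
}

#' Kaplan-Meier survival of binding-event lifetimes
#'
#' Product-limit estimator over the event times with right censoring
#' (events persisting at movie end), with a percentile-bootstrap 95
#' percent band from resampling events with replacement. The band is
#' constrained to cover the point estimate.
#'
#' @param lifetimes positive dwell times, s.
#' @param censored logical, TRUE where the event was still bound at the
#'   end of the observation.
#' @param n_bootstrap number of bootstrap resamples (>= 100).
#' @param conf confidence level of the band.
#' @param seed integer seed.
#' @return a \code{\linkS4class{SurvivalCurve}}.
#' @examples
#' km <- kaplanMeier(c(1, 2, 3), c(FALSE, TRUE, FALSE), n_bootstrap = 100)
#' @export
kaplanMeier <- function(lifetimes, censored = rep(FALSE, length(lifetimes)),
                        n_bootstrap = 1000, conf = 0.95, seed = 1) {
    if (any(lifetimes <= 0)) stop("lifetimes must be > 0")
    if (all(censored)) stop("all observations censored: no events")
    if (n_bootstrap < 100) stop("n_bootstrap must be >= 100")
    sf <- survival::survfit(
        survival::Surv(lifetimes, !censored) ~ 1, conf.type = "none")
    tgrid <- c(0, sf$time)
    s <- c(1, sf$surv)
    set.seed(.subSeed(seed, 11L))
    n <- length(lifetimes)
    bs <- matrix(NA_real_, n_bootstrap, length(tgrid))
    for (b in seq_len(n_bootstrap)) {
        i <- sample.int(n, n, replace = TRUE)
        if (all(censored[i])) { bs[b, ] <- 1; next }
        sfb <- survival::survfit(
            survival::Surv(lifetimes[i], !censored[i]) ~ 1,
            conf.type = "none")
        fn <- stats::stepfun(sfb$time, c(1, sfb$surv), right = FALSE)
        bs[b, ] <- fn(tgrid)
    }
    alpha <- (1 - conf) / 2
    lo <- pmin(apply(bs, 2, quantile, alpha), s)
    hi <- pmax(apply(bs, 2, quantile, 1 - alpha), s)
    new("SurvivalCurve", time = tgrid, surv = s, lower = unname(lo),
        upper = unname(hi), nEvents = sum(!censored),
        nCensored = sum(censored), nBootstrap = as.integer(n_bootstrap))
}

#' Evaluate a survival curve at given times
#'
#' @param curve a \code{\linkS4class{SurvivalCurve}}.
#' @param t times, s.
#' @return survival probabilities S(t) (right-continuous step function).
#' @export
survivalAt <- function(curve, t) {
    fn <- stats::stepfun(curve@time[-1], curve@surv, right = FALSE)
    fn(t)
}

#' Mean fluorescence amplitude per binding event
#'
#' If the table carries per-frame rows (a \code{frame} column), each
#' event's amplitude is time-averaged first; otherwise the stored
#' amplitude is taken as the per-event time average. A per-condition
#' summary (mean, sd, n per channel) is reported.
#'
#' @param table a \code{\linkS4class{CurtainEventTable}} or a
#'   data.frame with \code{event}, \code{amplitude} and optionally
#'   \code{frame} and \code{channel}.
#' @return list with \code{per_event} and \code{summary}.
#' @export
meanEventAmplitude <- function(table) {
    ev <- if (is(table, "CurtainEventTable")) curtainEvents(table) else table
    if (!"amplitude" %in% names(ev)) stop("amplitude column required")
    if (!"event" %in% names(ev)) ev$event <- seq_len(nrow(ev))
    if (!"channel" %in% names(ev)) ev$channel <- "all"
    per <- if ("frame" %in% names(ev)) {
        agg <- aggregate(amplitude ~ event + channel, data = ev, FUN = mean)
        agg[order(agg$event), , drop = FALSE]
    } else ev[c("event", "channel", "amplitude")]
    summ <- do.call(rbind, lapply(split(per, per$channel), function(d)
        data.frame(channel = d$channel[1], mean = mean(d$amplitude),
                   sd = if (nrow(d) > 1) sd(d$amplitude) else 0,
                   n = nrow(d))))
    rownames(summ) <- NULL
    list(per_event = per, summary = summ)
}

#' Build a kymogram (position x time intensity matrix) for one DNA
#'
#' Each event paints its amplitude into the position bin it occupies for
#' the frames between its start and end times. Frames with no recorded
#' signal hold the background value; their indices are flagged in the
#' \code{"missing_frames"} attribute.
#'
#' @param events data.frame for one DNA molecule with
#'   \code{position_kbp}, \code{t_start_s}, \code{t_end_s},
#'   \code{amplitude}.
#' @param frame_interval uniform frame interval, s.
#' @param movie_length movie length, s.
#' @param genome_length_kbp DNA length, kbp.
#' @param bin_kbp position bin size, kbp.
#' @param background background value for empty pixels.
#' @return numeric matrix (position bins x frames) with the
#'   \code{"missing_frames"} attribute.
#' @export
buildKymogram <- function(events, frame_interval, movie_length,
                          genome_length_kbp, bin_kbp = 0.5,
                          background = 0) {
    .assertScalarNum(frame_interval, "frame_interval", positive = TRUE)
    n_frames <- ceiling(movie_length / frame_interval)
    n_pos <- ceiling(genome_length_kbp / bin_kbp)
    ky <- matrix(background, n_pos, n_frames)
    covered <- rep(FALSE, n_frames)
    for (i in seq_len(nrow(events))) {
        r <- min(n_pos, max(1L, 1L + floor(events$position_kbp[i] / bin_kbp)))
        f0 <- max(1L, 1L + floor(events$t_start_s[i] / frame_interval))
        f1 <- min(n_frames, ceiling(events$t_end_s[i] / frame_interval))
        if (f1 >= f0) {
            ky[r, f0:f1] <- ky[r, f0:f1] + events$amplitude[i]
            covered[f0:f1] <- TRUE
        }
    }
    attr(ky, "missing_frames") <- which(!covered)
    ky
}
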