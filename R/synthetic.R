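# Synthetic-data generators. Each generator records the parameters it drew
# from (the ground truth); recovery tests read truth only from that record.

#' Default mass-calibration standards
#'
#' Nominal masses (kDa) for the calibration standards commonly used in
#' mass photometry: BSA, ovalbumin and aldolase (tetramer, HMW gel
#' filtration kit). These are configuration values, not constants wired
#' into the calibration code.
#'
#' @return named numeric vector of masses in kDa.
#' @export
massStandards <- function() {
    c(BSA = 66.4, ovalbumin = 43, aldolase = 158)
}

#' Simulate mass-photometry landing events from an oligomer mixture
#'
#' Draws event masses from a mixture of normal components (one per
#' oligomeric species) and converts them to instrument contrasts through a
#' linear calibration, \code{contrast = (mass - intercept) / slope}. A
#' matching set of calibration-standard acquisitions is generated with the
#' same calibration and noise so that the calibration stage can be
#' exercised end to end.
#'
#' @param species data.frame with columns \code{mass} (kDa, > 0) and
#'   \code{fraction} (summing to 1 within 1e-9).
#' @param n_events number of landing events (>= 1).
#' @param mass_noise_sd Gaussian mass noise, kDa.
#' @param calibration numeric, \code{c(slope, intercept)} in kDa per
#'   contrast unit and kDa; slope must be non-zero.
#' @param standards named numeric vector of standard masses (kDa) for the
#'   emitted calibration set; see \code{\link{massStandards}}.
#' @param n_standard events per calibration standard.
#' @param seed integer seed; fixed seed gives identical output.
#' @return list with elements \code{events} (a
#'   \code{\linkS4class{MassEventSet}} of contrasts, carrying ground
#'   truth) and \code{standards} (named list of \code{MassEventSet}, one
#'   per standard).
#' @examples
#' sim <- simMassEvents(data.frame(mass = c(120, 240),
#'                                 fraction = c(0.3, 0.7)),
#'                      n_events = 1000, mass_noise_sd = 12,
#'                      calibration = c(slope = 1000, intercept = 0),
#'                      seed = 1)
#' groundTruth(sim$events)$species
#' @export
simMassEvents <- function(species, n_events, mass_noise_sd,
                          calibration = c(slope = 1000, intercept = 0),
                          standards = massStandards(),
                          n_standard = 5000, seed = 1) {
    stopifnot(is.data.frame(species),
              all(c("mass", "fraction") %in% names(species)))
    if (any(species$mass <= 0))
        stop("species masses must be strictly positive")
    if (abs(sum(species$fraction) - 1) > 1e-9)
        stop("species fractions must sum to 1 (tolerance 1e-9)")
    if (n_events < 1) stop("n_events must be >= 1")
    slope <- unname(calibration[1]); intercept <- unname(calibration[2])
    if (slope == 0) stop("calibration slope must be non-zero")
    .assertScalarNum(mass_noise_sd, "mass_noise_sd", nonneg = TRUE)

    set.seed(.subSeed(seed, 1L))
    comp <- sample.int(nrow(species), n_events, replace = TRUE,
                       prob = species$fraction)
    masses <- rnorm(n_events, mean = species$mass[comp], sd = mass_noise_sd)
    contrast <- (masses - intercept) / slope
    truth <- list(stage = "massphot", species = species,
                  mass_noise_sd = mass_noise_sd,
                  calibration = c(slope = slope, intercept = intercept),
                  component = comp)
    events <- new("MassEventSet", contrast = contrast, groundTruth = truth)

    std <- lapply(seq_along(standards), function(i) {
        set.seed(.subSeed(seed, 100L + i))
        m <- rnorm(n_standard, standards[i], mass_noise_sd)
        new("MassEventSet", contrast = (m - intercept) / slope,
            groundTruth = list(stage = "massphot_standard",
                               mass = unname(standards[i]),
                               calibration = c(slope = slope,
                                               intercept = intercept)))
    })
    names(std) <- names(standards)
    list(events = events, standards = std)
}

#' Simulate a fluorescence-anisotropy titration
#'
#' Generates raw anisotropy values for a protein titration against a fixed
#' labelled nucleic acid. Without a competitor the expected signal follows
#' the Hill isotherm
#' \deqn{r(P) = r_{free} + (r_{bound} - r_{free}) \frac{P^h}{K_d^h + P^h};}
#' with a competitor the bound fraction comes from the exact
#' coupled-equilibrium solver (\code{\link{solveCompetition}}, one shared
#' site, so \code{h} must be 1). Gaussian noise is added to every point.
#'
#' @param kd dissociation constant, nM (> 0).
#' @param h Hill coefficient (> 0).
#' @param r_free,r_bound anisotropy of free and fully bound label
#'   (must differ).
#' @param protein_concs protein concentrations, nM, nonnegative and
#'   strictly increasing; must be non-empty.
#' @param noise_sd Gaussian anisotropy noise.
#' @param competitor optional list with \code{kd} (nM) and \code{conc}
#'   (total competitor, nM) for a shared-site competition titration.
#' @param labeled_conc total labelled species, nM (used only with a
#'   competitor, where depletion is modelled exactly).
#' @param replicate replicate label.
#' @param seed integer seed.
#' @return a \code{\linkS4class{BindingCurve}} carrying ground truth.
#' @examples
#' bc <- simAnisotropyCurve(kd = 10, h = 1, protein_concs = 10^seq(-1, 3,
#'                          length.out = 12), noise_sd = 0, seed = 1)
#' @export
simAnisotropyCurve <- function(kd, h = 1, r_free = 0.05, r_bound = 0.20,
                               protein_concs, noise_sd = 0,
                               competitor = NULL, labeled_conc = 1,
                               replicate = "r1", seed = 1) {
    .assertScalarNum(kd, "kd", positive = TRUE)
    .assertScalarNum(h, "h", positive = TRUE)
    if (r_bound == r_free) stop("r_bound must differ from r_free")
    if (!length(protein_concs)) stop("protein concentration grid is empty")
    if (any(protein_concs < 0)) stop("concentrations must be nonnegative")
    .assertIncreasing(protein_concs, "protein_concs")

    if (is.null(competitor) || isTRUE(competitor$conc == 0)) {
        theta <- ifelse(protein_concs == 0, 0,
                        protein_concs^h / (kd^h + protein_concs^h))
    } else {
        if (h != 1)
            warning("competition solver assumes one shared site; h ignored")
        theta <- solveCompetition(kd_labeled = kd,
                                  kd_competitor = competitor$kd,
                                  labeled_total = labeled_conc,
                                  competitor_total = competitor$conc,
                                  protein_total = protein_concs)$bound_fraction
    }
    set.seed(.subSeed(seed, 2L))
    r <- r_free + (r_bound - r_free) * theta +
        rnorm(length(theta), 0, noise_sd)
    new("BindingCurve", conc = protein_concs, raw = r, blank = r_free,
        replicate = replicate,
        groundTruth = list(stage = "binding", kd = kd, h = h,
                           r_free = r_free, r_bound = r_bound,
                           noise_sd = noise_sd, competitor = competitor,
                           labeled_conc = labeled_conc,
                           theta = theta))
}

#' Simulate an RNA-titration hexamer-dissociation series
#'
#' Trimer fractions at increasing RNA concentration drawn from the
#' four-parameter cooperative Hill dissociation model
#' \eqn{p_3(c) = f_{min} + (f_{max} - f_{min}) c^h / (K_{1/2}^h + c^h)}
#' with additive Gaussian noise. Defaults describe a cooperative
#' (h = 2.1) dissociation over a 0-200 nM titration.
#'
#' @param K_half half-dissociation RNA concentration, nM.
#' @param h Hill coefficient.
#' @param f_min,f_max trimer fraction without RNA and at saturation.
#' @param conc RNA concentration grid, nM (including 0).
#' @param noise_sd Gaussian noise on the fraction.
#' @param seed integer seed.
#' @return data.frame with \code{conc}, \code{fraction} and the ground
#'   truth in the \code{"groundTruth"} attribute.
#' @export
simDissociationSeries <- function(K_half = 50, h = 2.1, f_min = 0.1,
                                  f_max = 0.9,
                                  conc = c(0, 5, 10, 25, 50, 100, 150, 200),
                                  noise_sd = 0.05, seed = 1) {
    .assertScalarNum(K_half, "K_half", positive = TRUE)
    .assertScalarNum(h, "h", positive = TRUE)
    p <- f_min + (f_max - f_min) *
        ifelse(conc == 0, 0, conc^h / (K_half^h + conc^h))
    set.seed(.subSeed(seed, 4L))
    out <- data.frame(conc = conc,
                      fraction = p + rnorm(length(conc), 0, noise_sd))
    attr(out, "groundTruth") <- list(stage = "massphot_titration",
                                     K_half = K_half, h = h,
                                     f_min = f_min, f_max = f_max,
                                     noise_sd = noise_sd)
    out
}

#' Simulate a synthetic DNA substrate
#'
#' Random sequence of configurable G+C content with optional motif
#' instances planted at given positions (overwriting the background
#' sequence). Supplying a vector of G+C values creates equal-length
#' blocks of varying composition, emulating the domain-scale A/T-content
#' structure of real genomes (i.i.d. uniform sequences have almost no
#' window-level A/T variance).
#'
#' @param length_bp sequence length.
#' @param gc G+C fraction of the background; a vector gives one value
#'   per equal-length block.
#' @param motif optional motif string to plant (uppercase ACGT).
#' @param motif_positions 1-based start positions for planted copies.
#' @param seed integer seed.
#' @return a \code{\link[Biostrings]{DNAString}}.
#' @export
simGenome <- function(length_bp, gc = 0.5, motif = NULL,
                      motif_positions = integer(0), seed = 1) {
    .assertScalarNum(length_bp, "length_bp", positive = TRUE)
    set.seed(.subSeed(seed, 3L))
    block <- rep(gc, each = ceiling(length_bp / length(gc)))[seq_len(length_bp)]
    bases <- character(length_bp)
    for (g in unique(block)) {
        i <- which(block == g)
        p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
        bases[i] <- sample(names(p), length(i), replace = TRUE, prob = p)
    }
    if (!is.null(motif) && length(motif_positions)) {
        mchars <- strsplit(motif, "")[[1]]
        for (s in motif_positions) {
            if (s < 1 || s + length(mchars) - 1 > length_bp)
                stop("planted motif outside sequence")
            bases[s:(s + length(mchars) - 1)] <- mchars
        }
    }
    Biostrings::DNAString(paste(bases, collapse = ""))
}

#' Simulate a DNA-curtains binding-event table
#'
#' Per-DNA event counts are Poisson; binding positions are drawn from a
#' configurable sequence bias over the substrate; dwell times are
#' exponential and right-censored at movie end. A configurable fraction of
#' events is dual-labelled: the event appears in both colour channels at
#' the same position and time, linked through \code{partner_event}.
#' Random sub-streams are split per DNA molecule, so increasing
#' \code{n_dna} does not perturb events on earlier molecules.
#'
#' @param genome a \code{\linkS4class{GenomeTrack}} (required for the
#'   sequence-biased modes) or a plain length in bp for uniform positions.
#' @param n_dna number of DNA molecules.
#' @param events_per_dna_mean Poisson mean events per DNA.
#' @param position_bias \code{"uniform"}, \code{"at_weighted"} (per-bp
#'   weight \code{bias_weight} at A/T bases, 1 elsewhere) or
#'   \code{"motif_weighted"} (weight \code{bias_weight} inside motif
#'   sites, 1 elsewhere).
#' @param bias_weight multiplicative weight of the favoured positions.
#' @param dwell_mean mean dwell time, s (> 0).
#' @param movie_length movie length, s (> 0).
#' @param start_mode \code{"zero"}: all events start at t = 0 (lifetimes
#'   censored at the movie length); \code{"uniform"}: start times uniform
#'   over the movie.
#' @param dual_label_prob probability that an event carries both colours.
#' @param amplitude_mean,amplitude_sd Gaussian amplitude model.
#' @param experiment experiment label; \code{fov} label scheme is one fov
#'   per experiment here (splitting is an analysis-side concern).
#' @param seed integer seed.
#' @return a \code{\linkS4class{CurtainEventTable}} carrying ground truth.
#' @export
simCurtainEvents <- function(genome, n_dna = 20, events_per_dna_mean = 5,
                             position_bias = c("uniform", "at_weighted",
                                               "motif_weighted"),
                             bias_weight = 1, dwell_mean = 100,
                             movie_length = 600,
                             start_mode = c("zero", "uniform"),
                             dual_label_prob = 0, amplitude_mean = 100,
                             amplitude_sd = 10, experiment = "exp1",
                             seed = 1) {
    position_bias <- match.arg(position_bias)
    start_mode <- match.arg(start_mode)
    .assertScalarNum(dwell_mean, "dwell_mean", positive = TRUE)
    .assertScalarNum(movie_length, "movie_length", positive = TRUE)

    if (is(genome, "GenomeTrack")) {
        seqchar <- as.character(genome@sequence)
        glen <- nchar(seqchar)
    } else {
        glen <- as.integer(genome)
        if (glen <= 0) stop("genome length must be > 0")
        seqchar <- NULL
        if (position_bias != "uniform")
            stop("sequence-biased positions require a GenomeTrack")
    }

    w <- switch(position_bias,
        uniform = NULL,
        at_weighted = {
            b <- strsplit(seqchar, "")[[1]]
            ifelse(b %in% c("A", "T"), bias_weight, 1)
        },
        motif_weighted = {
            sites <- motifSites(genome)
            if (!nrow(sites))
                stop("motif_weighted bias needs motif sites in the GenomeTrack")
            wv <- rep(1, glen)
            for (i in seq_len(nrow(sites)))
                wv[sites$start[i]:sites$end[i]] <- bias_weight
            wv
        })

    rows <- vector("list", n_dna)
    eid <- 0L
    for (d in seq_len(n_dna)) {
        set.seed(.subSeed(seed, 1000L + d))
        k <- rpois(1, events_per_dna_mean)
        if (k == 0) next
        pos_bp <- if (is.null(w)) runif(k, 0, glen) else
            sample.int(glen, k, replace = TRUE, prob = w) - runif(k)
        t0 <- if (start_mode == "zero") rep(0, k) else
            runif(k, 0, movie_length)
        dwell <- rexp(k, rate = 1 / dwell_mean)
        t1 <- pmin(t0 + dwell, movie_length)
        cens <- (t0 + dwell) > movie_length
        dual <- runif(k) < dual_label_prob
        amp <- rnorm(k, amplitude_mean, amplitude_sd)
        ids <- eid + seq_len(k)
        eid <- eid + k
        base <- data.frame(event = ids, experiment = experiment,
                           fov = "fov1", dna = d,
                           position_kbp = pos_bp / 1000,
                           t_start_s = t0, t_end_s = t1, censored = cens,
                           channel = "green", amplitude = amp,
                           partner_event = NA_integer_)
        if (any(dual)) {
            part <- base[dual, , drop = FALSE]
            pids <- eid + seq_len(nrow(part))
            eid <- eid + nrow(part)
            base$partner_event[dual] <- pids
            part$partner_event <- part$event
            part$event <- pids
            part$channel <- "red"
            part$amplitude <- rnorm(nrow(part), amplitude_mean, amplitude_sd)
            base <- rbind(base, part)
        }
        rows[[d]] <- base
    }
    ev <- do.call(rbind, rows)
    if (is.null(ev))
        ev <- data.frame(event = integer(0), experiment = character(0),
                         fov = character(0), dna = integer(0),
                         position_kbp = numeric(0), t_start_s = numeric(0),
                         t_end_s = numeric(0), censored = logical(0),
                         channel = character(0), amplitude = numeric(0),
                         partner_event = integer(0))
    rownames(ev) <- NULL
    new("CurtainEventTable", events = ev, movieLength = movie_length,
        genomeLengthKbp = glen / 1000,
        groundTruth = list(stage = "curtains", n_dna = n_dna,
                           events_per_dna_mean = events_per_dna_mean,
                           position_bias = position_bias,
                           bias_weight = bias_weight,
                           dwell_mean = dwell_mean,
                           movie_length = movie_length,
                           dual_label_prob = dual_label_prob,
                           amplitude_mean = amplitude_mean,
                           amplitude_sd = amplitude_sd))
}

# Ellipse ROI layout on a regular grid, guaranteed disjoint.
#' @noRd
.gridLayout <- function(n_cells, ny, nx) {
    nc <- ceiling(sqrt(n_cells))
    nr <- ceiling(n_cells / nc)
    th <- ny / nr; tw <- nx / nc
    i <- seq_len(n_cells) - 1L
    data.frame(cy = (i %/% nc + 0.5) * th,
               cx = (i %% nc + 0.5) * tw,
               ry = 0.42 * th, rx = 0.42 * tw)
}

#' Simulate multi-channel 3D images of cells with diffraction-limited puncta
#'
#' Renders a 3-channel (\code{dna}, \code{protein}, \code{rna}) image
#' stack containing \code{n_cells} disjoint elliptical cells (2D labelled
#' ROI mask), a nuclear ellipsoid per cell in the DNA channel, and
#' RNA-channel puncta rendered as isotropic 3D Gaussians. A configurable
#' fraction of RNA puncta also receives a protein-channel Gaussian at the
#' same position (true colocalization). Background is Gaussian noise.
#'
#' @param n_cells number of cells.
#' @param shape integer c(z, y, x) voxel dimensions.
#' @param n_spots_per_cell spots per cell (exact count, or Poisson mean
#'   when \code{spot_count_model = "poisson"}).
#' @param spot_count_model \code{"fixed"} or \code{"poisson"}.
#' @param psf_sigma isotropic PSF sigma in voxels (>= 0.5).
#' @param colocalized_fraction probability an RNA spot carries protein.
#' @param intensity named per-channel peak amplitudes above background.
#' @param background_mean,background_sd Gaussian background model.
#' @param nucleus_frac nuclear semi-axes as a fraction of the cell's.
#' @param placement \code{"cytoplasm"} (spots outside the nucleus, the
#'   compartment analysed downstream) or \code{"anywhere"}.
#' @param roi_layout optional data.frame \code{cx, cy, rx, ry} (voxel
#'   units) overriding the default disjoint grid layout; overlapping
#'   ellipses are rejected.
#' @param seed integer seed; one sub-stream per cell.
#' @return list with \code{images} (named list of 3D arrays, dim
#'   \code{c(z, y, x)}), \code{mask} (y-by-x integer label matrix),
#'   \code{truth} (data.frame: one row per rendered spot with voxel
#'   position, cell, compartment and \code{colocalized} flag) and
#'   \code{params}.
#' @export
simSpotImages <- function(n_cells = 10, shape = c(16, 128, 128),
                          n_spots_per_cell = 15,
                          spot_count_model = c("fixed", "poisson"),
                          psf_sigma = 1.5, colocalized_fraction = 0,
                          intensity = c(dna = 300, protein = 500, rna = 500),
                          background_mean = 100, background_sd = 20,
                          nucleus_frac = 0.45,
                          placement = c("cytoplasm", "anywhere"),
                          roi_layout = NULL, seed = 1) {
    spot_count_model <- match.arg(spot_count_model)
    placement <- match.arg(placement)
    if (psf_sigma < 0.5) stop("psf_sigma must be >= 0.5 voxel")
    nz <- shape[1]; ny <- shape[2]; nx <- shape[3]

    lay <- if (is.null(roi_layout)) .gridLayout(n_cells, ny, nx) else roi_layout
    if (nrow(lay) != n_cells) stop("roi_layout must have one row per cell")

    # labelled ROI mask; overlapping cells are an error
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    mask <- matrix(0L, ny, nx)
    for (k in seq_len(n_cells)) {
        inside <- ((yy - lay$cy[k]) / lay$ry[k])^2 +
                  ((xx - lay$cx[k]) / lay$rx[k])^2 <= 1
        if (any(mask[inside] != 0L)) stop("cell ROIs overlap")
        mask[inside] <- k
    }

    # channel arrays are kept as plain locals so that rendering
    # sub-assignments run in place rather than copying 30+ MB per spot
    set.seed(.subSeed(seed, 11L))
    chDna <- array(rnorm(nz * ny * nx, background_mean, background_sd),
                   dim = c(nz, ny, nx))
    set.seed(.subSeed(seed, 12L))
    chProt <- array(rnorm(nz * ny * nx, background_mean, background_sd),
                    dim = c(nz, ny, nx))
    set.seed(.subSeed(seed, 13L))
    chRna <- array(rnorm(nz * ny * nx, background_mean, background_sd),
                   dim = c(nz, ny, nx))

    # nuclear ellipsoids in the DNA channel
    zc <- (nz + 1) / 2; rz <- nucleus_frac * nz / 2
    for (k in seq_len(n_cells)) {
        nry <- nucleus_frac * lay$ry[k]; nrx <- nucleus_frac * lay$rx[k]
        y0 <- max(1, floor(lay$cy[k] - nry)); y1 <- min(ny, ceiling(lay$cy[k] + nry))
        x0 <- max(1, floor(lay$cx[k] - nrx)); x1 <- min(nx, ceiling(lay$cx[k] + nrx))
        z0 <- max(1, floor(zc - rz)); z1 <- min(nz, ceiling(zc + rz))
        zi <- z0:z1; yi <- y0:y1; xi <- x0:x1
        zt <- ((zi - zc) / rz)^2
        ytq <- ((yi - lay$cy[k]) / nry)^2
        xtq <- ((xi - lay$cx[k]) / nrx)^2
        inb <- outer(outer(zt, ytq, `+`), xtq, `+`) <= 1
        add <- intensity["dna"] * inb
        chDna[zi, yi, xi] <- chDna[zi, yi, xi] + add
    }

    .inNucleus <- function(k, z, y, x) {
        nry <- nucleus_frac * lay$ry[k]; nrx <- nucleus_frac * lay$rx[k]
        ((z - zc) / rz)^2 + ((y - lay$cy[k]) / nry)^2 +
            ((x - lay$cx[k]) / nrx)^2 <= 1
    }
    rpsf <- ceiling(4 * psf_sigma)
    .spotPatch <- function(z, y, x, amp) {
        zi <- max(1, round(z) - rpsf):min(nz, round(z) + rpsf)
        yi <- max(1, round(y) - rpsf):min(ny, round(y) + rpsf)
        xi <- max(1, round(x) - rpsf):min(nx, round(x) + rpsf)
        list(zi = zi, yi = yi, xi = xi,
             g = amp * outer(outer(exp(-(zi - z)^2 / (2 * psf_sigma^2)),
                                   exp(-(yi - y)^2 / (2 * psf_sigma^2))),
                             exp(-(xi - x)^2 / (2 * psf_sigma^2))))
    }

    truth <- vector("list", n_cells)
    for (k in seq_len(n_cells)) {
        set.seed(.subSeed(seed, 5000L + k))
        nk <- if (spot_count_model == "poisson")
            rpois(1, n_spots_per_cell) else n_spots_per_cell
        if (nk == 0) next
        zs <- ys <- xs <- numeric(nk); compart <- character(nk)
        for (i in seq_len(nk)) {
            repeat {
                u <- runif(1); a <- runif(1, 0, 2 * pi)
                y <- lay$cy[k] + 0.92 * lay$ry[k] * sqrt(u) * sin(a)
                x <- lay$cx[k] + 0.92 * lay$rx[k] * sqrt(u) * cos(a)
                z <- runif(1, 2, nz - 1)
                nuc <- .inNucleus(k, z, y, x)
                if (placement == "anywhere" || !nuc) break
            }
            zs[i] <- z; ys[i] <- y; xs[i] <- x
            compart[i] <- if (.inNucleus(k, z, y, x)) "nuclear" else "cytoplasmic"
        }
        coloc <- runif(nk) < colocalized_fraction
        for (i in seq_len(nk)) {
            p <- .spotPatch(zs[i], ys[i], xs[i], intensity["rna"])
            chRna[p$zi, p$yi, p$xi] <- chRna[p$zi, p$yi, p$xi] + p$g
            if (coloc[i]) {
                p <- .spotPatch(zs[i], ys[i], xs[i], intensity["protein"])
                chProt[p$zi, p$yi, p$xi] <- chProt[p$zi, p$yi, p$xi] + p$g
            }
        }
        truth[[k]] <- data.frame(cell = k, z = zs, y = ys, x = xs,
                                 compartment = compart, colocalized = coloc)
    }
    truth <- if (all(vapply(truth, is.null, logical(1))))
        data.frame(cell = integer(0), z = numeric(0), y = numeric(0),
                   x = numeric(0), compartment = character(0),
                   colocalized = logical(0))
    else do.call(rbind, truth)
    rownames(truth) <- NULL
    list(images = list(dna = chDna, protein = chProt, rna = chRna),
         mask = mask, truth = truth,
         params = list(stage = "spots", n_cells = n_cells, shape = shape,
                       n_spots_per_cell = n_spots_per_cell,
                       psf_sigma = psf_sigma,
                       colocalized_fraction = colocalized_fraction,
                       intensity = intensity,
                       background_mean = background_mean,
                       background_sd = background_sd, seed = seed))
}
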