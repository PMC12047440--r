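# Cell-image analysis: 3D LoG spot detection, ROI assignment,
# nuclear/cytoplasmic classification, count-matched randomized null,
# median-normalized cross-channel intensities and the Mann-Whitney
# comparison, and puncta-chromatin colocalization.

# spherical aperture offsets (dz, dy, dx) for radius r
#' @noRd
.apertureOffsets <- function(r) {
    g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
    g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' 3D multiscale Laplacian-of-Gaussian spot detection
#'
#' Computes the scale-normalized negative LoG response at each scale,
#' collects 26-connected local maxima above a robust-noise threshold,
#' and merges duplicate detections across scales and within one blob
#' radius (greedy, strongest response first, minimum separation
#' \code{2 * sigma}). The threshold is expressed in units of the robust
#' noise of the response (median absolute deviation) so it transfers
#' across intensity scales. Coordinates are integer voxels (sub-voxel
#' localization is not attempted).
#'
#' @param image 3D numeric array, dim \code{c(z, y, x)}, or the list
#'   returned by \code{\link{simSpotImages}} (then \code{channel}
#'   selects the array).
#' @param channel channel name when \code{image} is a list.
#' @param sigmas LoG scales in voxels (default 0.75x, 1x and 1.5x
#'   \code{psf_sigma}).
#' @param psf_sigma nominal PSF sigma, voxels.
#' @param threshold detection threshold in robust-noise (MAD) units of
#'   the LoG response.
#' @return a \code{\linkS4class{SpotTable}} with origin
#'   \code{"detected"}; empty input gives an empty table.
#' @export
detectSpots <- function(image, channel = "rna", sigmas = NULL,
                        psf_sigma = 1.5, threshold = 6) {
    if (is.list(image) && !is.null(image$images))
        image <- image$images[[channel]]
    else if (is.list(image)) image <- image[[channel]]
    if (!is.array(image) || length(dim(image)) != 3)
        stop("image must be a 3D array (z, y, x)")
    if (is.null(sigmas)) sigmas <- psf_sigma * c(0.75, 1, 1.5)
    if (any(sigmas <= 0)) stop("sigmas must be > 0")
    dims <- as.integer(dim(image))
    storage.mode(image) <- "double"
    cand <- list()
    for (s in sigmas) {
        resp <- .logResponse3d(image, dims, s)
        # robust noise scale from a strided subsample (the response is
        # smooth; a ~250k-voxel subsample estimates the MAD to <1%)
        stride <- max(1L, length(resp) %/% 262144L)
        thr <- threshold * mad(resp[seq(1L, length(resp), by = stride)])
        pk <- .localMaxima3d(resp, dims, thr)
        if (nrow(pk))
            cand[[length(cand) + 1L]] <-
                data.frame(z = pk[, "z"], y = pk[, "y"], x = pk[, "x"],
                           sigma = s, response = pk[, "value"])
    }
    if (!length(cand)) {
        sp <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                         sigma = numeric(0), response = numeric(0),
                         origin = character(0))
        return(new("SpotTable", spots = sp,
                   metadata = list(sigmas = sigmas, threshold = threshold,
                                   dim = dims)))
    }
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$response), , drop = FALSE]
    keep <- logical(nrow(cand))
    kz <- ky <- kx <- ks <- numeric(0)
    for (i in seq_len(nrow(cand))) {
        if (length(kz)) {
            d2 <- (kz - cand$z[i])^2 + (ky - cand$y[i])^2 +
                  (kx - cand$x[i])^2
            minsep <- (2 * pmax(ks, cand$sigma[i]))^2
            if (any(d2 <= minsep)) next
        }
        keep[i] <- TRUE
        kz <- c(kz, cand$z[i]); ky <- c(ky, cand$y[i])
        kx <- c(kx, cand$x[i]); ks <- c(ks, cand$sigma[i])
    }
    sp <- cand[keep, , drop = FALSE]
    sp$origin <- "detected"
    rownames(sp) <- NULL
    new("SpotTable", spots = sp,
        metadata = list(sigmas = sigmas, threshold = threshold,
                        dim = dims))
}

#' Assign spots to labelled cell ROIs
#'
#' Each spot takes the ROI label of the mask pixel under its (y, x)
#' position; spots on background (label 0) are dropped and counted in
#' the metadata.
#'
#' @param spots a \code{\linkS4class{SpotTable}}.
#' @param mask y-by-x integer label matrix (0 = background).
#' @return the spot table with an \code{roi} column, background spots
#'   removed.
#' @export
assignROIs <- function(spots, mask) {
    sp <- spotData(spots)
    md <- spots@metadata
    if (!is.null(md$dim) && !all(dim(mask) == md$dim[2:3]))
        stop("mask shape does not match the image x-y shape")
    if (!nrow(sp)) {
        sp$roi <- integer(0)
        spots@spots <- sp
        return(spots)
    }
    sp$roi <- mask[cbind(round(sp$y), round(sp$x))]
    dropped <- sum(sp$roi == 0L)
    sp <- sp[sp$roi > 0L, , drop = FALSE]
    rownames(sp) <- NULL
    spots@spots <- sp
    spots@metadata$dropped_outside_roi <- dropped
    spots
}

# mean channel intensity over the spherical aperture, per spot
#' @noRd
.apertureIntensity <- function(sp, image, aperture) {
    off <- .apertureOffsets(aperture)
    dims <- dim(image)
    vapply(seq_len(nrow(sp)), function(i) {
        z <- round(sp$z[i]) + off$dz
        y <- round(sp$y[i]) + off$dy
        x <- round(sp$x[i]) + off$dx
        ok <- z >= 1 & z <= dims[1] & y >= 1 & y <= dims[2] &
              x >= 1 & x <= dims[3]
        mean(image[cbind(z[ok], y[ok], x[ok])])
    }, numeric(1))
}

#' Classify spots as nuclear or cytoplasmic
#'
#' Per-spot mean nuclear-channel intensity over the aperture,
#' thresholded by Otsu's method across all spots of the image. Nuclear
#' spots are flagged; downstream normalization excludes them (nascent
#' transcripts in the nucleus are not informative for cytoplasmic
#' assembly).
#'
#' @param spots a \code{\linkS4class{SpotTable}}.
#' @param image 3D nuclear-channel array or \code{simSpotImages} result.
#' @param nuclear_channel channel name when a list is given.
#' @param aperture aperture radius, voxels.
#' @return the spot table with \code{nuclear_intensity} and
#'   \code{compartment} columns.
#' @export
classifyCompartment <- function(spots, image, nuclear_channel = "dna",
                                aperture = 2) {
    if (is.list(image) && !is.null(image$images))
        image <- image$images[[nuclear_channel]]
    sp <- spotData(spots)
    if (!nrow(sp)) {
        sp$nuclear_intensity <- numeric(0)
        sp$compartment <- character(0)
        spots@spots <- sp
        return(spots)
    }
    sp$nuclear_intensity <- .apertureIntensity(sp, image, aperture)
    thr <- .otsuThreshold(sp$nuclear_intensity)
    sp$compartment <- ifelse(sp$nuclear_intensity > thr, "nuclear",
                             "cytoplasmic")
    if (all(sp$compartment == "nuclear"))
        warning("all spots classified nuclear; downstream input is empty")
    spots@spots <- sp
    spots@metadata$nuclear_threshold <- thr
    spots
}

#' Count-matched randomized spot null
#'
#' For every ROI, draws exactly as many random (y, x) positions as that
#' ROI has detected spots, uniformly from the ROI's own pixel set; each
#' z coordinate is drawn uniformly from the multiset of detected-spot z
#' values of the whole image (the z distribution is an image-level
#' property). Deterministic under the seed.
#'
#' @param spots a ROI-assigned \code{\linkS4class{SpotTable}} (detected).
#' @param mask y-by-x integer label mask.
#' @param seed integer seed.
#' @return a \code{\linkS4class{SpotTable}} with origin \code{"random"}.
#' @export
randomizeSpots <- function(spots, mask, seed = 1) {
    sp <- spotData(spots)
    sp <- sp[sp$origin == "detected", , drop = FALSE]
    if (!"roi" %in% names(sp))
        stop("spots must be ROI-assigned first (assignROIs)")
    set.seed(.subSeed(seed, 21L))
    zpool <- sp$z
    out <- lapply(sort(unique(sp$roi)), function(k) {
        n <- sum(sp$roi == k)
        pix <- which(mask == k, arr.ind = TRUE)
        if (!nrow(pix)) stop("ROI ", k, " has no pixels")
        i <- sample.int(nrow(pix), n, replace = TRUE)
        data.frame(z = sample(zpool, n, replace = TRUE),
                   y = as.numeric(pix[i, 1]), x = as.numeric(pix[i, 2]),
                   sigma = NA_real_, response = NA_real_,
                   origin = "random", roi = k)
    })
    out <- if (length(out)) do.call(rbind, out) else
        data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                   sigma = numeric(0), response = numeric(0),
                   origin = character(0), roi = integer(0))
    keep <- intersect(names(out), names(sp))
    new("SpotTable", spots = rbind(sp[keep], out[keep]),
        metadata = spots@metadata)
}

#' Measure and median-normalize spot intensities in a target channel
#'
#' Mean intensity over a fixed spherical aperture per spot (detected and
#' random) in the target channel; each spot's intensity is divided by
#' the median intensity of the random spots of its own ROI. ROIs whose
#' random median is 0 are excluded and reported.
#'
#' @param spots a \code{\linkS4class{SpotTable}} containing detected and
#'   random spots (see \code{\link{randomizeSpots}}).
#' @param image 3D array of the target channel or \code{simSpotImages}
#'   result.
#' @param channel channel name when a list is given.
#' @param aperture aperture radius, voxels.
#' @return the spot table with \code{intensity} and
#'   \code{normalized_intensity} columns; excluded ROIs in
#'   \code{metadata$excluded_rois}.
#' @export
measureSpotIntensity <- function(spots, image, channel = "protein",
                                 aperture = 2) {
    if (is.list(image) && !is.null(image$images))
        image <- image$images[[channel]]
    sp <- spotData(spots)
    if (!all(c("detected", "random") %in% sp$origin))
        stop("both detected and random spots are required")
    sp$intensity <- .apertureIntensity(sp, image, aperture)
    med <- tapply(sp$intensity[sp$origin == "random"],
                  sp$roi[sp$origin == "random"], median)
    bad <- names(med)[med == 0]
    if (length(bad)) {
        sp <- sp[!sp$roi %in% as.integer(bad), , drop = FALSE]
        warning("excluded ROI(s) with zero random median: ",
                paste(bad, collapse = ", "))
    }
    sp$normalized_intensity <- sp$intensity /
        as.numeric(med[as.character(sp$roi)])
    spots@spots <- sp
    spots@metadata$excluded_rois <- as.integer(bad)
    spots
}

#' Mann-Whitney comparison of detected vs random normalized intensities
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on the pooled
#' normalized intensities of detected spots against the randomized null.
#'
#' @param spots a measured \code{\linkS4class{SpotTable}} (see
#'   \code{\link{measureSpotIntensity}}).
#' @return list with \code{U}, \code{p_value} and group sizes.
#' @export
compareSpotIntensity <- function(spots) {
    sp <- spotData(spots)
    if (!"normalized_intensity" %in% names(sp))
        stop("spots must be measured first (measureSpotIntensity)")
    a <- sp$normalized_intensity[sp$origin == "detected"]
    b <- sp$normalized_intensity[sp$origin == "random"]
    if (length(a) < 2 || length(b) < 2)
        stop("each group needs at least 2 spots")
    wt <- wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
    list(U = unname(wt$statistic), p_value = wt$p.value,
         n_detected = length(a), n_random = length(b))
}

#' Fraction of puncta colocalized with chromatin, per cell
#'
#' A punctum colocalizes if its center falls inside the (optionally
#' dilated) chromatin mask. Cells without puncta have an undefined
#' fraction and are excluded (and counted).
#'
#' @param puncta a ROI-assigned \code{\linkS4class{SpotTable}}.
#' @param chromatin_mask logical y-by-x matrix (or 0/1).
#' @param dilation square structuring radius in pixels (default 0).
#' @return list with \code{per_cell} (data.frame \code{roi},
#'   \code{n_puncta}, \code{fraction}) and \code{n_cells_excluded}.
#' @export
chromatinColocalizationFraction <- function(puncta, chromatin_mask,
                                            dilation = 0) {
    sp <- spotData(puncta)
    sp <- sp[sp$origin == "detected", , drop = FALSE]
    if (!"roi" %in% names(sp)) stop("puncta must be ROI-assigned")
    m <- chromatin_mask != 0
    if (dilation > 0) {
        md <- m
        ny <- nrow(m); nx <- ncol(m)
        for (dy in -dilation:dilation) for (dx in -dilation:dilation) {
            ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
            xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
            md <- md | m[ys, xs]
        }
        m <- md
    }
    inmask <- m[cbind(round(sp$y), round(sp$x))]
    per <- do.call(rbind, lapply(sort(unique(sp$roi)), function(k) {
        i <- sp$roi == k
        data.frame(roi = k, n_puncta = sum(i),
                   fraction = mean(inmask[i]))
    }))
    list(per_cell = per, n_cells_excluded = 0L)
}

#' Puncta counts per cell
#'
#' @param spots a ROI-assigned \code{\linkS4class{SpotTable}}.
#' @param n_cells optionally, the total number of cells, so cells with
#'   zero detected puncta are reported as 0.
#' @return data.frame with \code{roi} and \code{count}.
#' @export
countPuncta <- function(spots, n_cells = NULL) {
    sp <- spotData(spots)
    sp <- sp[sp$origin == "detected", , drop = FALSE]
    if (!"roi" %in% names(sp)) stop("spots must be ROI-assigned")
    tb <- table(factor(sp$roi,
                       levels = if (is.null(n_cells)) sort(unique(sp$roi))
                                else seq_len(n_cells)))
    data.frame(roi = as.integer(names(tb)), count = as.integer(tb))
}

#' Full spot colocalization pipeline
#'
#' Detect (RNA channel) -> assign ROIs -> optionally classify and keep
#' cytoplasmic spots -> count-matched randomization -> aperture
#' measurement and per-ROI median normalization (target channel) ->
#' two-sided Mann-Whitney test. Deterministic given (image, mask, seed).
#'
#' @param images named list of 3D channel arrays (or
#'   \code{simSpotImages} result).
#' @param mask labelled ROI mask (taken from the \code{simSpotImages}
#'   result if missing).
#' @param detect_channel,measure_channel channel names.
#' @param classify run nuclear/cytoplasmic classification (needs a
#'   \code{dna} channel) and keep only cytoplasmic spots.
#' @param psf_sigma,sigmas,threshold,aperture see the stage functions.
#' @param seed integer seed for the randomization.
#' @return list with \code{spots} (measured \code{SpotTable}),
#'   \code{test} (U, p) and \code{counts} per cell.
#' @export
spotPipeline <- function(images, mask = NULL, detect_channel = "rna",
                         measure_channel = "protein", classify = FALSE,
                         psf_sigma = 1.5, sigmas = NULL, threshold = 6,
                         aperture = 2, seed = 1) {
    if (!is.null(images$images)) {
        if (is.null(mask)) mask <- images$mask
        images <- images$images
    }
    det <- detectSpots(images[[detect_channel]], psf_sigma = psf_sigma,
                       sigmas = sigmas, threshold = threshold)
    det <- assignROIs(det, mask)
    if (classify) {
        det <- classifyCompartment(det, images$dna)
        sp <- spotData(det)
        det@spots <- sp[sp$compartment == "cytoplasmic", , drop = FALSE]
    }
    both <- randomizeSpots(det, mask, seed = seed)
    both <- measureSpotIntensity(both, images[[measure_channel]],
                                 aperture = aperture)
    list(spots = both, test = compareSpotIntensity(both),
         counts = countPuncta(both))
}
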