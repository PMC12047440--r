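# 3D spot detection, ROI assignment, compartment classification,
# randomized null, normalization and the colocalization statistics.

test_that("LoG detection finds rendered spots with high precision and recall", {
    sim <- simSpotImages(n_cells = 10, shape = c(24, 160, 160),
                         n_spots_per_cell = 5, psf_sigma = 1.5,
                         intensity = c(dna = 300, protein = 500, rna = 200),
                         background_sd = 20, seed = 51)
    det <- spotData(detectSpots(sim$images$rna, psf_sigma = 1.5))
    truth <- sim$truth
    # match detections to truth within 2 voxels
    d2 <- outer(det$z, truth$z, "-")^2 + outer(det$y, truth$y, "-")^2 +
        outer(det$x, truth$x, "-")^2
    matched_truth <- apply(d2, 2, min) <= 4
    matched_det <- apply(d2, 1, min) <= 4
    expect_gte(mean(matched_truth), 0.95)   # recall
    expect_gte(mean(matched_det), 0.95)     # precision
    err <- sqrt(apply(d2, 2, min)[matched_truth])
    expect_lte(stats::quantile(err, 0.9), sqrt(3))
})

test_that("blank images yield no detections and close pairs merge", {
    set.seed(1)
    blank <- array(rnorm(16 * 64 * 64, 100, 10), dim = c(16, 64, 64))
    expect_equal(nrow(spotData(detectSpots(blank))), 0)

    img <- array(rnorm(16 * 64 * 64, 0, 0.01), dim = c(16, 64, 64))
    for (dx in c(0, 2)) {
        ctr <- c(8, 32, 30 + dx)
        for (z in 1:16) for (y in 25:40) for (x in 22:42)
            img[z, y, x] <- img[z, y, x] +
                500 * exp(-sum((c(z, y, x) - ctr)^2) / (2 * 1.5^2))
    }
    det <- spotData(detectSpots(img, psf_sigma = 2, sigmas = 2))
    expect_equal(nrow(det), 1)
})

test_that("ROI assignment drops background spots and matches the truth", {
    sim <- simSpotImages(n_cells = 6, shape = c(12, 96, 96),
                         n_spots_per_cell = 4, background_sd = 10,
                         seed = 52)
    det <- assignROIs(detectSpots(sim$images$rna), sim$mask)
    sp <- spotData(det)
    truth <- sim$truth
    for (i in seq_len(nrow(sp))) {
        j <- which.min((truth$z - sp$z[i])^2 + (truth$y - sp$y[i])^2 +
                       (truth$x - sp$x[i])^2)
        expect_equal(sp$roi[i], truth$cell[j])
    }
    # a spot fabricated on background is excluded
    fake <- det
    fk <- spotData(det)[1, ]
    fk$y <- 1; fk$x <- 1
    fake@spots <- rbind(spotData(det), fk)
    refq <- assignROIs(fake, sim$mask)
    expect_equal(nrow(spotData(refq)), nrow(sp))
})

test_that("nuclear/cytoplasmic classification matches the rendered truth", {
    sim <- simSpotImages(n_cells = 6, shape = c(24, 160, 160),
                         n_spots_per_cell = 8, placement = "anywhere",
                         background_sd = 10, seed = 53)
    det <- assignROIs(detectSpots(sim$images$rna), sim$mask)
    det <- classifyCompartment(det, sim$images$dna)
    sp <- spotData(det)
    truth <- sim$truth
    lab <- vapply(seq_len(nrow(sp)), function(i) {
        j <- which.min((truth$z - sp$z[i])^2 + (truth$y - sp$y[i])^2 +
                       (truth$x - sp$x[i])^2)
        truth$compartment[j]
    }, character(1))
    expect_gte(mean(sp$compartment == lab), 0.95)
})

test_that("randomized null is count-matched, in-ROI, and uniform", {
    sim <- simSpotImages(n_cells = 5, shape = c(10, 80, 80),
                         n_spots_per_cell = 7, background_sd = 10,
                         seed = 54)
    det <- assignROIs(detectSpots(sim$images$rna), sim$mask)
    rnd <- randomizeSpots(det, sim$mask, seed = 3)
    sp <- spotData(rnd)
    for (k in unique(sp$roi)) {
        expect_equal(sum(sp$roi == k & sp$origin == "random"),
                     sum(sp$roi == k & sp$origin == "detected"))
    }
    ran <- sp[sp$origin == "random", ]
    expect_true(all(sim$mask[cbind(ran$y, ran$x)] == ran$roi))
    # z values come from the detected multiset
    expect_true(all(ran$z %in% sp$z[sp$origin == "detected"]))

    # degenerate z distribution propagates
    one <- det
    one@spots$z <- 5
    rz <- spotData(randomizeSpots(one, sim$mask, seed = 4))
    expect_true(all(rz$z[rz$origin == "random"] == 5))

    # uniform marginals in a rectangular ROI (chi-square at alpha 0.01)
    mask <- matrix(0L, 60, 60); mask[11:50, 11:50] <- 1L
    fab <- new("SpotTable",
               spots = data.frame(z = rep(5, 1e4), y = 30, x = 30,
                                  sigma = 1.5, response = 1,
                                  origin = "detected", roi = 1L),
               metadata = list(dim = c(10L, 60L, 60L)))
    rr <- spotData(randomizeSpots(fab, mask, seed = 5))
    rr <- rr[rr$origin == "random", ]
    for (col in c("y", "x")) {
        tab <- table(cut(rr[[col]], breaks = seq(10.5, 50.5, by = 4)))
        expect_gt(stats::chisq.test(tab)$p.value, 0.01)
    }
})

test_that("uniform images normalize to 1 and per-ROI medians are pinned", {
    sim <- simSpotImages(n_cells = 4, shape = c(10, 64, 64),
                         n_spots_per_cell = 5, background_sd = 10,
                         seed = 55)
    det <- assignROIs(detectSpots(sim$images$rna), sim$mask)
    rnd <- randomizeSpots(det, sim$mask, seed = 6)
    flat <- array(7, dim = c(10, 64, 64))
    mm <- measureSpotIntensity(rnd, flat)
    expect_true(all(spotData(mm)$normalized_intensity == 1))
    # per-ROI median of normalized random intensities is 1 (odd counts)
    mm2 <- measureSpotIntensity(rnd, sim$images$protein)
    sp <- spotData(mm2)
    for (k in unique(sp$roi)) {
        v <- sp$normalized_intensity[sp$roi == k & sp$origin == "random"]
        if (length(v) %% 2 == 1) expect_equal(median(v), 1)
    }
})

test_that("the Mann-Whitney comparison detects true colocalization and not its absence", {
    simP <- simSpotImages(n_cells = 8, shape = c(16, 128, 128),
                          n_spots_per_cell = 10,
                          colocalized_fraction = 0.8, seed = 56)
    resP <- spotPipeline(simP, seed = 56)
    expect_lt(resP$test$p_value, 1e-4)

    sim0 <- simSpotImages(n_cells = 8, shape = c(16, 128, 128),
                          n_spots_per_cell = 10,
                          colocalized_fraction = 0, seed = 57)
    res0 <- spotPipeline(sim0, seed = 57)
    expect_gt(res0$test$p_value, 0.01)
    expect_error(compareSpotIntensity(res0$spots), NA)
})

test_that("chromatin colocalization fractions follow the planted geometry", {
    sp <- data.frame(z = 5, y = c(10, 11, 12, 30, 31), x = rep(10, 5),
                     origin = "detected", roi = 1L)
    tab <- new("SpotTable", spots = sp, metadata = list())
    maskAll <- matrix(TRUE, 40, 40)
    expect_equal(chromatinColocalizationFraction(tab, maskAll)$
                     per_cell$fraction, 1.0)
    expect_equal(chromatinColocalizationFraction(tab, !maskAll)$
                     per_cell$fraction, 0.0)

    set.seed(8)
    mask <- matrix(FALSE, 40, 40); mask[1:40, 1:20] <- TRUE
    n <- 50
    inm <- runif(n) < 0.6
    spb <- data.frame(z = 5, y = sample(1:40, n, TRUE),
                      x = ifelse(inm, sample(1:20, n, TRUE),
                                 sample(21:40, n, TRUE)),
                      origin = "detected", roi = 1L)
    tb <- new("SpotTable", spots = spb, metadata = list())
    fr <- chromatinColocalizationFraction(tb, mask)$per_cell$fraction
    expect_lt(abs(fr - 0.6), 0.15)
})

test_that("puncta counts per cell track the generator", {
    sim <- simSpotImages(n_cells = 5, shape = c(12, 96, 96),
                         n_spots_per_cell = 5, background_sd = 10,
                         seed = 58)
    det <- assignROIs(detectSpots(sim$images$rna), sim$mask)
    ct <- countPuncta(det, n_cells = 5)
    expect_equal(sum(ct$count), nrow(sim$truth))

    simPo <- simSpotImages(n_cells = 30, shape = c(12, 256, 256),
                           n_spots_per_cell = 6,
                           spot_count_model = "poisson",
                           background_sd = 10, seed = 59)
    detP <- assignROIs(detectSpots(simPo$images$rna), simPo$mask)
    ctP <- countPuncta(detP, n_cells = 30)
    expect_lt(abs(mean(ctP$count) - 6) / 6, 0.15)
})

test_that("the spot pipeline is deterministic given image, mask and seed", {
    sim <- simSpotImages(n_cells = 4, shape = c(10, 64, 64),
                         n_spots_per_cell = 5, seed = 60)
    r1 <- spotPipeline(sim, seed = 9)
    r2 <- spotPipeline(sim, seed = 9)
    expect_identical(spotData(r1$spots), spotData(r2$spots))
    expect_identical(r1$test, r2$test)
})
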