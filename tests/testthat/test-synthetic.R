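# Generators: determinism, documented invariants, and agreement between
# generated data and the recorded ground truth.

test_that("generators are byte-identical under a fixed seed", {
    a <- simMassEvents(data.frame(mass = c(120, 240), fraction = c(.3, .7)),
                       500, 12, seed = 9)
    b <- simMassEvents(data.frame(mass = c(120, 240), fraction = c(.3, .7)),
                       500, 12, seed = 9)
    expect_identical(a$events@contrast, b$events@contrast)
    expect_identical(a$standards$BSA@contrast, b$standards$BSA@contrast)

    g <- simGenome(2000, seed = 2)
    ta <- simCurtainEvents(genomeTrack(g), n_dna = 10, seed = 5,
                           dual_label_prob = 0.3)
    tb <- simCurtainEvents(genomeTrack(g), n_dna = 10, seed = 5,
                           dual_label_prob = 0.3)
    expect_identical(curtainEvents(ta), curtainEvents(tb))

    sa <- simSpotImages(n_cells = 4, shape = c(8, 64, 64),
                        n_spots_per_cell = 3, seed = 3)
    sb <- simSpotImages(n_cells = 4, shape = c(8, 64, 64),
                        n_spots_per_cell = 3, seed = 3)
    expect_identical(sa$images$rna, sb$images$rna)
    expect_identical(sa$truth, sb$truth)
})

test_that("per-DNA sub-streams are stable when more DNA is added", {
    g <- genomeTrack(simGenome(3000, seed = 1))
    t10 <- curtainEvents(simCurtainEvents(g, n_dna = 10, seed = 4))
    t20 <- curtainEvents(simCurtainEvents(g, n_dna = 20, seed = 4))
    expect_identical(t10[t10$dna <= 10, c("dna", "position_kbp", "t_end_s")],
                     t20[t20$dna <= 10, c("dna", "position_kbp", "t_end_s")])
})

test_that("mass-event generator validates inputs and round-trips at zero noise", {
    expect_error(simMassEvents(data.frame(mass = 120, fraction = 0.9),
                               10, 5), "sum to 1")
    expect_error(simMassEvents(data.frame(mass = -5, fraction = 1),
                               10, 5), "positive")
    sim <- simMassEvents(data.frame(mass = 120, fraction = 1), 1000, 0,
                         calibration = c(slope = 500, intercept = 20),
                         seed = 1)
    masses <- 500 * sim$events@contrast + 20
    expect_equal(masses, rep(120, 1000))
})

test_that("mixture weights are recovered by nearest-species assignment", {
    sim <- simMassEvents(data.frame(mass = c(120, 240),
                                    fraction = c(0.3, 0.7)),
                         20000, 12, seed = 11)
    tr <- groundTruth(sim$events)
    m <- tr$calibration["slope"] * sim$events@contrast +
        tr$calibration["intercept"]
    w120 <- mean(abs(m - 120) < abs(m - 240))
    expect_lt(abs(w120 - 0.3), 0.02)
})

test_that("anisotropy generator reproduces Hill arithmetic and null competitor", {
    bc <- simAnisotropyCurve(kd = 10, h = 1, protein_concs = c(1, 5, 10, 50),
                             noise_sd = 0, seed = 1)
    expect_equal(groundTruth(bc)$theta[3], 0.5)
    b0 <- simAnisotropyCurve(kd = 10, h = 1,
                             protein_concs = c(1, 5, 10, 50), noise_sd = 0,
                             competitor = list(kd = 5, conc = 0), seed = 1)
    expect_equal(bc@raw, b0@raw)
    expect_error(simAnisotropyCurve(kd = 10, h = 1,
                                    protein_concs = numeric(0)), "empty")
})

test_that("competitive generator matches the equilibrium half-saturation shifts", {
    # weak competitor in excess: multiplicative closed-form limit
    concs <- 10^seq(-2, 3, length.out = 400)
    bc <- simAnisotropyCurve(kd = 3.9, h = 1, protein_concs = concs,
                             noise_sd = 0,
                             competitor = list(kd = 390, conc = 100),
                             labeled_conc = 0.01, seed = 1)
    th <- groundTruth(bc)$theta
    half <- approx(th, concs, xout = 0.5)$y
    closed <- 3.9 * (1 + 100 / 390)
    expect_lt(abs(half - closed) / closed, 0.02)

    # strong competitor: protein-sequestration (additive) shift
    bc2 <- simAnisotropyCurve(kd = 18.9, h = 1,
                              protein_concs = 10^seq(-1, 4,
                                                     length.out = 400),
                              noise_sd = 0,
                              competitor = list(kd = 3.9, conc = 100),
                              labeled_conc = 1, seed = 1)
    th2 <- groundTruth(bc2)$theta
    half2 <- approx(th2, 10^seq(-1, 4, length.out = 400), xout = 0.5)$y
    additive <- 18.9 + 100 * 18.9 / (3.9 + 18.9) + 0.5
    expect_lt(abs(half2 - additive) / additive, 0.02)
})

test_that("curtain event positions are uniform when unbiased", {
    tab <- simCurtainEvents(48502, n_dna = 2000, events_per_dna_mean = 50,
                            seed = 21)
    ev <- curtainEvents(tab)
    expect_gte(nrow(ev), 90000)
    h <- positionHistogram(tab)
    expected <- sum(h@counts) / 24
    # 3-sigma Poisson band per bin
    expect_true(all(abs(h@counts - expected) < 3 * sqrt(expected)))
})

test_that("dwell censoring follows exponential survival arithmetic", {
    tab <- simCurtainEvents(48502, n_dna = 400, events_per_dna_mean = 10,
                            dwell_mean = 750, movie_length = 600,
                            start_mode = "zero", seed = 8)
    ev <- curtainEvents(tab)
    expect_true(all(ev$t_end_s <= 600))
    expect_true(all(ev$censored == (ev$t_end_s == 600)))
    expect_lt(abs(mean(ev$censored) - exp(-600 / 750)), 0.02)
})

test_that("motif-weighted positions are enriched at planted sites", {
    g <- simGenome(20000, motif = "TTTTTAA",
                   motif_positions = seq(1000, 19000, by = 1000), seed = 5)
    gt <- genomeTrack(g, motif = "TTTTTAA", strand_policy = "forward")
    w <- 8
    tab <- simCurtainEvents(gt, n_dna = 2000, events_per_dna_mean = 20,
                            position_bias = "motif_weighted",
                            bias_weight = w, seed = 6)
    ev <- curtainEvents(tab)
    sites <- motifSites(gt)
    inSite <- rep(FALSE, 20000)
    for (i in seq_len(nrow(sites))) inSite[sites$start[i]:sites$end[i]] <- TRUE
    bp <- pmin(pmax(ceiling(ev$position_kbp * 1000), 1), 20000)
    dens_site <- mean(inSite[bp]) / mean(inSite)
    dens_bg <- (1 - mean(inSite[bp])) / (1 - mean(inSite))
    expect_lt(abs(dens_site / dens_bg - w) / w, 0.15)
})

test_that("spot image generator bookkeeping and colocalization flags hold", {
    sim <- simSpotImages(n_cells = 10, shape = c(8, 96, 96),
                         n_spots_per_cell = 5, colocalized_fraction = 1,
                         background_sd = 5, seed = 12)
    expect_equal(nrow(sim$truth), 50)
    expect_true(all(sim$truth$colocalized))
    # every true RNA spot has elevated protein intensity at its position
    bg <- median(sim$images$protein)
    at <- sim$images$protein[cbind(round(sim$truth$z), round(sim$truth$y),
                                   round(sim$truth$x))]
    expect_true(all(at > bg + 10 * 5))
    # ROI labels of the rendered positions match the truth cell
    lab <- sim$mask[cbind(round(sim$truth$y), round(sim$truth$x))]
    expect_equal(lab, sim$truth$cell)
    expect_error(simSpotImages(n_cells = 2, shape = c(8, 64, 64),
                               roi_layout = data.frame(
                                   cy = c(32, 33), cx = c(32, 33),
                                   ry = c(20, 20), rx = c(20, 20))),
                 "overlap")
    expect_error(simSpotImages(psf_sigma = 0.2), "psf_sigma")
})
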