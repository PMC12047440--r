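# Curtain event analysis: per-DNA counts, colocalization, position
# histograms, sequence tracks, enrichment, survival, amplitudes,
# kymograms.

.mkTable <- function(df, movie = 600, glen = 48.502) {
    need <- list(event = seq_len(nrow(df)), experiment = "e1", fov = "f1",
                 dna = 1L, position_kbp = 1, t_start_s = 0, t_end_s = 10,
                 censored = FALSE, channel = "green", amplitude = 100,
                 partner_event = NA_integer_)
    for (nm in names(need)) if (!nm %in% names(df)) df[[nm]] <- need[[nm]]
    new("CurtainEventTable", events = df, movieLength = movie,
        genomeLengthKbp = glen)
}

test_that("events per DNA averages across experiments with a SEM", {
    tab <- .mkTable(data.frame(experiment = rep("e1", 30)))
    res <- eventsPerDNA(tab, data.frame(experiment = "e1", fov = "f1",
                                        n_dna = 10))
    expect_equal(res$mean, 3.0)
    expect_equal(res$sem, 0)

    tab3 <- .mkTable(data.frame(
        experiment = rep(c("e1", "e2", "e3"), times = c(20, 30, 40))))
    res3 <- eventsPerDNA(tab3, data.frame(experiment = c("e1", "e2", "e3"),
                                          fov = "f1", n_dna = 10))
    expect_equal(res3$mean, 3.0)
    expect_equal(res3$sem, 0.577, tolerance = 1e-3)

    expect_error(eventsPerDNA(tab, data.frame(experiment = "e1",
                                              fov = "other", n_dna = 5)),
                 "missing dna_counts")
})

test_that("events per DNA is invariant to fov splitting", {
    ev <- data.frame(experiment = "e1",
                     fov = rep(c("f1", "f2"), times = c(12, 18)))
    whole <- eventsPerDNA(.mkTable(transform(ev, fov = "f1")),
                          data.frame(experiment = "e1", fov = "f1",
                                     n_dna = 10))
    split <- eventsPerDNA(.mkTable(ev),
                          data.frame(experiment = "e1",
                                     fov = c("f1", "f2"), n_dna = c(4, 6)))
    expect_equal(whole$mean, split$mean)
})

test_that("per-nM normalization and weighted averages follow hand arithmetic", {
    expect_equal(normalizePerRNA(3, 0.03), 100)
    expect_error(normalizePerRNA(3, 0), "> 0")
    expect_equal(weightedAverage(c(10, 2), c(1, 3)), 4.0)
    expect_equal(weightedAverage(c(2, 4, 9), c(1, 1, 1)), 5.0)
})

test_that("two-colour colocalization handles exact overlap and disjoint channels", {
    base <- data.frame(position_kbp = runif(20, 0, 48), dna = rep(1:4, 5),
                       t_start_s = runif(20, 0, 500))
    dup <- rbind(cbind(base, channel = "green"),
                 cbind(base, channel = "red"))
    dup$t_end_s <- dup$t_start_s + 5
    res <- colocalizationFraction(.mkTable(dup))
    expect_equal(res$fraction, 1.0)

    disj <- dup
    disj$dna <- ifelse(disj$channel == "green", disj$dna, disj$dna + 10)
    expect_equal(colocalizationFraction(.mkTable(disj))$fraction, 0.0)

    expect_error(colocalizationFraction(.mkTable(
        data.frame(channel = rep("green", 5)))), "two channels")
})

test_that("colocalization recovers the generator's dual-label probability", {
    tab <- simCurtainEvents(48502, n_dna = 200, events_per_dna_mean = 5,
                            dual_label_prob = 0.5, seed = 14)
    res <- colocalizationFraction(tab)
    expect_lt(abs(res$fraction - 0.5), 0.05)
    # symmetry under channel swap
    ev <- curtainEvents(tab)
    ev$channel <- ifelse(ev$channel == "green", "red", "green")
    swapped <- tab; swapped@events <- ev
    expect_equal(colocalizationFraction(swapped)$fraction, res$fraction)
})

test_that("position histogram uses half-open 2-kbp bins and conserves counts", {
    h1 <- positionHistogram(.mkTable(data.frame(position_kbp = rep(1, 7))))
    expect_equal(h1@counts[1], 7)
    hb <- positionHistogram(.mkTable(data.frame(position_kbp = 2.0)))
    expect_equal(hb@counts[2], 1)   # 2.0 falls in [2, 4)
    expect_equal(sum(hb@counts), 1)

    set.seed(3)
    pos <- runif(1e5, 0, 48)
    hu <- positionHistogram(pos)
    expect_lt(max(hu@counts) / min(hu@counts), 1.2)
    expect_equal(hu@counts, as.numeric(bruteBinCounts(pos, 0, 2, 24)))
    ho <- positionHistogram(c(50, 1))
    expect_equal(ho@outOfRange, 1L)
})

test_that("motif scan matches a brute-force oracle on random sequences", {
    f <- findMotifSites("TTTTTAATTTTTAA", "TTTTTAA", "forward")
    expect_equal(f$start, c(1, 8))
    r <- findMotifSites("TTAAAAA", "TTTTTAA", "both")
    expect_equal(nrow(r), 1)
    expect_equal(r$strand, "-")
    expect_error(findMotifSites("ACGT", "TTNTT"), "uppercase")

    for (s in 1:5) {
        seqc <- as.character(simGenome(5000, gc = 0.4, seed = 100 + s))
        got <- findMotifSites(seqc, "TTTTTAA", "both")
        ora <- bruteMotifScan(seqc, "TTTTTAA")
        rownames(got) <- rownames(ora) <- NULL
        expect_equal(got, ora)
    }
})

test_that("A/T-content track is exact on constructed sequences", {
    allA <- atContentTrack(strrep("A", 100), window = 10, step = 10)
    expect_true(all(allA$at == 1))
    expect_equal(atContentTrack("ATGC", window = 4)$at, 0.5)
    blocks <- paste0(strrep("AT", 10), strrep("GC", 10),
                     strrep("AT", 10), strrep("GC", 10))
    tr <- atContentTrack(blocks, window = 20, step = 20)
    expect_equal(tr$at, c(1, 0, 1, 0))
    expect_error(atContentTrack("ACGT", window = 0), "> 0")
    expect_error(atContentTrack("ACGT", window = 10), "exceeds")
})

test_that("enrichment test is extreme for AT-only placement and calibrated under the null", {
    g <- genomeTrack(simGenome(20000, gc = 0.5, seed = 9), at_window = 200,
                     at_step = 200)
    at <- atContent(g)
    best <- at$center_bp[which.max(at$at)] / 1000
    res <- positionEnrichmentTest(rep(best, 50), g, n_permutations = 200,
                                  seed = 1)
    expect_equal(res$p_value, 1 / 201)

    ps <- vapply(1:200, function(r) {
        pos <- runif(30, 0, 20)
        positionEnrichmentTest(pos, g, n_permutations = 100,
                               seed = 500 + r)$p_value
    }, numeric(1))
    expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
    expect_error(positionEnrichmentTest(numeric(0), g), "no positions")
})

test_that("AT-biased events give a significant enrichment p-value", {
    # substrate with domain-scale A/T structure, as in real genomes
    g <- genomeTrack(simGenome(20000, gc = c(0.65, 0.4, 0.55, 0.3, 0.6,
                                             0.45, 0.7, 0.35), seed = 9))
    tab <- simCurtainEvents(g, n_dna = 100, events_per_dna_mean = 5,
                            position_bias = "at_weighted", bias_weight = 3,
                            seed = 10)
    ev <- curtainEvents(tab)
    res <- positionEnrichmentTest(ev$position_kbp, g,
                                  n_permutations = 500, seed = 2)
    expect_lt(res$p_value, 0.01)
})

test_that("Kaplan-Meier equals the empirical survival when nothing is censored", {
    for (s in 1:5) {
        set.seed(200 + s)
        lt <- rexp(40, 1 / 50) + 1
        km <- kaplanMeier(lt, n_bootstrap = 100, seed = s)
        tq <- c(0, sort(lt), max(lt) + 1)
        expect_equal(survivalAt(km, tq), empiricalSurvival(lt, tq))
    }
})

test_that("Kaplan-Meier reproduces the hand product-limit calculation", {
    km <- kaplanMeier(c(1, 2, 3), censored = c(FALSE, TRUE, FALSE),
                      n_bootstrap = 100, seed = 1)
    expect_equal(survivalAt(km, c(0, 1, 2, 3)), c(1, 2 / 3, 2 / 3, 0))
    expect_error(kaplanMeier(c(1, 2), censored = c(TRUE, TRUE)),
                 "censored")
    # bootstrap band covers the point estimate everywhere
    expect_true(all(km@lower <= km@surv + 1e-12))
    expect_true(all(km@upper >= km@surv - 1e-12))
})

test_that("censored exponential dwell times give the closed-form survival", {
    set.seed(77)
    dwell <- rexp(300, 1 / 750)
    cens <- dwell > 600
    km <- kaplanMeier(pmin(dwell, 600), cens, n_bootstrap = 300, seed = 3)
    s300 <- survivalAt(km, 300)
    i <- max(which(km@time <= 300))
    expect_gte(exp(-300 / 750), km@lower[i])
    expect_lte(exp(-300 / 750), km@upper[i])
    expect_lt(abs(s300 - exp(-0.4)), 0.08)
})

test_that("event amplitudes summarize per event and per condition", {
    tab <- .mkTable(data.frame(amplitude = rep(100, 10)))
    res <- meanEventAmplitude(tab)
    expect_true(all(res$per_event$amplitude == 100))
    expect_equal(res$summary$mean, 100)

    tr <- data.frame(event = c(1, 1, 1, 2), frame = c(1, 2, 3, 1),
                     amplitude = c(90, 100, 110, 55))
    pr <- meanEventAmplitude(tr)
    expect_equal(pr$per_event$amplitude, c(100, 55))

    a <- simCurtainEvents(48502, n_dna = 300, events_per_dna_mean = 5,
                          amplitude_mean = 100, seed = 4)
    b <- simCurtainEvents(48502, n_dna = 300, events_per_dna_mean = 5,
                          amplitude_mean = 200, seed = 5)
    ra <- meanEventAmplitude(a)$summary$mean
    rb <- meanEventAmplitude(b)$summary$mean
    expect_lt(abs(rb / ra - 2), 0.2)
})

test_that("kymograms paint stripes where and when events occur", {
    ev <- data.frame(position_kbp = 10.2, t_start_s = 0, t_end_s = 600,
                     amplitude = 50)
    ky <- buildKymogram(ev, frame_interval = 10, movie_length = 600,
                        genome_length_kbp = 48.5)
    row <- 1 + floor(10.2 / 0.5)
    expect_true(all(ky[row, ] == 50))
    expect_true(all(ky[-row, ] == 0))

    ev2 <- data.frame(position_kbp = 10.2, t_start_s = 300, t_end_s = 600,
                      amplitude = 50)
    ky2 <- buildKymogram(ev2, 10, 600, 48.5)
    expect_true(all(ky2[row, 1:30] == 0))
    expect_true(all(ky2[row, 31:60] == 50))
    expect_equal(attr(ky2, "missing_frames"), 1:30)

    ev3 <- rbind(ev, transform(ev, position_kbp = 30.1))
    ky3 <- buildKymogram(ev3, 10, 600, 48.5)
    expect_equal(sum(rowSums(ky3) > 0), 2)
})
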