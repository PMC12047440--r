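# Independent oracles used by the recovery and equivalence tests. These
# deliberately avoid the package's own code paths.

# brute-force motif scan (both strands), 1-based coordinates
bruteMotifScan <- function(seq_chars, motif) {
    n <- nchar(seq_chars)
    m <- nchar(motif)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]),
                                       collapse = ""))
    hits <- data.frame(start = integer(0), end = integer(0),
                       strand = character(0))
    for (i in seq_len(n - m + 1)) {
        sub <- substr(seq_chars, i, i + m - 1)
        if (sub == motif)
            hits <- rbind(hits, data.frame(start = i, end = i + m - 1,
                                           strand = "+"))
        if (sub == rc)
            hits <- rbind(hits, data.frame(start = i, end = i + m - 1,
                                           strand = "-"))
    }
    hits[order(hits$start), , drop = FALSE]
}

# empirical survival function (no censoring): S(t) = P(T > t)
empiricalSurvival <- function(lifetimes, t) {
    vapply(t, function(tt) mean(lifetimes > tt), numeric(1))
}

# brute-force competition equilibrium: grid search over free protein
bruteCompetitionBound <- function(kdL, kdC, LT, CT, PT, ngrid = 2e6) {
    P <- seq(0, PT, length.out = ngrid)
    resid <- abs(P + LT * P / (kdL + P) + CT * P / (kdC + P) - PT)
    Pfree <- P[which.min(resid)]
    (Pfree / (kdL + Pfree))
}

# brute-force fixed-bin histogram
bruteBinCounts <- function(x, lo, width, nbins) {
    counts <- integer(nbins)
    for (v in x) {
        b <- floor((v - lo) / width) + 1
        if (b >= 1 && b <= nbins && v >= lo) counts[b] <- counts[b] + 1L
    }
    counts
}
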