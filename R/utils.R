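# Internal helpers shared across modules.

#' @noRd
.assertScalarNum <- function(x, name, positive = FALSE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
    if (positive && x <= 0)
        stop(sprintf("'%s' must be > 0", name), call. = FALSE)
    if (nonneg && x < 0)
        stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
    invisible(x)
}

#' @noRd
.assertIncreasing <- function(x, name, strict = TRUE) {
    d <- diff(x)
    ok <- if (strict) all(d > 0) else all(d >= 0)
    if (!ok)
        stop(sprintf("'%s' must be %sincreasing", name,
                     if (strict) "strictly " else ""), call. = FALSE)
    invisible(x)
}

# Derive a reproducible sub-seed from a master seed and a stream index.
# Keeps the result a valid 32-bit integer.
#' @noRd
.subSeed <- function(seed, stream) {
    s <- (as.double(seed) * 48271 + as.double(stream) * 1103) %% 2147483629
    as.integer(s)
}

# Otsu threshold on a numeric vector (between-class variance maximisation
# over a fixed-bin histogram). Used for per-spot nuclear-intensity
# classification where the input is a vector of spot measurements, not an
# image, so image-package thresholders do not apply.
#' @noRd
.otsuThreshold <- function(x, nbins = 256L) {
    x <- x[is.finite(x)]
    if (length(x) < 2L || diff(range(x)) == 0)
        return(max(x, -Inf))
    h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
              plot = FALSE)
    w <- h$counts / sum(h$counts)
    mids <- h$mids
    omega <- cumsum(w)
    mu <- cumsum(w * mids)
    mu_t <- mu[length(mu)]
    sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
    sigma_b[!is.finite(sigma_b)] <- 0
    mids[which.max(sigma_b)]
}

#' @noRd
.meanSem <- function(x) {
    n <- length(x)
    c(mean = mean(x),
      sem = if (n > 1L) stats::sd(x) / sqrt(n) else 0)
}
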