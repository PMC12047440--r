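# Mass photometry: contrast calibration, fixed-width mass histograms,
# Gaussian oligomer deconvolution, the cooperative hexamer-dissociation
# model, and the footprint occupancy model of trimer stoichiometry on RNA.

#' OligomerFit: Gaussian deconvolution of a mass histogram
#'
#' @slot table data.frame with one row per species (\code{"1"},
#'   \code{"3"}, \code{"6"}, \code{">6"}): peak mass \code{mu} (kDa),
#'   \code{sigma} (kDa), \code{area} (events) and relative
#'   \code{fraction} (areas divided by the summed area).
#' @slot sse residual sum of squares of the fit.
#' @slot converged logical.
#' @export
setClass("OligomerFit",
    slots = c(table = "data.frame", sse = "numeric", converged = "logical"))

setValidity("OligomerFit", function(object) {
    tb <- object@table
    if (abs(sum(tb$fraction) - 1) > 1e-9)
        return("species fractions must sum to 1")
    act <- tb[tb$fraction > 0, ]
    if (nrow(act) > 1 && any(diff(act$mu) <= 0))
        return("peak masses must increase with oligomer order")
    TRUE
})

setMethod("show", "OligomerFit", function(object) {
    cat("OligomerFit (sse =", signif(object@sse, 4), ")\n")
    print(transform(object@table, mu = signif(mu, 4),
                    sigma = signif(sigma, 3),
                    fraction = round(fraction, 3)))
})

#' HillFit: a fitted Hill model
#'
#' Container for Hill-equation fits: equilibrium binding
#' (\code{model = "binding"}, parameters \code{kd}, \code{h}) or
#' RNA-induced hexamer dissociation (\code{model = "dissociation"},
#' parameters \code{K_half}, \code{h}, \code{f_min}, \code{f_max}).
#'
#' @slot coefficients named numeric parameter estimates.
#' @slot se named numeric standard errors (from the fit covariance).
#' @slot model \code{"binding"} or \code{"dissociation"}.
#' @slot fitted fitted values on the input grid.
#' @slot data list with the fitted grid and response.
#' @export
setClass("HillFit",
    slots = c(coefficients = "numeric", se = "numeric",
              model = "character", fitted = "numeric", data = "list"))

setValidity("HillFit", function(object) {
    co <- object@coefficients
    if (!is.null(co["h"]) && !is.na(co["h"]) && co["h"] <= 0)
        return("Hill coefficient must be > 0")
    TRUE
})

setMethod("show", "HillFit", function(object) {
    cat("HillFit (", object@model, "):\n", sep = "")
    est <- rbind(estimate = object@coefficients,
                 se = object@se[names(object@coefficients)])
    print(signif(est, 4))
})

#' @rdname HillFit-class
#' @param object a \code{HillFit}.
#' @export
setMethod("coef", "HillFit", function(object) object@coefficients)

#' Fit the contrast-to-mass calibration line
#'
#' Least-squares line through (median contrast, known mass) pairs of the
#' calibration standards: \code{mass = slope * contrast + intercept}.
#'
#' @param standards named list of \code{\linkS4class{MassEventSet}}, one
#'   acquisition per standard (at least 2).
#' @param known_masses named numeric, known standard masses in kDa,
#'   matched to \code{standards} by name (or by position if unnamed).
#' @return list with \code{slope} (kDa per contrast unit),
#'   \code{intercept} (kDa) and per-standard \code{residuals} (kDa).
#' @examples
#' sim <- simMassEvents(data.frame(mass = 120, fraction = 1), 100, 5,
#'                      seed = 1)
#' cal <- calibrateMass(sim$standards, massStandards())
#' @export
calibrateMass <- function(standards, known_masses = massStandards()) {
    if (length(standards) < 2L)
        stop("at least 2 calibration standards are required")
    if (!is.null(names(standards)) && !is.null(names(known_masses)))
        known_masses <- known_masses[names(standards)]
    if (anyNA(known_masses) || length(known_masses) != length(standards))
        stop("known_masses must match the standards")
    med <- vapply(standards, function(s) median(s@contrast), numeric(1))
    if (diff(range(med)) == 0)
        stop("degenerate calibration: all standards have equal contrast")
    for (i in seq_along(standards)) {
        h <- hist(standards[[i]]@contrast, breaks = 15, plot = FALSE)
        cnt <- h$counts
        pk <- which(cnt > 0.25 * max(cnt) &
                    cnt >= c(-Inf, head(cnt, -1)) &
                    cnt >= c(tail(cnt, -1), -Inf))
        if (length(pk) > 1 && any(diff(pk) > 2))
            warning(sprintf("standard %d contrast distribution looks multimodal",
                            i))
    }
    fit <- stats::lm(known_masses ~ med)
    co <- coef(fit)
    se <- if (length(standards) > 2)
        summary(fit)$coefficients[, "Std. Error"] else c(NA_real_, NA_real_)
    list(slope = unname(co[2]), intercept = unname(co[1]),
         slope_se = unname(se[2]), intercept_se = unname(se[1]),
         residuals = setNames(unname(residuals(fit)), names(standards)))
}

#' Apply a mass calibration to a contrast event set
#'
#' @param events a \code{\linkS4class{MassEventSet}} of contrasts.
#' @param calibration result of \code{\link{calibrateMass}}.
#' @return the event set with masses filled in
#'   (\code{mass = slope * contrast + intercept}).
#' @export
applyCalibration <- function(events, calibration) {
    if (calibration$slope == 0) stop("calibration slope must be non-zero")
    events@mass <- calibration$slope * events@contrast + calibration$intercept
    events@calibration <- calibration
    validObject(events)
    events
}

#' Build the standard 100-bin, 8-kDa mass histogram
#'
#' Fixed binning used for oligomer deconvolution: 100 uniform bins of
#' exactly 8 kDa starting at \code{lower_edge} (default 0), half-open
#' \code{[lo, hi)}. Events outside the range are counted and reported but
#' excluded from the bins.
#'
#' @param masses numeric masses in kDa, or a calibrated
#'   \code{\linkS4class{MassEventSet}}.
#' @param lower_edge left edge of the first bin, kDa.
#' @param bin_width bin width, kDa.
#' @param n_bins number of bins.
#' @return a \code{\linkS4class{MassHistogram}}.
#' @export
buildMassHistogram <- function(masses, lower_edge = 0, bin_width = 8,
                               n_bins = 100) {
    if (is(masses, "MassEventSet")) masses <- eventMasses(masses)
    if (!length(masses)) stop("no masses supplied")
    if (any(!is.finite(masses))) stop("masses must be finite")
    breaks <- lower_edge + bin_width * (0:n_bins)
    idx <- findInterval(masses, breaks, left.open = FALSE,
                        rightmost.closed = FALSE)
    inr <- idx >= 1L & idx <= n_bins & masses < breaks[n_bins + 1L]
    counts <- tabulate(idx[inr], nbins = n_bins)
    new("MassHistogram", breaks = breaks, counts = as.numeric(counts),
        outOfRange = sum(!inr))
}

#' Savitzky-Golay smoothing of a mass histogram
#'
#' Quadratic Savitzky-Golay filter with a span of nine bins, used to
#' visualize low-abundance higher-order oligomer peaks. Raw counts are
#' preserved; peak fitting operates on the raw counts.
#'
#' @param hist a \code{\linkS4class{MassHistogram}}.
#' @param p polynomial order.
#' @param n filter span in bins (odd).
#' @return the histogram with \code{smoothed} counts filled in.
#' @export
smoothMassHistogram <- function(hist, p = 2, n = 9) {
    if (length(hist@counts) < n)
        stop("filter span exceeds the number of bins")
    hist@smoothed <- as.numeric(signal::sgolayfilt(hist@counts, p = p, n = n))
    validObject(hist)
    hist
}

#' Deconvolve oligomeric species from a mass histogram
#'
#' Fits a sum of Gaussian peaks to the raw histogram counts, one peak per
#' oligomeric species: monomer, trimer, hexamer (initialized at 1x, 3x
#' and 6x the monomer mass, means constrained to +/- 25 percent of the
#' initialization) plus one unconstrained high-mass component for
#' higher-order oligomers (">6"). Relative species abundance is the
#' fitted area divided by the summed area; species whose fraction falls
#' below \code{area_floor} are reported as 0.
#'
#' @param hist a \code{\linkS4class{MassHistogram}} (raw counts are fit).
#' @param monomer_mass monomer mass in kDa (default 40).
#' @param area_floor minimum relative fraction below which a species is
#'   reported as absent.
#' @return an \code{\linkS4class{OligomerFit}}.
#' @export
fitOligomerPeaks <- function(hist, monomer_mass = 40, area_floor = 0.02) {
    .assertScalarNum(monomer_mass, "monomer_mass", positive = TRUE)
    centers <- head(hist@breaks, -1) + diff(hist@breaks) / 2
    counts <- hist@counts
    bw <- diff(hist@breaks)[1]
    n_par <- 12L
    if (sum(counts) < 10 * n_par)
        warning("fewer events than 10x the parameter count; fit may be unstable")

    mu0 <- c(1, 3, 6) * monomer_mass
    mu_hi0 <- 10 * monomer_mass
    lower <- c(A = rep(0, 4),
               mu = c(0.75 * mu0, 6.5 * monomer_mass),
               sigma = rep(max(bw / 2, 2), 4))
    upper <- c(A = rep(2 * sum(counts), 4),
               mu = c(1.25 * mu0, max(centers)),
               sigma = rep(25 * monomer_mass, 4))
    a0 <- vapply(c(mu0, mu_hi0), function(m) {
        j <- which.min(abs(centers - m))
        max(sum(counts[max(1, j - 2):min(length(counts), j + 2)]), 1)
    }, numeric(1))
    par0 <- c(a0, mu0, mu_hi0, rep(max(monomer_mass / 3, 2 * bw), 4))

    model <- function(par) {
        A <- par[1:4]; mu <- par[5:8]; s <- par[9:12]
        y <- 0
        for (k in 1:4) y <- y + A[k] * bw * dnorm(centers, mu[k], s[k])
        y
    }
    obj <- function(par) sum((counts - model(par))^2)
    fit <- optim(par0, obj, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 2000,
                                               factr = 1e4))
    if (fit$convergence != 0)
        stop("oligomer peak fit did not converge: ", fit$message)
    A <- fit$par[1:4]; mu <- fit$par[5:8]; s <- fit$par[9:12]
    frac <- A / sum(A)
    drop <- frac < area_floor
    A[drop] <- 0
    frac <- if (sum(A) > 0) A / sum(A) else rep(0, 4)
    tb <- data.frame(species = c("1", "3", "6", ">6"), mu = mu, sigma = s,
                     area = A, fraction = frac)
    # absent species carry no meaningful peak position
    tb$mu[drop] <- NA_real_
    tb$sigma[drop] <- NA_real_
    new("OligomerFit", table = tb, sse = fit$value, converged = TRUE)
}

#' Fit the cooperative RNA-induced hexamer-dissociation model
#'
#' Fits the four-parameter Hill model of the trimer fraction against RNA
#' concentration,
#' \deqn{p_3(c) = f_{min} + (f_{max} - f_{min}) \frac{c^h}{K_{1/2}^h + c^h},}
#' describing cooperative dissociation of ORF1p hexamers as RNA occupies
#' trimer binding sites. Standard errors come from the fit covariance.
#'
#' @param series data.frame with columns \code{conc} (RNA, nM,
#'   nonnegative and strictly increasing, including 0) and
#'   \code{fraction} (trimer fraction in [0, 1]); at least 5 points.
#' @return a \code{\linkS4class{HillFit}} with parameters \code{K_half},
#'   \code{h}, \code{f_min}, \code{f_max}.
#' @export
fitHillDissociation <- function(series) {
    stopifnot(is.data.frame(series),
              all(c("conc", "fraction") %in% names(series)))
    if (nrow(series) < 5) stop("at least 5 concentration points required")
    if (!any(series$conc == 0))
        stop("the titration must include a 0-concentration point")
    .assertIncreasing(series$conc, "conc")
    cpos <- series$conc[series$conc > 0]
    start <- list(f_min = min(series$fraction),
                  f_max = max(series$fraction),
                  K_half = median(cpos), h = 1.5)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            fraction ~ f_min + (f_max - f_min) * ifelse(conc == 0, 0,
                conc^h / (K_half^h + conc^h)),
            data = series, start = start,
            lower = c(f_min = 0, f_max = 0, K_half = 1e-6, h = 0.1),
            upper = c(f_min = 1, f_max = 1, K_half = 1e6, h = 10),
            control = minpack.lm::nls.lm.control(maxiter = 500)),
        error = function(e) stop("Hill dissociation fit failed: ",
                                 conditionMessage(e)))
    co <- coef(fit)
    if (co["h"] <= 0.1 + 1e-6 || co["h"] >= 10 - 1e-6)
        warning("fitted Hill coefficient at parameter bound")
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 4))
    new("HillFit", coefficients = co, se = se[names(co)],
        model = "dissociation", fitted = as.numeric(fitted(fit)),
        data = list(conc = series$conc, response = series$fraction))
}

#' Footprint occupancy model of trimer stoichiometry on RNA
#'
#' Model constants for direct ORF1p-trimer binding along an RNA: each
#' trimer occupies a 30-nt footprint and consecutive trimers require a
#' 45-nt periodicity (a 15-nt linker between footprints).
#'
#' @param footprint nt bound per trimer (> 0).
#' @param spacing nt of RNA consumed per additional trimer
#'   (>= footprint).
#' @param monomers_per_trimer monomers per trimer.
#' @return list of model constants.
#' @export
footprintModel <- function(footprint = 30, spacing = 45,
                           monomers_per_trimer = 3) {
    .assertScalarNum(footprint, "footprint", positive = TRUE)
    if (spacing < footprint) stop("spacing must be >= footprint")
    list(footprint = footprint, spacing = spacing,
         monomers_per_trimer = monomers_per_trimer)
}

#' Maximum number of directly bound trimers on an RNA
#'
#' Under the footprint model, an RNA of length L admits 0 trimers when
#' L < footprint and otherwise
#' \code{floor((L - footprint) / spacing) + 1}. A 1970-nt RNA admits 44
#' trimers; 90 nt is the shortest length of the 30/60/90/120-nt series
#' that admits two.
#'
#' @param rna_length RNA length(s) in nt (>= 0); vectorized.
#' @param model a \code{\link{footprintModel}}.
#' @return integer vector of maximal trimer counts.
#' @examples
#' maxTrimers(c(30, 60, 90, 120))
#' maxTrimers(1970)
#' @export
maxTrimers <- function(rna_length, model = footprintModel()) {
    if (any(rna_length < 0)) stop("rna_length must be >= 0")
    ifelse(rna_length < model$footprint, 0L,
           as.integer(floor((rna_length - model$footprint) /
                            model$spacing) + 1))
}

#' Protein excess that saturates an RNA's direct binding sites
#'
#' Monomer:RNA molar ratio at which every direct trimer site on the RNA
#' is occupied: \code{monomers_per_trimer * maxTrimers(L)}. Both the
#' exact value and the value rounded to two significant figures are
#' reported (a 1970-nt RNA gives 132, i.e. a ~130-fold molar excess).
#'
#' @inheritParams maxTrimers
#' @return list with \code{exact} and \code{rounded} (2 significant
#'   figures) molar ratios.
#' @export
saturationExcess <- function(rna_length, model = footprintModel()) {
    ex <- model$monomers_per_trimer * maxTrimers(rna_length, model)
    list(exact = ex, rounded = signif(ex, 2))
}
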