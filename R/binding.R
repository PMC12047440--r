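# Equilibrium binding: anisotropy normalization, Hill K_d fits, and the
# exact two-species shared-site competition model.

#' Normalize an anisotropy titration
#'
#' The protein-free control (blank) is subtracted from every point and the
#' result min-max scaled: the smallest value maps to 0 and the largest to
#' 1 exactly. The transformation is invariant to positive affine
#' transforms of the raw signal.
#'
#' @param curve a \code{\linkS4class{BindingCurve}} with raw values and a
#'   blank; at least 4 points.
#' @return the curve with \code{normalized} filled in.
#' @export
normalizeAnisotropy <- function(curve) {
    stopifnot(is(curve, "BindingCurve"))
    if (length(curve@conc) < 4)
        stop("at least 4 titration points required")
    r <- curve@raw - curve@blank
    rng <- range(r)
    if (diff(rng) == 0)
        stop("flat curve: max equals min after blank subtraction")
    curve@normalized <- (r - rng[1]) / diff(rng)
    validObject(curve)
    curve
}

#' Fit a Hill binding isotherm to a normalized titration
#'
#' Least-squares fit of the Hill isotherm
#' \eqn{y(P) = s_0 + (s_1 - s_0)\, P^h / (K_d^h + P^h)} to the
#' normalized anisotropy signal, with the Hill coefficient fitted
#' freely. The affine amplitude terms \eqn{s_0, s_1} absorb the residual
#' distortion that min-max normalization introduces on a finite
#' titration range (the smallest and largest measured points are pinned
#' to 0 and 1 even though the true bound fraction there is not exactly 0
#' or 1); with them, a noise-free titration returns the generating
#' \eqn{K_d} and \eqn{h} exactly. The bound fraction at \eqn{K_d} is 0.5
#' by construction.
#' Protein concentration is treated as total; at 1 nM labelled oligo,
#' ligand depletion is negligible over the fitted range (see
#' \code{\link{depletionIsotherm}} for the depletion-aware variant).
#' When a list of replicate curves is supplied, each is fitted separately
#' and the parameter means and SEMs across replicates are reported.
#'
#' @param curve a normalized \code{\linkS4class{BindingCurve}}, or a list
#'   of replicate curves.
#' @return a \code{\linkS4class{HillFit}} (parameters \code{kd},
#'   \code{h}); for replicate lists, the fit of the first replicate with
#'   \code{data$replicates} holding per-replicate estimates and
#'   \code{data$mean_kd}, \code{data$sem_kd}.
#' @examples
#' bc <- simAnisotropyCurve(kd = 3.9, h = 1,
#'                          protein_concs = 10^seq(-1, 3, length.out = 12),
#'                          noise_sd = 0, seed = 1)
#' fit <- fitHillBinding(normalizeAnisotropy(bc))
#' coef(fit)["kd"]
#' @export
fitHillBinding <- function(curve) {
    if (is.list(curve) && !is(curve, "BindingCurve")) {
        fits <- lapply(curve, fitHillBinding)
        kds <- vapply(fits, function(f) coef(f)[["kd"]], numeric(1))
        out <- fits[[1]]
        out@data$replicates <- data.frame(
            replicate = vapply(curve, function(x) x@replicate, character(1)),
            kd = kds,
            h = vapply(fits, function(f) coef(f)[["h"]], numeric(1)))
        ms <- .meanSem(kds)
        out@data$mean_kd <- unname(ms["mean"])
        out@data$sem_kd <- unname(ms["sem"])
        return(out)
    }
    stopifnot(is(curve, "BindingCurve"))
    if (!length(curve@normalized))
        stop("curve must be normalized first (normalizeAnisotropy)")
    df <- data.frame(P = curve@conc, y = curve@normalized)
    if (nrow(df) < 5)
        stop("at least 5 titration points required")
    half <- df$P[which.min(abs(df$y - 0.5))]
    if (min(df$y) > 0.3 || max(df$y) < 0.7)
        warning("titration does not bracket half-saturation well")
    pPos <- df$P[df$P > 0]
    kdStarts <- unique(pmax(c(half, exp(mean(log(pPos))),
                              quantile(pPos, 0.25),
                              quantile(pPos, 0.75)), 1e-3))
    # multi-start: the Hill surface has corner local minima (h at its
    # bounds trading off against kd); keep the lowest-SSE solution
    fit <- NULL; err <- NULL
    for (k0 in kdStarts) for (h0 in c(1, 2, 0.5)) {
        cand <- tryCatch(
            minpack.lm::nlsLM(y ~ s0 + (s1 - s0) *
                                  ifelse(P == 0, 0, P^h / (kd^h + P^h)),
                              data = df,
                              start = list(kd = k0, h = h0, s0 = 0,
                                           s1 = 1),
                              lower = c(kd = 1e-9, h = 0.1, s0 = -0.2,
                                        s1 = 0.8),
                              upper = c(kd = 1e9, h = 10, s0 = 0.2,
                                        s1 = 1.5),
                              control = minpack.lm::nls.lm.control(
                                  maxiter = 500)),
            error = function(e) { err <<- conditionMessage(e); NULL })
        if (!is.null(cand) &&
            (is.null(fit) || deviance(cand) < deviance(fit)))
            fit <- cand
    }
    if (is.null(fit)) stop("Hill binding fit failed: ", err)
    co <- coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, 2))
    new("HillFit", coefficients = co, se = se[names(co)],
        model = "binding", fitted = as.numeric(fitted(fit)),
        data = list(conc = df$P, response = df$y,
                    replicate = curve@replicate))
}

#' Depletion-aware single-site isotherm
#'
#' Exact bound fraction of a labelled ligand at total concentration
#' \code{L_total} titrated with total protein \code{P_total} for a
#' single site of dissociation constant \code{kd} (quadratic solution of
#' the mass-action equilibrium). Reduces to the hyperbolic isotherm as
#' \code{L_total} goes to 0.
#'
#' @param P_total total protein, nM (vectorized).
#' @param kd dissociation constant, nM.
#' @param L_total total labelled ligand, nM.
#' @return bound fraction per point.
#' @export
depletionIsotherm <- function(P_total, kd, L_total = 1) {
    .assertScalarNum(kd, "kd", positive = TRUE)
    b <- P_total + L_total + kd
    PL <- (b - sqrt(b^2 - 4 * P_total * L_total)) / 2
    PL / L_total
}

#' Solve two-species shared-site competition equilibria
#'
#' For each total protein concentration, solves the coupled mass-action
#' equilibria of a labelled species L and an unlabelled competitor C for
#' one shared binding site,
#' \deqn{P + L \rightleftharpoons PL \quad (K_{d,L}), \qquad
#'       P + C \rightleftharpoons PC \quad (K_{d,C}),}
#' under conservation of P, L and C, by bracketed root finding on the
#' free-protein concentration (relative tolerance 1e-12).
#'
#' Two regimes are worth distinguishing for a protein titration against
#' a fixed trace of labelled species. In the negligible-depletion limit
#' (a weak competitor in excess, \eqn{K_{d,C} \gg K_{d,L}}, so that free
#' protein stays well below \eqn{K_{d,C}} over the fitted range) the
#' competitor consumes free protein proportionally and the total-protein
#' axis is rescaled: the apparent labelled K_d approaches the classical
#' closed form \eqn{K_{d,L} (1 + C_T / K_{d,C})}. A strong competitor
#' (\eqn{K_{d,C} \ll C_T}), in contrast, is stoichiometrically saturated
#' by the titrated protein, and the exact solution gives an additive
#' shift of the total-protein half-saturation,
#' \eqn{K_{d,L} + C_T K_{d,L} / (K_{d,C} + K_{d,L}) + L_T/2}.
#'
#' @param kd_labeled,kd_competitor dissociation constants, nM (> 0).
#' @param labeled_total,competitor_total total concentrations, nM
#'   (competitor may be 0).
#' @param protein_total numeric grid of total protein, nM.
#' @return data.frame with \code{protein_total}, free protein \code{P},
#'   \code{PL}, \code{PC} and \code{bound_fraction} = PL / L_total.
#' @examples
#' solveCompetition(18.9, 3.9, 1, 100, c(10, 100, 1000))
#' @export
solveCompetition <- function(kd_labeled, kd_competitor, labeled_total,
                             competitor_total, protein_total) {
    .assertScalarNum(kd_labeled, "kd_labeled", positive = TRUE)
    .assertScalarNum(kd_competitor, "kd_competitor", positive = TRUE)
    .assertScalarNum(labeled_total, "labeled_total", positive = TRUE)
    .assertScalarNum(competitor_total, "competitor_total", nonneg = TRUE)

    one <- function(PT) {
        if (PT == 0)
            return(c(P = 0, PL = 0, PC = 0))
        # free protein consumed by both complexes
        f <- function(P) P + labeled_total * P / (kd_labeled + P) +
            competitor_total * P / (kd_competitor + P) - PT
        r <- uniroot(f, lower = 0, upper = PT, tol = 1e-12 * max(PT, 1))
        P <- r$root
        c(P = P, PL = labeled_total * P / (kd_labeled + P),
          PC = competitor_total * P / (kd_competitor + P))
    }
    sol <- t(vapply(protein_total, one, numeric(3)))
    data.frame(protein_total = protein_total, P = sol[, "P"],
               PL = sol[, "PL"], PC = sol[, "PC"],
               bound_fraction = sol[, "PL"] / labeled_total)
}

#' Fold change in apparent affinity between two binding fits
#'
#' Ratio of the competed to the direct apparent dissociation constant.
#' For the ideal shared-site model this equals
#' \code{1 + C_T / kd_competitor} only in the weak-competitor
#' negligible-depletion limit; with a strong competitor the ideal fold
#' is \code{1 + C_T / (kd_competitor + kd_labeled)} (protein
#' sequestration; see \code{\link{solveCompetition}}). An empirically
#' measured fold change can differ from either ideal prediction.
#'
#' @param direct,competed \code{\linkS4class{HillFit}} objects (model
#'   \code{"binding"}).
#' @return numeric fold change \code{competed kd / direct kd}.
#' @export
apparentKdFoldChange <- function(direct, competed) {
    stopifnot(is(direct, "HillFit"), is(competed, "HillFit"))
    unname(coef(competed)[["kd"]] / coef(direct)[["kd"]])
}
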