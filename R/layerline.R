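#' First maximum of a squared Bessel function
#'
#' Abscissa of the first local maximum of J_n(x)^2 for x > 0, located
#' numerically (coarse grid scan followed by golden-section refinement).
#' This is the key constant in the layer-line first-maximum relation for
#' the myosin head radius.
#'
#' @param n Bessel order (integer >= 0).
#' @return the abscissa, accurate to ~1e-8.
#' @examples
#' besselFirstMax(1)   # 1.84118378
#' besselFirstMax(4)   # 5.31755313
#' @export
besselFirstMax <- function(n) {
    if (n < 0 || n %% 1 != 0) stop("n must be a non-negative integer")
    f <- function(x) besselJ(x, n)^2
    xs <- seq(1e-3, n + 8, by = 0.01)
    v <- f(xs)
    i <- which(diff(sign(diff(v))) < 0)[1] + 1L
    if (is.na(i)) stop("no interior maximum located")
    optimize(f, c(xs[i - 1], xs[i + 1]), maximum = TRUE,
             tol = 1e-10)$maximum
}

#' Myosin head radius from a layer-line first maximum
#'
#' The radial intensity of a layer line from heads arranged quasi-helically
#' at radius Rm follows J_n(2 pi Rm R)^2, so the first maximum at radius
#' r_max gives \eqn{R_m = x^*_n / (2 \pi \, r_{max})} with x*_n the first
#' maximum of J_n^2.  This is the exact inverse of the generator's
#' peak-position relation for the same Bessel order, so generator-analyzer
#' round trips are exact; the absolute calibration depends on the order
#' convention (configurable, default MLL1 -> 1, MLL4 -> 4).
#'
#' @param rMax radial position of the first maximum (nm^-1), > 0.
#' @param n Bessel order.
#' @return Rm in nm.
#' @examples
#' rmFromFirstMax(0.0234, 1)   # ~12.52 nm
#' rmFromFirstMax(0.062, 4)    # ~13.65 nm
#' @export
rmFromFirstMax <- function(rMax, n) {
    if (any(rMax <= 0)) stop("rMax must be > 0")
    besselFirstMax(n) / (2 * pi * rMax)
}

## 3 background Gaussians centered on the meridian + the layer-line peak.
## par: (b1, s1) meridional, (b2, s2) proximal, (b3, s3) broad,
##      (a, c, s) layer-line peak
.layerLineModel <- function(par, x) {
    par[1] * exp(-x^2 / (2 * par[2]^2)) +
        par[3] * exp(-x^2 / (2 * par[4]^2)) +
        par[5] * exp(-x^2 / (2 * par[6]^2)) +
        par[7] * exp(-(x - par[8])^2 / (2 * par[9]^2))
}

#' Fit a layer-line radial trace
#'
#' Simultaneous fit of the layer-line cross-section: three background
#' Gaussians centered on the meridian (the meridional peak itself, a
#' narrower meridian-proximal background, and a broad diffuse background,
#' with ordered width windows to keep the components identifiable) plus a
#' single Gaussian for the layer-line intensity around its first maximum.
#' The first-maximum position is then refined as the local maximum of the
#' background-subtracted trace (quadratic interpolation), which tracks the
#' true mode of the asymmetric Bessel lobe better than the Gaussian
#' center.
#'
#' When the Bessel order of the line is known (the usual case, since
#' analysis and modelling share one order convention), the first-maximum
#' position is instead taken from a joint fit in which the layer-line peak
#' has its physical shape, a scaled J_n(2 pi Rm R)^2 - the Bessel lobe is
#' asymmetric, and a Gaussian centroid systematically underestimates its
#' mode, most severely for low orders close to the meridian.  The Gaussian
#' component still provides the integrated intensity.
#'
#' @param trace a radial \linkS4class{Trace1D} from
#'   \code{\link{projectBand}} over a layer-line axial band.
#' @param besselOrder Bessel order of the line, or NULL if unknown (the
#'   first maximum is then refined as an interpolated local maximum).
#' @param minPeakRadius smallest radial coordinate considered for the
#'   layer-line peak (nm^-1); separates it from the meridian.
#' @return A \linkS4class{LayerLineFit} with Rm unset.  A peak area
#'   consistent with zero is flagged \code{"no_ordered_heads"}.
#' @export
fitLayerLine <- function(trace, besselOrder = NULL, minPeakRadius = 0.02) {
    x <- trace@coordinate
    y <- trace@intensity
    ysm <- if (length(y) > 11) signal::sgolayfilt(y, p = 2, n = 9) else y
    ## initialize the peak from the hull-residual so a weak layer line on
    ## a strong monotone background is still found
    hull <- .lowerHull(x, ysm)
    resid0 <- ysm - approx(x[hull], ysm[hull], xout = x)$y
    far <- x >= minPeakRadius
    c0 <- x[far][which.max(resid0[far])]
    a0 <- max(resid0[far], 1e-9)
    lower <- c(0, 5e-4, 0, 6e-3, 0, 0.03,
               0, minPeakRadius, 1.5e-3)
    upper <- c(Inf, 6e-3, Inf, 0.03, Inf, 0.15,
               Inf, max(x), 0.016)
    ## deterministic multi-start over the background width decomposition;
    ## the three ordered components admit local minima
    widthInits <- list(c(2e-3, 0.015, 0.08, 0.006),
                       c(2e-3, 0.008, 0.05, 0.006),
                       c(4e-3, 0.02, 0.10, 0.006),
                       c(1e-3, 0.010, 0.04, 0.006),
                       c(2e-3, 0.015, 0.08, 0.012),
                       c(2e-3, 0.008, 0.05, 0.012),
                       c(4e-3, 0.02, 0.10, 0.012),
                       c(1e-3, 0.010, 0.04, 0.012))
    sol <- NULL
    for (wi in widthInits) {
        par0 <- c(b1 = max(ysm[1], 0), s1 = wi[1],
                  b2 = max(ysm[x >= 0.01][1], 0), s2 = wi[2],
                  b3 = max(min(ysm), 0) + 1e-6, s3 = wi[3],
                  a = a0, c = c0, s = wi[4])
        cand <- minpack.lm::nls.lm(
            par = pmin(pmax(par0, lower), upper), lower = lower,
            upper = upper,
            fn = function(p) y - .layerLineModel(p, x),
            control = minpack.lm::nls.lm.control(ftol = 1e-12,
                                                 ptol = 1e-12,
                                                 maxiter = 1000))
        if (is.null(sol) || cand$deviance < sol$deviance) sol <- cand
    }
    par <- sol$par
    rss <- sol$deviance
    np <- length(par)
    J <- .numericJacobian(function(p) .layerLineModel(p, x), par)
    covm <- tryCatch(solve(crossprod(J)) * rss / max(length(y) - np, 1),
                     error = function(e) matrix(NA_real_, np, np))
    se <- sqrt(pmax(diag(covm), 0))
    area <- par[["a"]] * par[["s"]] * sqrt(2 * pi)
    seArea <- area * sqrt((se[7] / max(par[["a"]], 1e-12))^2 +
                              (se[9] / max(par[["s"]], 1e-12))^2)
    flags <- character()
    noise <- sd(y - .layerLineModel(par, x))
    if (par[["a"]] < 3 * noise ||
        (is.finite(seArea) && area < seArea)) {
        flags <- "no_ordered_heads"
    }
    rMax <- par[["c"]]
    if (!is.null(besselOrder)) {
        bf <- .besselJointFit(x, y, besselOrder, par, c0, a0)
        if (length(flags) && !is.null(bf) && bf$decisive) {
            ## the Gaussian peak was absorbed by the background components
            ## (degenerate near the meridian) but the Bessel-shaped fit is
            ## unambiguous: trust it
            flags <- character()
            area <- bf$area
            seArea <- bf$seArea
        }
        if (!length(flags) && !is.null(bf) && bf$ok)
            rMax <- besselFirstMax(besselOrder) / (2 * pi * bf$rho)
    } else if (!length(flags)) {
        ## refine the first maximum as the interpolated local maximum of
        ## the background-subtracted trace
        bgpar <- par; bgpar[["a"]] <- 0
        resid <- ysm - .layerLineModel(bgpar, x)
        win <- which(abs(x - par[["c"]]) <= 2 * par[["s"]] &
                         x >= minPeakRadius)
        if (length(win) >= 3) {
            i <- win[which.max(resid[win])]
            if (i > 1 && i < length(x)) {
                dy1 <- resid[i] - resid[i - 1]
                dy2 <- resid[i] - resid[i + 1]
                denom <- dy1 + dy2
                if (denom > 0)
                    rMax <- x[i] + 0.5 * (x[i + 1] - x[i]) *
                        (dy1 - dy2) / denom
            } else rMax <- x[i]
        }
    }
    r2 <- 1 - rss / sum((y - mean(y))^2)
    bg <- par[1:6]
    names(bg) <- c("meridionalAmp", "meridionalWidth", "proximalAmp",
                   "proximalWidth", "broadAmp", "broadWidth")
    new("LayerLineFit", rMax = rMax, area = unname(area),
        normalized = NA_real_, bgParams = bg, peakCenter = par[["c"]],
        peakSigma = par[["s"]],
        Rm = NA_real_, besselOrder = NA_real_,
        axialCenter = mean(trace@band),
        se = c(area = unname(seArea), center = unname(se[8])),
        gof = list(rss = rss, r2 = r2, info = sol$info),
        flags = flags, trace = trace,
        fitted = .layerLineModel(par, x))
}

## Joint fit: 3 background Gaussians + a * J_n(2 pi rho R)^2.  Exact model
## of the rendered layer line, so the first-maximum position is unbiased by
## the asymmetry of the Bessel lobe.  Returns NULL on failure.
.besselJointFit <- function(x, y, n, gaussPar, c0, a0) {
    xstar <- besselFirstMax(n)
    cInit <- if (gaussPar[["a"]] > 0) gaussPar[["c"]] else c0
    rho0 <- min(max(xstar / (2 * pi * max(cInit, 1e-4)), 6), 24)
    aInit <- max(gaussPar[["a"]], a0, 1e-9)
    model <- function(p) {
        p[1] * exp(-x^2 / (2 * p[2]^2)) +
            p[3] * exp(-x^2 / (2 * p[4]^2)) +
            p[5] * exp(-x^2 / (2 * p[6]^2)) +
            p[7] * besselJ(2 * pi * p[8] * x, n)^2
    }
    bgModel <- function(p) {
        p[1] * exp(-x^2 / (2 * p[2]^2)) +
            p[3] * exp(-x^2 / (2 * p[4]^2)) +
            p[5] * exp(-x^2 / (2 * p[6]^2))
    }
    par0 <- c(gaussPar[1:6], a = aInit / max(besselJ(xstar, n)^2, 1e-9),
              rho = rho0)
    lower <- c(0, 5e-4, 0, 6e-3, 0, 0.03, 0, 5)
    upper <- c(Inf, 6e-3, Inf, 0.03, Inf, 0.5, Inf, 30)
    sol <- try(minpack.lm::nls.lm(
        par = pmin(pmax(par0, lower), upper), lower = lower, upper = upper,
        fn = function(p) y - model(p),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                             maxiter = 1000)), silent = TRUE)
    if (inherits(sol, "try-error")) return(NULL)
    p <- sol$par
    rss <- sol$deviance
    solBG <- minpack.lm::nls.lm(
        par = gaussPar[1:6], lower = lower[1:6], upper = upper[1:6],
        fn = function(q) y - bgModel(q),
        control = minpack.lm::nls.lm.control(maxiter = 500))
    J <- .numericJacobian(model, p)
    covm <- tryCatch(solve(crossprod(J)) * rss / max(length(y) - 8, 1),
                     error = function(e) matrix(NA_real_, 8, 8))
    seAmp <- sqrt(max(covm[7, 7], 0))
    ## one-sided integrated intensity of the Bessel component
    dx <- mean(diff(x))
    areaB <- p[[7]] * sum(besselJ(2 * pi * p[[8]] * x, n)^2) * dx
    list(rho = p[[8]], amp = p[[7]], area = unname(areaB),
         seArea = if (is.finite(seAmp) && p[[7]] > 0)
             unname(areaB * seAmp / p[[7]]) else NA_real_,
         ok = p[[7]] > 0,
         decisive = is.finite(seAmp) && p[[7]] > 5 * seAmp &&
             rss < 0.25 * solBG$deviance)
}

#' Layer-line analysis of a diffraction image
#'
#' Folds the image (optionally), projects the layer-line axial band onto
#' the equatorial direction, fits the trace with
#' \code{\link{fitLayerLine}}, derives the myosin head radius from the
#' first maximum, and (when a \linkS4class{BackgroundModel} is supplied)
#' records the diffuse-normalized integrated intensity.
#'
#' @param image a \linkS4class{DiffractionImage}.
#' @param band axial integration limits (nm^-1); the default
#'   [0.088, 0.097] isolates the fourth myosin layer line while minimizing
#'   actomyosin contamination.
#' @param besselOrder Bessel order for the Rm relation (default 4 for
#'   MLL4).
#' @param background optional \linkS4class{BackgroundModel} for diffuse
#'   normalization.
#' @param fold quadrant-fold before projecting.
#' @return A \linkS4class{LayerLineFit}.
#' @examples
#' img <- renderPattern(latticeModel(), detectorGeometry(), "resting",
#'                      seed = 1)
#' ll <- analyzeLayerLine(img)
#' firstMaximum(ll); headRadius(ll)
#' @export
analyzeLayerLine <- function(image, band = c(0.088, 0.097),
                             besselOrder = 4, background = NULL,
                             fold = TRUE) {
    if (fold) image <- quadrantFold(image)
    tr <- projectBand(image, "onto_equatorial_direction", band)
    fit <- fitLayerLine(tr, besselOrder = besselOrder)
    fit@besselOrder <- besselOrder
    if (!length(fit@flags))
        fit@Rm <- rmFromFirstMax(fit@rMax, besselOrder)
    if (!is.null(background))
        fit@normalized <- normalizeByDiffuse(fit@area, background)
    fit
}

#' Residual layer-line intensity ratio between two states
#'
#' The ratio of normalized integrated layer-line intensities (for example
#' contracting over resting MLL4).  Values below the noise floor are
#' clipped at zero.
#'
#' @param iActive,iRest normalized integrated intensities, each divided by
#'   its own diffuse background; \code{iRest} must be > 0.  Either may be
#'   a \linkS4class{LayerLineFit} flagged "no_ordered_heads", which counts
#'   as zero intensity.
#' @return iActive / iRest, clipped at 0.
#' @export
residualIntensityRatio <- function(iActive, iRest) {
    geti <- function(z) {
        if (is(z, "LayerLineFit")) {
            if ("no_ordered_heads" %in% fitFlags(z)) 0
            else integratedIntensity(z)
        } else as.numeric(z)
    }
    ir <- geti(iRest)
    if (ir <= 0) stop("resting intensity must be > 0")
    max(0, geti(iActive) / ir)
}

## Fit a Gaussian center on an axial trace near an expected position.
.axialPeakCenter <- function(trace, zExpect, halfWindow = 0.006) {
    z <- trace@coordinate
    v <- trace@intensity
    keep <- abs(z - zExpect) <= halfWindow
    if (sum(keep) < 5)
        stop("axial window around ", signif(zExpect, 3),
             " nm^-1 not covered by the trace")
    z <- z[keep]; v <- v[keep]
    v <- v - min(v)
    if (max(v) <= 0) stop("no axial peak found near ", signif(zExpect, 3))
    ## Gaussian on a linear baseline: the diffuse background slopes across
    ## the window and would otherwise bias the fitted center
    par0 <- c(a = max(v), c = z[which.max(v)], s = 1.5e-3,
              b0 = 0, b1 = 0)
    rng <- diff(range(z))
    sol <- minpack.lm::nls.lm(
        par = par0, lower = c(0, min(z), 3e-4, -Inf, -Inf),
        upper = c(Inf, max(z), halfWindow, Inf, Inf),
        fn = function(p) v - (p[1] * exp(-(z - p[2])^2 / (2 * p[3]^2)) +
                                  p[4] + p[5] * (z - zExpect)),
        control = minpack.lm::nls.lm.control(ftol = 1e-12, maxiter = 500))
    if (sol$par[["a"]] <= 0)
        stop("no axial peak found near ", signif(zExpect, 3))
    sol$par[["c"]]
}

#' Fractional axial spacing shift of a layer line between two states
#'
#' Fits the axial centers Z of layer line l in two axial traces and
#' returns (Z_rest / Z_active) - 1, which is positive when the real-space
#' axial repeat increases on activation (the ~1% myosin spacing change
#' moves the layer lines inward).
#'
#' @param traceRest,traceActive axial \linkS4class{Trace1D}s from
#'   \code{\link{projectBand}} (onto the meridian).
#' @param l layer-line index.
#' @param cMyosin resting myosin repeat (nm) used to locate the search
#'   window.
#' @return the fractional shift.
#' @export
axialSpacingShift <- function(traceRest, traceActive, l, cMyosin = 43) {
    zExpect <- l / cMyosin
    zr <- .axialPeakCenter(traceRest, zExpect)
    za <- .axialPeakCenter(traceActive, zExpect)
    zr / za - 1
}

#' Integrated tropomyosin/ALL2 intensity
#'
#' Sums the background-subtracted intensity in the outer part of the
#' second actin layer line (the tropomyosin-sensitive band) and
#' normalizes by the diffuse background.  The band excludes the inner
#' portion of ALL2.
#'
#' @param image a \linkS4class{DiffractionImage} (raw; folded and
#'   background-subtracted internally unless \code{fold = FALSE}).
#' @param axialBand axial limits (nm^-1) around the second actin layer
#'   line (default centered on 2/35.9 nm^-1).
#' @param radialBand radial limits (nm^-1) selecting the outer portion.
#' @param fold fold and background-subtract first.
#' @return dimensionless normalized intensity.
#' @export
tmAll2Intensity <- function(image,
                            axialBand = c(0.0517, 0.0597),
                            radialBand = c(0.045, 0.095),
                            fold = TRUE) {
    if (axialBand[1] >= axialBand[2] || radialBand[1] >= radialBand[2])
        stop("band limits must be ordered")
    geom <- geometry(image)
    co <- reciprocalCoordinates(geom)
    lim <- max(abs(c(co$rx, co$rz)))
    if (axialBand[1] > lim || radialBand[1] > lim)
        stop("Tm/ALL2 band lies outside the detector")
    if (fold) image <- quadrantFold(image)
    bg <- estimateCircularBackground(image)
    sub <- subtractBackground(image, bg)
    x <- counts(sub)
    x[is.na(x)] <- 0
    wz <- .bandCover(co$rz, axialBand, co$step)
    wx <- .bandCover(co$rx, radialBand, co$step)
    total <- as.numeric(t(wz) %*% x %*% wx)
    normalizeByDiffuse(total, bg)
}

.bandCover <- function(r, band, k) {
    lo <- abs(r) - k / 2
    hi <- abs(r) + k / 2
    pmax(0, (pmin(hi, band[2]) - pmax(lo, band[1])) / k)
}
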