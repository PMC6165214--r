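#' Disorder-decomposed equatorial peak width
#'
#' The radial width of equatorial reflection (h,k) decomposes as
#' \deqn{\sigma_{hk} = \sqrt{\sigma_c^2 + \sigma_d^2 \theta_{hk}^2 +
#'   \sigma_s^2 \theta_{hk}^4}}
#' where sigma_c is the instrumental beam width, sigma_d reflects
#' heterogeneity in interfilament spacing among myofibrils (scales with
#' theta), and sigma_s reflects paracrystalline (liquid-like) disorder of
#' the second kind (scales with theta^2).
#'
#' @param theta dimensionless lattice index theta_hk (may be a vector).
#' @param sigmaC,sigmaD,sigmaS width components (nm^-1), all >= 0.
#' @return sigma_hk in nm^-1.
#' @examples
#' widthModel(1, 0.84e-3, 1.36e-3, 0.54e-3)       # ~1.687e-3
#' widthModel(sqrt(3), 0.84e-3, 1.36e-3, 0.54e-3) # ~2.980e-3
#' @export
widthModel <- function(theta, sigmaC, sigmaD, sigmaS) {
    if (any(c(sigmaC, sigmaD, sigmaS) < 0))
        stop("width components must be >= 0")
    sqrt(sigmaC^2 + sigmaD^2 * theta^2 + sigmaS^2 * theta^4)
}

#' Remove a convex-hull baseline from a trace
#'
#' Subtracts the lower convex hull of the (coordinate, intensity) point
#' set, the standard smooth-background removal for equatorial traces.  The
#' output is exactly zero at both endpoints and at every hull contact
#' point, and non-negative everywhere the input touched its hull.
#'
#' @param trace a \linkS4class{Trace1D} with at least 3 points.
#' @return the baseline-removed \linkS4class{Trace1D}.
#' @export
convexHullBaseline <- function(trace) {
    x <- trace@coordinate
    y <- trace@intensity
    if (length(x) < 3)
        stop("convex-hull baseline needs at least 3 points")
    hull <- .lowerHull(x, y)
    base <- approx(x[hull], y[hull], xout = x)$y
    trace1D(x, y - base, band = trace@band, axis = trace@axis)
}

## Andrew's monotone chain, lower hull only; x assumed strictly increasing.
.lowerHull <- function(x, y) {
    n <- length(x)
    hull <- integer(0)
    for (i in seq_len(n)) {
        while (length(hull) >= 2) {
            j <- hull[length(hull)]
            k <- hull[length(hull) - 1]
            ## drop j if it lies on or above the chord k -> i
            if ((x[j] - x[k]) * (y[i] - y[k]) -
                (y[j] - y[k]) * (x[i] - x[k]) <= 0)
                hull <- hull[-length(hull)]
            else break
        }
        hull <- c(hull, i)
    }
    hull
}

## Multi-Gaussian equator model: areas a[1..5] at lattice radii theta/d10
## with widths from the disorder model.
.equatorThetas <- sqrt(c(1, 3, 4, 7, 9))

.equatorModel <- function(par, x, sigmaC, nOrders) {
    d10 <- par[1]
    s <- widthModel(.equatorThetas[seq_len(nOrders)], sigmaC,
                    par[2], par[3])
    y <- numeric(length(x))
    for (i in seq_len(nOrders)) {
        y <- y + par[3 + i] / (sqrt(2 * pi) * s[i]) *
            exp(-(x - .equatorThetas[i] / d10)^2 / (2 * s[i]^2))
    }
    y
}

.numericJacobian <- function(fn, par, eps = 1e-6) {
    f0 <- fn(par)
    J <- matrix(0, length(f0), length(par))
    for (i in seq_along(par)) {
        h <- eps * max(abs(par[i]), 1e-8)
        pp <- par; pp[i] <- pp[i] + h
        J[, i] <- (fn(pp) - f0) / h
    }
    J
}

.localMaxima <- function(y) {
    n <- length(y)
    if (n < 3) return(integer(0))
    which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Fit the equatorial trace with five lattice-constrained Gaussians
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the first five
#' diffraction orders (1,0), (1,1), (2,0), (2,1), (3,0) as Gaussians whose
#' centers are hard-constrained to the hexagonal lattice (theta_hk / d10)
#' and whose widths follow \code{\link{widthModel}} with sigma_c fixed.
#' Free parameters: d10, sigma_d, sigma_s and the five Gaussian areas.
#' Initialization takes the two largest local maxima as (1,0) and (1,1);
#' if they are closer than three beam widths, d10 is re-seeded from the
#' global maximum taken as (1,0).  Reported intensities are Gaussian areas
#' (robust to exposure), and I11/I10 is the area ratio.
#'
#' @param trace a baseline-removed radial \linkS4class{Trace1D} covering
#'   at least the (1,0) ... (3,0) radii.
#' @param sigmaC fixed instrumental width (nm^-1).
#' @param nOrders number of orders fitted (default 5).
#' @param restarts maximum deterministic re-initializations on
#'   non-convergence.
#' @return An \linkS4class{EquatorFit}.
#' @export
fitEquator <- function(trace, sigmaC = 0.84e-3, nOrders = 5, restarts = 5) {
    x <- trace@coordinate
    y <- trace@intensity
    ysm <- if (length(y) > 11) signal::sgolayfilt(y, p = 2, n = 7) else y
    peaks <- .localMaxima(ysm)
    peaks <- peaks[ysm[peaks] > 0.02 * max(ysm)]
    if (length(peaks) < 2)
        stop("could not locate both the (1,0) and (1,1) reflections ",
             "above noise; refusing to report a ratio")
    ord <- peaks[order(ysm[peaks], decreasing = TRUE)][1:2]
    p10 <- x[min(ord)]
    p11 <- x[max(ord)]
    if (abs(p11 - p10) < 3 * sigmaC) {
        ## degenerate initialization: re-seed from the global maximum
        p10 <- x[which.max(ysm)]
        p11 <- p10 * sqrt(3)
    }
    d10i <- 1 / p10
    si <- widthModel(.equatorThetas[1:2], sigmaC, 1.4e-3, 0.6e-3)
    areas0 <- pmax(c(ysm[min(ord)] * si[1], ysm[max(ord)] * si[2]) *
                       sqrt(2 * pi), 1e-9)
    par0 <- c(d10i, 1.4e-3, 0.6e-3, areas0[1], areas0[2],
              rep(0.1 * areas0[1], nOrders - 2))

    resid <- function(par) y - .equatorModel(par, x, sigmaC, nOrders)
    lower <- c(d10i * 0.7, 0, 0, rep(0, nOrders))
    upper <- c(d10i * 1.3, 0.05, 0.05, rep(Inf, nOrders))
    jitter <- rbind(1, cbind(1.05, 0.8, 1.3, 1, 1, 1, 1, 1),
                    cbind(0.95, 1.3, 0.7, 1, 1, 1, 1, 1),
                    cbind(1.02, 0.5, 1.6, 1, 1, 1, 1, 1),
                    cbind(0.98, 1.6, 0.5, 1, 1, 1, 1, 1),
                    cbind(1.0, 2.0, 2.0, 1, 1, 1, 1, 1))
    best <- NULL
    for (r in seq_len(min(restarts + 1, nrow(jitter)))) {
        p0 <- par0 * jitter[r, seq_along(par0)]
        sol <- try(minpack.lm::nls.lm(
            par = pmin(pmax(p0, lower), upper), lower = lower, upper = upper,
            fn = resid,
            control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                                 maxiter = 500)),
            silent = TRUE)
        if (inherits(sol, "try-error")) next
        if (is.null(best) || sol$deviance < best$deviance) best <- sol
        if (best$deviance <= 1e-10 * sum(y^2) ||
            (r == 1 && sol$info %in% 1:4)) break
    }
    if (is.null(best))
        stop("equatorial fit failed to converge after restarts")
    par <- best$par
    rss <- best$deviance
    n <- length(y)
    np <- length(par)
    fittedAt <- function(p) .equatorModel(p, x, sigmaC, nOrders)
    J <- .numericJacobian(function(p) .equatorModel(p, x, sigmaC, nOrders),
                          par)
    ## heteroskedasticity-consistent (sandwich) covariance: counting noise
    ## scales with intensity, so the homoskedastic formula understates the
    ## uncertainty at the peaks
    ## sandwich covariance with a smoothed variance function: counting
    ## noise scales with intensity, and modelling var_i = b0 + b1*fitted_i
    ## (rather than using raw squared residuals) keeps the estimate stable
    ## at the sparse high-leverage peak points
    r <- y - fittedAt(par)
    covm <- tryCatch({
        Ai <- solve(crossprod(J))
        h <- pmin(rowSums((J %*% Ai) * J), 0.9)
        mu <- fittedAt(par)
        vfit <- lm(I(r^2 / (1 - h)) ~ mu)
        v <- pmax(fitted(vfit), mean(r^2) * 1e-3)
        Ai %*% crossprod(J * sqrt(v / (1 - h))) %*% Ai
    }, error = function(e) matrix(NA_real_, np, np))
    se <- sqrt(pmax(diag(covm), 0))
    areas <- par[3 + seq_len(nOrders)]
    names(areas) <- .equatorLabels[seq_len(nOrders)]
    ratio <- areas[["1,1"]] / areas[["1,0"]]
    vr <- covm[5, 5] / areas[[1]]^2 +
        covm[4, 4] * areas[[2]]^2 / areas[[1]]^4 -
        2 * covm[4, 5] * areas[[2]] / areas[[1]]^3
    seAll <- c(d10 = se[1], sigmaD = se[2], sigmaS = se[3],
               structure(se[3 + seq_len(nOrders)],
                         names = paste0("area", .equatorLabels[seq_len(nOrders)])),
               ratio = sqrt(max(vr, 0)))
    flags <- character()
    if (!best$info %in% 1:4) flags <- c(flags, "no_convergence")
    if (is.finite(seAll[["area1,1"]]) &&
        areas[["1,1"]] < 3 * seAll[["area1,1"]])
        flags <- c(flags, "low_confidence_11")
    fitted <- .equatorModel(par, x, sigmaC, nOrders)
    r2 <- 1 - rss / sum((y - mean(y))^2)
    new("EquatorFit", d10 = par[1], areas = areas, ratio = ratio,
        sigmaC = sigmaC, sigmaD = par[2], sigmaS = par[3],
        axialWidth = NA_real_, se = seAll,
        gof = list(rss = rss, r2 = r2, info = best$info,
                   message = best$message),
        flags = flags, trace = trace, fitted = fitted)
}

#' Change in the equatorial intensity ratio between two states
#'
#' @param rest,active \linkS4class{EquatorFit} objects (or bare ratios)
#'   for the reference and the active state.
#' @return active ratio minus resting ratio; antisymmetric under swap.
#' @examples
#' deltaRatio(0.421, 1.175)   # 0.754
#' deltaRatio(0.421, 2.13)    # 1.709
#' @export
deltaRatio <- function(rest, active) {
    getr <- function(z) {
        if (is(z, "EquatorFit")) {
            if ("no_convergence" %in% fitFlags(z))
                stop("cannot compute a ratio change from a non-converged fit")
            intensityRatio(z)
        } else as.numeric(z)
    }
    getr(active) - getr(rest)
}

#' Measure the axial width of an equatorial reflection
#'
#' Fits a Gaussian to the meridian-parallel cross-section through the
#' reflection center of a folded, background-subtracted image.  The
#' fitted axial center must sit on the equator; a displaced or absent peak
#' (as when the image axes are transposed) is an error, not a value.
#'
#' @param image a folded, background-subtracted
#'   \linkS4class{DiffractionImage}.
#' @param reflection integer(2) Miller indices, default (1,0).
#' @param fit the converged \linkS4class{EquatorFit} locating the peak.
#' @param window axial half-range used for the cross-section (nm^-1).
#' @return axial Gaussian sigma in nm^-1.
#' @export
measureAxialWidth <- function(image, reflection = c(1, 0), fit,
                              window = 0.02) {
    theta <- thetaHK(reflection[1], reflection[2])
    R <- theta / d10(fit)
    sHK <- widthModel(theta, fit@sigmaC, fit@sigmaD, fit@sigmaS)
    co <- reciprocalCoordinates(geometry(image))
    colsel <- abs(abs(co$rx) - R) <= 1.5 * sHK
    if (!any(colsel))
        stop("reflection radius outside the detector")
    x <- counts(image)
    x[is.na(x)] <- 0
    prof <- rowSums(x[, colsel, drop = FALSE])
    keep <- abs(co$rz) <= window
    z <- co$rz[keep]
    v <- prof[keep]
    v <- v - median(v[abs(z) > 0.6 * window])
    noise <- mad(v[abs(z) > 0.6 * window])
    if (max(v) < 6 * max(noise, 1e-12))
        stop("no equatorial reflection found at the expected position; ",
             "check the image orientation (meridian must run along rows)")
    par0 <- c(amp = max(v), center = 0, s = 2.7e-3)
    sol <- minpack.lm::nls.lm(
        par = par0,
        lower = c(0, -window, 1e-5), upper = c(Inf, window, window),
        fn = function(p) v - p[1] * exp(-(z - p[2])^2 / (2 * p[3]^2)),
        control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200))
    if (abs(sol$par[2]) > 3e-3)
        stop("axial cross-section peak is off the equator (center ",
             signif(sol$par[2], 3), " nm^-1); check image orientation")
    unname(sol$par[3])
}

#' Full equatorial analysis of a diffraction image
#'
#' The image pipeline behind the equatorial intensity ratio: quadrant
#' fold, circularly symmetric background subtraction, projection of an
#' equatorial band onto the radial axis, convex-hull baseline removal, and
#' the constrained five-order Gaussian fit.
#'
#' @param image a \linkS4class{DiffractionImage} (raw; folding and
#'   background subtraction are applied unless disabled).
#' @param sigmaC fixed instrumental width (nm^-1).
#' @param axialBand axial integration limits for the equatorial box
#'   (nm^-1); the default just encloses the reflections.
#' @param fitRange radial range fitted (nm^-1); excludes the beam region.
#' @param fold,subtract run the folding / background-subtraction steps.
#' @param measureAxial also measure the (1,0) axial width from the 2D
#'   image.
#' @param nOrders number of equatorial orders fitted.
#' @return An \linkS4class{EquatorFit}.
#' @examples
#' img <- renderPattern(latticeModel(), detectorGeometry(), "resting",
#'                      seed = 1)
#' fit <- analyzeEquator(img)
#' intensityRatio(fit)
#' @export
analyzeEquator <- function(image, sigmaC = 0.84e-3,
                           axialBand = c(0, 0.009),
                           fitRange = c(0.012, 0.096),
                           fold = TRUE, subtract = TRUE,
                           measureAxial = FALSE, nOrders = 5) {
    if (fold) image <- quadrantFold(image)
    imgSub <- image
    if (subtract) {
        bg <- estimateCircularBackground(image)
        imgSub <- subtractBackground(image, bg)
    }
    tr <- projectBand(imgSub, "onto_equatorial_direction", axialBand)
    keep <- tr@coordinate >= fitRange[1] & tr@coordinate <= fitRange[2]
    tr <- trace1D(tr@coordinate[keep], tr@intensity[keep],
                  band = axialBand, axis = "radial")
    tr <- convexHullBaseline(tr)
    fit <- fitEquator(tr, sigmaC = sigmaC, nOrders = nOrders)
    if (measureAxial)
        fit@axialWidth <- measureAxialWidth(imgSub, c(1, 0), fit)
    fit
}
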