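#' Ordered head fraction from a residual intensity ratio
#'
#' Helical diffraction intensity is proportional to the square of the
#' coherently ordered mass, so the fraction of myosin heads remaining in
#' the quasi-helically ordered resting configuration is the square root of
#' the residual layer-line intensity ratio.  Ratios above 1 (ordering
#' enhanced, e.g. by blebbistatin) return a fraction above 1 with a flag
#' attribute.
#'
#' @param residualRatio active/resting normalized layer-line intensity,
#'   >= 0.
#' @return the ordered head fraction; attribute \code{flag =
#'   "enhanced_ordering"} when the input exceeds 1.
#' @examples
#' orderedHeadFraction(0.28)   # ~0.53
#' @export
orderedHeadFraction <- function(residualRatio) {
    if (any(residualRatio < 0)) stop("residual ratio must be >= 0")
    out <- sqrt(residualRatio)
    if (any(residualRatio > 1))
        attr(out, "flag") <- "enhanced_ordering"
    out
}

#' Recruited and remaining head fractions from ratio changes
#'
#' Assuming the equatorial intensity ratio change is linear in the number
#' of recruited myosin heads, with rigor (all heads recruited to actin) as
#' the full-scale reference, the recruited fraction in a state is the
#' state's ratio change divided by the rigor ratio change.
#'
#' @param deltaRatioState ratio change (active minus resting) in the
#'   state of interest.
#' @param deltaRatioRigor ratio change in rigor, > 0.
#' @return named numeric with \code{recruited} and \code{remaining}
#'   fractions, summing to 1.
#' @examples
#' recruitedFraction(0.76, 1.72)   # recruited ~0.44, remaining ~0.56
#' @export
recruitedFraction <- function(deltaRatioState, deltaRatioRigor) {
    if (deltaRatioRigor <= 0)
        stop("rigor ratio change must be > 0")
    f <- deltaRatioState / deltaRatioRigor
    c(recruited = f, remaining = 1 - f)
}

#' Muscle cross-sectional area from mass and length
#'
#' csa = mass / (density * length), with the ml-to-mm^3 conversion, under
#' the standard assumption of a muscle density of 1.06 g/ml.
#'
#' @param mass muscle mass (g).
#' @param length muscle length (mm).
#' @param density muscle density (g/ml).
#' @return cross-sectional area in mm^2.
#' @examples
#' crossSectionalArea(0.0106, 10)   # 1 mm^2
#' @export
crossSectionalArea <- function(mass, length, density = 1.06) {
    if (any(c(mass, length, density) <= 0))
        stop("mass, length and density must be > 0")
    mass / (density * length) * 1000
}

#' Specific tension
#'
#' @param force force (mN).
#' @param csa cross-sectional area (mm^2).
#' @return specific tension in mN/mm^2.
#' @export
specificTension <- function(force, csa) {
    if (any(csa <= 0)) stop("cross-sectional area must be > 0")
    force / csa
}

#' Build a mechanics table with derived quantities
#'
#' @param state character state labels.
#' @param force force (mN).
#' @param length muscle length L0 (mm).
#' @param mass muscle mass (g).
#' @param density muscle density (g/ml).
#' @param passive optional passive tension (mN/mm^2).
#' @return data.frame with csa (mm^2) and specificTension (mN/mm^2) added.
#' @export
mechanicsTable <- function(state, force, length, mass, density = 1.06,
                           passive = NA_real_) {
    csa <- crossSectionalArea(mass, length, density)
    data.frame(state = state, force = force, length = length, mass = mass,
               csa = csa, specificTension = specificTension(force, csa),
               passive = passive, stringsAsFactors = FALSE)
}

#' Linear regression of an intensity measure on tension
#'
#' Ordinary (optionally weighted) least squares with the slope standard
#' error, R^2 and the two-sided p-value for a non-zero slope.
#'
#' @param x,y predictor (e.g. active tension) and response (e.g. ratio
#'   change), n >= 3.
#' @param uncertainties optional per-point standard deviations of y; used
#'   as inverse-variance weights.
#' @return list with slope, intercept, their standard errors, r2 and
#'   pSlope.
#' @examples
#' fitTensionLinear(0:10, 0.0025 * (0:10))$slope   # 0.0025
#' @export
fitTensionLinear <- function(x, y, uncertainties = NULL) {
    if (length(x) < 3) stop("need at least 3 points")
    if (var(x) == 0) stop("predictor has zero variance")
    w <- if (is.null(uncertainties)) NULL else 1 / uncertainties^2
    fit <- if (is.null(w)) lm(y ~ x) else lm(y ~ x, weights = w)
    s <- summary(fit)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         slopeSE = s$coefficients[2, 2],
         interceptSE = s$coefficients[1, 2],
         r2 = s$r.squared, pSlope = s$coefficients[2, 4], fit = fit)
}

#' Second-order polynomial regression
#'
#' Used to describe non-linear intensity-tension relationships (no
#' physical interpretation of the coefficients is implied).
#'
#' @param x,y data, n >= 4.
#' @return list with coefficients (intercept, linear, quadratic), their
#'   standard errors and r2.
#' @export
fitTensionPoly2 <- function(x, y) {
    if (length(x) < 4) stop("need at least 4 points")
    fit <- lm(y ~ x + I(x^2))
    s <- summary(fit)
    list(coefficients = unname(coef(fit)),
         se = unname(s$coefficients[, 2]), r2 = s$r.squared, fit = fit)
}

#' Hill versus linear description of the ratio-tension relation
#'
#' Fits both a Hill curve \eqn{y = y_{max} x^h / (x_{50}^h + x^h)} and a
#' straight line to normalized ratio-change versus normalized tension
#' data, and compares them by an extra-sum-of-squares F-test (the linear
#' model is treated as the restricted description; AICc for both is also
#' reported since the models are not strictly nested).  The slope of the
#' low-tension linear regime (x <= \code{lowTensionMax}) is reported
#' separately.
#'
#' @param x normalized tension in [0, 1], n >= 6.
#' @param y normalized ratio change.
#' @param lowTensionMax upper limit of the low-tension linear regime.
#' @return list with \code{hill} (ymax, x50, h), \code{linear} (slope,
#'   intercept, r2), \code{pComparison} (F-test p for the Hill fit
#'   improving on the line), \code{aicc} (named, hill and linear),
#'   \code{lowTension} (slope, slopeSE, r2) and \code{flags}.
#' @export
hillVsLinear <- function(x, y, lowTensionMax = 0.6) {
    if (length(x) < 6) stop("need at least 6 points")
    if (any(x < 0 | x > 1)) stop("x must be normalized to [0, 1]")
    n <- length(x)
    lin <- lm(y ~ x)
    rssLin <- sum(resid(lin)^2)
    flags <- character()
    hill <- tryCatch(
        minpack.lm::nlsLM(y ~ ymax * x^h / (x50^h + x^h),
                          start = list(ymax = max(y), x50 = 0.5, h = 2),
                          lower = c(1e-6, 1e-3, 0.2),
                          upper = c(Inf, 2, 25),
                          control = minpack.lm::nls.lm.control(
                              maxiter = 500)),
        error = function(e) NULL)
    if (is.null(hill)) {
        flags <- "hill_nonconvergent_fell_back_to_linear"
        rssHill <- rssLin
        hillPars <- c(ymax = NA, x50 = NA, h = NA)
        p <- 1
    } else {
        rssHill <- sum(resid(hill)^2)
        hillPars <- coef(hill)
        dfHill <- n - 3
        F <- ((rssLin - rssHill) / 1) / (rssHill / dfHill)
        p <- if (F > 0) pf(F, 1, dfHill, lower.tail = FALSE) else 1
    }
    aicc <- function(rss, k) {
        n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
    }
    low <- x <= lowTensionMax
    lowFit <- if (sum(low) >= 3) fitTensionLinear(x[low], y[low]) else NULL
    list(hill = hillPars,
         linear = list(slope = unname(coef(lin)[2]),
                       intercept = unname(coef(lin)[1]),
                       r2 = summary(lin)$r.squared),
         pComparison = p,
         aicc = c(hill = aicc(rssHill, 4), linear = aicc(rssLin, 3)),
         lowTension = if (is.null(lowFit)) NULL else
             list(slope = lowFit$slope, slopeSE = lowFit$slopeSE,
                  r2 = lowFit$r2),
         flags = flags)
}
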