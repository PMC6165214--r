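#' Hexagonal lattice index theta_hk
#'
#' The reciprocal radius of equatorial reflection (h,k) of a hexagonal
#' lattice with plane spacing d10 is theta_hk / d10, with
#' theta_hk = sqrt(h^2 + k^2 + h k).
#'
#' @param h,k integer Miller indices; (0,0) is not a reflection.
#' @return theta_hk (dimensionless).
#' @examples
#' thetaHK(1, 0)   # 1
#' thetaHK(1, 1)   # sqrt(3)
#' @export
thetaHK <- function(h, k) {
    if (any(c(h, k) %% 1 != 0))
        stop("h and k must be integers")
    if (h == 0 && k == 0)
        stop("(0,0) is not a valid reflection")
    sqrt(h^2 + k^2 + h * k)
}

## Reflections modelled on the equator, in radial order.
.equatorOrders <- list(c(1, 0), c(1, 1), c(2, 0), c(2, 1), c(3, 0))
.equatorLabels <- c("1,0", "1,1", "2,0", "2,1", "3,0")

## Cylindrical Gaussian form factor: the simplest monotone radial decay.
.formFactor <- function(R, rho) exp(-2 * pi^2 * rho^2 * R^2)

.rhoThickOf <- function(model)
    if (is.na(model@rhoThick)) model@rmTrue else model@rhoThick

#' Equatorial structure factor of the two-filament unit cell
#'
#' The unit cell has a thick-filament site at (0,0) carrying the backbone
#' mass plus the fraction (1 - p) of the head mass, and two thin-filament
#' sites at (1/3, 2/3) and (2/3, 1/3), each carrying the thin-filament mass
#' plus p/2 of the head mass, where p is the head partition.  Each site is
#' weighted by a cylindrical Gaussian form factor, and
#' \eqn{F(h,k) = \sum_j m_j \phi_j(R_{hk}) e^{2\pi i (h x_j + k y_j)}}.
#' The 1,0 lattice planes contain only thick filaments, so moving head mass
#' to the thin-filament sites (raising p) raises I11/I10.
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param h,k Miller indices.
#' @return the intensity |F(h,k)|^2 (arbitrary units).
#' @seealso \code{\link{equatorIntensityRatio}}, \code{\link{solveHeadPartition}}
#' @export
equatorStructureFactor <- function(model, h, k) {
    theta <- thetaHK(h, k)
    R <- theta / model@d10
    mThick <- model@massBackbone + (1 - model@headPartition) * model@massHeads
    mThin <- model@massThin + model@headPartition * model@massHeads / 2
    phase <- exp(2i * pi * (h * 1 / 3 + k * 2 / 3)) +
        exp(2i * pi * (h * 2 / 3 + k * 1 / 3))
    F <- mThick * .formFactor(R, .rhoThickOf(model)) +
        mThin * .formFactor(R, model@rhoThin) * phase
    Mod(F)^2
}

#' Theoretical equatorial intensity ratio I11/I10
#'
#' @param model a \linkS4class{LatticeModel}.
#' @return |F(1,1)|^2 / |F(1,0)|^2.
#' @export
equatorIntensityRatio <- function(model) {
    equatorStructureFactor(model, 1, 1) / equatorStructureFactor(model, 1, 0)
}

.ratioAtPartition <- function(model, p) {
    model@headPartition <- p
    equatorIntensityRatio(model)
}

#' Solve the head partition for a target I11/I10
#'
#' Calibrates the generator to a desired equatorial intensity ratio by
#' bisection on the head partition p, over which the theoretical ratio is
#' strictly increasing (the 1,0 planes lose head mass as the 1,1 planes
#' gain it).
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param targetRatio desired I11/I10.
#' @param tol convergence tolerance on the ratio.
#' @return the head partition p in [0, 1].
#' @examples
#' m <- latticeModel()
#' p <- solveHeadPartition(m, 0.421)
#' @export
solveHeadPartition <- function(model, targetRatio, tol = 1e-9) {
    r0 <- .ratioAtPartition(model, 0)
    r1 <- .ratioAtPartition(model, 1)
    if (targetRatio < r0 - tol || targetRatio > r1 + tol)
        stop(sprintf(
            "target ratio %.4g outside achievable range [%.4g, %.4g]",
            targetRatio, r0, r1))
    if (targetRatio <= r0) return(0)
    if (targetRatio >= r1) return(1)
    uniroot(function(p) .ratioAtPartition(model, p) - targetRatio,
            c(0, 1), tol = 1e-12)$root
}

#' Construct a LatticeModel
#'
#' Defaults describe a resting fast-twitch mouse muscle under the study
#' conditions this package emulates: d10 = 36 nm, resting equatorial
#' intensity ratio 0.421 (the head partition is solved for this target when
#' \code{headPartition = NA}), resting head radius Rm = 12.53 nm, resting
#' disorder widths sigma_d = 1.36e-3 and sigma_s = 0.54e-3 nm^-1 with
#' instrumental sigma_c = 0.84e-3 nm^-1, 70% of heads quasi-helically
#' ordered, and an exposure of 1e6 expected counts.
#'
#' @param d10 lattice plane spacing (nm).
#' @param massBackbone,massThin,massHeads relative masses.
#' @param headPartition fraction of head mass at thin-filament sites; NA
#'   solves for \code{restingRatio}.
#' @param restingRatio target I11/I10 used when \code{headPartition} is NA.
#' @param rhoThick,rhoThin form-factor radii (nm); \code{rhoThick = NA}
#'   tracks \code{rmTrue}.
#' @param fOrdered ordered head fraction.
#' @param rmTrue myosin head radius (nm).
#' @param besselOrders named numeric mapping layer-line index to Bessel
#'   order.
#' @param cMyosin,cActin axial repeats (nm).
#' @param actinSymmetry subunits per turns of the actin helix.
#' @param spacingFactor fractional axial repeat increase on activation.
#' @param sigmaC,sigmaD,sigmaS equatorial width components (nm^-1).
#' @param sigmaAxial axial sigma of the equatorial reflections (nm^-1).
#' @param sigmaLL axial sigma of the layer lines (nm^-1).
#' @param amplitudes named numeric component amplitude scales.
#' @param meridionalCatalog data.frame(label, spacing, amplitude, family).
#' @param background named numeric background parameters.
#' @param activation thin-filament activation level in [0, 1].
#' @param actinScale actin layer-line amplitude multiplier.
#' @param amOn render actomyosin layer lines.
#' @param exposureScale expected total counts.
#' @return A \linkS4class{LatticeModel}.
#' @examples
#' m <- latticeModel()
#' equatorIntensityRatio(m)   # 0.421 by calibration
#' @export
latticeModel <- function(d10 = 36,
                         massBackbone = 10, massThin = 0.2, massHeads = 1.2,
                         headPartition = NA_real_, restingRatio = 0.421,
                         rhoThick = NA_real_, rhoThin = 4.5,
                         fOrdered = 0.7, rmTrue = 12.53,
                         besselOrders = c("1" = 1, "4" = 4),
                         cMyosin = 43, cActin = 35.9,
                         actinSymmetry = c(13, 6), spacingFactor = 0,
                         sigmaC = 0.84e-3, sigmaD = 1.36e-3,
                         sigmaS = 0.54e-3, sigmaAxial = 2.7e-3,
                         sigmaLL = 2.2e-3,
                         amplitudes = c(equator = 0.01, mll1 = 40,
                                        mll4 = 10, actin = 0.5, am = 3,
                                        tm = 2.5),
                         meridionalCatalog = defaultMeridionalCatalog(),
                         background = c(broadAmp = 1, broadWidth = 0.05,
                                        proxAmp = 0.5, proxWidthX = 0.008,
                                        proxWidthZ = 0.09),
                         activation = 0, actinScale = 1, amOn = FALSE,
                         exposureScale = 1e6) {
    m <- new("LatticeModel", d10 = d10, massBackbone = massBackbone,
             massThin = massThin, massHeads = massHeads,
             headPartition = if (is.na(headPartition)) 0 else headPartition,
             rhoThick = rhoThick, rhoThin = rhoThin, fOrdered = fOrdered,
             rmTrue = rmTrue, besselOrders = besselOrders,
             cMyosin = cMyosin, cActin = cActin,
             actinSymmetry = actinSymmetry, spacingFactor = spacingFactor,
             sigmaC = sigmaC, sigmaD = sigmaD, sigmaS = sigmaS,
             sigmaAxial = sigmaAxial, sigmaLL = sigmaLL,
             amplitudes = amplitudes,
             meridionalCatalog = meridionalCatalog,
             background = background, activation = activation,
             actinScale = actinScale, amOn = amOn,
             exposureScale = exposureScale)
    if (is.na(headPartition))
        m@headPartition <- solveHeadPartition(m, restingRatio)
    m
}

#' Default meridional reflection catalog
#'
#' Myosin meridionals M3 (14.3 nm) and M6 (7.2 nm); troponin orders on the
#' 38.7 nm thin-filament repeat; MyBP-C orders indexing on a ~44 nm repeat
#' (rendered as simple Gaussian peaks).  Only the myosin family moves with
#' the activation spacing change.
#'
#' @return data.frame with columns label, spacing (nm), amplitude, family.
#' @export
defaultMeridionalCatalog <- function() {
    data.frame(
        label = c("M3", "M6", "Tn1", "Tn2", "Tn3", "C1", "C2", "C4"),
        spacing = c(43 / 3, 43 / 6, 38.7, 38.7 / 2, 38.7 / 3,
                    44, 22, 11),
        amplitude = c(6, 3, 2, 1, 0.8, 1.5, 0.8, 0.8),
        family = c("myosin", "myosin", "troponin", "troponin", "troponin",
                   "mybpc", "mybpc", "mybpc"),
        stringsAsFactors = FALSE)
}

#' Axial center of a myosin layer line
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param l layer-line index.
#' @return l / (cMyosin * (1 + spacingFactor)) in nm^-1.
#' @export
layerLineAxialCenter <- function(model, l) {
    l / (model@cMyosin * (1 + model@spacingFactor))
}

#' Radial intensity profile of a myosin layer line
#'
#' The quasi-helical arrangement of ordered myosin heads at radius Rm gives
#' layer line l a radial profile proportional to J_n(2 pi Rm R)^2 with n the
#' Bessel order assigned to that line, scaled by the square of the ordered
#' head fraction (diffraction intensity is proportional to the square of
#' the coherently ordered mass).
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param l layer-line index; must be present in \code{besselOrders}.
#' @return a function of R (nm^-1) returning intensity; attributes
#'   \code{axialCenter} (nm^-1) and \code{besselOrder} record the line
#'   geometry.
#' @examples
#' prof <- layerLineProfile(latticeModel(rmTrue = 13.65), 4)
#' optimize(prof, c(0.02, 0.09), maximum = TRUE)$maximum  # ~0.062 nm^-1
#' @export
layerLineProfile <- function(model, l) {
    if (l < 1) stop("layer-line index must be >= 1")
    key <- as.character(l)
    if (!key %in% names(model@besselOrders))
        stop("no Bessel order configured for layer line ", l)
    n <- model@besselOrders[[key]]
    ampName <- paste0("mll", l)
    amp <- if (ampName %in% names(model@amplitudes))
        model@amplitudes[[ampName]] else 1
    f2 <- model@fOrdered^2
    rm <- model@rmTrue
    fun <- function(R) f2 * amp * besselJ(2 * pi * rm * R, n)^2
    attr(fun, "axialCenter") <- layerLineAxialCenter(model, l)
    attr(fun, "besselOrder") <- n
    fun
}

#' Reciprocal radii of the modelled equatorial reflections
#'
#' @param model a \linkS4class{LatticeModel}.
#' @return named numeric, theta_hk / d10 for (1,0) ... (3,0) in nm^-1.
#' @export
equatorPeakRadii <- function(model) {
    r <- vapply(.equatorOrders, function(hk) thetaHK(hk[1], hk[2]),
                numeric(1)) / model@d10
    names(r) <- .equatorLabels
    r
}

#' Noise-free equatorial trace
#'
#' Renders a one-dimensional equatorial intensity trace as a sum of
#' Gaussian reflections at the lattice radii theta_hk/d10 with widths from
#' \code{\link{widthModel}}.  Used to generate trace-level fixtures with
#' exact ground truth.
#'
#' @param coordinate radial coordinate values (nm^-1).
#' @param d10 lattice spacing (nm).
#' @param areas length-5 Gaussian areas for (1,0), (1,1), (2,0), (2,1),
#'   (3,0).
#' @param sigmaC,sigmaD,sigmaS width components (nm^-1).
#' @return a \linkS4class{Trace1D} (axis "radial").
#' @export
equatorTrace <- function(coordinate, d10, areas, sigmaC = 0.84e-3,
                         sigmaD = 1.36e-3, sigmaS = 0.54e-3) {
    stopifnot(length(areas) == 5)
    thetas <- vapply(.equatorOrders, function(hk) thetaHK(hk[1], hk[2]),
                     numeric(1))
    y <- numeric(length(coordinate))
    for (i in seq_along(thetas)) {
        s <- widthModel(thetas[i], sigmaC, sigmaD, sigmaS)
        y <- y + areas[i] / (sqrt(2 * pi) * s) *
            exp(-(coordinate - thetas[i] / d10)^2 / (2 * s^2))
    }
    trace1D(coordinate, y, band = range(coordinate), axis = "radial")
}

#' Apply a physiological state preset to a model
#'
#' State presets emulate resting, tetanically contracting, rigor,
#' blebbistatin-inhibited and BTS-inhibited muscle:
#' \describe{
#'   \item{resting}{the model unchanged; activation 0.}
#'   \item{contracting}{ordered fraction multiplied by
#'     \code{contractingFactor} (default sqrt(0.28), the square root of the
#'     residual layer-line intensity ratio), a 1% increase of the myosin
#'     axial repeat, doubled liquid-like disorder sigma_s, head partition
#'     raised to reach \code{contractingRatio}, full thin-filament
#'     activation.}
#'   \item{rigor}{no ordered heads, strong actin and actomyosin layer
#'     lines, maximal head partition.}
#'   \item{blebbistatin}{ordering enhanced (\code{blebOrderingFactor}),
#'     head radius reduced (\code{blebRmFactor}), head partition lowered
#'     (\code{blebPartitionFactor}); no activation.}
#'   \item{BTS}{resting-like ordering and structure; force inhibition only.}
#' }
#' All presets can be overridden by modifying the returned model.
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param state one of "resting", "contracting", "rigor", "blebbistatin",
#'   "BTS".
#' @param contractingFactor multiplier on the ordered fraction when
#'   contracting.
#' @param contractingRatio target I11/I10 when contracting.
#' @param blebOrderingFactor multiplier on the ordered fraction under
#'   blebbistatin (capped at 1).
#' @param blebRmFactor multiplier on Rm under blebbistatin (12.31/12.53
#'   reproduces the printed resting-vs-blebbistatin head radii).
#' @param blebPartitionFactor multiplier on the head partition under
#'   blebbistatin.
#' @return the modified \linkS4class{LatticeModel}.
#' @export
applyStatePreset <- function(model, state = c("resting", "contracting",
                                              "rigor", "blebbistatin",
                                              "BTS"),
                             contractingFactor = sqrt(0.28),
                             contractingRatio = 1.175,
                             blebOrderingFactor = 1.36,
                             blebRmFactor = 12.31 / 12.53,
                             blebPartitionFactor = 0.8) {
    state <- match.arg(state)
    m <- model
    if (state == "contracting") {
        m@fOrdered <- min(1, m@fOrdered * contractingFactor)
        m@spacingFactor <- 0.01
        m@sigmaS <- 2 * m@sigmaS
        m@headPartition <- solveHeadPartition(m, contractingRatio)
        m@activation <- 1
    } else if (state == "rigor") {
        m@fOrdered <- 0
        m@actinScale <- 8
        m@amOn <- TRUE
        m@headPartition <- 1
        m@activation <- 1
    } else if (state == "blebbistatin") {
        m@fOrdered <- min(1, m@fOrdered * blebOrderingFactor)
        m@rmTrue <- m@rmTrue * blebRmFactor
        m@headPartition <- m@headPartition * blebPartitionFactor
        m@activation <- 0
    }
    ## BTS: resting-like ordering with force-only inhibition - structurally
    ## identical to resting.
    validObject(m)
    m
}

## Expected (noise-free) counts for a model on a geometry, scaled so the
## image total equals exposureScale.  All components are separable in the
## axial (rows) and radial (columns) reciprocal coordinates, built as outer
## products.
.renderExpected <- function(model, geometry) {
    co <- reciprocalCoordinates(geometry)
    ax <- abs(co$rx)          # radial distance from the meridian, per column
    az <- abs(co$rz)          # axial distance from the equator, per row
    bg <- model@background
    amp <- model@amplitudes

    gauss <- function(x, mu, s) exp(-(x - mu)^2 / (2 * s^2))

    ## diffuse background: broad circular + meridian-proximal stripe
    img <- bg[["broadAmp"]] *
        outer(gauss(co$rz, 0, bg[["broadWidth"]]),
              gauss(co$rx, 0, bg[["broadWidth"]]))
    img <- img + bg[["proxAmp"]] *
        outer(gauss(co$rz, 0, bg[["proxWidthZ"]]),
              gauss(co$rx, 0, bg[["proxWidthX"]]))

    ## equatorial reflections: areas proportional to |F(h,k)|^2, radial
    ## widths from the disorder model, common axial width
    axialEq <- gauss(co$rz, 0, model@sigmaAxial)
    for (i in seq_along(.equatorOrders)) {
        hk <- .equatorOrders[[i]]
        theta <- thetaHK(hk[1], hk[2])
        s <- widthModel(theta, model@sigmaC, model@sigmaD, model@sigmaS)
        area <- amp[["equator"]] * equatorStructureFactor(model, hk[1], hk[2])
        img <- img + area / (2 * pi * s * model@sigmaAxial) *
            outer(axialEq, gauss(ax, theta / model@d10, s))
    }

    ## myosin layer lines (intensity ~ fOrdered^2, Bessel radial profile)
    if (model@fOrdered > 0) {
        for (key in names(model@besselOrders)) {
            l <- as.numeric(key)
            prof <- layerLineProfile(model, l)
            z0 <- attr(prof, "axialCenter")
            img <- img + outer(gauss(az, z0, model@sigmaLL), prof(ax))
        }
    }

    ## actin layer lines on the 35.9 nm repeat: ALL1 plus the split ALL2
    ## whose outer (tropomyosin-sensitive) part scales with activation
    aAct <- amp[["actin"]] * model@actinScale
    zA1 <- 1 / model@cActin
    img <- img + aAct * outer(gauss(az, zA1, model@sigmaLL),
                              gauss(ax, 0.030, 0.015))
    zA2 <- 2 / model@cActin
    img <- img + 0.5 * aAct * outer(gauss(az, zA2, model@sigmaLL),
                                    gauss(ax, 0.025, 0.008))
    tmAmp <- amp[["tm"]] * (0.4 + 0.6 * model@activation)
    img <- img + tmAmp * outer(gauss(az, zA2, model@sigmaLL),
                               gauss(ax, 0.065, 0.010))

    ## actomyosin layer lines (rigor): ~1/24 and ~1/10.3 nm^-1 axially.
    ## AM+1 is azimuthally offset from the equator-parallel integration
    ## bands; an azimuthally uniform render cannot represent that, so its
    ## amplitude is attenuated and its axial profile kept narrow to keep
    ## its band contribution at the small level the offset produces.
    if (model@amOn) {
        img <- img + amp[["am"]] *
            outer(gauss(az, 1 / 24, model@sigmaLL),
                  gauss(ax, 0.075, 0.012))
        img <- img + 0.02 * amp[["am"]] *
            outer(gauss(az, 1 / 10.3, 1.2e-3),
                  gauss(ax, 0.075, 0.012))
    }

    ## meridional catalog; myosin family follows the activation spacing
    cat <- model@meridionalCatalog
    if (nrow(cat)) {
        radial <- gauss(ax, 0, 1.5e-3)
        for (i in seq_len(nrow(cat))) {
            sp <- cat$spacing[i]
            if (cat$family[i] == "myosin")
                sp <- sp * (1 + model@spacingFactor)
            img <- img + cat$amplitude[i] *
                outer(gauss(az, 1 / sp, 1.2e-3), radial)
        }
    }

    img * (model@exposureScale / sum(img))
}

## Poisson-sample a matrix of expected counts with an isolated RNG state.
.poissonSample <- function(lambda, seed) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    matrix(rpois(length(lambda), lambda), nrow = nrow(lambda))
}

#' Render a synthetic diffraction pattern
#'
#' Composes equatorial reflections, myosin and actin layer lines,
#' actomyosin lines (rigor), meridional reflections and diffuse background
#' into an expected-count image scaled to the model's exposure, then
#' applies Poisson counting noise with the given seed.  The same model,
#' geometry, state and seed always produce the identical image.
#'
#' @param model a \linkS4class{LatticeModel} (resting parameterization).
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @param state physiological state preset; see
#'   \code{\link{applyStatePreset}}.
#' @param seed integer seed for the counting noise.
#' @param noise render Poisson noise (TRUE) or the expected counts (FALSE).
#' @param ... passed to \code{\link{applyStatePreset}}.
#' @return A \linkS4class{DiffractionImage} whose provenance records the
#'   state, seed and full ground truth.
#' @examples
#' img <- renderPattern(latticeModel(exposureScale = 1e5),
#'                      detectorGeometry(imageShape = c(221L, 221L)),
#'                      state = "resting", seed = 1)
#' @export
renderPattern <- function(model, geometry,
                          state = c("resting", "contracting", "rigor",
                                    "blebbistatin", "BTS"),
                          seed = 1L, noise = TRUE, ...) {
    state <- match.arg(state)
    m <- applyStatePreset(model, state, ...)
    lambda <- .renderExpected(m, geometry)
    counts <- if (noise) .poissonSample(lambda, seed) else lambda
    warn <- character()
    peak10 <- max(lambda[abs(reciprocalCoordinates(geometry)$rz) <
                             2 * m@sigmaAxial, , drop = FALSE])
    if (peak10 < 9)  # (1,0) peak below ~3 sigma of its own counting noise
        warn <- "low_exposure: equatorial peaks are near the noise floor"
    diffractionImage(counts, geometry,
                     provenance = list(state = state, seed = seed,
                                       noise = noise,
                                       groundTruth = .modelAsList(m),
                                       warnings = warn))
}

.modelAsList <- function(model) {
    sl <- slotNames(model)
    out <- lapply(sl, function(s) slot(model, s))
    names(out) <- sl
    out$meridionalCatalog <- NULL
    out
}
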