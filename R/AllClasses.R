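#' DetectorGeometry: pixel-to-reciprocal-space calibration
#'
#' Maps detector pixel coordinates to reciprocal space (nm^-1) under the
#' small-angle approximation \eqn{R = r_{pix} \cdot s / (D \lambda)}, where
#' \eqn{s} is the pixel size, \eqn{D} the sample-to-detector distance and
#' \eqn{\lambda} the wavelength.  The approximation is adequate for
#' R <= 0.25 nm^-1 at ~2 m camera length.
#'
#' Coordinate convention: the meridian (fiber axis) runs along matrix rows
#' (axis 1), the equator along matrix columns (axis 2).  The beam center is
#' given in (row, column) order in 1-based, fractional pixel units.
#'
#' @slot pixelSize pixel size in mm.
#' @slot beamCenter numeric(2), (row, col) of the beam center in pixels.
#' @slot distance sample-to-detector distance in m.
#' @slot wavelength X-ray wavelength in nm.
#' @slot imageShape integer(2), image dimensions (rows, cols).
#' @name DetectorGeometry-class
#' @rdname DetectorGeometry-class
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
         representation(pixelSize = "numeric", beamCenter = "numeric",
                        distance = "numeric", wavelength = "numeric",
                        imageShape = "integer"))

setValidity("DetectorGeometry", function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive length (mm)")
    if (length(object@distance) != 1 || object@distance <= 0)
        msg <- c(msg, "distance must be a single positive length (m)")
    if (length(object@wavelength) != 1 || object@wavelength <= 0)
        msg <- c(msg, "wavelength must be a single positive length (nm)")
    if (length(object@imageShape) != 2 || any(object@imageShape < 3))
        msg <- c(msg, "imageShape must be two pixel counts >= 3")
    if (length(object@beamCenter) != 2 ||
        any(object@beamCenter < 1) ||
        any(object@beamCenter > object@imageShape))
        msg <- c(msg, "beam center must lie inside the image")
    if (length(msg)) msg else TRUE
})

#' Construct a DetectorGeometry
#'
#' Defaults describe a small-angle camera typical of muscle fiber
#' diffraction: 0.1 mm pixels, 2 m camera length, 0.1033 nm (12 keV)
#' wavelength, a 441 x 441 pixel field with the beam in the exact center.
#' This gives 4.84e-4 nm^-1 per pixel, so the detector edge along an axis is
#' at ~0.107 nm^-1, covering the first five equatorial orders of a ~36 nm
#' lattice and the first four myosin layer lines.
#'
#' @param pixelSize pixel size (mm).
#' @param distance sample-to-detector distance (m).
#' @param wavelength wavelength (nm).
#' @param imageShape integer(2) image dimensions (rows, cols).
#' @param beamCenter numeric(2) beam center (row, col), fractional pixels;
#'   defaults to the image center.
#' @return A \linkS4class{DetectorGeometry}.
#' @examples
#' geom <- detectorGeometry()
#' reciprocalStep(geom)
#' @export
detectorGeometry <- function(pixelSize = 0.1, distance = 2,
                             wavelength = 0.1033,
                             imageShape = c(441L, 441L),
                             beamCenter = (imageShape + 1) / 2) {
    new("DetectorGeometry", pixelSize = pixelSize,
        beamCenter = as.numeric(beamCenter), distance = distance,
        wavelength = wavelength, imageShape = as.integer(imageShape))
}

#' @rdname accessors
#' @export
setMethod("beamCenter", "DetectorGeometry", function(object) object@beamCenter)

#' @rdname accessors
#' @export
setMethod("imageShape", "DetectorGeometry", function(object) object@imageShape)

setMethod("show", "DetectorGeometry", function(object) {
    cat("DetectorGeometry:", paste(object@imageShape, collapse = " x "),
        "pixels\n")
    cat("  pixel", object@pixelSize, "mm | distance", object@distance,
        "m | wavelength", object@wavelength, "nm\n")
    cat("  beam center (row, col):",
        paste(signif(object@beamCenter, 6), collapse = ", "),
        "| step", signif(reciprocalStep(object), 4), "nm^-1/pixel\n")
})

#' LatticeModel: ground truth for the synthetic pattern generator
#'
#' Describes the myofilament lattice and diffraction model used by
#' \code{\link{renderPattern}}: the hexagonal lattice spacing d10 and a
#' two-filament unit cell (thick filament at the origin, thin filaments at
#' the trigonal points) whose head mass is partitioned between thick- and
#' thin-filament sites; the quasi-helically ordered head fraction and head
#' radius Rm governing the myosin layer lines; disorder width components for
#' the equatorial reflections; axial repeats for myosin, actin, troponin and
#' MyBP-C families; and background/exposure settings.
#'
#' @slot d10 lattice plane spacing (nm).
#' @slot massBackbone,massThin,massHeads relative masses (arbitrary units);
#'   massThin is per thin-filament site.
#' @slot headPartition fraction of head mass located at thin-filament sites,
#'   in [0, 1].
#' @slot rhoThick,rhoThin cylindrical Gaussian form-factor radii (nm);
#'   \code{rhoThick = NA} means "use \code{rmTrue}".
#' @slot fOrdered fraction of heads in the quasi-helically ordered
#'   configuration, in [0, 1].
#' @slot rmTrue radius of the myosin head center of mass (nm).
#' @slot besselOrders named numeric; names are layer-line indices, values the
#'   Bessel order used for that line (default MLL1 -> 1, MLL4 -> 4).
#' @slot cMyosin myosin axial repeat (nm).
#' @slot cActin actin helical repeat (nm).
#' @slot actinSymmetry numeric(2), subunits per turns (13/6).
#' @slot spacingFactor fractional increase of the myosin axial repeat on
#'   activation (~0.01 when contracting).
#' @slot sigmaC,sigmaD,sigmaS equatorial width components (nm^-1): beam
#'   width, interfilament-spacing heterogeneity, liquid-like disorder.
#' @slot sigmaAxial axial (meridian-parallel) Gaussian sigma of the
#'   equatorial reflections (nm^-1).
#' @slot sigmaLL axial Gaussian sigma of the layer lines (nm^-1).
#' @slot amplitudes named numeric amplitude scales for the pattern
#'   components (equator, mll1, mll4, actin, am, tm).
#' @slot meridionalCatalog data.frame with columns label, spacing (nm),
#'   amplitude, family ("myosin", "troponin", "mybpc").
#' @slot background named numeric: broad Gaussian amplitude/width and
#'   meridian-proximal Gaussian amplitude/radial width/axial width.
#' @slot activation thin-filament activation level in [0, 1]; scales the
#'   outer tropomyosin/ALL2 band.
#' @slot actinScale multiplier on actin layer-line amplitudes (large in
#'   rigor).
#' @slot amOn logical; render actomyosin layer lines (rigor).
#' @slot exposureScale expected total counts in a rendered pattern.
#' @name LatticeModel-class
#' @rdname LatticeModel-class
#' @exportClass LatticeModel
setClass("LatticeModel",
         representation(d10 = "numeric", massBackbone = "numeric",
                        massThin = "numeric", massHeads = "numeric",
                        headPartition = "numeric", rhoThick = "numeric",
                        rhoThin = "numeric", fOrdered = "numeric",
                        rmTrue = "numeric", besselOrders = "numeric",
                        cMyosin = "numeric", cActin = "numeric",
                        actinSymmetry = "numeric", spacingFactor = "numeric",
                        sigmaC = "numeric", sigmaD = "numeric",
                        sigmaS = "numeric", sigmaAxial = "numeric",
                        sigmaLL = "numeric", amplitudes = "numeric",
                        meridionalCatalog = "data.frame",
                        background = "numeric", activation = "numeric",
                        actinScale = "numeric", amOn = "logical",
                        exposureScale = "numeric"))

setValidity("LatticeModel", function(object) {
    msg <- character()
    if (object@d10 <= 0) msg <- c(msg, "d10 must be > 0")
    if (any(c(object@massBackbone, object@massThin, object@massHeads) < 0))
        msg <- c(msg, "masses must be >= 0")
    if (object@headPartition < 0 || object@headPartition > 1)
        msg <- c(msg, "headPartition must be in [0, 1]")
    if (object@fOrdered < 0 || object@fOrdered > 1)
        msg <- c(msg, "fOrdered must be in [0, 1]")
    if (object@rmTrue <= 0) msg <- c(msg, "rmTrue must be > 0")
    if (object@cMyosin <= 0 || object@cActin <= 0)
        msg <- c(msg, "axial repeats must be > 0")
    if (object@spacingFactor < 0) msg <- c(msg, "spacingFactor must be >= 0")
    if (is.null(names(object@besselOrders)) ||
        any(object@besselOrders %% 1 != 0))
        msg <- c(msg, "besselOrders must be integers named by layer line")
    if (any(c(object@sigmaC, object@sigmaD, object@sigmaS) < 0))
        msg <- c(msg, "width components must be >= 0")
    if (object@exposureScale <= 0) msg <- c(msg, "exposureScale must be > 0")
    if (length(msg)) msg else TRUE
})

setMethod("show", "LatticeModel", function(object) {
    cat("LatticeModel: d10", object@d10, "nm | head partition",
        signif(object@headPartition, 4), "| f_ordered",
        signif(object@fOrdered, 4), "\n")
    cat("  Rm", object@rmTrue, "nm | repeats", object@cMyosin, "nm (myosin),",
        object@cActin, "nm (actin", paste(object@actinSymmetry, collapse = "/"),
        ") | spacing factor", object@spacingFactor, "\n")
    cat("  widths (nm^-1): sigma_c", object@sigmaC, "sigma_d", object@sigmaD,
        "sigma_s", object@sigmaS, "\n")
    cat("  theoretical I11/I10:",
        signif(equatorIntensityRatio(object), 4),
        "| exposure", format(object@exposureScale, big.mark = ","),
        "counts\n")
})

#' @rdname accessors
#' @export
setMethod("d10", "LatticeModel", function(object) object@d10)

#' DiffractionImage: a 2D detector image with geometry
#'
#' Counts are non-negative (Poisson-distributed when rendered with noise);
#' masked pixels are NA.  Provenance records the state label, seed and, for
#' synthetic images, the full ground truth model.
#'
#' @slot counts numeric matrix of counts; NA marks masked pixels.
#' @slot geometry the \linkS4class{DetectorGeometry}.
#' @slot provenance free-form list of metadata.
#' @name DiffractionImage-class
#' @rdname DiffractionImage-class
#' @exportClass DiffractionImage
setClass("DiffractionImage",
         representation(counts = "matrix", geometry = "DetectorGeometry",
                        provenance = "list"))

setValidity("DiffractionImage", function(object) {
    msg <- character()
    if (!all(dim(object@counts) == object@geometry@imageShape))
        msg <- c(msg, "counts dimensions must match geometry imageShape")
    ## background-subtracted images may carry noise-level negatives
    if (!isTRUE(object@provenance$backgroundSubtracted) &&
        any(object@counts < 0, na.rm = TRUE))
        msg <- c(msg, "counts must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a DiffractionImage
#'
#' @param counts numeric matrix of detector counts (NA = masked).
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @param provenance list of metadata.
#' @return A \linkS4class{DiffractionImage}.
#' @export
diffractionImage <- function(counts, geometry, provenance = list()) {
    new("DiffractionImage", counts = counts, geometry = geometry,
        provenance = provenance)
}

#' @rdname accessors
#' @export
setMethod("counts", "DiffractionImage", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("geometry", "DiffractionImage", function(object) object@geometry)

#' @rdname accessors
#' @export
setMethod("provenance", "DiffractionImage", function(object) object@provenance)

setMethod("show", "DiffractionImage", function(object) {
    cat("DiffractionImage:", paste(dim(object@counts), collapse = " x "),
        "pixels |", format(round(sum(object@counts, na.rm = TRUE)),
                           big.mark = ","), "total counts\n")
    st <- object@provenance$state
    if (!is.null(st)) cat("  state:", st,
                          "| seed:", object@provenance$seed %||% NA, "\n")
})

#' Trace1D: a one-dimensional projection of a diffraction image
#'
#' @slot coordinate reciprocal-space axis (nm^-1), strictly increasing.
#' @slot intensity projected intensity (counts); small negatives are
#'   tolerated after baseline removal.
#' @slot band numeric(2), the integration limits (nm^-1) across the trace.
#' @slot axis "axial" (projected onto the meridian) or "radial" (projected
#'   onto the equatorial direction).
#' @name Trace1D-class
#' @rdname Trace1D-class
#' @exportClass Trace1D
setClass("Trace1D",
         representation(coordinate = "numeric", intensity = "numeric",
                        band = "numeric", axis = "character"))

setValidity("Trace1D", function(object) {
    msg <- character()
    if (length(object@coordinate) != length(object@intensity))
        msg <- c(msg, "coordinate and intensity must have equal length")
    if (is.unsorted(object@coordinate, strictly = TRUE))
        msg <- c(msg, "coordinate must be strictly increasing")
    if (length(object@band) != 2 || diff(object@band) < 0)
        msg <- c(msg, "band limits must be ordered")
    if (length(msg)) msg else TRUE
})

#' Construct a Trace1D
#'
#' @param coordinate reciprocal coordinate values (nm^-1).
#' @param intensity intensity values.
#' @param band integration band (nm^-1) used to form the trace.
#' @param axis "axial" or "radial".
#' @return A \linkS4class{Trace1D}.
#' @export
trace1D <- function(coordinate, intensity, band = range(coordinate),
                    axis = "radial") {
    new("Trace1D", coordinate = as.numeric(coordinate),
        intensity = as.numeric(intensity), band = as.numeric(band),
        axis = axis)
}

setMethod("show", "Trace1D", function(object) {
    cat("Trace1D (", object@axis, "): ", length(object@coordinate),
        " points, coordinate ", signif(min(object@coordinate), 4), " to ",
        signif(max(object@coordinate), 4), " nm^-1\n", sep = "")
    cat("  integration band:", paste(signif(object@band, 4), collapse = " - "),
        "nm^-1\n")
})

#' BackgroundModel: circularly symmetric diffuse background
#'
#' @slot radius radii of the annuli (nm^-1).
#' @slot profile background intensity per pixel at each radius.
#' @slot totalDiffuse sum of the expanded 2D background image (counts);
#'   the denominator for diffuse normalization.
#' @slot flags character; "corner_extrapolated" when outer annuli were empty.
#' @name BackgroundModel-class
#' @rdname BackgroundModel-class
#' @exportClass BackgroundModel
setClass("BackgroundModel",
         representation(radius = "numeric", profile = "numeric",
                        totalDiffuse = "numeric", flags = "character"))

setValidity("BackgroundModel", function(object) {
    msg <- character()
    if (length(object@radius) != length(object@profile))
        msg <- c(msg, "radius and profile must have equal length")
    if (any(object@profile < 0))
        msg <- c(msg, "profile must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("totalDiffuse", "BackgroundModel",
          function(object) object@totalDiffuse)

setMethod("show", "BackgroundModel", function(object) {
    cat("BackgroundModel:", length(object@radius), "annuli | total diffuse",
        format(round(object@totalDiffuse), big.mark = ","), "counts\n")
    if (length(object@flags)) cat("  flags:",
                                  paste(object@flags, collapse = ", "), "\n")
})

#' EquatorFit: result of the constrained five-order equatorial fit
#'
#' Peak centers are constrained to the hexagonal lattice (theta_hk / d10)
#' and widths to the disorder model
#' sigma_hk = sqrt(sigma_c^2 + sigma_d^2 theta^2 + sigma_s^2 theta^4).
#' Reported intensities are Gaussian areas.
#'
#' @slot d10 fitted lattice spacing (nm).
#' @slot areas named Gaussian areas for (1,0), (1,1), (2,0), (2,1), (3,0).
#' @slot ratio I11/I10 (area ratio).
#' @slot sigmaC fixed instrumental width (nm^-1).
#' @slot sigmaD,sigmaS fitted disorder widths (nm^-1).
#' @slot axialWidth axial Gaussian sigma of the (1,0) reflection (nm^-1);
#'   NA until measured from the 2D image.
#' @slot se named standard errors (d10, sigmaD, sigmaS, areas, ratio).
#' @slot gof list with rss, r2, convergence info.
#' @slot flags character vector, e.g. "low_confidence_11".
#' @slot trace the fitted \linkS4class{Trace1D} (baseline-removed).
#' @slot fitted model curve evaluated on the trace coordinate.
#' @name EquatorFit-class
#' @rdname EquatorFit-class
#' @exportClass EquatorFit
setClass("EquatorFit",
         representation(d10 = "numeric", areas = "numeric", ratio = "numeric",
                        sigmaC = "numeric", sigmaD = "numeric",
                        sigmaS = "numeric", axialWidth = "numeric",
                        se = "numeric", gof = "list", flags = "character",
                        trace = "Trace1D", fitted = "numeric"))

#' @rdname accessors
#' @export
setMethod("d10", "EquatorFit", function(object) object@d10)

#' @rdname accessors
#' @export
setMethod("intensityRatio", "EquatorFit", function(object) object@ratio)

#' @rdname accessors
#' @export
setMethod("peakAreas", "EquatorFit", function(object) object@areas)

#' @rdname accessors
#' @export
setMethod("sigmaD", "EquatorFit", function(object) object@sigmaD)

#' @rdname accessors
#' @export
setMethod("sigmaS", "EquatorFit", function(object) object@sigmaS)

#' @rdname accessors
#' @export
setMethod("fitFlags", "EquatorFit", function(object) object@flags)

setMethod("show", "EquatorFit", function(object) {
    cat("EquatorFit: d10 =", signif(object@d10, 6), "nm | I11/I10 =",
        signif(object@ratio, 4), "\n")
    cat("  widths (nm^-1): sigma_c", signif(object@sigmaC, 3), "(fixed),",
        "sigma_d", signif(object@sigmaD, 3), ", sigma_s",
        signif(object@sigmaS, 3), "\n")
    cat("  areas:", paste(names(object@areas),
                          signif(object@areas, 4), collapse = " | "), "\n")
    cat("  R^2 =", signif(object@gof$r2, 5), "\n")
    if (length(object@flags)) cat("  flags:",
                                  paste(object@flags, collapse = ", "), "\n")
})

#' LayerLineFit: result of the layer-line trace fit
#'
#' The radial trace across a layer-line band is fitted with three background
#' Gaussians centered on the meridian (broad diffuse, meridian-proximal, and
#' the meridional peak itself) plus a single Gaussian for the layer-line
#' first maximum.
#'
#' @slot rMax radial position of the first maximum (nm^-1).
#' @slot area integrated Gaussian area of the layer-line peak (counts).
#' @slot normalized diffuse-normalized intensity (dimensionless); NA until a
#'   \linkS4class{BackgroundModel} is supplied.
#' @slot bgParams named parameters of the three background Gaussians.
#' @slot peakCenter,peakSigma Gaussian center and sigma of the layer-line
#'   peak (nm^-1).
#' @slot Rm derived myosin head radius (nm); NA until derived.
#' @slot besselOrder Bessel order used for the Rm relation.
#' @slot axialCenter axial center of the integration band (nm^-1).
#' @slot se named standard errors.
#' @slot gof list with rss, r2.
#' @slot flags character, e.g. "no_ordered_heads".
#' @slot trace the fitted \linkS4class{Trace1D}.
#' @slot fitted model curve on the trace coordinate.
#' @name LayerLineFit-class
#' @rdname LayerLineFit-class
#' @exportClass LayerLineFit
setClass("LayerLineFit",
         representation(rMax = "numeric", area = "numeric",
                        normalized = "numeric", bgParams = "numeric",
                        peakCenter = "numeric", peakSigma = "numeric",
                        Rm = "numeric", besselOrder = "numeric",
                        axialCenter = "numeric", se = "numeric", gof = "list",
                        flags = "character", trace = "Trace1D",
                        fitted = "numeric"))

#' @rdname accessors
#' @export
setMethod("firstMaximum", "LayerLineFit", function(object) object@rMax)

#' @rdname accessors
#' @export
setMethod("headRadius", "LayerLineFit", function(object) object@Rm)

#' @rdname accessors
#' @export
setMethod("integratedIntensity", "LayerLineFit", function(object) {
    if (!is.na(object@normalized)) object@normalized else object@area
})

#' @rdname accessors
#' @export
setMethod("fitFlags", "LayerLineFit", function(object) object@flags)

setMethod("show", "LayerLineFit", function(object) {
    cat("LayerLineFit: first maximum at", signif(object@rMax, 4),
        "nm^-1 | area", signif(object@area, 5), "\n")
    if (!is.na(object@normalized))
        cat("  diffuse-normalized intensity:",
            signif(object@normalized, 4), "\n")
    if (!is.na(object@Rm))
        cat("  Rm =", signif(object@Rm, 4), "nm (Bessel order",
            object@besselOrder, ")\n")
    cat("  R^2 =", signif(object@gof$r2, 5), "\n")
    if (length(object@flags)) cat("  flags:",
                                  paste(object@flags, collapse = ", "), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
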