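#' Write a diffraction image to TIFF with a ground-truth sidecar
#'
#' Writes the counts as 32-bit float TIFF (or 16-bit integer), plus a JSON
#' sidecar (same path with extension .json) holding the provenance: state
#' label, seed and, for synthetic images, the full ground truth.
#'
#' @param image a \linkS4class{DiffractionImage}.
#' @param path output TIFF path.
#' @param bits "float32" or "int16".
#' @param sidecar write the JSON sidecar.
#' @return the TIFF path, invisibly.
#' @export
writePatternTIFF <- function(image, path, bits = c("float32", "int16"),
                             sidecar = TRUE) {
    bits <- match.arg(bits)
    x <- counts(image)
    x[is.na(x)] <- 0
    if (bits == "int16") {
        tiff::writeTIFF(x / max(x, 1), path, bits.per.sample = 16L)
    } else {
        ## writeTIFF stores [0,1] floats; keep counts via a scale attribute
        tiff::writeTIFF(x / max(x, 1), path, bits.per.sample = 32L)
    }
    if (sidecar) {
        side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
        if (side == path) side <- paste0(path, ".json")
        meta <- provenance(image)
        meta$maxCount <- max(x)
        meta$geometry <- list(pixelSize = geometry(image)@pixelSize,
                              beamCenter = geometry(image)@beamCenter,
                              distance = geometry(image)@distance,
                              wavelength = geometry(image)@wavelength,
                              imageShape = geometry(image)@imageShape)
        jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                             null = "null")
    }
    invisible(path)
}

#' Read a diffraction image from TIFF
#'
#' Counts are rescaled with the \code{maxCount} recorded in the JSON
#' sidecar when present (TIFF stores intensities normalized to [0, 1]).
#'
#' @param path TIFF path.
#' @param geometry a \linkS4class{DetectorGeometry}; when NULL the sidecar
#'   geometry is used.
#' @return A \linkS4class{DiffractionImage}.
#' @export
readPatternTIFF <- function(path, geometry = NULL) {
    x <- tiff::readTIFF(path)
    if (is.array(x) && length(dim(x)) == 3) x <- x[, , 1]
    side <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
    if (side == path) side <- paste0(path, ".json")
    prov <- list()
    if (file.exists(side)) {
        prov <- jsonlite::read_json(side, simplifyVector = TRUE)
        if (!is.null(prov$maxCount)) x <- x * prov$maxCount
        if (is.null(geometry) && !is.null(prov$geometry)) {
            g <- prov$geometry
            geometry <- detectorGeometry(pixelSize = g$pixelSize,
                                         distance = g$distance,
                                         wavelength = g$wavelength,
                                         imageShape = g$imageShape,
                                         beamCenter = g$beamCenter)
        }
        prov$maxCount <- NULL
        prov$geometry <- NULL
    }
    if (is.null(geometry))
        stop("no geometry supplied and no sidecar found")
    diffractionImage(x, geometry, as.list(prov))
}

#' Read or write detector geometry as YAML
#'
#' @param path YAML file path.
#' @return \code{readGeometryYAML} returns a
#'   \linkS4class{DetectorGeometry}.
#' @export
readGeometryYAML <- function(path) {
    g <- yaml::read_yaml(path)
    detectorGeometry(pixelSize = g$pixel_size_mm,
                     distance = g$distance_m,
                     wavelength = g$wavelength_nm,
                     imageShape = unlist(g$image_shape),
                     beamCenter = unlist(g$beam_center))
}

#' @rdname readGeometryYAML
#' @param geometry a \linkS4class{DetectorGeometry} to write.
#' @export
writeGeometryYAML <- function(geometry, path) {
    yaml::write_yaml(list(pixel_size_mm = geometry@pixelSize,
                          distance_m = geometry@distance,
                          wavelength_nm = geometry@wavelength,
                          image_shape = as.integer(geometry@imageShape),
                          beam_center = geometry@beamCenter),
                     path)
    invisible(path)
}

#' Read or write a 1D trace as CSV
#'
#' Two columns (coordinate in nm^-1, intensity) with a header comment
#' naming the projection axis and integration band.
#'
#' @param path CSV path.
#' @return \code{readTraceCSV} returns a \linkS4class{Trace1D}.
#' @export
readTraceCSV <- function(path) {
    hdr <- readLines(path, n = 1)
    axis <- "radial"; band <- NULL
    if (startsWith(hdr, "#")) {
        m <- regmatches(hdr, regexec(
            "axis=(\\w+)\\s+band=([0-9.eE+-]+):([0-9.eE+-]+)", hdr))[[1]]
        if (length(m) == 4) {
            axis <- m[2]
            band <- as.numeric(m[3:4])
        }
    }
    d <- read.csv(path, comment.char = "#")
    trace1D(d[[1]], d[[2]],
            band = band %||% range(d[[1]]), axis = axis)
}

#' @rdname readTraceCSV
#' @param trace a \linkS4class{Trace1D} to write.
#' @export
writeTraceCSV <- function(trace, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# axis=%s band=%g:%g", trace@axis,
                       trace@band[1], trace@band[2]), con)
    write.csv(data.frame(coordinate_nm_inv = trace@coordinate,
                         intensity = trace@intensity),
              con, row.names = FALSE)
    invisible(path)
}

#' Write a fit result as JSON
#'
#' Serializes an \linkS4class{EquatorFit} or \linkS4class{LayerLineFit}
#' (scalar fields and uncertainties; not the trace) to JSON.
#'
#' @param fit the fit object.
#' @param path output path.
#' @export
writeFitJSON <- function(fit, path) {
    out <- if (is(fit, "EquatorFit")) {
        list(type = "equator", d10 = fit@d10, areas = as.list(fit@areas),
             ratio = fit@ratio, sigmaC = fit@sigmaC, sigmaD = fit@sigmaD,
             sigmaS = fit@sigmaS, axialWidth = fit@axialWidth,
             se = as.list(fit@se), r2 = fit@gof$r2,
             flags = as.list(fit@flags))
    } else if (is(fit, "LayerLineFit")) {
        list(type = "layerline", rMax = fit@rMax, area = fit@area,
             normalized = fit@normalized, Rm = fit@Rm,
             besselOrder = fit@besselOrder,
             bgParams = as.list(fit@bgParams), r2 = fit@gof$r2,
             se = as.list(fit@se), flags = as.list(fit@flags))
    } else stop("unsupported fit object")
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
}

#' Read a mechanics table from CSV
#'
#' Expected columns: state, force_mN, length_mm, mass_g and optionally
#' passive_mN_mm2.  Cross-sectional area and specific tension are derived.
#'
#' @param path CSV path.
#' @param density muscle density (g/ml).
#' @return data.frame as from \code{\link{mechanicsTable}}.
#' @export
readMechanicsCSV <- function(path, density = 1.06) {
    d <- read.csv(path)
    need <- c("state", "force_mN", "length_mm", "mass_g")
    if (!all(need %in% names(d)))
        stop("mechanics CSV must have columns ",
             paste(need, collapse = ", "))
    mechanicsTable(d$state, d$force_mN, d$length_mm, d$mass_g,
                   density = density,
                   passive = if ("passive_mN_mm2" %in% names(d))
                       d$passive_mN_mm2 else NA_real_)
}
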