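#' Reciprocal-space step per pixel
#'
#' Under the small-angle approximation one pixel subtends
#' \code{pixelSize / (1000 * distance * wavelength)} nm^-1 (pixel size in mm,
#' distance in m, wavelength in nm).
#'
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @return nm^-1 per pixel.
#' @export
reciprocalStep <- function(geometry) {
    stopifnot(is(geometry, "DetectorGeometry"))
    geometry@pixelSize / (1000 * geometry@distance * geometry@wavelength)
}

#' Reciprocal coordinates of the pixel grid
#'
#' Returns the signed reciprocal coordinate of every row (axial, along the
#' meridian) and every column (radial, along the equator) relative to the
#' beam center, plus the per-pixel step.  The mapping is linear, hence
#' monotone in radial pixel distance and invertible over the image.
#'
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @return list with \code{rz} (rows, nm^-1), \code{rx} (columns, nm^-1) and
#'   \code{step} (nm^-1 per pixel).
#' @export
reciprocalCoordinates <- function(geometry) {
    k <- reciprocalStep(geometry)
    list(rz = (seq_len(geometry@imageShape[1]) - geometry@beamCenter[1]) * k,
         rx = (seq_len(geometry@imageShape[2]) - geometry@beamCenter[2]) * k,
         step = k)
}

#' Convert a reciprocal radius to a pixel distance
#'
#' @param geometry a \linkS4class{DetectorGeometry}.
#' @param R reciprocal radius (nm^-1).
#' @return pixel distance from the beam center.
#' @export
reciprocalToPixel <- function(geometry, R) R / reciprocalStep(geometry)
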