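#' @import methods
NULL

#' Accessor generics
#'
#' Accessors for the central value classes: detector counts and geometry,
#' fitted lattice spacing and equatorial intensity ratio, disorder width
#' components, layer-line first-maximum position, myosin head radius, and
#' diffuse-background totals.
#'
#' @param object an object of one of the package's S4 classes.
#' @return The slot value; see the class documentation for units.
#' @name accessors
#' @rdname accessors
#' @examples
#' geom <- detectorGeometry()
#' imageShape(geom)
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("beamCenter", function(object) standardGeneric("beamCenter"))

#' @rdname accessors
#' @export
setGeneric("imageShape", function(object) standardGeneric("imageShape"))

#' @rdname accessors
#' @export
setGeneric("d10", function(object) standardGeneric("d10"))

#' @rdname accessors
#' @export
setGeneric("intensityRatio", function(object) standardGeneric("intensityRatio"))

#' @rdname accessors
#' @export
setGeneric("peakAreas", function(object) standardGeneric("peakAreas"))

#' @rdname accessors
#' @export
setGeneric("sigmaD", function(object) standardGeneric("sigmaD"))

#' @rdname accessors
#' @export
setGeneric("sigmaS", function(object) standardGeneric("sigmaS"))

#' @rdname accessors
#' @export
setGeneric("firstMaximum", function(object) standardGeneric("firstMaximum"))

#' @rdname accessors
#' @export
setGeneric("headRadius", function(object) standardGeneric("headRadius"))

#' @rdname accessors
#' @export
setGeneric("integratedIntensity",
           function(object) standardGeneric("integratedIntensity"))

#' @rdname accessors
#' @export
setGeneric("totalDiffuse", function(object) standardGeneric("totalDiffuse"))

#' @rdname accessors
#' @export
setGeneric("fitFlags", function(object) standardGeneric("fitFlags"))
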