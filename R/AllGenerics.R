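#' @rdname accessors
#' @export
setGeneric("pixelCount", function(x) standardGeneric("pixelCount"))

#' @rdname accessors
#' @export
setGeneric("boundary", function(x) standardGeneric("boundary"))

#' @rdname accessors
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' @rdname accessors
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' @rdname accessors
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname accessors
#' @export
setGeneric("labels2d", function(x) standardGeneric("labels2d"))

#' Accessors for nucmorph objects
#'
#' \code{pixelCount} returns the number of pixels of a nucleus,
#' \code{boundary} its closed (row, col) polygon, \code{centroid} and
#' \code{bbox} its pixel-set centroid and tight bounding box,
#' \code{calibration} the physical length per pixel, and \code{labels2d} the
#' integer label matrix of a \linkS4class{LabeledMask}.
#'
#' @param x a \linkS4class{NucleusShape}, \linkS4class{GrayImage} or
#'   \linkS4class{LabeledMask}.
#' @name accessors
#' @rdname accessors
NULL

setMethod("pixelCount", "NucleusShape", function(x) nrow(x@pixels))
setMethod("boundary", "NucleusShape", function(x) x@boundary)
setMethod("centroid", "NucleusShape", function(x) x@centroid)
setMethod("bbox", "NucleusShape", function(x) x@bbox)
setMethod("calibration", "NucleusShape", function(x) x@calibration)
setMethod("calibration", "GrayImage", function(x) x@calibration)
setMethod("labels2d", "LabeledMask", function(x) x@labels)

setMethod("show", "GrayImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("GrayImage %d x %d, %d-bit, %.4g %s/px\n",
                d[1], d[2], object@bitDepth, object@calibration, object@unit))
})

setMethod("show", "LabeledMask", function(object) {
    cat(sprintf("LabeledMask %d x %d, %d nuclei, %d-connectivity\n",
                nrow(object@labels), ncol(object@labels),
                max(object@labels), object@connectivity))
})

setMethod("show", "NucleusShape", function(object) {
    cat(sprintf(
        "NucleusShape #%d: %d px, centroid (%.1f, %.1f), %d boundary vertices\n",
        object@id, nrow(object@pixels), object@centroid[1],
        object@centroid[2], nrow(object@boundary)))
})

setMethod("show", "ReferenceModel", function(object) {
    th <- nmaThresholds(object)
    cat("ReferenceModel (normal nucleus population)\n")
    cat(sprintf("  area: %.4g +/- %.4g  (n = %d)\n",
                object@meanArea, object@sdArea, object@nReference))
    cat(sprintf("  NII : %.4g +/- %.4g\n", object@meanNII, object@sdNII))
    cat(sprintf("  k   : area %.2g, NII %.2g, small-irregular %.2g\n",
                object@kArea, object@kNII, object@kNIISi))
    cat(sprintf("  thresholds: area [%.4g, %.4g], NII irregular > %.4g, SI > %.4g\n",
                th["areaLow"], th["areaHigh"], th["niiIrr"], th["niiSi"]))
})

setMethod("show", "PhenotypeSpec", function(object) {
    cat(sprintf(
        "PhenotypeSpec '%s': n=%d, area %.4g +/- %.4g px^2, elongation %.3g, amplitude %.3g (harmonics %s)\n",
        object@name, object@n, object@areaMean, object@areaSd,
        object@elongation, object@irregularityAmplitude,
        if (length(object@harmonics)) paste(object@harmonics, collapse = ",")
        else "-"))
})

setMethod("show", "SyntheticScene", function(object) {
    d <- dim(object@image@pixels)
    cat(sprintf("SyntheticScene: %d nuclei in a %d x %d frame (%s)\n",
                length(object@shapes), d[1], d[2],
                paste(unique(object@truth$phenotype), collapse = ", ")))
})
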