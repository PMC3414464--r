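#' @import methods
NULL

#' Grayscale fluorescence micrograph
#'
#' Container for a single-channel fluorescence image of stained nuclei,
#' stored as a numeric matrix in (row, col) orientation with pixel centers at
#' integer coordinates (1-based). Intensities are kept on the original
#' integer scale of the acquisition bit depth.
#'
#' @slot pixels numeric matrix of non-negative intensities.
#' @slot bitDepth integer, 8 or 16.
#' @slot calibration physical length per pixel (default 1, unit "px").
#' @slot unit length unit label for the calibration.
#'
#' @export
setClass("GrayImage",
    representation(pixels = "matrix", bitDepth = "integer",
                   calibration = "numeric", unit = "character"),
    prototype(bitDepth = 16L, calibration = 1, unit = "px"))

setValidity("GrayImage", function(object) {
    msg <- NULL
    d <- dim(object@pixels)
    if (any(d < 64L))
        msg <- c(msg, "image must be at least 64x64 pixels")
    if (!object@bitDepth %in% c(8L, 16L))
        msg <- c(msg, "bitDepth must be 8 or 16")
    px <- object@pixels
    if (any(!is.finite(px)) || min(px) < 0 || max(px) > 2^object@bitDepth - 1)
        msg <- c(msg, "intensities must lie within the bit-depth range")
    if (length(object@calibration) != 1L || object@calibration <= 0)
        msg <- c(msg, "calibration must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' Labeled nucleus mask
#'
#' Integer label image of segmented nuclei: 0 marks background and k > 0 the
#' pixels of nucleus k. Labels are contiguous 1..K in raster-scan order of
#' first occurrence.
#'
#' @slot labels integer matrix, same dimensions as the source image.
#' @slot connectivity pixel connectivity used for labeling (4 or 8).
#'
#' @export
setClass("LabeledMask",
    representation(labels = "matrix", connectivity = "integer"),
    prototype(connectivity = 8L))

setValidity("LabeledMask", function(object) {
    msg <- NULL
    lab <- object@labels
    if (any(lab < 0) || any(lab != round(lab)))
        msg <- c(msg, "labels must be non-negative integers")
    k <- max(lab)
    if (k > 0) {
        present <- sort(unique(lab[lab > 0]))
        if (!identical(as.integer(present), seq_len(k)))
            msg <- c(msg, "labels must be contiguous integers 1..K")
    }
    if (!object@connectivity %in% c(4L, 8L))
        msg <- c(msg, "connectivity must be 4 or 8")
    if (is.null(msg)) TRUE else msg
})

#' Segmentation parameters
#'
#' Tunable knobs of the nucleus segmentation recipe: Gaussian smoothing,
#' automatic (Otsu) or fixed thresholding, hole filling, area filtering,
#' optional border exclusion and optional distance-transform watershed
#' splitting of touching nuclei.
#'
#' @slot smoothingSigma Gaussian pre-smoothing sigma in pixels (0 disables).
#' @slot thresholdMethod "otsu" or "fixed".
#' @slot thresholdValue intensity threshold when thresholdMethod = "fixed".
#' @slot minArea minimum region area in px^2; smaller regions are dropped.
#' @slot maxArea maximum region area in px^2 (NA for no upper bound).
#' @slot excludeBorder drop regions touching the image border.
#' @slot splitTouching split touching nuclei by distance-transform watershed.
#' @slot connectivity 4 or 8 (pixel adjacency for labeling).
#'
#' @export
setClass("SegmentationParams",
    representation(smoothingSigma = "numeric", thresholdMethod = "character",
                   thresholdValue = "numeric", minArea = "numeric",
                   maxArea = "numeric", excludeBorder = "logical",
                   splitTouching = "logical", connectivity = "integer"),
    prototype(smoothingSigma = 1, thresholdMethod = "otsu",
              thresholdValue = NA_real_, minArea = 50, maxArea = NA_real_,
              excludeBorder = TRUE, splitTouching = FALSE,
              connectivity = 8L))

setValidity("SegmentationParams", function(object) {
    msg <- NULL
    if (!object@thresholdMethod %in% c("otsu", "fixed"))
        msg <- c(msg, "thresholdMethod must be 'otsu' or 'fixed'")
    if (object@thresholdMethod == "fixed" && !is.finite(object@thresholdValue))
        msg <- c(msg, "fixed thresholding needs a finite thresholdValue")
    if (object@minArea <= 0)
        msg <- c(msg, "minArea must be positive")
    if (is.finite(object@maxArea) && object@maxArea <= object@minArea)
        msg <- c(msg, "maxArea must exceed minArea")
    if (!object@connectivity %in% c(4L, 8L))
        msg <- c(msg, "connectivity must be 4 or 8")
    if (object@smoothingSigma < 0)
        msg <- c(msg, "smoothingSigma must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' One segmented nucleus
#'
#' Pixel set, sub-pixel boundary polygon (traced at the 0.5 iso-level of the
#' mask, counter-clockwise in (row, col) coordinates), centroid, tight
#' bounding box and spatial calibration of a single nucleus.
#'
#' @slot id integer nucleus label.
#' @slot pixels integer matrix with columns (row, col), one row per pixel.
#' @slot boundary numeric matrix with columns (row, col); closed polygon
#'   (first vertex not repeated), vertices may be sub-pixel.
#' @slot centroid numeric length-2 (row, col), pixel-set centroid.
#' @slot bbox numeric length-4 (minRow, minCol, maxRow, maxCol) over pixels.
#' @slot calibration physical length per pixel.
#'
#' @export
setClass("NucleusShape",
    representation(id = "integer", pixels = "matrix", boundary = "matrix",
                   centroid = "numeric", bbox = "numeric",
                   calibration = "numeric"),
    prototype(id = 1L, calibration = 1))

setValidity("NucleusShape", function(object) {
    msg <- NULL
    if (ncol(object@pixels) != 2L || nrow(object@pixels) < 1L)
        msg <- c(msg, "pixels must be an n x 2 (row, col) matrix")
    if (ncol(object@boundary) != 2L || nrow(object@boundary) < 3L)
        msg <- c(msg, "boundary must have at least 3 (row, col) vertices")
    if (length(object@centroid) != 2L || any(!is.finite(object@centroid)))
        msg <- c(msg, "centroid must be finite (row, col)")
    if (length(object@bbox) != 4L)
        msg <- c(msg, "bbox must be (minRow, minCol, maxRow, maxCol)")
    else {
        b <- object@bbox
        p <- object@pixels
        if (nrow(p) >= 1L && ncol(p) == 2L &&
            !(b[1] == min(p[, 1]) && b[2] == min(p[, 2]) &&
              b[3] == max(p[, 1]) && b[4] == max(p[, 2])))
            msg <- c(msg, "bbox must tightly bound the pixel set")
    }
    if (object@calibration <= 0)
        msg <- c(msg, "calibration must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Reference model of the normal nucleus population
#'
#' Mean and sample standard deviation (n - 1 denominator) of area and NII
#' estimated from a curated set of normal nuclei, together with the SD
#' multipliers that define the class boundaries: \code{kArea} for the
#' small/large area cuts, \code{kNII} for the regular/irregular NII cut and
#' \code{kNIISi} for the upper NII bound of the small (mitotic) class.
#'
#' @slot meanArea,sdArea area statistics (calibrated units^2).
#' @slot meanNII,sdNII NII statistics (dimensionless).
#' @slot kArea,kNII,kNIISi positive SD multipliers, kNIISi > kNII.
#' @slot nReference number of curated normal nuclei used.
#'
#' @export
setClass("ReferenceModel",
    representation(meanArea = "numeric", sdArea = "numeric",
                   meanNII = "numeric", sdNII = "numeric",
                   kArea = "numeric", kNII = "numeric", kNIISi = "numeric",
                   nReference = "integer"),
    prototype(kArea = 2, kNII = 2, kNIISi = 4))

setValidity("ReferenceModel", function(object) {
    msg <- NULL
    if (object@sdArea <= 0 || object@sdNII <= 0)
        msg <- c(msg, "sdArea and sdNII must be positive")
    if (object@kArea <= 0 || object@kNII <= 0)
        msg <- c(msg, "kArea and kNII must be positive")
    if (object@kNIISi <= object@kNII)
        msg <- c(msg, "kNIISi must exceed kNII")
    if (object@nReference < 3L)
        msg <- c(msg, "at least 3 reference nuclei are required")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic phenotype specification
#'
#' Parameters of one simulated nuclear phenotype: target area distribution,
#' elongation (the axis ratio of the moment-equivalent ellipse) and radial
#' boundary perturbation (relative amplitude spread over the given
#' angular harmonics).
#'
#' @slot name phenotype name.
#' @slot n number of nuclei to generate.
#' @slot areaMean,areaSd target area distribution in px^2.
#' @slot elongation axis ratio >= 1.
#' @slot irregularityAmplitude total relative radial perturbation in [0, 0.5).
#' @slot harmonics integer wave numbers m >= 2 carrying the perturbation.
#' @slot seed optional RNG seed for standalone generation (NA = use the
#'   current RNG stream).
#'
#' @export
setClass("PhenotypeSpec",
    representation(name = "character", n = "integer",
                   areaMean = "numeric", areaSd = "numeric",
                   elongation = "numeric", irregularityAmplitude = "numeric",
                   harmonics = "integer", seed = "integer"),
    prototype(n = 1L, elongation = 1, irregularityAmplitude = 0,
              harmonics = integer(0), seed = NA_integer_))

setValidity("PhenotypeSpec", function(object) {
    msg <- NULL
    if (object@n < 1L) msg <- c(msg, "n must be >= 1")
    if (object@areaMean <= 0) msg <- c(msg, "areaMean must be positive")
    if (object@areaSd < 0) msg <- c(msg, "areaSd must be >= 0")
    if (object@elongation < 1) msg <- c(msg, "elongation must be >= 1")
    amp <- object@irregularityAmplitude
    if (amp < 0 || amp >= 0.5)
        msg <- c(msg, "irregularityAmplitude must lie in [0, 0.5)")
    if (amp > 0 && length(object@harmonics) == 0L)
        msg <- c(msg, "harmonics needed when irregularityAmplitude > 0")
    if (length(object@harmonics) && any(object@harmonics < 2L))
        msg <- c(msg, "harmonics must be integers >= 2")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic scene with ground truth
#'
#' A rendered micrograph plus the complete generating truth: one
#' \linkS4class{NucleusShape} per nucleus and a truth table with phenotype
#' labels and generator parameters.
#'
#' @slot image the rendered \linkS4class{GrayImage}.
#' @slot shapes list of \linkS4class{NucleusShape} objects.
#' @slot truth data.frame with columns nucleus_id, phenotype, target_area,
#'   amplitude, elongation, center_row, center_col.
#'
#' @export
setClass("SyntheticScene",
    representation(image = "GrayImage", shapes = "list", truth = "data.frame"))

setValidity("SyntheticScene", function(object) {
    msg <- NULL
    if (length(object@shapes) != nrow(object@truth))
        msg <- c(msg, "one truth row per shape required")
    need <- c("nucleus_id", "phenotype", "target_area", "amplitude",
              "elongation", "center_row", "center_col")
    if (!all(need %in% names(object@truth)))
        msg <- c(msg, "truth table is missing required columns")
    if (is.null(msg)) TRUE else msg
})

#' The seven nuclear phenotype classes
#'
#' Factor levels of the NMA classification, ordered as conventionally listed:
#' N (normal), I (irregular), LR (large regular), LI (large irregular),
#' SR (small regular), S (small), SI (small irregular).
#'
#' @export
NMA_CLASSES <- c("N", "I", "LR", "LI", "SR", "S", "SI")
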