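# Core of the analysis: the Nuclear Irregularity Index
#   NII = Aspect - AreaBox + RadRatio + Roundness
# (AreaBox enters negatively: box-filling regular shapes lower the index),
# the reference model calibrated on curated normal nuclei, and the
# seven-class partition of the (area, NII) plane.

#' Nuclear Irregularity Index
#'
#' NII = Aspect - AreaBox + RadRatio + Roundness. For an ideal circle under
#' the package's measurement definitions this is 1 - pi/4 + 1 + 1 = 2.215
#' (to three decimals). Given a measurement table, the NII column is added
#' (or recomputed); given four numerics, the index is returned directly.
#'
#' @param x a measurement data.frame with columns Aspect, AreaBox, RadRatio,
#'   Roundness, or a numeric vector of aspect values.
#' @param areaBox,radRatio,roundness numeric vectors, used when \code{x} is
#'   numeric.
#' @return the table with an NII column, or a numeric vector.
#' @examples
#' computeNII(1, 0.785, 1, 1)        # 2.215
#' computeNII(2.0, 0.5, 3.0, 1.8)    # 6.3
#' @export
computeNII <- function(x, areaBox = NULL, radRatio = NULL, roundness = NULL) {
    if (is.data.frame(x)) {
        need <- c("Aspect", "AreaBox", "RadRatio", "Roundness")
        miss <- setdiff(need, names(x))
        if (length(miss))
            stop("missing measurement column(s): ", paste(miss, collapse = ", "))
        bad <- !stats::complete.cases(x[need])
        if (any(bad))
            stop("non-finite measurement components in row(s): ",
                 paste(which(bad), collapse = ", "))
        x$NII <- x$Aspect - x$AreaBox + x$RadRatio + x$Roundness
        return(x)
    }
    if (is.null(areaBox) || is.null(radRatio) || is.null(roundness))
        stop("areaBox, radRatio and roundness are required")
    x - areaBox + radRatio + roundness
}

#' Calibrate the normal reference population
#'
#' Estimates mean and sample standard deviation (n - 1 denominator) of area
#' and NII from a curated set of normal nuclei — the caller excludes mitoses
#' and clearly abnormal nuclei beforehand; no automatic curation is done —
#' and stores the SD multipliers that will define the class boundaries.
#'
#' @param x a measurement data.frame with Area and NII columns (NII is
#'   computed on the fly when absent), or a numeric vector of areas.
#' @param nii numeric vector of NII values when \code{x} is numeric.
#' @param kArea SD multiplier for the small/large area boundaries.
#' @param kNII SD multiplier for the regular/irregular NII boundary.
#' @param kNIISi SD multiplier for the small vs small-irregular boundary;
#'   must exceed \code{kNII}.
#' @return a \linkS4class{ReferenceModel}.
#' @export
fitReference <- function(x, nii = NULL, kArea = 2, kNII = 2, kNIISi = 4) {
    if (is.data.frame(x)) {
        if (!"NII" %in% names(x)) x <- computeNII(x)
        area <- x$Area
        nii <- x$NII
    } else area <- x
    if (is.null(nii)) stop("NII values are required")
    if (length(area) != length(nii))
        stop("area and NII must have the same length")
    n <- length(area)
    if (n < 3L) stop("at least 3 curated reference nuclei are required")
    if (any(!is.finite(area)) || any(!is.finite(nii)))
        stop("non-finite reference values")
    sdA <- stats::sd(area); sdN <- stats::sd(nii)
    if (sdA == 0 || sdN == 0)
        stop("degenerate reference: zero standard deviation")
    if (n < 50L)
        warning(sprintf(
            "only %d reference nuclei; at least 100 per condition is recommended",
            n))
    new("ReferenceModel", meanArea = mean(area), sdArea = sdA,
        meanNII = mean(nii), sdNII = sdN, kArea = kArea, kNII = kNII,
        kNIISi = kNIISi, nReference = as.integer(n))
}

#' Class boundary thresholds of a reference model
#'
#' Derived view of the model: \code{areaLow}/\code{areaHigh} are the mean
#' area -/+ kArea SD, \code{niiIrr} is mean NII + kNII SD (the
#' regular/irregular cut) and \code{niiSi} is mean NII + kNIISi SD (above
#' which small nuclei are called small-irregular). A non-positive
#' \code{areaLow} is clamped to zero with a warning.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @return named numeric vector (areaLow, areaHigh, niiIrr, niiSi).
#' @export
nmaThresholds <- function(model) {
    lo <- model@meanArea - model@kArea * model@sdArea
    if (lo <= 0) {
        warning("areaLow clamped to 0: reference area spread exceeds its mean")
        lo <- 0
    }
    c(areaLow = lo,
      areaHigh = model@meanArea + model@kArea * model@sdArea,
      niiIrr = model@meanNII + model@kNII * model@sdNII,
      niiSi = model@meanNII + model@kNIISi * model@sdNII)
}

#' Classify nuclei into the seven NMA phenotype classes
#'
#' Partition of the (area, NII) plane, exhaustive and mutually exclusive,
#' with boundaries inclusive on the less-pathological side:
#' \itemize{
#'   \item size: small if area < areaLow, large if area > areaHigh,
#'     normal-sized otherwise;
#'   \item normal-sized: N if NII <= niiIrr, else I;
#'   \item large: LR if NII <= niiIrr, else LI;
#'   \item small: SR if NII <= niiIrr; SI if NII > niiSi; S in between.
#' }
#' N marks undisturbed interphase nuclei, I/LI mitotic-catastrophe-like
#' irregularity, LR senescent enlargement, SR apoptotic condensation, S the
#' mitotic band and SI damaged mitoses or fragments.
#'
#' @param x a measurement data.frame (NII computed on the fly when absent),
#'   or a numeric vector of areas.
#' @param model a \linkS4class{ReferenceModel}.
#' @param nii numeric vector of NII values when \code{x} is numeric.
#' @return for a data.frame input, the table with a Class factor column
#'   (levels \code{NMA_CLASSES}); for numeric input, the factor itself.
#' @export
classifyNuclei <- function(x, model, nii = NULL) {
    validObject(model)
    if (is.data.frame(x)) {
        if (!"NII" %in% names(x)) x <- computeNII(x)
        x$Class <- classifyNuclei(x$Area, model, x$NII)
        return(x)
    }
    area <- x
    if (is.null(nii)) stop("NII values are required")
    if (any(!is.finite(area)) || any(!is.finite(nii)))
        stop("non-finite area or NII")
    th <- nmaThresholds(model)
    cls <- character(length(area))
    small <- area < th["areaLow"]
    large <- area > th["areaHigh"]
    mid <- !small & !large
    regular <- nii <= th["niiIrr"]
    cls[mid & regular] <- "N"
    cls[mid & !regular] <- "I"
    cls[large & regular] <- "LR"
    cls[large & !regular] <- "LI"
    cls[small & regular] <- "SR"
    cls[small & !regular & nii <= th["niiSi"]] <- "S"
    cls[small & nii > th["niiSi"]] <- "SI"
    factor(cls, levels = NMA_CLASSES)
}

#' Per-class population summary
#'
#' Counts, percentages of total and per-class mean area and NII — the
#' numbers reported in the boxes of an NMA plot. Classes with no members are
#' reported with count 0 and undefined (NA) means.
#'
#' @param x a classified measurement data.frame (Class column present), or a
#'   factor of classes.
#' @param area,nii numeric vectors when \code{x} is a factor.
#' @return data.frame with one row per class (class, count, percent,
#'   mean_area, mean_nii) and attribute \code{n} = total nuclei.
#' @export
summarizePopulations <- function(x, area = NULL, nii = NULL) {
    if (is.data.frame(x)) {
        if (!"Class" %in% names(x)) stop("table has no Class column")
        return(summarizePopulations(x$Class, x$Area, x$NII))
    }
    cls <- factor(x, levels = NMA_CLASSES)
    n <- length(cls)
    if (n == 0L) stop("empty classification")
    counts <- table(cls)
    meanBy <- function(v) {
        if (is.null(v)) return(rep(NA_real_, length(NMA_CLASSES)))
        vapply(NMA_CLASSES, function(k) {
            sel <- cls == k
            if (any(sel)) mean(v[sel]) else NA_real_
        }, numeric(1))
    }
    out <- data.frame(class = NMA_CLASSES,
                      count = as.integer(counts),
                      percent = 100 * as.integer(counts) / n,
                      mean_area = meanBy(area),
                      mean_nii = meanBy(nii),
                      stringsAsFactors = FALSE)
    attr(out, "n") <- n
    out
}

#' Outline of the normal ellipse
#'
#' The ellipse visualizing the joint reference distribution in the
#' (NII, area) plane: centered at (meanNII, meanArea) with semi-axes
#' (kNII sdNII, kArea sdArea). It is a visualization of the reference
#' cloud; classification itself uses the rectangular thresholds.
#'
#' @param model a \linkS4class{ReferenceModel}.
#' @param nPoints number of polyline points.
#' @return numeric matrix with columns (nii, area); closed polyline, first
#'   point at angle 0.
#' @export
ellipseOutline <- function(model, nPoints = 180L) {
    validObject(model)
    th <- seq(0, 2 * pi, length.out = nPoints + 1L)
    cbind(nii = model@meanNII + model@kNII * model@sdNII * cos(th),
          area = model@meanArea + model@kArea * model@sdArea * sin(th))
}
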