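# Synthetic nuclei: star-shaped radial-Fourier boundaries
#   r(theta) = R (1 + sum_m a_m cos(m theta + phi_m))
# anisotropically scaled by (sqrt(e), 1/sqrt(e)) -- which makes the
# parameter e the axis ratio of the result -- and randomly rotated. The
# total perturbation amplitude is split evenly over the harmonics, so
# amplitude < 0.5 keeps r(theta) > 0 and the boundary simple (star-shaped).
# R is set analytically so the continuous polygon area equals the drawn
# target: area = pi R^2 (1 + sum a_m^2 / 2) (the anisotropic scaling has
# unit determinant).

#' Construct a phenotype specification
#'
#' @param name phenotype name.
#' @param n number of nuclei.
#' @param areaMean,areaSd target area distribution (px^2).
#' @param elongation axis ratio of the generated nuclei (>= 1).
#' @param irregularityAmplitude total relative radial perturbation, [0, 0.5).
#' @param harmonics integer wave numbers >= 2 carrying the perturbation.
#' @param seed optional seed for standalone shape generation.
#' @return a \linkS4class{PhenotypeSpec}.
#' @export
phenotypeSpec <- function(name, n = 1L, areaMean = 2000, areaSd = 0,
                          elongation = 1, irregularityAmplitude = 0,
                          harmonics = integer(0), seed = NA_integer_) {
    new("PhenotypeSpec", name = name, n = as.integer(n), areaMean = areaMean,
        areaSd = areaSd, elongation = elongation,
        irregularityAmplitude = irregularityAmplitude,
        harmonics = as.integer(harmonics), seed = as.integer(seed))
}

#' Preset phenotype panel
#'
#' The four morphologies of the standard validation scene, relative to a
#' normal mean area A: normal interphase (area A, mild elongation 1.2,
#' amplitude 0.03), senescent large-regular (3A, same regular boundary),
#' apoptotic small-regular (0.4A, nearly circular), and
#' mitotic-catastrophe-like irregular (1--3A, amplitude 0.25 over
#' harmonics 2--6).
#'
#' @param areaMean normal mean area A in px^2.
#' @param n nuclei per phenotype.
#' @return named list of four \linkS4class{PhenotypeSpec} objects.
#' @export
presetPhenotypes <- function(areaMean = 2000, n = 50L) {
    list(
        normal = phenotypeSpec("normal", n, areaMean, 0.10 * areaMean,
                               elongation = 1.2,
                               irregularityAmplitude = 0.03,
                               harmonics = 3:5),
        senescent = phenotypeSpec("senescent", n, 3 * areaMean,
                                  0.30 * areaMean, elongation = 1.2,
                                  irregularityAmplitude = 0.03,
                                  harmonics = 3:5),
        apoptotic = phenotypeSpec("apoptotic", n, 0.4 * areaMean,
                                  0.04 * areaMean, elongation = 1.05,
                                  irregularityAmplitude = 0.02,
                                  harmonics = 3:5),
        irregular = phenotypeSpec("irregular", n, 2 * areaMean,
                                  0.35 * areaMean, elongation = 1.3,
                                  irregularityAmplitude = 0.25,
                                  harmonics = 2:6))
}

# Draw the generating parameters of one nucleus from the current RNG
# stream. Phases are resampled (up to 100 times) if r(theta) would touch
# zero; with the even amplitude split this cannot happen for amplitude
# < 0.5, but the guard keeps the contract explicit.
.drawShapeParams <- function(spec) {
    area <- -1
    while (area < 16 * pi)   # reject absurdly small draws (< r 4 px)
        area <- stats::rnorm(1, spec@areaMean, spec@areaSd)
    m <- spec@harmonics
    aM <- if (length(m)) rep(spec@irregularityAmplitude / length(m),
                             length(m)) else numeric(0)
    thetaGrid <- seq(0, 2 * pi, length.out = 721L)
    for (attempt in seq_len(100L)) {
        phi <- if (length(m)) stats::runif(length(m), 0, 2 * pi) else numeric(0)
        pert <- rep(0, length(thetaGrid))
        for (i in seq_along(m))
            pert <- pert + aM[i] * cos(m[i] * thetaGrid + phi[i])
        if (all(1 + pert > 0.05)) break
        if (attempt == 100L)
            stop("could not draw a simple boundary after 100 attempts")
    }
    R <- sqrt(area / (pi * (1 + sum(aM^2) / 2)))
    list(targetArea = area, R = R, harmonics = m, aM = aM, phases = phi,
         rotation = stats::runif(1, 0, 2 * pi), elongation = spec@elongation)
}

.radialProfile <- function(theta, p) {
    r <- rep(p$R, length(theta))
    for (i in seq_along(p$harmonics))
        r <- r + p$R * p$aM[i] * cos(p$harmonics[i] * theta + p$phases[i])
    r
}

# Boundary polygon (row, col) of a parameterized nucleus at a given center.
.shapeBoundary <- function(p, center, nVertices = 360L) {
    theta <- seq(0, 2 * pi, length.out = nVertices + 1L)[-(nVertices + 1L)]
    r <- .radialProfile(theta, p)
    x <- r * cos(theta) * sqrt(p$elongation)
    y <- r * sin(theta) / sqrt(p$elongation)
    cs <- cos(p$rotation); sn <- sin(p$rotation)
    cbind(center[1] + cs * x - sn * y,
          center[2] + sn * x + cs * y)
}

# Pixels (row, col) inside the nucleus: exact polar test in the canonical
# frame (inverse rotation, inverse anisotropic scaling).
.shapePixels <- function(p, center) {
    ext <- max(.radialProfile(seq(0, 2 * pi, length.out = 721L), p)) *
        sqrt(p$elongation) + 1
    rows <- floor(center[1] - ext):ceiling(center[1] + ext)
    cols <- floor(center[2] - ext):ceiling(center[2] + ext)
    g <- expand.grid(row = rows, col = cols)
    dr <- g$row - center[1]; dc <- g$col - center[2]
    cs <- cos(p$rotation); sn <- sin(p$rotation)
    u <- (cs * dr + sn * dc) / sqrt(p$elongation)
    v <- (-sn * dr + cs * dc) * sqrt(p$elongation)
    rho <- sqrt(u^2 + v^2)
    theta <- atan2(v, u)
    inside <- rho <= .radialProfile(theta, p)
    matrix(as.integer(c(g$row[inside], g$col[inside])), ncol = 2L)
}

.buildShape <- function(p, center, id = 1L) {
    px <- .shapePixels(p, center)
    if (nrow(px) < 4L) stop("degenerate synthetic shape (too few pixels)")
    new("NucleusShape", id = as.integer(id), pixels = px,
        boundary = .shapeBoundary(p, center),
        centroid = c(mean(px[, 1]), mean(px[, 2])),
        bbox = c(min(px[, 1]), min(px[, 2]), max(px[, 1]), max(px[, 2])),
        calibration = 1)
}

# Maximum radial extent (px) of a parameterized nucleus, any direction.
.shapeExtent <- function(p) {
    theta <- seq(0, 2 * pi, length.out = 721L)
    b <- .shapeBoundary(p, c(0, 0))
    max(sqrt(rowSums(b^2)))
}

#' Generate one synthetic nucleus
#'
#' Draws a nucleus from the phenotype's distributions (target area, random
#' harmonic phases and orientation) and rasterizes it at the given center.
#' When the spec carries a seed, the RNG is seeded first; otherwise the
#' current RNG stream is consumed, so population generation stays fully
#' reproducible from a single seed.
#'
#' @param spec a \linkS4class{PhenotypeSpec}.
#' @param center (row, col) to place the nucleus at; chosen from the shape
#'   extent when NULL.
#' @param id nucleus id recorded on the shape.
#' @return a \linkS4class{NucleusShape}; the drawn generating parameters are
#'   attached as attribute \code{"params"}.
#' @export
generateShape <- function(spec, center = NULL, id = 1L) {
    validObject(spec)
    if (!is.na(spec@seed)) set.seed(spec@seed)
    p <- .drawShapeParams(spec)
    if (is.null(center)) {
        # a half-integer center avoids the degenerate pixel-symmetric
        # rasterization (an integer-centered disk of radius R spans 2R+1
        # pixel rows instead of the generic 2R)
        ext <- ceiling(.shapeExtent(p)) + 2.5
        center <- c(ext, ext)
    }
    s <- .buildShape(p, center, id)
    attr(s, "params") <- p
    s
}

#' Generate a synthetic micrograph with ground truth
#'
#' Places nuclei drawn from the given phenotype specs into the frame by
#' rejection sampling (no two nuclei overlap, none touches the border) and
#' renders them with per-nucleus intensity, a 1 px Gaussian blur and
#' additive Gaussian noise at the stated signal-to-noise ratio
#' (\code{snr = Inf} for a noise-free scene). Fully reproducible from
#' \code{seed}.
#'
#' @param specs list of \linkS4class{PhenotypeSpec} objects.
#' @param frameSize (rows, cols) of the rendered image.
#' @param snr signal-to-noise ratio: (mean nucleus intensity - background)
#'   divided by the noise SD.
#' @param seed RNG seed (NULL = current stream).
#' @param background background intensity (16-bit scale).
#' @param intensity mean nucleus intensity (16-bit scale).
#' @return a \linkS4class{SyntheticScene}.
#' @export
generatePopulation <- function(specs, frameSize = c(1024L, 1024L), snr = 20,
                               seed = NULL, background = 2000,
                               intensity = 45000) {
    if (is(specs, "PhenotypeSpec")) specs <- list(specs)
    lapply(specs, validObject)
    if (!is.null(seed)) set.seed(seed)
    frameArea <- prod(frameSize)
    totalArea <- sum(vapply(specs, function(s) s@n * s@areaMean, numeric(1)))
    if (totalArea >= 0.3 * frameArea)
        stop("requested nuclei cover >= 30% of the frame; use a larger frame")
    shapes <- list(); truth <- list()
    centers <- matrix(numeric(0), ncol = 2)
    extents <- numeric(0)
    gains <- numeric(0)
    id <- 0L
    for (spec in specs) {
        for (i in seq_len(spec@n)) {
            id <- id + 1L
            p <- .drawShapeParams(spec)
            gains <- c(gains, stats::runif(1, 0.85, 1.15))
            ext <- .shapeExtent(p) + 2
            margin <- ext + 4
            if (2 * margin >= min(frameSize))
                stop("frame too small for the requested nuclei; use a larger frame")
            placed <- FALSE
            for (try in seq_len(1000L)) {
                cen <- c(stats::runif(1, margin, frameSize[1] - margin),
                         stats::runif(1, margin, frameSize[2] - margin))
                if (nrow(centers) == 0 ||
                    all(sqrt((centers[, 1] - cen[1])^2 +
                             (centers[, 2] - cen[2])^2) >
                        extents + ext + 2)) {
                    placed <- TRUE; break
                }
            }
            if (!placed)
                stop("could not place all nuclei after 1000 rejections; use a larger frame")
            centers <- rbind(centers, cen)
            extents <- c(extents, ext)
            shapes[[id]] <- .buildShape(p, cen, id)
            truth[[id]] <- data.frame(
                nucleus_id = id, phenotype = spec@name,
                target_area = p$targetArea,
                amplitude = spec@irregularityAmplitude,
                elongation = spec@elongation,
                center_row = cen[1], center_col = cen[2],
                stringsAsFactors = FALSE)
        }
    }
    img <- matrix(background, frameSize[1], frameSize[2])
    for (i in seq_along(shapes))
        img[shapes[[i]]@pixels] <- intensity * gains[i]
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img / 65535),
                                             sigma = 1)) * 65535
    if (is.finite(snr))
        img <- img + stats::rnorm(length(img),
                                  sd = (intensity - background) / snr)
    img <- round(pmin(pmax(img, 0), 65535))
    new("SyntheticScene",
        image = grayImage(img, bitDepth = 16L),
        shapes = shapes,
        truth = do.call(rbind, truth))
}

#' Attach ground-truth phenotypes to measured nuclei
#'
#' Matches each measured nucleus to the nearest ground-truth center of a
#' synthetic scene (nuclei never overlap, so nearest-center assignment is
#' unambiguous for correctly segmented nuclei) and adds a
#' \code{phenotype} column.
#'
#' @param table measurement data.frame with centroid_row/centroid_col
#'   columns (as produced by \code{\link{measureNuclei}}).
#' @param scene the generating \linkS4class{SyntheticScene}.
#' @return the table with an added phenotype column.
#' @export
matchTruth <- function(table, scene) {
    if (!all(c("centroid_row", "centroid_col") %in% names(table)))
        stop("table lacks centroid columns")
    tr <- scene@truth
    idx <- vapply(seq_len(nrow(table)), function(i) {
        d <- (tr$center_row - table$centroid_row[i])^2 +
             (tr$center_col - table$centroid_col[i])^2
        which.min(d)
    }, integer(1))
    table$phenotype <- tr$phenotype[idx]
    table
}
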