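#' Construct a GrayImage
#'
#' @param pixels numeric matrix of intensities in (row, col) orientation.
#' @param bitDepth 8 or 16.
#' @param calibration physical length per pixel.
#' @param unit length unit label.
#' @return a \linkS4class{GrayImage}.
#' @export
grayImage <- function(pixels, bitDepth = 16L, calibration = 1, unit = "px") {
    new("GrayImage", pixels = pixels, bitDepth = as.integer(bitDepth),
        calibration = calibration, unit = unit)
}

#' Construct segmentation parameters
#'
#' Defaults follow the recipe used throughout the package: light Gaussian
#' smoothing (sigma 1 px), Otsu thresholding, hole filling, a 50 px^2 minimum
#' area excluding debris, border exclusion (partial nuclei bias area
#' downward) and no watershed splitting.
#'
#' @param smoothingSigma Gaussian sigma in px (0 disables smoothing).
#' @param thresholdMethod "otsu" or "fixed".
#' @param thresholdValue intensity cut when \code{thresholdMethod = "fixed"}.
#' @param minArea,maxArea region area bounds in px^2 (maxArea NA = none).
#' @param excludeBorder drop regions touching the image edge.
#' @param splitTouching split touching nuclei by distance-transform watershed.
#' @param connectivity 4 or 8.
#' @return a \linkS4class{SegmentationParams}.
#' @export
segmentationParams <- function(smoothingSigma = 1, thresholdMethod = "otsu",
                               thresholdValue = NA_real_, minArea = 50,
                               maxArea = NA_real_, excludeBorder = TRUE,
                               splitTouching = FALSE, connectivity = 8L) {
    new("SegmentationParams", smoothingSigma = smoothingSigma,
        thresholdMethod = match.arg(thresholdMethod, c("otsu", "fixed")),
        thresholdValue = thresholdValue, minArea = minArea, maxArea = maxArea,
        excludeBorder = excludeBorder, splitTouching = splitTouching,
        connectivity = as.integer(connectivity))
}

# Connected-component labeling on the pixel adjacency graph.
# Deterministic: labels are 1..K in raster-scan order of first occurrence.
.labelComponents <- function(fg, connectivity = 8L) {
    out <- matrix(0L, nrow(fg), ncol(fg))
    idx <- which(fg > 0)
    if (length(idx) == 0L) return(out)
    nr <- nrow(fg)
    np <- length(fg)
    pos <- integer(np)
    pos[idx] <- seq_along(idx)
    r <- ((idx - 1L) %% nr) + 1L
    co <- ((idx - 1L) %/% nr) + 1L
    edge1 <- integer(0); edge2 <- integer(0)
    addEdges <- function(dr, dc) {
        nb <- idx + dr + dc * nr
        ok <- (r + dr >= 1L) & (r + dr <= nr) & (co + dc <= ncol(fg)) &
              (co + dc >= 1L)
        ok[ok] <- fg[nb[ok]] > 0
        list(pos[idx[ok]], pos[nb[ok]])
    }
    steps <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8L)
        steps <- c(steps, list(c(1L, 1L), c(-1L, 1L)))
    for (s in steps) {
        e <- addEdges(s[1], s[2])
        edge1 <- c(edge1, e[[1]]); edge2 <- c(edge2, e[[2]])
    }
    g <- igraph::make_graph(rbind(edge1, edge2), n = length(idx),
                            directed = FALSE)
    comp <- igraph::components(g)$membership
    relab <- integer(max(comp))
    relab[unique(comp)] <- seq_along(unique(comp))
    out[idx] <- relab[comp]
    out
}

# Renumber labels 1..K in raster-scan order of first occurrence.
.compactLabels <- function(lab) {
    ids <- unique(lab[lab > 0])
    if (length(ids) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
    relab <- integer(max(ids))
    relab[ids] <- seq_along(ids)
    out <- matrix(0L, nrow(lab), ncol(lab))
    out[lab > 0] <- relab[lab[lab > 0]]
    out
}

#' Segment nuclei in a fluorescence image
#'
#' Pipeline: Gaussian smoothing, automatic (Otsu) or fixed thresholding,
#' hole filling, connected-component labeling, optional distance-transform
#' watershed splitting of touching nuclei, area filtering and optional
#' exclusion of border-touching regions. Deterministic for fixed inputs.
#'
#' An image with no foreground after thresholding (e.g. flat or empty)
#' yields an all-zero mask with a warning, not an error.
#'
#' @param image a \linkS4class{GrayImage} or a plain numeric matrix.
#' @param params a \linkS4class{SegmentationParams}.
#' @return a \linkS4class{LabeledMask}.
#' @export
segmentNuclei <- function(image, params = segmentationParams()) {
    if (is.matrix(image)) image <- grayImage(image, bitDepth = 16L)
    validObject(image); validObject(params)
    px <- image@pixels / (2^image@bitDepth - 1)
    if (params@smoothingSigma > 0)
        px <- EBImage::imageData(EBImage::gblur(EBImage::Image(px),
                                                sigma = params@smoothingSigma))
    rng <- range(px)
    if (diff(rng) < 1e-9) {
        warning("flat image: no foreground after thresholding")
        return(new("LabeledMask",
                   labels = matrix(0L, nrow(px), ncol(px)),
                   connectivity = params@connectivity))
    }
    thr <- if (params@thresholdMethod == "otsu")
        EBImage::otsu(EBImage::Image(px), range = rng)
    else params@thresholdValue / (2^image@bitDepth - 1)
    fg <- matrix(0L, nrow(px), ncol(px))
    fg[px > thr] <- 1L
    if (sum(fg) == 0L) {
        warning("no foreground after thresholding")
        return(new("LabeledMask", labels = fg,
                   connectivity = params@connectivity))
    }
    fg <- matrix(as.integer(EBImage::imageData(EBImage::fillHull(EBImage::Image(fg)))),
                 nrow(fg), ncol(fg))
    lab <- .labelComponents(fg, params@connectivity)
    if (params@splitTouching && max(lab) > 0) {
        dm <- EBImage::distmap(EBImage::Image(fg))
        ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
        lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(fg), ncol(fg))
        lab[fg == 0L] <- 0L
    }
    if (max(lab) > 0) {
        sizes <- tabulate(lab[lab > 0], nbins = max(lab))
        drop <- which(sizes < params@minArea)
        if (is.finite(params@maxArea))
            drop <- union(drop, which(sizes > params@maxArea))
        if (params@excludeBorder) {
            edge <- unique(c(lab[1, ], lab[nrow(lab), ],
                             lab[, 1], lab[, ncol(lab)]))
            drop <- union(drop, edge[edge > 0])
        }
        if (length(drop)) lab[lab %in% drop] <- 0L
    }
    new("LabeledMask", labels = .compactLabels(lab),
        connectivity = params@connectivity)
}

# Sub-pixel boundary of one labeled region: 0.5 iso-contour of its binary
# mask on a 1-pixel padded crop, oriented counter-clockwise (positive
# shoelace area in (row, col) coordinates).
.traceBoundary <- function(lab, id) {
    sel <- which(lab == id, arr.ind = TRUE)
    r0 <- min(sel[, 1]); r1 <- max(sel[, 1])
    c0 <- min(sel[, 2]); c1 <- max(sel[, 2])
    sub <- matrix(0, r1 - r0 + 3L, c1 - c0 + 3L)
    sub[cbind(sel[, 1] - r0 + 2L, sel[, 2] - c0 + 2L)] <- 1
    cl <- grDevices::contourLines(x = seq_len(nrow(sub)) + r0 - 2L,
                                  y = seq_len(ncol(sub)) + c0 - 2L,
                                  z = sub, levels = 0.5)
    if (length(cl) == 0L) return(NULL)
    areas <- vapply(cl, function(ct) {
        p <- cbind(ct$x, ct$y)
        abs(.shoelace(p))
    }, numeric(1))
    ct <- cl[[which.max(areas)]]
    p <- cbind(ct$x, ct$y)
    # contourLines closes the loop by repeating the first vertex
    if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (.shoelace(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    p
}

.shoelace <- function(p) {
    q <- rbind(p, p[1, ])
    sum(q[-nrow(q), 1] * q[-1, 2] - q[-1, 1] * q[-nrow(q), 2]) / 2
}

#' Extract nucleus shapes from a labeled mask
#'
#' Produces one \linkS4class{NucleusShape} per label, with the boundary
#' traced as the sub-pixel 0.5 iso-contour of the region mask
#' (counter-clockwise). Regions whose contour degenerates to fewer than
#' 3 vertices are excluded with a warning.
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @param calibration physical length per pixel.
#' @return list of \linkS4class{NucleusShape} objects (possibly empty).
#' @export
extractShapes <- function(mask, calibration = 1) {
    lab <- labels2d(mask)
    k <- max(lab)
    if (k == 0L) return(list())
    out <- vector("list", k)
    kept <- logical(k)
    for (id in seq_len(k)) {
        sel <- which(lab == id, arr.ind = TRUE)
        poly <- .traceBoundary(lab, id)
        if (is.null(poly) || nrow(poly) < 3L) {
            warning(sprintf("region %d has a degenerate boundary; excluded", id))
            next
        }
        out[[id]] <- new("NucleusShape", id = id,
            pixels = matrix(as.integer(sel), ncol = 2L),
            boundary = poly,
            centroid = c(mean(sel[, 1]), mean(sel[, 2])),
            bbox = c(min(sel[, 1]), min(sel[, 2]),
                     max(sel[, 1]), max(sel[, 2])),
            calibration = calibration)
        kept[id] <- TRUE
    }
    out[kept]
}

#' Read a fluorescence image from TIFF or PNG
#'
#' Reads 8- or 16-bit grayscale TIFF or PNG; the first channel of
#' multi-channel images is used.
#'
#' @param path file path (.tif/.tiff/.png).
#' @param calibration physical length per pixel.
#' @param unit length unit label.
#' @return a \linkS4class{GrayImage}.
#' @export
readNucleusImage <- function(path, calibration = 1, unit = "px") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("tif", "tiff")) {
        img <- tiff::readTIFF(path, as.is = TRUE)
        if (length(dim(img)) == 3L) img <- img[, , 1]
        depth <- if (max(img) > 255) 16L else 8L
        grayImage(img, bitDepth = depth, calibration = calibration,
                  unit = unit)
    } else if (ext == "png") {
        img <- png::readPNG(path)
        if (length(dim(img)) == 3L) img <- img[, , 1]
        # readPNG rescales to [0,1]; assume 16-bit when fractional steps
        # are finer than 1/255
        vals <- unique(round(img * 255, 8))
        depth <- if (all(abs(vals - round(vals)) < 1e-8)) 8L else 16L
        grayImage(round(img * (2^depth - 1)), bitDepth = depth,
                  calibration = calibration, unit = unit)
    } else stop("unsupported image format: ", ext)
}

#' Write / read a 16-bit label TIFF
#'
#' Label masks travel as 16-bit grayscale TIFF with the label id as the
#' pixel value, so externally edited masks round-trip unchanged.
#'
#' @param mask a \linkS4class{LabeledMask}.
#' @param path output path.
#' @return \code{writeLabelMask} invisibly returns \code{path};
#'   \code{readLabelMask} returns a \linkS4class{LabeledMask}.
#' @export
writeLabelMask <- function(mask, path) {
    lab <- labels2d(mask)
    if (max(lab) > 65535) stop("more than 65535 labels")
    tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' @rdname writeLabelMask
#' @param connectivity connectivity recorded on the mask read back.
#' @export
readLabelMask <- function(path, connectivity = 8L) {
    lab <- round(tiff::readTIFF(path) * 65535)
    new("LabeledMask",
        labels = .compactLabels(matrix(as.integer(lab), nrow(lab), ncol(lab))),
        connectivity = as.integer(connectivity))
}
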