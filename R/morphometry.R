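# The five NMA measurements. Conventions:
#   Area      = pixel count x calibration^2 (particle-analysis convention)
#   Aspect    = major/minor axis ratio of the second-moment-equivalent ellipse
#   AreaBox   = pixel area / axis-aligned bounding-box area, in (0, 1]
#   RadRatio  = max / min centroid-to-boundary distance (min taken
#               point-to-segment over the polyline)
#   Roundness = perimeter^2 / (4 pi area); 1 for a circle by the
#               isoperimetric equality
# Perimeter is the arc length of the sub-pixel 0.5-level contour after one
# (1,2,1)/4 moving-average smoothing pass; raw pixel-edge perimeters
# overestimate a circle's by up to 27% and would push its roundness to 1.27.

#' Nucleus area
#'
#' Pixel count times the squared spatial calibration.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return area in calibrated length units squared.
#' @export
measureArea <- function(shape) {
    pixelCount(shape) * shape@calibration^2
}

# Second central moments of the pixel set (pixel centers).
.pixelMoments <- function(shape) {
    p <- shape@pixels
    r <- p[, 1] - mean(p[, 1]); c <- p[, 2] - mean(p[, 2])
    list(mu20 = mean(r^2), mu02 = mean(c^2), mu11 = mean(r * c))
}

#' Aspect ratio of the moment-equivalent ellipse
#'
#' Ratio of the major to the minor axis of the ellipse with the same second
#' central moments as the pixel set; 1 for a circle, invariant under
#' rotation. Shapes whose minor axis collapses below one pixel (e.g. a
#' one-pixel-wide line) are rejected as degenerate.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return dimensionless aspect ratio >= 1.
#' @export
measureAspect <- function(shape) {
    m <- .pixelMoments(shape)
    tr <- m$mu20 + m$mu02
    det <- sqrt((m$mu20 - m$mu02)^2 + 4 * m$mu11^2)
    lmax <- (tr + det) / 2
    lmin <- (tr - det) / 2
    # minor axis full length of the equivalent ellipse, in px
    if (lmin <= 0 || 4 * sqrt(lmin) < 1)
        stop("degenerate shape: minor axis below one pixel")
    sqrt(lmax / lmin)
}

#' Area box
#'
#' Pixel area divided by the area of the axis-aligned bounding box. 1 for an
#' axis-aligned rectangle, pi/4 for a circle. Not invariant under arbitrary
#' rotations (the box is axis-aligned by convention); invariant under 90
#' degree rotations.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return dimensionless ratio in (0, 1].
#' @export
measureAreaBox <- function(shape) {
    b <- shape@bbox
    pixelCount(shape) / ((b[3] - b[1] + 1) * (b[4] - b[2] + 1))
}

# Minimum distance from a point to a closed polyline (point-to-segment).
.minDistToPolygon <- function(pt, poly) {
    q <- rbind(poly, poly[1, ])
    a <- q[-nrow(q), , drop = FALSE]
    b <- q[-1, , drop = FALSE]
    ab <- b - a
    ap <- cbind(pt[1] - a[, 1], pt[2] - a[, 2])
    len2 <- pmax(rowSums(ab^2), 1e-12)
    t <- pmax(0, pmin(1, rowSums(ap * ab) / len2))
    cl <- a + ab * t
    min(sqrt((pt[1] - cl[, 1])^2 + (pt[2] - cl[, 2])^2))
}

# Even-odd point-in-polygon test.
.pointInPolygon <- function(pt, poly) {
    n <- nrow(poly)
    j <- c(n, seq_len(n - 1L))
    xi <- poly[, 1]; yi <- poly[, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pt[2]) != (yj > pt[2])) &
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
    sum(cross) %% 2L == 1L
}

#' Radius ratio
#'
#' Maximum over minimum distance from the pixel-set centroid to the boundary;
#' the minimum is measured point-to-segment over the polyline, not
#' vertex-only. 1 for a circle, a/b for an ellipse. For strongly non-convex
#' shapes whose centroid falls outside the boundary the ratio is still
#' computed, with a warning.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return dimensionless ratio >= 1.
#' @export
measureRadiusRatio <- function(shape) {
    cen <- shape@centroid
    poly <- shape@boundary
    if (!.pointInPolygon(cen, poly))
        warning(sprintf("nucleus %d: centroid outside boundary", shape@id))
    dmax <- max(sqrt((poly[, 1] - cen[1])^2 + (poly[, 2] - cen[2])^2))
    dmin <- .minDistToPolygon(cen, poly)
    if (dmin <= 0) stop("centroid lies on the boundary")
    dmax / dmin
}

# Douglas-Peucker indices of an open polyline: vertices farther than eps
# from the chord are kept recursively.
.dpIndices <- function(p, eps) {
    n <- nrow(p)
    if (n <= 2L) return(seq_len(n))
    a <- p[1, ]; b <- p[n, ]
    ab <- b - a
    len2 <- sum(ab^2)
    d <- if (len2 < 1e-12)
        sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2)
    else abs(ab[2] * (p[, 1] - a[1]) - ab[1] * (p[, 2] - a[2])) / sqrt(len2)
    i <- which.max(d)
    if (d[i] <= eps) return(c(1L, n))
    left <- .dpIndices(p[1:i, , drop = FALSE], eps)
    right <- .dpIndices(p[i:n, , drop = FALSE], eps) + i - 1L
    c(left[-length(left)], right)
}

# Simplify a closed polygon to within eps (px) of itself, anchored at its
# two most mutually distant vertices so the result is independent of where
# the contour tracer happened to start.
.simplifyClosed <- function(p, eps = 0.6) {
    cen <- colMeans(p)
    i1 <- which.max((p[, 1] - cen[1])^2 + (p[, 2] - cen[2])^2)
    p <- rbind(p[i1:nrow(p), , drop = FALSE],
               p[seq_len(i1 - 1L), , drop = FALSE])
    i2 <- which.max((p[, 1] - p[1, 1])^2 + (p[, 2] - p[1, 2])^2)
    a <- p[1:i2, , drop = FALSE]
    b <- rbind(p[i2:nrow(p), , drop = FALSE], p[1, , drop = FALSE])
    ia <- .dpIndices(a, eps)
    ib <- .dpIndices(b, eps)
    rbind(a[ia[-length(ia)], , drop = FALSE],
          b[ib[-length(ib)], , drop = FALSE])
}

#' Nucleus perimeter
#'
#' Arc length of the boundary polygon after simplification to a 0.6 px
#' tolerance (Douglas-Peucker), times the spatial calibration. The
#' simplification collapses the half-pixel staircase of traced iso-contours
#' — which would otherwise overestimate a circle's perimeter by over 5% —
#' into long chords while keeping genuine corners exactly, and is invariant
#' to where the contour tracer started.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return perimeter in calibrated length units.
#' @export
measurePerimeter <- function(shape) {
    p <- .simplifyClosed(shape@boundary)
    q <- rbind(p, p[1, ])
    sum(sqrt(rowSums(diff(q)^2))) * shape@calibration
}

#' Roundness (isoperimetric quotient)
#'
#' perimeter^2 / (4 pi area): exactly 1 for an ideal circle, larger for any
#' other shape; grows with both elongation and boundary convolution.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @return dimensionless roundness.
#' @export
measureRoundness <- function(shape) {
    per <- measurePerimeter(shape)
    area <- measureArea(shape)
    rou <- per^2 / (4 * pi * area)
    if (rou < 1 - 0.05)
        warning(sprintf("nucleus %d: roundness %.3f below the discretization floor",
                        shape@id, rou))
    rou
}

#' Measure one nucleus
#'
#' Computes the five NMA measurements (plus the perimeter intermediate) for
#' a single nucleus. The NII column is left unset; see
#' \code{\link{computeNII}}.
#'
#' @param shape a \linkS4class{NucleusShape}.
#' @param imageId image identifier recorded on the row.
#' @return one-row data.frame with columns nucleus_id, image_id, Area,
#'   Aspect, AreaBox, RadRatio, Roundness, Perimeter, flag.
#' @export
measureShape <- function(shape, imageId = "image") {
    flag <- ""
    rr <- withCallingHandlers(
        measureRadiusRatio(shape),
        warning = function(w) {
            flag <<- "centroid_outside"
            invokeRestart("muffleWarning")
        })
    rou <- suppressWarnings(measureRoundness(shape))
    data.frame(nucleus_id = shape@id, image_id = imageId,
               Area = measureArea(shape), Aspect = measureAspect(shape),
               AreaBox = measureAreaBox(shape), RadRatio = rr,
               Roundness = rou, Perimeter = measurePerimeter(shape),
               centroid_row = shape@centroid[1],
               centroid_col = shape@centroid[2],
               flag = flag, stringsAsFactors = FALSE)
}

#' Measure a list of nuclei
#'
#' Applies \code{\link{measureShape}} to every shape; nuclei that fail a
#' measurement (e.g. degenerate minor axis) are reported by a warning naming
#' the nucleus and excluded from the table, never silently dropped.
#'
#' @param shapes list of \linkS4class{NucleusShape} objects.
#' @param imageId image identifier recorded on every row.
#' @return data.frame with one row per successfully measured nucleus.
#' @export
measureNuclei <- function(shapes, imageId = "image") {
    if (length(shapes) == 0L)
        return(data.frame(nucleus_id = integer(0), image_id = character(0),
                          Area = numeric(0), Aspect = numeric(0),
                          AreaBox = numeric(0), RadRatio = numeric(0),
                          Roundness = numeric(0), Perimeter = numeric(0),
                          centroid_row = numeric(0),
                          centroid_col = numeric(0),
                          flag = character(0), stringsAsFactors = FALSE))
    rows <- lapply(shapes, function(s) {
        tryCatch(measureShape(s, imageId), error = function(e) {
            warning(sprintf("nucleus %d not measured: %s", s@id,
                            conditionMessage(e)))
            NULL
        })
    })
    do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
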