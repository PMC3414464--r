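# Fixture builders: rasterized masks from predicates on pixel-center
# coordinates, and shapes traced from them through the package's own
# extraction path.

maskFromPredicate <- function(n, f, connectivity = 8L) {
    m <- matrix(0L, n, n)
    m[which(outer(seq_len(n), seq_len(n), f))] <- 1L
    new("LabeledMask", labels = m, connectivity = as.integer(connectivity))
}

shapeFromPredicate <- function(n, f, calibration = 1) {
    extractShapes(maskFromPredicate(n, f), calibration)[[1]]
}

# Canonical fixtures. Centers are off-integer to avoid the degenerate
# pixel-symmetric rasterization (an integer-centered disk of radius R
# spans 2R+1 pixel rows instead of the generic 2R).
diskShape <- function(R = 50, n = 2 * R + 60, cen = c(n / 2 + 0.5, n / 2 + 0.3),
                      calibration = 1) {
    shapeFromPredicate(n, function(i, j)
        (i - cen[1])^2 + (j - cen[2])^2 <= R^2, calibration)
}

squareShape <- function(side = 100, n = side + 20) {
    shapeFromPredicate(n, function(i, j)
        i > 10 & i <= 10 + side & j > 10 & j <= 10 + side)
}

# Ellipse with semi-axes (a, b), rotated by angle (radians).
ellipseShape <- function(a = 60, b = 30, angle = 0, n = 2 * max(a, b) + 60) {
    cen <- c(n / 2 + 0.5, n / 2 + 0.3)
    shapeFromPredicate(n, function(i, j) {
        u <- (i - cen[1]) * cos(angle) + (j - cen[2]) * sin(angle)
        v <- -(i - cen[1]) * sin(angle) + (j - cen[2]) * cos(angle)
        (u / a)^2 + (v / b)^2 <= 1
    })
}

# Ramanujan's approximation to the ellipse perimeter (oracle for roundness).
ellipsePerimeter <- function(a, b) {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Hand-computable reference model: areas {90,100,110}, NIIs {2.1,2.2,2.3},
# k = 2/2/4 gives thresholds 80 / 120 / 2.4 / 2.6.
referenceModelFixture <- function() {
    suppressWarnings(fitReference(c(90, 100, 110), c(2.1, 2.2, 2.3),
                                  kArea = 2, kNII = 2, kNIISi = 4))
}

# Flat 8-bit rendering of a mask (foreground 200, background 10).
renderMask <- function(mask, fg = 200, bg = 10) {
    px <- labels2d(mask)
    img <- matrix(bg, nrow(px), ncol(px))
    img[px > 0] <- fg
    grayImage(img, bitDepth = 8L)
}
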