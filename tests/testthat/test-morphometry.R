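# Analytic oracles: disk of radius R (area pi R^2, all dimensionless
# descriptors 1, AreaBox pi/4), square (AreaBox 1, RadRatio sqrt(2),
# Roundness 4/pi), ellipse with semi-axes (a, b) (Aspect = RadRatio = a/b,
# perimeter from Ramanujan's approximation).

test_that("disk measurements match the analytic circle", {
    d <- diskShape(50)
    expect_lt(abs(measureArea(d) - pi * 2500) / (pi * 2500), 0.01)
    expect_lt(abs(measureAspect(d) - 1), 0.02)
    expect_lt(abs(measureAreaBox(d) - pi / 4), 0.01)
    expect_lt(abs(measureRadiusRatio(d) - 1), 0.03)
    expect_lt(abs(measureRoundness(d) - 1), 0.05)
    expect_lt(abs(measurePerimeter(d) - 2 * pi * 50) / (2 * pi * 50), 0.02)
})

test_that("square measurements match the closed forms", {
    sq <- squareShape(100)
    expect_identical(measureArea(sq), 10000)
    expect_identical(measureAreaBox(sq), 1)
    expect_lt(abs(measureRadiusRatio(sq) - sqrt(2)), 0.05)
    expect_lt(abs(measureRoundness(sq) - 4 / pi), 0.05)
    sq10 <- squareShape(10)
    expect_lt(abs(measurePerimeter(sq10) - 40), 2)
})

test_that("calibration scales area quadratically and perimeter linearly", {
    sq1 <- shapeFromPredicate(30, function(i, j)
        i > 10 & i <= 20 & j > 10 & j <= 20, calibration = 1)
    sq05 <- shapeFromPredicate(30, function(i, j)
        i > 10 & i <= 20 & j > 10 & j <= 20, calibration = 0.5)
    expect_identical(measureArea(sq1), 100)
    expect_identical(measureArea(sq05), 25)
    expect_equal(measurePerimeter(sq05), measurePerimeter(sq1) / 2)
})

test_that("ellipse aspect and radius ratio equal the axis ratio at any angle", {
    for (ang in c(0, 37 * pi / 180)) {
        e <- ellipseShape(60, 30, angle = ang)
        expect_lt(abs(measureAspect(e) - 2), 0.03)
        expect_lt(abs(measureRadiusRatio(e) - 2), 0.05)
    }
    e0 <- ellipseShape(60, 30)
    rouOracle <- ellipsePerimeter(60, 30)^2 / (4 * pi * pi * 60 * 30)
    expect_lt(abs(measureRoundness(e0) - rouOracle), 0.05)
})

test_that("a right triangle half-fills its bounding box", {
    tri <- shapeFromPredicate(120, function(i, j)
        i > 10 & j > 10 & (i - 10) + (j - 10) <= 100)
    expect_lt(abs(measureAreaBox(tri) - 0.5), 0.02)
})

test_that("one-pixel-wide lines are rejected as degenerate", {
    line <- shapeFromPredicate(64, function(i, j) i == 30 & j > 10 & j <= 50)
    expect_error(measureAspect(line), "degenerate")
})

test_that("all five measurements are invariant under 90-degree rotation", {
    m <- maskFromPredicate(160, function(i, j) {
        u <- (i - 80.5) * cos(0.6) + (j - 80.2) * sin(0.6)
        v <- -(i - 80.5) * sin(0.6) + (j - 80.2) * cos(0.6)
        (u / 55)^2 + (v / 32)^2 <= 1
    })
    lab <- labels2d(m)
    rot <- new("LabeledMask", labels = t(lab)[ncol(lab):1, ],
               connectivity = 8L)
    a <- measureShape(extractShapes(m)[[1]])
    b <- measureShape(extractShapes(rot)[[1]])
    for (col in c("Area", "Aspect", "AreaBox", "RadRatio", "Roundness"))
        expect_lt(abs(b[[col]] - a[[col]]) / a[[col]], 0.005)
})

test_that("dimensionless measurements are scale-invariant", {
    small <- ellipseShape(30, 18, angle = 0.4)
    big <- ellipseShape(60, 36, angle = 0.4)
    a <- measureShape(small); b <- measureShape(big)
    expect_lt(abs(b$Area / a$Area - 4), 4 * 0.02)
    for (col in c("Aspect", "AreaBox", "RadRatio", "Roundness"))
        expect_lt(abs(b[[col]] - a[[col]]) / a[[col]], 0.02)
    expect_lt(abs(b$Perimeter / a$Perimeter - 2), 2 * 0.01)
})

test_that("a 45-degree rotated square has AreaBox about one half", {
    rot45 <- shapeFromPredicate(160, function(i, j)
        abs(i - 80.5) + abs(j - 80.2) <= 50)
    expect_lt(abs(measureAreaBox(rot45) - 0.5), 0.03)
})

test_that("roundness and radius ratio increase with boundary perturbation", {
    rou <- c(); rr <- c()
    for (k in seq_along(c(0, 0.1, 0.2, 0.3))) {
        amp <- c(0, 0.1, 0.2, 0.3)[k]
        s <- generateShape(phenotypeSpec("star", areaMean = pi * 50^2,
                                         irregularityAmplitude = amp,
                                         harmonics = c(3L, 5L),
                                         seed = 100L + k))
        m <- suppressWarnings(measureShape(s))
        rou <- c(rou, m$Roundness); rr <- c(rr, m$RadRatio)
    }
    expect_true(all(diff(rou) > 0))
    expect_true(all(diff(rr) > 0))
})

test_that("aspect recovers the generating axis ratio of random ellipses", {
    set.seed(7)
    for (i in 1:20) {
        a <- runif(1, 20, 80)
        b <- runif(1, 20, a)
        ang <- runif(1, 0, pi)
        e <- ellipseShape(a, b, angle = ang)
        expect_lt(abs(measureAspect(e) - a / b) / (a / b), 0.03)
    }
})

test_that("failed nuclei are reported, not silently dropped", {
    good <- diskShape(20)
    line <- shapeFromPredicate(64, function(i, j) i == 30 & j > 10 & j <= 50)
    line@id <- 2L
    expect_warning(tab <- measureNuclei(list(good, line)),
                   "nucleus 2 not measured")
    expect_identical(nrow(tab), 1L)
    expect_identical(nrow(measureNuclei(list())), 0L)
})
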