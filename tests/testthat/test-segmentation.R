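test_that("flat or empty images yield an all-zero mask with a warning", {
    img <- grayImage(matrix(0, 64, 64), bitDepth = 8L)
    expect_warning(mask <- segmentNuclei(img), "flat|foreground")
    expect_identical(max(labels2d(mask)), 0L)

    img2 <- grayImage(matrix(37, 80, 80), bitDepth = 8L)
    expect_warning(mask2 <- segmentNuclei(img2), "flat|foreground")
    expect_identical(max(labels2d(mask2)), 0L)
})

test_that("a rendered disk is segmented with close to its analytic area", {
    mask0 <- maskFromPredicate(128, function(i, j)
        (i - 64.5)^2 + (j - 64.3)^2 <= 30^2)
    img <- renderMask(mask0)
    mask <- segmentNuclei(img, segmentationParams(minArea = 100))
    expect_identical(max(labels2d(mask)), 1L)
    area <- sum(labels2d(mask) > 0)
    expect_lt(abs(area - pi * 30^2) / (pi * 30^2), 0.02)
})

test_that("watershed splitting separates two touching disks", {
    touching <- function(i, j)
        (i - 70.5)^2 + (j - 100.3)^2 <= 900 |
        (i - 131.5)^2 + (j - 100.3)^2 <= 900
    img <- renderMask(maskFromPredicate(200, touching))
    merged <- segmentNuclei(img, segmentationParams(splitTouching = FALSE))
    expect_identical(max(labels2d(merged)), 1L)
    split <- segmentNuclei(img, segmentationParams(splitTouching = TRUE))
    expect_identical(max(labels2d(split)), 2L)
})

test_that("border-touching regions are dropped when excludeBorder is set", {
    edge <- function(i, j) (i - 5)^2 + (j - 64)^2 <= 400
    img <- renderMask(maskFromPredicate(128, edge))
    kept <- segmentNuclei(img, segmentationParams(excludeBorder = FALSE,
                                                  smoothingSigma = 0))
    expect_identical(max(labels2d(kept)), 1L)
    dropped <- segmentNuclei(img, segmentationParams(excludeBorder = TRUE,
                                                     smoothingSigma = 0))
    expect_identical(max(labels2d(dropped)), 0L)
})

test_that("connectivity 4 vs 8 differs on diagonally touching blocks", {
    diag2 <- function(i, j)
        (i > 10 & i <= 20 & j > 10 & j <= 20) |
        (i > 20 & i <= 30 & j > 20 & j <= 30)
    img <- renderMask(maskFromPredicate(64, diag2))
    p8 <- segmentationParams(smoothingSigma = 0, minArea = 10,
                             excludeBorder = FALSE, connectivity = 8L)
    p4 <- segmentationParams(smoothingSigma = 0, minArea = 10,
                             excludeBorder = FALSE, connectivity = 4L)
    expect_identical(max(labels2d(segmentNuclei(img, p8))), 1L)
    expect_identical(max(labels2d(segmentNuclei(img, p4))), 2L)
})

test_that("extracted shapes carry correct pixel sets, bboxes and centroids", {
    sq <- shapeFromPredicate(30, function(i, j)
        i > 10 & i <= 20 & j > 12 & j <= 22)
    expect_identical(pixelCount(sq), 100L)
    expect_equal(bbox(sq), c(11, 13, 20, 22))
    expect_equal(centroid(sq), c(15.5, 17.5))

    d <- diskShape(50)
    expect_lt(max(abs(centroid(d) - c(80.5, 80.3))), 0.5)

    expect_identical(extractShapes(new("LabeledMask",
                                       labels = matrix(0L, 64, 64))), list())
})

test_that("segmentation is translation-equivariant", {
    base <- function(i, j) (i - 40.5)^2 + (j - 40.2)^2 <= 20^2
    imgA <- renderMask(maskFromPredicate(160, base))
    imgB <- renderMask(maskFromPredicate(160, function(i, j)
        base(i - 23, j - 41)))
    sa <- extractShapes(segmentNuclei(imgA))[[1]]
    sb <- extractShapes(segmentNuclei(imgB))[[1]]
    expect_identical(pixelCount(sa), pixelCount(sb))
    expect_equal(centroid(sb) - centroid(sa), c(23, 41))
    expect_equal(bbox(sb) - bbox(sa), c(23, 41, 23, 41))
})

test_that("relabeling a binarized rendering of a mask is idempotent", {
    spec <- presetPhenotypes(n = 6L)$normal
    scene <- generatePopulation(spec, frameSize = c(512L, 512L), snr = Inf,
                                seed = 11)
    mask1 <- segmentNuclei(scene@image)
    img2 <- renderMask(mask1)
    mask2 <- segmentNuclei(img2, segmentationParams(smoothingSigma = 0))
    expect_identical(max(labels2d(mask1)), max(labels2d(mask2)))
})

test_that("labels are contiguous and each foreground pixel has one label", {
    scene <- generatePopulation(presetPhenotypes(n = 5L)$irregular,
                                frameSize = c(512L, 512L), snr = 30,
                                seed = 4)
    lab <- labels2d(segmentNuclei(scene@image))
    k <- max(lab)
    expect_gt(k, 0L)
    expect_identical(sort(unique(as.vector(lab[lab > 0]))), seq_len(k))
    shapes <- extractShapes(segmentNuclei(scene@image))
    expect_identical(sum(vapply(shapes, pixelCount, integer(1))),
                     sum(lab > 0))
})

test_that("label masks round-trip through 16-bit TIFF", {
    scene <- generatePopulation(presetPhenotypes(n = 3L)$normal,
                                frameSize = c(256L, 256L), snr = Inf,
                                seed = 2)
    mask <- segmentNuclei(scene@image)
    path <- withr::local_tempfile(fileext = ".tif")
    writeLabelMask(mask, path)
    back <- readLabelMask(path)
    expect_identical(labels2d(back), labels2d(mask))
})
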