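test_that("NII is the exact signed sum of its four components", {
    expect_equal(computeNII(1, 0.785, 1, 1), 2.215, tolerance = 1e-15)
    expect_equal(computeNII(2.0, 0.5, 3.0, 1.8), 6.3, tolerance = 1e-15)
    d <- suppressWarnings(measureShape(diskShape(50)))
    d <- computeNII(d)
    expect_lt(abs(d$NII - 2.215), 0.1)
})

test_that("NII on a table requires all four component columns", {
    df <- data.frame(Aspect = 1, AreaBox = 0.8, Roundness = 1)
    expect_error(computeNII(df), "RadRatio")
    df2 <- data.frame(Aspect = 1, AreaBox = NA_real_, RadRatio = 1,
                      Roundness = 1)
    expect_error(computeNII(df2), "non-finite")
})

test_that("the reference fit reproduces hand-computed statistics", {
    model <- referenceModelFixture()
    expect_equal(model@meanArea, 100)
    expect_equal(model@sdArea, 10)
    expect_equal(model@meanNII, 2.2)
    expect_equal(model@sdNII, 0.1)
    th <- nmaThresholds(model)
    expect_equal(unname(th), c(80, 120, 2.4, 2.6), tolerance = 1e-12)
})

test_that("degenerate reference sets are rejected", {
    expect_error(suppressWarnings(fitReference(rep(100, 5), rep(2.2, 5))),
                 "degenerate")
    expect_error(fitReference(c(90, 100), c(2.1, 2.2)), "at least 3")
    expect_warning(fitReference(c(90, 100, 110), c(2.1, 2.2, 2.3)),
                   "recommended")
})

test_that("the fit recovers the generating parameters of simulated normals", {
    set.seed(19)
    n <- 200
    area <- rnorm(n, 100, 10)
    nii <- rnorm(n, 2.2, 0.1)
    model <- fitReference(area, nii)
    expect_lt(abs(model@meanArea - 100), 2 * 10 / sqrt(n))
    expect_lt(abs(model@meanNII - 2.2), 2 * 0.1 / sqrt(n))
})

test_that("the seven worked classifications follow the class semantics", {
    model <- referenceModelFixture()
    cases <- list(list(100, 2.2, "N"), list(100, 2.5, "I"),
                  list(130, 2.3, "LR"), list(130, 3.0, "LI"),
                  list(70, 2.3, "SR"), list(70, 2.5, "S"),
                  list(70, 2.7, "SI"))
    for (cs in cases)
        expect_identical(as.character(classifyNuclei(cs[[1]], model,
                                                     cs[[2]])), cs[[3]])
    # boundaries are inclusive on the less-pathological side
    th <- nmaThresholds(model)
    expect_identical(as.character(classifyNuclei(th[["areaHigh"]], model,
                                                 th[["niiIrr"]])), "N")
    expect_identical(as.character(classifyNuclei(70, model,
                                                 th[["niiSi"]])), "S")
})

test_that("classification partitions the whole (area, NII) plane", {
    model <- referenceModelFixture()
    set.seed(5)
    area <- runif(10000, 100 - 6 * 10, 100 + 6 * 10)
    nii <- runif(10000, 2.2 - 6 * 0.1, 2.2 + 6 * 0.1)
    cls <- classifyNuclei(area, model, nii)
    expect_false(any(is.na(cls)))
    expect_identical(length(cls), 10000L)
    expect_error(classifyNuclei(c(100, NaN), model, c(2.2, 2.2)),
                 "non-finite")
})

test_that("classification is invariant under a global area rescaling", {
    model <- referenceModelFixture()
    set.seed(8)
    area <- runif(500, 40, 160)
    nii <- runif(500, 1.9, 2.9)
    cls1 <- classifyNuclei(area, model, nii)
    scaled <- suppressWarnings(fitReference(c(90, 100, 110) * 3.7,
                                            c(2.1, 2.2, 2.3)))
    cls2 <- classifyNuclei(area * 3.7, scaled, nii)
    expect_identical(cls1, cls2)
})

test_that("increasing NII at normal size switches N to I exactly once", {
    model <- referenceModelFixture()
    nii <- seq(1.8, 3.2, by = 0.01)
    cls <- as.character(classifyNuclei(rep(100, length(nii)), model, nii))
    expect_identical(unique(cls), c("N", "I"))
    expect_identical(sum(diff(cls == "N") != 0), 1L)
})

test_that("most reference nuclei fall inside their own normal class", {
    set.seed(33)
    area <- rnorm(300, 100, 10)
    nii <- rnorm(300, 2.2, 0.1)
    model <- fitReference(area, nii)
    cls <- classifyNuclei(area, model, nii)
    expect_gte(mean(cls == "N"), 0.90)
})

test_that("population summaries count, percentage and average correctly", {
    cls <- factor(c("N", "N", "SR", "LI"), levels = NMA_CLASSES)
    s <- summarizePopulations(cls, area = c(100, 102, 60, 150),
                              nii = c(2.2, 2.1, 2.2, 3.1))
    expect_equal(s$percent[s$class == "N"], 50)
    expect_equal(s$percent[s$class == "SR"], 25)
    expect_equal(s$percent[s$class == "LI"], 25)
    expect_equal(s$percent[s$class == "I"], 0)
    expect_true(is.na(s$mean_area[s$class == "I"]))
    expect_equal(s$mean_area[s$class == "N"], 101)
    expect_equal(sum(s$percent), 100, tolerance = 1e-9)
    expect_identical(attr(s, "n"), 4L)

    allN <- summarizePopulations(factor(rep("N", 10), levels = NMA_CLASSES))
    expect_equal(allN$percent[allN$class == "N"], 100)
    expect_error(summarizePopulations(factor(character(0),
                                             levels = NMA_CLASSES)), "empty")
})

test_that("the normal ellipse has the documented center and semi-axes", {
    model <- referenceModelFixture()
    ell <- ellipseOutline(model, nPoints = 180L)
    expect_equal(unname(ell[1, ]), c(2.4, 100))     # angle 0
    expect_equal(unname(ell[46, ]), c(2.2, 120))    # angle 90
    resid <- ((ell[, "nii"] - 2.2) / 0.2)^2 + ((ell[, "area"] - 100) / 20)^2
    expect_lt(max(abs(resid - 1)), 1e-9)
})
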