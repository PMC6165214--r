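test_that("the width model reproduces its closed form", {
    expect_equal(widthModel(0, 0.84e-3, 1.36e-3, 0.54e-3), 0.84e-3)
    expect_equal(widthModel(1, 0.84e-3, 1.36e-3, 0.54e-3), 1.6872e-3,
                 tolerance = 1e-4)
    expect_equal(widthModel(sqrt(3), 0.84e-3, 1.36e-3, 0.54e-3), 2.9797e-3,
                 tolerance = 1e-4)
    ## strictly increasing in theta when disorder is present
    th <- seq(0.5, 3, by = 0.1)
    expect_true(all(diff(widthModel(th, 0.84e-3, 1.36e-3, 0.54e-3)) > 0))
    expect_error(widthModel(1, -1e-3, 1e-3, 1e-3), ">= 0")
})

test_that("the convex-hull baseline vanishes on linear and convex traces", {
    x <- seq(0, 1, length.out = 50)
    lin <- convexHullBaseline(trace1D(x, 2 + 3 * x))
    expect_equal(lin@intensity, rep(0, 50), tolerance = 1e-12)
    bowl <- convexHullBaseline(trace1D(x, (x - 0.5)^2))
    expect_equal(bowl@intensity, rep(0, 50), tolerance = 1e-12)
    expect_error(convexHullBaseline(trace1D(c(0, 1), c(1, 1))),
                 "at least 3")
})

test_that("hull removal recovers a Gaussian riding on a ramp", {
    x <- seq(0, 0.1, length.out = 400)
    peak <- 5 / (sqrt(2 * pi) * 0.003) *
        exp(-(x - 0.05)^2 / (2 * 0.003^2))
    tr <- convexHullBaseline(trace1D(x, 40 + 200 * x + peak))
    expect_equal(trapz(x, tr@intensity), 5, tolerance = 0.02)
    expect_equal(tr@intensity[1], 0)
    expect_equal(tr@intensity[length(x)], 0)
})

test_that("the equator fit recovers a noise-free trace to 0.1%", {
    co <- seq(0.012, 0.096, by = 4.84e-4)
    tr <- equatorTrace(co, 36, c(50, 25, 3, 0.5, 0.5),
                       sigmaC = 0.84e-3, sigmaD = 1.4e-3, sigmaS = 0.5e-3)
    f <- fitEquator(tr, sigmaC = 0.84e-3)
    expect_equal(d10(f), 36, tolerance = 1e-3)
    expect_equal(intensityRatio(f), 0.5, tolerance = 1e-3)
    expect_equal(sigmaD(f), 1.4e-3, tolerance = 1e-3)
    expect_equal(sigmaS(f), 0.5e-3, tolerance = 1e-3)
    expect_equal(unname(peakAreas(f)), c(50, 25, 3, 0.5, 0.5),
                 tolerance = 1e-3)
})

test_that("fitted Gaussian areas agree with numeric integration", {
    ## oracle equivalence on an isolated single-peak trace
    co <- seq(0.012, 0.096, by = 2e-4)
    tr <- equatorTrace(co, 36, c(12, 6, 0.5, 0.1, 0.1),
                       sigmaC = 0.84e-3, sigmaD = 1.4e-3, sigmaS = 0.5e-3)
    f <- fitEquator(tr, sigmaC = 0.84e-3)
    for (i in 1:2) {
        s <- widthModel(sqrt(c(1, 3))[i], 0.84e-3, sigmaD(f), sigmaS(f))
        ctr <- sqrt(c(1, 3))[i] / d10(f)
        comp <- peakAreas(f)[[i]] / (sqrt(2 * pi) * s) *
            exp(-(co - ctr)^2 / (2 * s^2))
        expect_equal(trapz(co, comp) / peakAreas(f)[[i]], 1,
                     tolerance = 0.005)
    }
})

test_that("Poisson ensembles recover ratio and widths within uncertainty", {
    co <- seq(0.012, 0.096, by = 4.84e-4)
    tru <- equatorTrace(co, 36, c(50, 21, 3, 0.5, 0.5),
                        sigmaC = 0.84e-3, sigmaD = 1.36e-3,
                        sigmaS = 0.54e-3)
    fits <- lapply(1:20, function(s) {
        set.seed(s)
        fitEquator(trace1D(co, rpois(length(co), tru@intensity * 20) / 20),
                   sigmaC = 0.84e-3)
    })
    ratios <- vapply(fits, intensityRatio, numeric(1))
    expect_equal(mean(ratios), 21 / 50, tolerance = 0.02)
    sdHat <- vapply(fits, sigmaD, numeric(1))
    ssHat <- vapply(fits, sigmaS, numeric(1))
    expect_lt(abs(mean(sdHat) - 1.36e-3),
              max(2 * sd(sdHat) / sqrt(20), 0.02 * 1.36e-3))
    expect_lt(abs(mean(ssHat) - 0.54e-3),
              max(2 * sd(ssHat) / sqrt(20), 0.02 * 0.54e-3))
})

test_that("a trace with only the (1,0) peak errors instead of reporting 0", {
    co <- seq(0.012, 0.096, by = 4.84e-4)
    tr <- equatorTrace(co, 36, c(50, 0, 0, 0, 0),
                       sigmaC = 0.84e-3, sigmaD = 1.4e-3, sigmaS = 0.5e-3)
    expect_error(fitEquator(tr, sigmaC = 0.84e-3), "refusing")
})

test_that("parameter recovery is unbiased with calibrated intervals", {
    ## grid over ratios and the resting/contracting sigma_s conditions
    co <- seq(0.012, 0.096, by = 4.84e-4)
    for (cond in list(c(0.4, 0.54e-3), c(1.2, 0.54e-3), c(2.1, 1.08e-3))) {
        tru <- equatorTrace(co, 36, c(40, 40 * cond[1], 3, 0.5, 0.5),
                            sigmaC = 0.84e-3, sigmaD = 1.36e-3,
                            sigmaS = cond[2])
        est <- se <- numeric(50)
        for (s in 1:50) {
            set.seed(1000 + s)
            f <- fitEquator(trace1D(co, rpois(length(co),
                                              tru@intensity * 20) / 20),
                            sigmaC = 0.84e-3)
            est[s] <- intensityRatio(f)
            se[s] <- f@se[["ratio"]]
        }
        expect_lt(abs(mean(est) / cond[1] - 1), 0.02)
        cover <- mean(abs(est - cond[1]) <= se)
        expect_gte(cover, 0.55)
        expect_lte(cover, 0.85)
    }
})

test_that("raising the generator head partition raises the fitted ratio", {
    g <- fixtureGeometry()
    m <- fixtureModel()
    ratios <- vapply(c(0.3, 0.5, 0.7), function(p) {
        m@headPartition <- p
        intensityRatio(analyzeEquator(
            renderPattern(m, g, "resting", seed = 1, noise = FALSE)))
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))
})

test_that("delta ratio matches the printed state differences", {
    expect_equal(deltaRatio(0.421, 1.175), 0.754, tolerance = 1e-12)
    expect_equal(deltaRatio(0.421, 2.13), 1.709, tolerance = 1e-12)
    expect_equal(deltaRatio(0.5, 0.5), 0)
    expect_equal(deltaRatio(0.3, 0.9), -deltaRatio(0.9, 0.3))
})

test_that("axial widths are recovered and orientation errors are loud", {
    f <- fixtureFolded("resting", seed = 7)
    sub <- subtractBackground(f, fixtureBackground("resting", 7))
    fit <- analyzeEquator(fixtureRender("resting", seed = 7))
    aw <- measureAxialWidth(sub, c(1, 0), fit)
    expect_equal(aw, 2.7e-3, tolerance = 0.05)
    ## doubling exposure leaves the width unchanged
    m2 <- latticeModel(exposureScale = 2e6)
    i2 <- renderPattern(m2, fixtureGeometry(), "resting", seed = 7)
    f2 <- quadrantFold(i2)
    sub2 <- subtractBackground(f2, estimateCircularBackground(f2))
    expect_equal(measureAxialWidth(sub2, c(1, 0), fit), aw,
                 tolerance = 0.05)
    ## transposed image: the reflection is no longer on the equator
    tp <- diffractionImage(t(counts(sub)), geometry(sub), provenance(sub))
    expect_error(measureAxialWidth(tp, c(1, 0), fit), "orientation")
})
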