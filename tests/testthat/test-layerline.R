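test_that("Bessel first maxima match independent numeric values", {
    ## frozen from maximizing J_n(x)^2 on a fine grid (independent of the
    ## golden-section path in the implementation)
    expect_equal(besselFirstMax(1), 1.84118378, tolerance = 1e-7)
    expect_equal(besselFirstMax(3), 4.20118894, tolerance = 1e-7)
    expect_equal(besselFirstMax(4), 5.31755313, tolerance = 1e-7)
    expect_error(besselFirstMax(-1), "non-negative")
})

test_that("the Rm relation inverts the generator peak position", {
    expect_equal(rmFromFirstMax(besselFirstMax(1) / (2 * pi * 12.5), 1),
                 12.5, tolerance = 1e-9)
    expect_equal(rmFromFirstMax(0.0234, 1), 12.52, tolerance = 1e-3)
    expect_equal(rmFromFirstMax(0.062, 4), 13.65, tolerance = 1e-3)
    expect_error(rmFromFirstMax(0, 1), "> 0")
})

test_that("the trace fit recovers a Bessel lobe on a known background", {
    ## independent trace construction: J4^2 profile (Rm 12.5) + the
    ## three-Gaussian background + Poisson noise
    x <- seq(0, 0.106, by = 4.84e-4)
    bgTruth <- 200 * exp(-x^2 / (2 * 0.002^2)) +
        120 * exp(-x^2 / (2 * 0.012^2)) +
        80 * exp(-x^2 / (2 * 0.08^2))
    peak <- 400 * besselJ(2 * pi * 12.5 * x, 4)^2
    set.seed(11)
    y <- rpois(length(x), bgTruth + peak)
    fit <- fitLayerLine(trace1D(x, y), besselOrder = 4)
    rTrue <- besselFirstMax(4) / (2 * pi * 12.5)
    expect_equal(firstMaximum(fit), rTrue, tolerance = 0.01)
    ## truth restricted to the first lobe, the region the Gaussian models
    areaTrue <- trapz(x, peak)
    expect_equal(fit@area, areaTrue, tolerance = 0.05)
    expect_length(fitFlags(fit), 0)
})

test_that("background-only traces are flagged as having no ordered heads", {
    x <- seq(0, 0.106, by = 4.84e-4)
    bgTruth <- 200 * exp(-x^2 / (2 * 0.002^2)) +
        120 * exp(-x^2 / (2 * 0.012^2)) +
        80 * exp(-x^2 / (2 * 0.08^2))
    set.seed(5)
    fit <- fitLayerLine(trace1D(x, rpois(length(x), bgTruth)),
                        besselOrder = 4)
    expect_true("no_ordered_heads" %in% fitFlags(fit))
})

test_that("rigor patterns yield a flagged zero-intensity layer line", {
    for (s in 1:2) {
        lrig <- analyzeLayerLine(fixtureRender("rigor", seed = s))
        expect_true("no_ordered_heads" %in% fitFlags(lrig))
        lr <- analyzeLayerLine(fixtureRender("resting", seed = s),
                               background = fixtureBackground("resting", s))
        expect_equal(residualIntensityRatio(lrig, lr), 0)
    }
})

test_that("residual intensity ratios behave at the boundaries", {
    expect_equal(residualIntensityRatio(3.2, 3.2), 1)
    expect_equal(residualIntensityRatio(-0.5, 2), 0)   # clipped at 0
    expect_error(residualIntensityRatio(1, 0), "> 0")
})

test_that("paired states recover the injected residual MLL4 ratio", {
    res <- vapply(1:4, function(s) {
        ir <- fixtureRender("resting", seed = s)
        ic <- fixtureRender("contracting", seed = 1000 + s,
                            contractingFactor = sqrt(0.27))
        lr <- analyzeLayerLine(ir,
                               background = fixtureBackground("resting", s))
        fc <- quadrantFold(ic)
        lc <- analyzeLayerLine(ic,
                               background = estimateCircularBackground(fc))
        residualIntensityRatio(lc, lr)
    }, numeric(1))
    expect_equal(mean(res), 0.27, tolerance = 0.075)
})

test_that("Rm round trips hold across orders and radii", {
    g <- fixtureGeometry()
    for (n in c(1, 3, 4)) for (rm in c(11, 12.5, 14)) {
        mi <- latticeModel(rmTrue = rm, besselOrders = c("1" = 1, "4" = n))
        nf <- renderPattern(mi, g, "resting", seed = 1, noise = FALSE)
        ll <- analyzeLayerLine(nf, band = c(0.088, 0.097),
                               besselOrder = n, fold = FALSE)
        expect_lt(abs(headRadius(ll) / rm - 1), 0.01)
    }
    ## with counting noise at the default condition
    rms <- vapply(1:5, function(s) {
        headRadius(analyzeLayerLine(fixtureRender("resting", seed = s)))
    }, numeric(1))
    expect_true(all(abs(rms / 12.53 - 1) < 0.03))
})

test_that("the first maximum position is independent of the ordered fraction", {
    g <- fixtureGeometry()
    r <- vapply(c(0.35, 0.7), function(f) {
        nf <- renderPattern(latticeModel(fOrdered = f), g, "resting",
                            seed = 1, noise = FALSE)
        firstMaximum(analyzeLayerLine(nf, fold = FALSE))
    }, numeric(1))
    expect_equal(r[1], r[2], tolerance = 1e-3)
})

test_that("normalized MLL4 intensity follows the mass-squared law", {
    g <- fixtureGeometry()
    fs <- c(0.25, 0.5, 1.0)
    norm <- vapply(fs, function(f) {
        nf <- quadrantFold(renderPattern(latticeModel(fOrdered = f), g,
                                         "resting", seed = 1,
                                         noise = FALSE))
        bg <- estimateCircularBackground(nf)
        ll <- fitLayerLine(projectBand(nf, "onto_equatorial_direction",
                                       c(0.088, 0.097)), besselOrder = 4)
        normalizeByDiffuse(ll@area, bg)
    }, numeric(1))
    l <- lm(norm ~ I(fs^2))
    expect_gt(summary(l)$r.squared, 0.99)
    expect_lt(abs(coef(l)[1]) / max(norm), 0.02)
})

test_that("the 1% axial spacing change is detected from paired traces", {
    trRest <- projectBand(fixtureFolded("resting", seed = 1, noise = FALSE),
                          "onto_meridian", c(0.03, 0.077))
    trAct <- projectBand(fixtureFolded("contracting", seed = 1,
                                       noise = FALSE),
                         "onto_meridian", c(0.03, 0.077))
    expect_equal(axialSpacingShift(trRest, trAct, 4), 0.01,
                 tolerance = 0.05)
    expect_equal(axialSpacingShift(trRest, trRest, 4), 0)
    ## epsilon = 0 contracting intensities: no shift beyond noise
    mc <- applyStatePreset(fixtureModel(), "contracting")
    mc@spacingFactor <- 0
    i0 <- renderPattern(mc, fixtureGeometry(), "resting", seed = 21)
    tr0 <- projectBand(quadrantFold(i0), "onto_meridian", c(0.03, 0.077))
    trR <- projectBand(fixtureFolded("resting", seed = 22),
                       "onto_meridian", c(0.03, 0.077))
    expect_lt(abs(axialSpacingShift(trR, tr0, 4)), 0.003)
})

test_that("Tm/ALL2 intensity tracks activation and ignores exposure", {
    act <- tmAll2Intensity(fixtureRender("contracting", seed = 5))
    rest <- tmAll2Intensity(fixtureRender("resting", seed = 5))
    expect_gt(act / rest, 2)
    m2 <- latticeModel(exposureScale = 2e6)
    act2 <- tmAll2Intensity(renderPattern(m2, fixtureGeometry(),
                                          "contracting", seed = 5))
    expect_equal(act2 / act, 1, tolerance = 0.05)
    expect_error(tmAll2Intensity(fixtureRender("resting", seed = 5),
                                 axialBand = c(0.06, 0.05)), "ordered")
    expect_error(tmAll2Intensity(fixtureRender("resting", seed = 5),
                                 axialBand = c(0.5, 0.6)),
                 "outside the detector")
})
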