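test_that("quadrant folding averages mirrored pixels and is idempotent", {
    gm <- detectorGeometry(imageShape = c(41L, 41L))
    x <- matrix(0, 41, 41)
    x[21 + 10, 21 + 5] <- 4
    fx <- counts(quadrantFold(diffractionImage(x, gm)))
    for (sr in c(-1, 1)) for (sc in c(-1, 1))
        expect_equal(fx[21 + sr * 10, 21 + sc * 5], 1)
    expect_equal(sum(fx), 4)

    img <- fixtureRender("resting", seed = 2)
    f1 <- quadrantFold(img)
    f2 <- quadrantFold(f1)
    expect_equal(counts(f2), counts(f1), tolerance = 1e-12)
    ## folding a symmetric image changes nothing
    nf <- fixtureRender("resting", seed = 1, noise = FALSE)
    expect_equal(counts(quadrantFold(nf)), counts(nf), tolerance = 1e-10)
})

test_that("folding excludes masked pixels with a per-pixel divisor", {
    gm <- detectorGeometry(imageShape = c(21L, 21L))
    x <- matrix(1, 21, 21)
    x[11 + 5, 11 + 3] <- NA        # one mirror partner masked
    x[11 - 5, 11 + 3] <- 7
    x[11 + 5, 11 - 3] <- 7
    x[11 - 5, 11 - 3] <- 7
    fx <- counts(quadrantFold(diffractionImage(x, gm)))
    expect_equal(fx[11 + 5, 11 + 3], 7)   # mean of the 3 unmasked mirrors
    expect_equal(fx[11, 11], 1)
})

test_that("folding preserves the mean intensity", {
    img <- fixtureRender("resting", seed = 2)
    expect_equal(mean(counts(quadrantFold(img))), mean(counts(img)),
                 tolerance = 1e-3)
})

test_that("the circular background reproduces a smooth symmetric image", {
    g <- fixtureGeometry()
    co <- reciprocalCoordinates(g)
    img <- outer(exp(-co$rz^2 / (2 * 0.04^2)),
                 exp(-co$rx^2 / (2 * 0.04^2))) * 100
    bg <- estimateCircularBackground(diffractionImage(img, g))
    b2 <- backgroundImage(bg, g)
    rel <- abs(b2 - img) / img
    expect_lt(median(rel[img > 1]), 0.02)
})

test_that("background plus sharp peaks decomposes: near-zero plateaus remain", {
    g <- fixtureGeometry()
    co <- reciprocalCoordinates(g)
    smooth <- outer(exp(-co$rz^2 / (2 * 0.05^2)),
                    exp(-co$rx^2 / (2 * 0.05^2))) * 50
    peaks <- 400 * outer(exp(-co$rz^2 / (2 * 0.003^2)),
                         exp(-(abs(co$rx) - 0.03)^2 / (2 * 0.002^2)))
    di <- diffractionImage(smooth + peaks, g)
    sub <- subtractBackground(di, estimateCircularBackground(di))
    x <- counts(sub)
    plateau <- abs(abs(co$rx) - 0.06) < 0.005
    expect_lt(max(abs(x[, plateau])) / max(peaks), 0.02)
})

test_that("the estimated background stays at or below the diffraction signal", {
    ## on the expected-count image the diffuse estimate must sit under the
    ## pattern almost everywhere; on noisy counts, within counting noise
    ## on pure-diffuse pixels the estimate equals the image, so allow the
    ## interpolation wiggle of the smoothed profile
    f <- fixtureFolded("resting", seed = 1, noise = FALSE)
    bg <- estimateCircularBackground(f)
    b2 <- backgroundImage(bg, geometry(f))
    expect_gt(mean(b2 <= counts(f) * 1.005 + 1e-6), 0.97)
    fn <- fixtureFolded("resting", seed = 1)
    b2n <- backgroundImage(estimateCircularBackground(fn), geometry(fn))
    expect_gt(mean(b2n <= counts(fn) + 2 * sqrt(pmax(b2n, 1))), 0.97)
})

test_that("an all-zero image gives zero diffuse and a normalization error", {
    g <- detectorGeometry(imageShape = c(41L, 41L))
    bg <- estimateCircularBackground(diffractionImage(matrix(0, 41, 41), g))
    expect_equal(totalDiffuse(bg), 0)
    expect_error(normalizeByDiffuse(1, bg), "normalization")
})

test_that("diffuse normalization is exact and scale invariant", {
    bg <- new("BackgroundModel", radius = 1, profile = 1, totalDiffuse = 5,
              flags = character())
    expect_equal(normalizeByDiffuse(10, bg), 2)
    bg2 <- new("BackgroundModel", radius = 1, profile = 3.7,
               totalDiffuse = 5 * 3.7, flags = character())
    expect_equal(normalizeByDiffuse(10 * 3.7, bg2),
                 normalizeByDiffuse(10, bg))
})

test_that("normalized layer-line intensity is exposure independent", {
    m2 <- latticeModel(exposureScale = 2e6)
    i1 <- fixtureRender("resting", seed = 4)
    i2 <- renderPattern(m2, fixtureGeometry(), "resting", seed = 4)
    n1 <- integratedIntensity(
        analyzeLayerLine(i1, background = fixtureBackground("resting", 4)))
    f2 <- quadrantFold(i2)
    n2 <- integratedIntensity(
        analyzeLayerLine(i2, background = estimateCircularBackground(f2)))
    expect_equal(n2 / n1, 1, tolerance = 0.03)
})

test_that("band projection is flat on uniform images and linear", {
    g <- detectorGeometry(imageShape = c(61L, 61L))
    u <- diffractionImage(matrix(1, 61, 61), g)
    k <- reciprocalStep(g)
    t1 <- projectBand(u, "onto_equatorial_direction",
                      c(5.5 * k, 10.5 * k))
    t2 <- projectBand(u, "onto_equatorial_direction",
                      c(5.5 * k, 15.5 * k))
    inner1 <- t1@intensity[5:25]
    expect_lt(diff(range(inner1)), 1e-9)
    expect_equal(mean(t2@intensity[5:25]) / mean(inner1), 2,
                 tolerance = 1e-9)

    a <- matrix(runif(61^2), 61); b <- matrix(runif(61^2), 61)
    pa <- projectBand(diffractionImage(a, g), "onto_meridian",
                      c(0, 8 * k))@intensity
    pb <- projectBand(diffractionImage(b, g), "onto_meridian",
                      c(0, 8 * k))@intensity
    pab <- projectBand(diffractionImage(2 * a + 3 * b, g), "onto_meridian",
                       c(0, 8 * k))@intensity
    expect_equal(pab, 2 * pa + 3 * pb, tolerance = 1e-9)
    expect_error(projectBand(u, "onto_meridian", c(0.5, 0.6)),
                 "outside the detector")
    expect_error(projectBand(u, "onto_meridian", c(0.01, 0.001)),
                 "lo < hi")
})

test_that("the MLL4 band projection peaks at the generator first maximum", {
    nf <- fixtureFolded("resting", seed = 1, noise = FALSE)
    nf <- subtractBackground(nf, estimateCircularBackground(nf))
    tr <- projectBand(nf, "onto_equatorial_direction", c(0.088, 0.097))
    rTrue <- besselFirstMax(4) / (2 * pi * 12.53)
    sub <- tr@coordinate > 0.03
    rHat <- tr@coordinate[sub][which.max(tr@intensity[sub])]
    expect_lt(abs(rHat - rTrue), 1.5 * reciprocalStep(fixtureGeometry()))
})

test_that("axial traces show the myosin layer lines at l/43", {
    tr <- projectBand(fixtureFolded("resting", seed = 1, noise = FALSE),
                      "onto_meridian", c(0.03, 0.077))
    for (l in c(1, 4)) {
        i <- which.min(abs(tr@coordinate - l / 43))
        w <- (i - 4):(i + 4)
        expect_lte(abs(which.max(tr@intensity[w]) - 5), 1)
    }
})
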