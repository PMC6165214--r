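## Shared fixtures: the default study-condition model and detector, plus a
## memo cache so expensive renders are built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixtureGeometry <- function() detectorGeometry()

fixtureModel <- function() {
    if (is.null(.fixtureCache$model))
        .fixtureCache$model <- latticeModel()
    .fixtureCache$model
}

## memoized render keyed by state/seed/noise
fixtureRender <- function(state = "resting", seed = 1, noise = TRUE, ...) {
    key <- paste(state, seed, noise, ..., sep = "_")
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- renderPattern(fixtureModel(),
                                              fixtureGeometry(),
                                              state = state, seed = seed,
                                              noise = noise, ...)
    .fixtureCache[[key]]
}

fixtureFolded <- function(state = "resting", seed = 1, noise = TRUE, ...) {
    key <- paste("fold", state, seed, noise, ..., sep = "_")
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <- quadrantFold(fixtureRender(state, seed,
                                                           noise, ...))
    .fixtureCache[[key]]
}

fixtureBackground <- function(state = "resting", seed = 1, noise = TRUE,
                              ...) {
    key <- paste("bg", state, seed, noise, ..., sep = "_")
    if (is.null(.fixtureCache[[key]]))
        .fixtureCache[[key]] <-
            estimateCircularBackground(fixtureFolded(state, seed, noise,
                                                     ...))
    .fixtureCache[[key]]
}

## independent trapezoid integration (oracle for fitted Gaussian areas)
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
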