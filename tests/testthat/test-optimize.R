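test_that("a monotone objective on a box lands at the upper bound", {
    m <- mmToyModel(vmax = 1, km = 0.5, s0 = 10)
    obj <- objectiveSpec(maximize = "v",
                         decision = data.frame(parameter = "v.vmax",
                                               lower = 0.5, upper = 2))
    res <- optimizeFlux(m, obj, seed = 1,
                        settings = simulationSettings(tEnd = 1, interval = 0.5),
                        nStarts = 2, maxit = 60)
    expect_equal(unname(res@par), 2, tolerance = 1e-3)
    expect_gte(res@value, res@fluxes["initial", "v"])
})

test_that("an empty decision set returns the initial fluxes unchanged", {
    m <- mmToyModel()
    obj <- objectiveSpec(maximize = "v")
    res <- optimizeFlux(m, obj, seed = 1,
                        settings = simulationSettings(tEnd = 1, interval = 0.5))
    expect_identical(res@fluxes["initial", ], res@fluxes["optimized", ])
})

test_that("optimization is deterministic under a fixed seed and never degrades", {
    m <- mmToyModel(vmax = 1, km = 0.5, s0 = 10)
    obj <- objectiveSpec(maximize = "v",
                         decision = data.frame(parameter = c("v.vmax", "v.km.S"),
                                               lower = c(0.5, 0.1),
                                               upper = c(2, 1)))
    run <- function() optimizeFlux(m, obj, seed = 7,
        settings = simulationSettings(tEnd = 1, interval = 0.5),
        nStarts = 2, maxit = 40)
    r1 <- run(); r2 <- run()
    expect_identical(r1@par, r2@par)
    expect_identical(r1@value, r2@value)
    expect_true(all(diff(r1@trace$incumbent) >= 0))  # incumbent never degrades
})

test_that("objectives referencing unknown reactions are rejected", {
    m <- mmToyModel()
    expect_error(optimizeFlux(m, objectiveSpec(maximize = "nope"), seed = 1),
                 "unknown reactions")
    expect_error(objectiveSpec(maximize = "v", minimize = "v"), "disjoint")
})

test_that("a self-fit at the true parameters has near-zero residuals", {
    m <- mmToyModel(vmax = 1, km = 0.5, s0 = 10)
    obs <- generateObservations(m, simulationSettings(tEnd = 20, interval = 2),
                                noiseCV = 0, seed = 1, species = "S")
    free <- data.frame(parameter = c("v.vmax", "v.km.S"),
                       lower = c(0.1, 0.05), upper = c(10, 5))
    fit <- fitParameters(m, obs, free, seed = 1)
    expect_lt(fit@rss, 1e-12)
    expect_equal(unname(fit@par), c(1, 0.5), tolerance = 1e-6)
})

test_that("noiseless recovery from a perturbed start is sharp", {
    truth <- mmToyModel(vmax = 1, km = 0.5, s0 = 10)
    obs <- generateObservations(truth,
        simulationSettings(tEnd = 25, interval = 0.5),   # 50 points
        noiseCV = 0, seed = 1, species = "S")
    start <- setModelParameters(truth, c(v.vmax = 2.4, v.km.S = 1.7))
    free <- data.frame(parameter = c("v.vmax", "v.km.S"),
                       lower = c(0.1, 0.05), upper = c(10, 5))
    fit <- fitParameters(start, obs, free, seed = 1, nStarts = 12)
    expect_lt(abs(fit@par[["v.vmax"]] - 1), 1e-3)
    expect_lt(abs(fit@par[["v.km.S"]] - 0.5) / 0.5, 1e-3)
    expect_true(fit@converged)
})

test_that("fitting validates its inputs", {
    m <- mmToyModel()
    obs <- data.frame(time = 1, species = "ghost", value = 1)
    free <- data.frame(parameter = "v.vmax", lower = 0.1, upper = 10)
    expect_error(fitParameters(m, obs, free), "not in model")
    expect_error(fitParameters(m, data.frame(time = 1, species = "S", value = 1),
                               data.frame(parameter = "zz.vmax", lower = 1,
                                          upper = 2)), "unknown free")
})
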