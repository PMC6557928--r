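test_that("parameter-table generation is deterministic and in range", {
    skel <- readKineticModel(srcmModelPath())
    t1 <- generateParameterTable(skel, seed = 7)
    t2 <- generateParameterTable(skel, seed = 7)
    expect_identical(t1@table, t2@table)
    expect_false(identical(t1@table,
                           generateParameterTable(skel, seed = 8)@table))

    ranges <- list(km = c(0.01, 10), vmax = c(0.1, 10), k = c(0.01, 10),
                   initial = c(0.05, 5))
    for (seed in 1:100) {
        tab <- generateParameterTable(skel, seed = seed, ranges = ranges)@table
        kin <- tab[tab$component == "kinetics", ]
        for (p in c("km", "vmax", "k")) {
            v <- kin$value[kin$parameter == p]
            expect_true(all(v >= ranges[[p]][1] & v <= ranges[[p]][2]))
        }
    }
    expect_error(generateParameterTable(skel, ranges = list(km = c(10, 1),
        vmax = c(0.1, 10), k = c(0.01, 10), initial = c(0.05, 5))),
        "configuration error")
})

test_that("generated tables cover the shipped network completely", {
    skel <- readKineticModel(srcmModelPath())
    tab <- generateParameterTable(skel, seed = 3)
    model <- buildSRCMModel(params = tab)
    expect_identical(nrow(validateModel(model)), 0L)
})

test_that("random parameterizations keep batch simulations well-behaved", {
    # fixed seed panel: every generated parameterization must integrate to
    # the batch horizon with finite, non-negative concentrations
    skel <- readKineticModel(srcmModelPath())
    for (seed in 1:6) {
        m <- buildSRCMModel(generateParameterTable(skel, seed = seed))
        tr <- suppressWarnings(
            simulateDeterministic(m, simulationSettings(tEnd = 100,
                                                        interval = 10)))
        expect_true(all(is.finite(concMatrix(tr))))
        expect_true(all(concMatrix(tr) >= 0))
    }
})

test_that("observation noise is reproducible and mean-preserving", {
    m <- mmToyModel()
    st <- simulationSettings(tEnd = 10)
    clean <- generateObservations(m, st, noiseCV = 0, seed = 1, species = "S")
    tr <- simulateDeterministic(m, st)
    expect_equal(clean@data$value, unname(concMatrix(tr)[, "S"]))

    o1 <- generateObservations(m, st, noiseCV = 0.05, seed = 4, species = "S")
    o2 <- generateObservations(m, st, noiseCV = 0.05, seed = 4, species = "S")
    expect_identical(o1@data, o2@data)
    expect_true(all(o1@data$value >= 0))
})

test_that("the empirical noise CV matches the requested CV", {
    m <- decayModel(k = 0, x0 = 2)   # constant truth = 2
    obs <- generateObservations(m, simulationSettings(tEnd = 999, interval = 1),
                                noiseCV = 0.05, seed = 2, species = "x")
    v <- obs@data$value   # 1000 points of constant truth = 2
    expect_identical(length(v), 1000L)
    cv <- sd(v) / mean(v)
    expect_gt(cv, 0.04); expect_lt(cv, 0.06)
    expect_equal(mean(v), 2, tolerance = 0.01)
})

test_that("full pipeline closure: generated data allow parameter recovery", {
    # generate -> build -> simulate -> observe -> fit on an identifiable
    # subset (the two amino-acid uptake constants, read off the feed decays)
    model <- buildSRCMModel()
    obs <- generateObservations(model, simulationSettings(tEnd = 60, interval = 5),
                                noiseCV = 0.02, seed = 11,
                                species = c("m_gly", "m_ala", "m_ac"))
    truth <- modelParameters(model)[c("T1.k", "T2.k")]
    start <- setModelParameters(model, truth * 3)
    free <- data.frame(parameter = names(truth),
                       lower = unname(truth) / 10, upper = unname(truth) * 10)
    fit <- fitParameters(start, obs, free, seed = 1)
    relErr <- abs(fit@par - truth) / truth
    expect_lt(max(relErr), 0.05)
})
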