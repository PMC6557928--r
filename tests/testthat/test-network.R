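test_that("stoichiometric matrix follows declaration order and signs", {
    m <- chainModel()
    S <- stoichiometricMatrix(m)
    expect_identical(dimnames(S), list(c("A", "B", "C"), c("r1", "r2")))
    expect_equal(unname(S), rbind(c(-1, 0), c(1, -1), c(0, 1)))
})

test_that("reversibility changes flux sign convention, not the column", {
    m <- kineticModel("rev", "CELL",
        data.frame(id = c("A", "B"), compartment = "CELL", initial = c(1, 0)),
        list(reaction("r", c(A = -1, B = 1),
                      gmaLaw(k = 1, exponents = c(A = 1), kr = 0.5,
                             rexponents = c(B = 1)), reversible = TRUE)))
    expect_equal(unname(stoichiometricMatrix(m)), cbind(c(-1, 1)))
    # net flux goes negative when the product dominates
    expect_lt(evaluateFluxes(m, c(A = 0.1, B = 3))[["r"]], 0)
})

test_that("boundary species are excluded from the mass balance rows", {
    m <- inflowSinkModel(0.5, mmLaw(vmax = 1, km = c(x = 2)))
    S <- stoichiometricMatrix(m)
    expect_identical(rownames(S), "x")
    expect_equal(odeRHS(m, initialState(m))[["src"]], 0)
})

test_that("flux evaluation dispatches by rate-law kind", {
    m <- chainModel(k1 = 1, k2 = 2)
    expect_equal(unname(evaluateFluxes(m, c(A = 1, B = 1, C = 0))), c(1, 2))
    expect_equal(unname(evaluateFluxes(m, c(A = 0, B = 0, C = 0))), c(0, 0))
    mm <- mmToyModel(vmax = 3, km = 0.4, s0 = 0.4)
    expect_equal(evaluateFluxes(mm, initialState(mm))[["v"]], 1.5)  # Vmax/2 at S=Km
})

test_that("mass-balance RHS equals the explicit matrix product S v", {
    m <- chainModel(k1 = 1, k2 = 2)
    expect_equal(unname(odeRHS(m, c(A = 1, B = 1, C = 0))), c(-1, -1, 2))
    for (seed in 1:10) {
        rn <- randomNetwork(seed)
        st <- initialState(rn)
        oracle <- as.numeric(stoichiometricMatrix(rn) %*% evaluateFluxes(rn, st))
        expect_equal(unname(odeRHS(rn, st)), oracle, tolerance = 1e-12)
    }
})

test_that("closed interconversion networks conserve total mass (1'S = 0)", {
    m <- kineticModel("cycle", "CELL",
        data.frame(id = c("A", "B", "C"), compartment = "CELL", initial = c(1, 1, 1)),
        list(reaction("ab", c(A = -1, B = 1), gmaLaw(k = 1, exponents = c(A = 1))),
             reaction("bc", c(B = -1, C = 1), gmaLaw(k = 1, exponents = c(B = 1))),
             reaction("ca", c(C = -1, A = 1), gmaLaw(k = 1, exponents = c(C = 1)))))
    expect_equal(unname(colSums(stoichiometricMatrix(m))), c(0, 0, 0))
})

test_that("validation reports collect all violations without stopping", {
    good <- buildSRCMModel()
    expect_identical(nrow(validateModel(good)), 0L)

    dangling <- kineticModel("bad", "CELL",
        data.frame(id = "A", compartment = "CELL", initial = 1),
        list(reaction("r", c(A = -1, ghost = 1), gmaLaw(k = 1, exponents = c(A = 1)))))
    rep <- validateModel(dangling)
    expect_identical(nrow(rep), 1L)
    expect_match(rep$message, "unknown species")

    badkm <- mmToyModel()
    badkm@reactions[[1]]@rateLaw@km[["S"]] <- 0
    rep2 <- validateModel(badkm)
    expect_identical(rep2$kind, "parameter")
})

test_that("unassigned parameters are a configuration error at evaluation", {
    m <- readKineticModel(srcmModelPath())   # values still NA
    expect_gt(sum(validateModel(m)$kind == "parameter"), 0)
    expect_error(evaluateFluxes(m, initialState(m)), "configuration error")
})

test_that("parameter ids round-trip through get/set", {
    m <- mmToyModel(vmax = 1, km = 0.5)
    theta <- modelParameters(m)
    expect_equal(theta[["v.vmax"]], 1)
    expect_equal(theta[["v.km.S"]], 0.5)
    expect_equal(theta[["init.S"]], 10)
    m2 <- setModelParameters(m, c(v.vmax = 2.5, init.S = 4))
    expect_equal(modelParameters(m2)[["v.vmax"]], 2.5)
    expect_equal(initialState(m2)[["S"]], 4)
    expect_error(setModelParameters(m, c(nope.vmax = 1)), "unknown reaction")
})
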