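test_that("steady states of inflow/sink toys match their closed forms", {
    # mass-action sink: x* = v0 / k
    ss <- findSteadyState(inflowSinkModel(1, gmaLaw(k = 2, exponents = c(x = 1))))
    expect_equal(ss@state[["x"]], 0.5, tolerance = 1e-8)
    expect_lt(ss@residualNorm, 1e-9)
    # MM sink: x* = Km v0 / (Vmax - v0)
    ss2 <- findSteadyState(inflowSinkModel(0.5, mmLaw(vmax = 1, km = c(x = 2))))
    expect_equal(ss2@state[["x"]], 2.0, tolerance = 1e-7)
    expect_true(isStable(ss2))
})

test_that("no steady state exists when inflow exceeds the sink capacity", {
    m <- inflowSinkModel(1.2, mmLaw(vmax = 1, km = c(x = 2)))
    expect_error(findSteadyState(m), "convergence error")
})

test_that("Jacobian eigenvalues recover analytic linear dynamics", {
    m <- decayModel(k = 0.3)
    eig <- jacobianEigenvalues(m, c(x = 1))
    expect_equal(Re(eig$values), -0.3, tolerance = 1e-6)
    expect_true(eig$stable)

    # linear cascade dA/dt = -k1 A, dB/dt = k1 A - k2 B: eigenvalues -k1, -k2
    m2 <- chainModel(k1 = 0.7, k2 = 1.3)
    eig2 <- jacobianEigenvalues(m2, c(A = 1, B = 1, C = 0))
    expect_equal(sort(Re(eig2$values)), c(-1.3, -0.7, 0), tolerance = 1e-6)

    ss <- findSteadyState(inflowSinkModel(1, gmaLaw(k = 2, exponents = c(x = 1))))
    expect_equal(Re(ss@eigenvalues), -2, tolerance = 1e-6)
    expect_true(ss@stable)
})

test_that("stability verdict agrees with perturbed long-time behavior", {
    m <- inflowSinkModel(1, gmaLaw(k = 2, exponents = c(x = 1)))
    ss <- findSteadyState(m)
    expect_true(isStable(ss))
    pert <- m
    pert@species$initial[pert@species$id == "x"] <- ss@state[["x"]] * 1.5
    tr <- simulateDeterministic(pert, simulationSettings(tEnd = 20))
    expect_equal(unname(concMatrix(tr)[21, "x"]), ss@state[["x"]], tolerance = 1e-5)
})

test_that("analytic elasticities match their closed forms", {
    m <- mmToyModel(vmax = 1, km = 0.5, s0 = 0.5)
    E <- elasticities(elasticityMatrix(m, c(S = 0.5, P = 0)))
    expect_equal(E["v", "S"], 0.5)           # Km/(Km+S) at S=Km
    expect_equal(E["v", "P"], 0)             # absent from the law

    g <- kineticModel("gma", "CELL",
        data.frame(id = "x", compartment = "CELL", initial = 2),
        list(reaction("r", c(x = -1), gmaLaw(k = 1, exponents = c(x = 0.37)))))
    E2 <- elasticities(elasticityMatrix(g, c(x = 2)))
    expect_equal(E2["r", "x"], 0.37)         # kinetic order, state-free
    E3 <- elasticities(elasticityMatrix(g, c(x = 5)))
    expect_equal(E3["r", "x"], 0.37)
})

test_that("zero flux makes the scaled elasticity undefined, not zero", {
    m <- mmToyModel(vmax = 1, km = 0.5, s0 = 0)
    E <- elasticities(elasticityMatrix(m, c(S = 0, P = 0)))
    expect_true(is.na(E["v", "S"]) || E["v", "S"] == 1)  # S=0: sat term -> 1
    rev <- fccToyModel(k1 = 1, kr = 1, k2 = 1)
    # state where the net reversible flux is exactly zero
    E2 <- elasticities(elasticityMatrix(rev, c(A = 1, X = 1)))
    expect_true(is.na(E2["e1", "A"]))
})

test_that("analytic elasticities agree with finite differences on random nets", {
    for (seed in 1:8) {
        rn <- randomNetwork(seed)
        st <- initialState(rn)
        E <- elasticities(elasticityMatrix(rn, st))
        v0 <- evaluateFluxes(rn, st)
        for (j in seq_along(v0)) {
            for (sp in names(st)) {
                if (v0[[j]] == 0) next
                h <- 1e-6 * st[[sp]]
                up <- st; up[sp] <- st[[sp]] + h
                dn <- st; dn[sp] <- st[[sp]] - h
                fd <- (evaluateFluxes(rn, up)[[j]] - evaluateFluxes(rn, dn)[[j]]) /
                    (2 * h) * st[[sp]] / v0[[j]]
                expect_equal(E[j, sp], fd, tolerance = 1e-6)
            }
        }
    }
})

test_that("flux control coefficients match the two-step closed form", {
    m <- fccToyModel(k1 = 2, kr = 1, k2 = 3)
    ss <- findSteadyState(m)
    ca <- fluxControlCoefficients(m, ss, targets = "e2")
    C <- fluxControl(ca)
    expect_equal(C[1, "e1"], 0.75, tolerance = 1e-3)   # k2/(kr+k2)
    expect_equal(C[1, "e2"], 0.25, tolerance = 1e-3)   # kr/(kr+k2)
    expect_equal(sum(C), 1, tolerance = 1e-3)          # summation theorem
    expect_false(any(ca@fccFlagged))
})

test_that("an irreversible supply-limited pathway gives C = (1, 0)", {
    m <- kineticModel("irr", "CELL",
        data.frame(id = c("A", "X"), compartment = "CELL",
                   initial = c(1, 0.1), boundary = c(TRUE, FALSE)),
        list(reaction("e1", c(A = -1, X = 1), gmaLaw(k = 1, exponents = c(A = 1))),
             reaction("e2", c(X = -1), gmaLaw(k = 2, exponents = c(X = 1)))))
    C <- fluxControl(fluxControlCoefficients(m, findSteadyState(m), targets = "e2"))
    expect_equal(C[1, "e1"], 1, tolerance = 1e-3)
    expect_equal(C[1, "e2"], 0, tolerance = 1e-3)
})

test_that("connectivity theorem holds on the two-step toy", {
    m <- fccToyModel(k1 = 2, kr = 1, k2 = 3)
    ss <- findSteadyState(m)
    C <- fluxControl(fluxControlCoefficients(m, ss, targets = "e2"))
    E <- elasticities(elasticityMatrix(m, ss@state))
    # sum_j C_j eps_{j,X} = 0 for the internal species X
    conn <- C[1, "e1"] * E["e1", "X"] + C[1, "e2"] * E["e2", "X"]
    expect_equal(conn, 0, tolerance = 1e-3)
})

test_that("local sensitivity reproduces the analytic decay derivative", {
    m <- decayModel(k = 0.1, x0 = 1)
    sens <- localSensitivity(m, simulationSettings(tEnd = 10), "deg.k")
    t <- sens$time
    analytic <- -t * exp(-0.1 * t)          # d/dk of exp(-k t)
    expect_equal(unname(sens$sensitivity[, "x"]), analytic, tolerance = 1e-4)
    expect_gt(sens$auc[["x"]], 0)
})

test_that("parameters outside every rate law have zero sensitivity", {
    m <- inflowSinkModel(1, gmaLaw(k = 2, exponents = c(x = 1)))
    # the clamped source concentration enters no rate law (zero-order inflow)
    sens <- localSensitivity(m, simulationSettings(tEnd = 5), "init.src")
    expect_equal(max(abs(sens$sensitivity)), 0)
})

test_that("central differences converge at second order (Richardson)", {
    m <- decayModel(k = 0.5, x0 = 1)
    exact <- function(t) -t * exp(-0.5 * t)
    err <- vapply(c(0.02, 0.01), function(h) {
        s <- localSensitivity(m, simulationSettings(tEnd = 6), "deg.k",
                              perturbation = h)
        max(abs(s$sensitivity[, "x"] - exact(s$time)))
    }, numeric(1))
    # halving the step should cut the error by about 4; allow slack
    expect_gt(err[1] / err[2], 3)
})
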