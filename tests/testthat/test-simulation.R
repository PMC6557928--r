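test_that("deterministic decay matches the exponential closed form", {
    tr <- simulateDeterministic(decayModel(k = 0.1, x0 = 1),
                                simulationSettings(tEnd = 10))
    expect_equal(unname(concMatrix(tr)[11, "x"]), exp(-1), tolerance = 1e-7)
    expect_equal(timeGrid(tr), 0:10)
})

test_that("closed interconversion conserves total concentration", {
    m <- kineticModel("ab", "CELL",
        data.frame(id = c("A", "B"), compartment = "CELL", initial = c(2, 1)),
        list(reaction("f", c(A = -1, B = 1), gmaLaw(k = 0.7, exponents = c(A = 1))),
             reaction("b", c(B = -1, A = 1), gmaLaw(k = 0.3, exponents = c(B = 1)))))
    tr <- simulateDeterministic(m, simulationSettings(tEnd = 20))
    tot <- rowSums(concMatrix(tr))
    expect_true(all(abs(tot - 3) < 1e-9))
})

test_that("MM consumption matches a high-accuracy reference integration", {
    m <- mmToyModel(vmax = 1, km = 1, s0 = 10)
    tr <- simulateDeterministic(m, simulationSettings(tEnd = 10))
    # independent fine-step reference: classical RK4 at dt = 1e-4
    ref <- local({
        s <- 10; dt <- 1e-4
        out <- numeric(11); out[1] <- s
        f <- function(s) -s / (1 + s)
        for (i in 1:10) {
            for (j in seq_len(1 / dt)) {
                k1 <- f(s); k2 <- f(s + dt / 2 * k1)
                k3 <- f(s + dt / 2 * k2); k4 <- f(s + dt * k3)
                s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
            }
            out[i + 1] <- s
        }
        out
    })
    expect_equal(unname(concMatrix(tr)[, "S"]), ref, tolerance = 1e-6)
})

test_that("trajectories are invariant under tolerance halving", {
    m <- srcmChemostat()
    base <- simulationSettings(tEnd = 30, interval = 5)
    tight <- simulationSettings(tEnd = 30, interval = 5, rtol = 5e-9, atol = 5e-13)
    d <- abs(concMatrix(simulateDeterministic(m, base)) -
             concMatrix(simulateDeterministic(m, tight)))
    expect_lt(max(d), 1e-6)
})

test_that("flux rows equal the rate laws evaluated at the stored states", {
    m <- buildSRCMModel()
    tr <- simulateDeterministic(m, simulationSettings(tEnd = 10, interval = 2))
    for (i in c(1, 3, 6)) {
        expect_equal(unname(fluxMatrix(tr)[i, ]),
                     unname(evaluateFluxes(m, concMatrix(tr)[i, ])),
                     tolerance = 1e-12)
    }
    expect_true(all(concMatrix(tr) >= 0))
})

test_that("integrator failure reports the last valid time", {
    # blow-up: autocatalytic second order growth overflows before tEnd
    m <- kineticModel("blow", "CELL",
        data.frame(id = "x", compartment = "CELL", initial = 1),
        list(reaction("auto", c(x = 1), gmaLaw(k = 1, exponents = c(x = 2)))))
    expect_error(suppressWarnings(
        simulateDeterministic(m, simulationSettings(tEnd = 10))),
        "simulation error")
})

test_that("zero-propensity stochastic systems stay constant", {
    m <- decayModel(k = 0, x0 = 5)
    tr <- simulateStochastic(m, simulationSettings(tEnd = 5, seed = 1, omega = 10))
    expect_true(all(concMatrix(tr)[, "x"] == 5))
})

test_that("identical seeds give bit-identical stochastic trajectories", {
    m <- chainModel(a0 = 2, b0 = 0, c0 = 0)
    s <- function(seed) simulateStochastic(m,
        simulationSettings(tEnd = 3, seed = seed, omega = 1000))
    expect_identical(concMatrix(s(42)), concMatrix(s(42)))
    expect_false(identical(concMatrix(s(42)), concMatrix(s(43))))
})

test_that("pure-death replicate mean matches the analytic decay mean", {
    m <- decayModel(k = 0.1, x0 = 100)
    set.seed(1)
    finals <- vapply(1:1000, function(r) {
        tr <- simulateStochastic(m, simulationSettings(tEnd = 5, interval = 5,
                                                       seed = 1000 + r, omega = 1))
        concMatrix(tr)[2, "x"]
    }, numeric(1))
    expected <- 100 * exp(-0.5)
    se <- sd(finals) / sqrt(length(finals))
    expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("stochastic simulation rejects unsupported structure", {
    frac <- kineticModel("frac", "CELL",
        data.frame(id = "x", compartment = "CELL", initial = 1),
        list(reaction("r", c(x = -0.5), gmaLaw(k = 1, exponents = c(x = 1)))))
    expect_error(simulateStochastic(frac,
        simulationSettings(tEnd = 1, seed = 1, omega = 10)), "non-integer")
    expect_error(simulateStochastic(decayModel(),
        simulationSettings(tEnd = 1, omega = 10)), "seed")
    expect_error(simulateStochastic(decayModel(),
        simulationSettings(tEnd = 1, seed = 1)), "omega")
})

test_that("large-omega stochastic means converge to the deterministic path", {
    m <- chainModel(k1 = 0.5, k2 = 0.3, a0 = 1, b0 = 0, c0 = 0)
    det <- concMatrix(simulateDeterministic(m, simulationSettings(tEnd = 10)))
    reps <- 40
    acc <- 0
    for (r in seq_len(reps)) {
        tr <- simulateStochastic(m, simulationSettings(tEnd = 10, seed = 500 + r,
                                                       omega = 1e5))
        acc <- acc + concMatrix(tr)
    }
    avg <- acc / reps
    i <- 2:11  # skip t=0 (exact by construction)
    relErr <- abs(avg[i, c("A", "B")] - det[i, c("A", "B")]) /
        pmax(det[i, c("A", "B")], 0.05)
    expect_lt(max(relErr), 0.02)
})

test_that("batch SRCM time course shows the acetate surge and monotone methane", {
    m <- buildSRCMModel()   # batch: finite gelatin-derived feed
    tr <- simulateDeterministic(m, simulationSettings(tEnd = 150))
    ac <- concMatrix(tr)[, "m_ac"]
    ch4 <- concMatrix(tr)[, "m_ch4"]
    peak <- which.max(ac)
    expect_gt(peak, 1)                       # rises first
    expect_lt(peak, length(ac))              # then falls
    expect_lt(ac[length(ac)], max(ac) * 0.9)
    expect_true(all(diff(ch4) > -1e-9))      # methane monotone non-decreasing
})

test_that("tidy trajectory export is long and complete", {
    tr <- simulateDeterministic(chainModel(), simulationSettings(tEnd = 2))
    df <- trajectoryToDataFrame(tr)
    expect_setequal(unique(df$kind), c("concentration", "flux"))
    expect_identical(nrow(df), length(timeGrid(tr)) * 5L)  # 3 species + 2 fluxes
})
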