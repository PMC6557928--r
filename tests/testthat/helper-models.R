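# Toy networks reused across the suite. All built in code; no fixtures.

# first-order decay x -> 0
decayModel <- function(k = 0.1, x0 = 1) {
    kineticModel("decay", "CELL",
        data.frame(id = "x", compartment = "CELL", initial = x0),
        list(reaction("deg", c(x = -1), gmaLaw(k = k, exponents = c(x = 1)))))
}

# irreversible two-step mass-action chain A -> B -> C
chainModel <- function(k1 = 1, k2 = 2, a0 = 1, b0 = 1, c0 = 0) {
    kineticModel("chain", "CELL",
        data.frame(id = c("A", "B", "C"), compartment = "CELL",
                   initial = c(a0, b0, c0)),
        list(reaction("r1", c(A = -1, B = 1), gmaLaw(k = k1, exponents = c(A = 1))),
             reaction("r2", c(B = -1, C = 1), gmaLaw(k = k2, exponents = c(B = 1)))))
}

# constant inflow v0 (zero-order from a clamped source) into a sink
inflowSinkModel <- function(v0, sinkLaw) {
    kineticModel("inflow-sink", "CELL",
        data.frame(id = c("src", "x"), compartment = "CELL",
                   initial = c(1, 0.1), boundary = c(TRUE, FALSE)),
        list(reaction("in", c(src = -1, x = 1), gmaLaw(k = v0)),
             reaction("out", c(x = -1), sinkLaw)))
}

# A (clamped) <-> X -> with mass action; closed-form flux control
# coefficients C1 = k2/(kr + k2), C2 = kr/(kr + k2)
fccToyModel <- function(k1 = 2, kr = 1, k2 = 3) {
    kineticModel("fcc-toy", "CELL",
        data.frame(id = c("A", "X"), compartment = "CELL",
                   initial = c(1, 0.1), boundary = c(TRUE, FALSE)),
        list(reaction("e1", c(A = -1, X = 1),
                      gmaLaw(k = k1, exponents = c(A = 1),
                             kr = kr, rexponents = c(X = 1)),
                      reversible = TRUE),
             reaction("e2", c(X = -1), gmaLaw(k = k2, exponents = c(X = 1)))))
}

# single Michaelis-Menten consumption S -> P, for fitting tests
mmToyModel <- function(vmax = 1, km = 0.5, s0 = 10) {
    kineticModel("mm-toy", "CELL",
        data.frame(id = c("S", "P"), compartment = "CELL", initial = c(s0, 0)),
        list(reaction("v", c(S = -1, P = 1), mmLaw(vmax = vmax, km = c(S = km)))))
}

# random mass-action network for oracle-equivalence property tests
randomNetwork <- function(seed, nSpecies = 4, nReactions = 5) {
    set.seed(seed)
    ids <- paste0("s", seq_len(nSpecies))
    rx <- lapply(seq_len(nReactions), function(j) {
        from <- sample(ids, 1)
        to <- sample(setdiff(ids, from), 1)
        reaction(paste0("r", j), stats::setNames(c(-1, 1), c(from, to)),
                 gmaLaw(k = stats::runif(1, 0.1, 2),
                        exponents = stats::setNames(stats::runif(1, 0.5, 2), from)))
    })
    kineticModel("random", "CELL",
        data.frame(id = ids, compartment = "CELL",
                   initial = stats::runif(nSpecies, 0.1, 2)), rx)
}

srcmChemostat <- function(model = buildSRCMModel()) {
    applyScenario(model, scenarioSpec("PAIR", clampFeeds = TRUE,
                                      clampSinks = TRUE))
}
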