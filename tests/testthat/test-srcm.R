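test_that("shipped model census reproduces the published structure", {
    cen <- modelCensus(buildSRCMModel())
    expect_identical(cen@reactions[["CAC"]], 7L)
    expect_identical(cen@metabolites[["CAC"]], 24L)
    expect_identical(cen@reactions[["MAC"]], 11L)
    expect_identical(cen@metabolites[["MAC"]], 37L)
    expect_identical(cen@transport[["CAC"]], 6L)
    expect_identical(cen@transport[["MAC"]], 6L)
})

test_that("census handles degenerate and toy models", {
    empty <- kineticModel("empty", c("A", "B"),
        data.frame(id = character(), compartment = character(),
                   initial = numeric()), list())
    cen <- modelCensus(empty)
    expect_true(all(cen@reactions == 0L) && all(cen@metabolites == 0L) &&
                all(cen@transport == 0L))
    toy <- modelCensus(chainModel())
    expect_identical(toy@reactions[["CELL"]], 2L)
    expect_identical(toy@metabolites[["CELL"]], 3L)
    expect_identical(toy@transport[["CELL"]], 0L)
})

test_that("every transporter connects exactly two compartments", {
    m <- buildSRCMModel()
    comp <- stats::setNames(modelSpecies(m)$compartment, speciesIds(m))
    for (r in modelReactions(m)) {
        if (is.na(r@transporterClass)) next
        expect_length(unique(comp[names(r@stoichiometry)]), 2L)
    }
})

test_that("missing parameter rows fail loudly with the reaction id", {
    tab <- defaultParameterTable()
    tab@table <- tab@table[!(tab@table$reaction %in% "R13"), ]
    expect_error(buildSRCMModel(tab), "R13")
})

test_that("scenarios clamp and feed the medium amino acids", {
    m <- buildSRCMModel()
    gly <- applyScenario(m, scenarioSpec("GLYCINE"))
    sp <- modelSpecies(gly)
    expect_equal(sp$initial[sp$id == "m_ala"], 0)
    expect_true(sp$boundary[sp$id == "m_ala"])   # excluded substrate clamped at 0
    expect_gt(sp$initial[sp$id == "m_gly"], 0)

    pair <- applyScenario(m, scenarioSpec("PAIR"))
    sp <- modelSpecies(pair)
    expect_equal(sp$initial[sp$id == "m_gly"], 21.4)
    expect_equal(sp$initial[sp$id == "m_ala"], 8.9)

    again <- applyScenario(pair, scenarioSpec("PAIR"))
    expect_identical(modelSpecies(again), modelSpecies(pair))  # idempotent

    expect_error(applyScenario(m, new("ScenarioSpec", mode = "PAIR",
                                      feed = c(glycine = 1, alanine = 1,
                                               leucine = 2),
                                      clampFeeds = FALSE, clampSinks = FALSE)),
                 "unknown substrate")
})

test_that("no methane is generated without amino-acid feed or internal pools", {
    m <- buildSRCMModel()
    sp <- modelSpecies(m)
    zero <- !sp$boundary | sp$id %in% c("m_h2")
    sp$initial[!sp$boundary] <- 0    # no feed, all internal pools empty
    sp$initial[sp$id == "m_h2"] <- 0 # no external electron donor either
    m@species <- sp
    tr <- simulateDeterministic(m, simulationSettings(tEnd = 20))
    expect_equal(max(abs(fluxMatrix(tr)[, "R13"])), 0)
    expect_equal(max(concMatrix(tr)[, "m_ch4"]), 0)
})

test_that("gelatin hydrolysate feed splits by the printed composition", {
    feed <- gelatinFeed(100)
    expect_equal(feed[["glycine"]], 21.4)
    expect_equal(feed[["proline"]], 12.4)
    expect_equal(feed[["alanine"]], 8.9)
    expect_true(all(gelatinFeed(0) == 0))
    ov <- gelatinFeed(5, composition = c(glycine = 1.0))
    expect_equal(unname(ov), 5)
    expect_error(gelatinFeed(10, composition = c(glycine = 0.8, alanine = 0.4)),
                 "sum")
    expect_error(gelatinFeed(-1), ">= 0")
})

test_that("net Stickland hydrogen coefficient is oxidation minus reduction", {
    expect_equal(sticklandHydrogenBalance(), 0.134)
    expect_equal(sticklandHydrogenBalance(0.2, 0.05), 0.15)
})
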