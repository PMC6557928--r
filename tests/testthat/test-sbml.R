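test_that("SBML round trip preserves census and rate evaluations", {
    m <- buildSRCMModel()
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(m, f)
    m2 <- importSBML(f)
    cen <- modelCensus(m2)
    expect_identical(unname(cen@reactions[c("CAC", "MAC")]), c(7L, 11L))
    expect_identical(unname(cen@metabolites[c("CAC", "MAC")]), c(24L, 37L))
    expect_identical(unname(cen@transport[c("CAC", "MAC")]), c(6L, 6L))
    set.seed(31)
    for (i in 1:10) {
        st <- initialState(m)
        st[] <- runif(length(st), 0, 3)
        expect_equal(evaluateFluxes(m2, st), evaluateFluxes(m, st),
                     tolerance = 1e-9)
    }
})

test_that("boundary species carry boundaryCondition=true", {
    m <- buildSRCMModel()
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(m, f)
    doc <- xml2::read_xml(f); xml2::xml_ns_strip(doc)
    node <- xml2::xml_find_first(doc, ".//species[@id='m_h2']")
    expect_identical(xml2::xml_attr(node, "boundaryCondition"), "true")
    node2 <- xml2::xml_find_first(doc, ".//species[@id='m_ac']")
    expect_identical(xml2::xml_attr(node2, "boundaryCondition"), "false")
})

test_that("imported MathML kinetic laws evaluate like the closed-form rates", {
    toy <- mmToyModel(vmax = 2, km = 0.5)
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(toy, f)
    back <- importSBML(f)
    expect_equal(evaluateFluxes(back, c(S = 0.5, P = 0))[["v"]],
                 mmRate(2, 0.5, 0.5))
    law <- modelReactions(back)[["v"]]@rateLaw
    expect_s4_class(law, "MichaelisMentenLaw")
    expect_equal(law@vmax, 2); expect_equal(law@km[["S"]], 0.5)
})

test_that("reactions without kinetic laws are an unsupported construct", {
    toy <- mmToyModel()
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(toy, f)
    txt <- readLines(f)
    txt <- txt[!grepl("kineticLaw|math|localParameter", txt)]
    f2 <- withr::local_tempfile(fileext = ".xml")
    writeLines(txt, f2)
    expect_error(importSBML(f2), "unsupported-construct")
})

test_that("unrecognized MathML shapes are rejected with the reaction id", {
    toy <- mmToyModel()
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(toy, f)
    txt <- readLines(f)
    i <- grep("<math", txt)
    txt[i] <- sub("<apply><times/>", "<apply><plus/>", txt[i])
    f2 <- withr::local_tempfile(fileext = ".xml")
    writeLines(txt, f2)
    expect_error(importSBML(f2), "unsupported-construct.*v")
})

test_that("negative initial concentrations fail validation on import", {
    toy <- mmToyModel()
    f <- withr::local_tempfile(fileext = ".xml")
    exportSBML(toy, f)
    txt <- sub('initialConcentration="10"', 'initialConcentration="-1"',
               readLines(f))
    f2 <- withr::local_tempfile(fileext = ".xml")
    writeLines(txt, f2)
    expect_error(importSBML(f2), "initial")
})

test_that("malformed XML is a parse error", {
    f <- withr::local_tempfile(fileext = ".xml")
    writeLines("<sbml><model>", f)
    expect_error(importSBML(f))
})
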