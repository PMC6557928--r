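#' Path to the packaged SRCM network definition
#'
#' The shipped three-compartment network (acidogen cytoplasm `CAC`, shared
#' `MEDIUM`, methanogen cytoplasm `MAC`): amino-acid catabolism through the
#' Stickland pair glycine/alanine to acetate in the acidogen, membrane
#' transport of the shared metabolites, and aceticlastic methanogenesis in
#' the methanogen. Rate-law parameter values are not part of the network
#' file; they are supplied from a [ParameterTable] by [buildSRCMModel()].
#'
#' @return file path of the YAML network definition.
#' @export
srcmModelPath <- function() {
    system.file("extdata", "srcm_model.yaml", package = "SRCMkinetics",
                mustWork = TRUE)
}

#' The shipped synthetic kinetic-parameter table
#'
#' A complete, clearly synthetic assignment of Michaelis-Menten constants,
#' transport rate constants and initial concentrations for the shipped SRCM
#' network, chosen to give physiologically plausible pool sizes (mmol/ml) and
#' fluxes (mmol/min/ml) in batch culture. It stands in for an experimentally
#' derived parameter set, which does not exist for this co-culture.
#'
#' @return a [ParameterTable].
#' @export
defaultParameterTable <- function() {
    readParameterTable(system.file("extdata", "srcm_parameters.tsv",
                                   package = "SRCMkinetics", mustWork = TRUE))
}

#' Apply a parameter table to a model
#'
#' Fills unassigned (or overrides assigned) rate-law values and initial
#' concentrations from the long-format table. Rows whose reaction or species
#' id does not exist in the model raise a configuration error.
#'
#' @param model a [KineticModel].
#' @param params a [ParameterTable].
#' @return the updated model.
#' @export
applyParameterTable <- function(model, params) {
    stopifnot(is(model, "KineticModel"), is(params, "ParameterTable"))
    tab <- params@table
    vals <- numeric(0)
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        id <- if (row$component == "initial") {
            paste0("init.", row$species)
        } else switch(row$parameter,
            vmax = paste0(row$reaction, ".vmax"),
            km = paste0(row$reaction, ".km.", row$species),
            k = paste0(row$reaction, ".k"),
            exponent = paste0(row$reaction, ".exp.", row$species),
            stop("configuration error: unknown parameter kind '",
                 row$parameter, "'"))
        vals[id] <- row$value
    }
    setModelParameters(model, vals)
}

#' Assemble the SRCM kinetic model
#'
#' Reads the packaged network definition, merges in the kinetic parameters
#' and initial concentrations, and validates the result. The parameter table
#' must cover every reaction of the network (Vmax and Km per driving
#' substrate for the Michaelis-Menten intracellular reactions, a rate
#' constant for each generalized-mass-action transport reaction); missing
#' coverage raises a configuration error naming the uncovered reaction ids.
#'
#' @param params a [ParameterTable]; defaults to the shipped synthetic table.
#' @param file optional alternative network definition.
#' @return a validated [KineticModel].
#' @examples
#' model <- buildSRCMModel()
#' modelCensus(model)
#' @export
buildSRCMModel <- function(params = defaultParameterTable(), file = srcmModelPath()) {
    model <- readKineticModel(file)
    model <- applyParameterTable(model, params)
    rep <- validateModel(model)
    missing <- rep$where[rep$kind == "parameter"]
    if (length(missing))
        stop("configuration error: parameter table does not cover reactions: ",
             paste(unique(missing), collapse = ", "))
    if (nrow(rep))
        stop("model validation failed:\n",
             paste(sprintf("  [%s] %s: %s", rep$kind, rep$where, rep$message),
                   collapse = "\n"))
    model
}

#' Model census
#'
#' Per-compartment counts: intracellular reactions are attributed to the
#' compartment their participants live in; metabolites (including enzyme
#' species held at constant concentration) are counted by owning compartment;
#' transport reactions are counted per membrane, i.e. attributed to both
#' compartments they connect.
#'
#' @param object a [KineticModel].
#' @return a [ModelCensus].
#' @export
setMethod("modelCensus", "KineticModel", function(object) {
    cps <- object@compartments$id
    comp <- stats::setNames(object@species$compartment, object@species$id)
    z <- stats::setNames(integer(length(cps)), cps)
    reactions <- z; transport <- z
    metabolites <- z
    tb <- table(object@species$compartment)
    metabolites[names(tb)] <- as.integer(tb)
    for (r in object@reactions) {
        touched <- unique(comp[names(r@stoichiometry)])
        touched <- touched[!is.na(touched)]
        if (!is.na(r@transporterClass)) {
            transport[touched] <- transport[touched] + 1L
        } else if (length(touched) >= 1L) {
            reactions[touched[1]] <- reactions[touched[1]] + 1L
        }
    }
    new("ModelCensus", reactions = reactions, metabolites = metabolites,
        transport = transport)
})

setMethod("show", "ModelCensus", function(object) {
    cat("ModelCensus\n")
    for (cp in names(object@reactions))
        cat(sprintf("  %s: %d intracellular reactions, %d metabolites, %d transport reactions\n",
                    cp, object@reactions[[cp]], object@metabolites[[cp]],
                    object@transport[[cp]]))
    invisible(object)
})

## medium feed species ids of the shipped network
.feedSpecies <- c(glycine = "m_gly", alanine = "m_ala", proline = "m_pro")

#' Substrate-constraint scenarios
#'
#' Constructs a [ScenarioSpec]. In `GLYCINE` (resp. `ALANINE`) mode the other
#' amino acid's feed is clamped to zero; `PAIR` supplies both. Default feed
#' concentrations come from [gelatinFeed()] with 100 mmol of amino-acid
#' units, i.e. glycine 21.4, proline 12.4, alanine 8.9 mmol.
#'
#' @param mode `"GLYCINE"`, `"ALANINE"` or `"PAIR"`.
#' @param feed named numeric (names among `glycine`, `alanine`, `proline`),
#'   mmol/ml; defaults to the gelatin-hydrolysate composition restricted to
#'   the mode's substrates.
#' @param clampFeeds clamp amino-acid feeds at their set values (chemostat
#'   supply) instead of letting a finite batch feed deplete.
#' @param clampSinks clamp terminal product accumulation pools (species
#'   flagged `sink`), required for steady-state analysis.
#' @return a [ScenarioSpec].
#' @export
scenarioSpec <- function(mode = c("PAIR", "GLYCINE", "ALANINE"), feed = NULL,
                         clampFeeds = FALSE, clampSinks = FALSE) {
    mode <- match.arg(mode)
    if (is.null(feed)) {
        full <- gelatinFeed(100)
        feed <- switch(mode,
            PAIR = full[c("glycine", "alanine", "proline")],
            GLYCINE = c(glycine = unname(full["glycine"]), alanine = 0),
            ALANINE = c(alanine = unname(full["alanine"]), glycine = 0))
    }
    new("ScenarioSpec", mode = mode, feed = feed, clampFeeds = clampFeeds,
        clampSinks = clampSinks)
}

#' Apply a scenario to a model
#'
#' Returns a copy of the model with the medium amino-acid feeds set per the
#' scenario. Feeds named in the scenario but absent from the model raise a
#' configuration error. In single-substrate modes the excluded amino acid is
#' clamped at zero. With `clampFeeds` the feed species become boundary
#' (constant supply); with `clampSinks` the terminal accumulation pools are
#' clamped as well, which removes the zero eigenvalues those pools would
#' otherwise contribute and makes a steady state well-defined. Applying the
#' same scenario twice is idempotent.
#'
#' @param object a [KineticModel].
#' @param scenario a [ScenarioSpec].
#' @return the modified copy.
#' @export
setMethod("applyScenario", "KineticModel", function(object, scenario) {
    stopifnot(is(scenario, "ScenarioSpec"))
    validObject(scenario)
    feed <- scenario@feed
    unknownName <- setdiff(names(feed), names(.feedSpecies))
    if (length(unknownName))
        stop("configuration error: unknown substrate id(s): ",
             paste(unknownName, collapse = ", "))
    sp <- object@species
    excluded <- switch(scenario@mode, GLYCINE = "alanine", ALANINE = "glycine",
                       PAIR = character(0))
    for (aa in union(names(feed), excluded)) {
        sid <- .feedSpecies[[aa]]
        i <- match(sid, sp$id)
        if (is.na(i))
            stop("configuration error: model has no medium species '", sid, "'")
        val <- if (aa %in% names(feed)) feed[[aa]] else 0
        if (aa %in% excluded) val <- 0
        sp$initial[i] <- val
        sp$boundary[i] <- scenario@clampFeeds || aa %in% excluded
    }
    if (scenario@clampSinks) sp$boundary[sp$sink] <- TRUE
    object@species <- sp
    validObject(object)
    object
})

#' Gelatin-hydrolysate amino-acid feed
#'
#' Splits a total amount of amino-acid units into per-amino-acid amounts
#' using the composition of pure gelatin hydrolysate, whose major amino
#' acids are glycine (21.4%), proline (12.4%) and alanine (8.9%).
#'
#' @param total total amino-acid units, mmol (>= 0).
#' @param composition named fractions (>= 0, summing to at most 1)
#'   overriding the default.
#' @return named numeric of per-amino-acid mmol amounts.
#' @examples
#' gelatinFeed(100)   # glycine 21.4, proline 12.4, alanine 8.9
#' @export
gelatinFeed <- function(total,
                        composition = c(glycine = 0.214, proline = 0.124,
                                        alanine = 0.089)) {
    if (!is.numeric(total) || length(total) != 1L || total < 0)
        stop("total must be a single number >= 0")
    if (any(composition < 0))
        stop("configuration error: composition fractions must be >= 0")
    if (sum(composition) > 1 + 1e-12)
        stop("configuration error: composition fractions sum to more than 1")
    total * composition
}

#' Net hydrogen coefficient of coupled Stickland fermentation
#'
#' In a Stickland pair the oxidative branch releases H2 and the reductive
#' branch consumes it. Per carbon mole of protein consumed the oxidations
#' produce 0.174 mol H2 while the reductions take up 0.040 mol, leaving a
#' theoretical net stoichiometric coefficient of 0.134 mol H2 available to
#' hydrogen-consuming methanogens.
#'
#' @param oxidative mol H2 produced by the oxidative branch per carbon mole.
#' @param reductive mol H2 consumed by the reductive branch per carbon mole.
#' @return net H2 stoichiometric coefficient (mol per carbon mole).
#' @examples
#' sticklandHydrogenBalance()   # 0.134
#' @export
sticklandHydrogenBalance <- function(oxidative = 0.174, reductive = 0.040) {
    if (oxidative < 0 || reductive < 0)
        stop("branch coefficients must be >= 0")
    oxidative - reductive
}
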