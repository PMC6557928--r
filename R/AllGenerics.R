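#' @export
setGeneric("speciesIds", function(object, ...) standardGeneric("speciesIds"))

#' @export
setGeneric("reactionIds", function(object, ...) standardGeneric("reactionIds"))

#' @export
setGeneric("modelSpecies", function(object, ...) standardGeneric("modelSpecies"))

#' @export
setGeneric("modelReactions", function(object, ...) standardGeneric("modelReactions"))

#' @export
setGeneric("modelCompartments", function(object, ...) standardGeneric("modelCompartments"))

#' @export
setGeneric("initialState", function(object, ...) standardGeneric("initialState"))

#' @export
setGeneric("stoichiometricMatrix", function(object, ...) standardGeneric("stoichiometricMatrix"))

#' @export
setGeneric("evaluateFluxes", function(object, state, ...) standardGeneric("evaluateFluxes"))

#' @export
setGeneric("odeRHS", function(object, state, t = 0, ...) standardGeneric("odeRHS"))

#' @export
setGeneric("validateModel", function(object, ...) standardGeneric("validateModel"))

#' @export
setGeneric("modelCensus", function(object, ...) standardGeneric("modelCensus"))

#' @export
setGeneric("applyScenario", function(object, scenario, ...) standardGeneric("applyScenario"))

#' @export
setGeneric("modelParameters", function(object, ...) standardGeneric("modelParameters"))

#' @export
setGeneric("setModelParameters", function(object, values, ...) standardGeneric("setModelParameters"))

#' @export
setGeneric("timeGrid", function(object, ...) standardGeneric("timeGrid"))

#' @export
setGeneric("concMatrix", function(object, ...) standardGeneric("concMatrix"))

#' @export
setGeneric("fluxMatrix", function(object, ...) standardGeneric("fluxMatrix"))

#' @export
setGeneric("elasticities", function(object, ...) standardGeneric("elasticities"))

#' @export
setGeneric("fluxControl", function(object, ...) standardGeneric("fluxControl"))

#' @export
setGeneric("isStable", function(object, ...) standardGeneric("isStable"))
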