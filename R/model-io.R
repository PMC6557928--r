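## Structured-text (YAML) model interchange.
##
## Schema:
##   name, units
##   compartments: [{id, label}]
##   species:      [{id, name, compartment, initial, charge, boundary, sink, note}]
##   reactions:    [{id, name, ec, transporterClass, reversible, note,
##                   stoichiometry: {species: coefficient},
##                   rateLaw: {kind: MM|GMA, vmax, km: {species: value},
##                             k, exponents: {species: value},
##                             vmaxr, kmr, kr, rexponents, modifiers}}]
## Missing numeric values (~) are read as NA placeholders to be filled from a
## ParameterTable.

.num1 <- function(x, default = NA_real_) {
    if (is.null(x)) default else as.numeric(x)
}

.namedNum <- function(x) {
    if (is.null(x) || length(x) == 0) return(numeric(0))
    stats::setNames(vapply(x, .num1, numeric(1)), names(x))
}

.lawFromList <- function(l) {
    kind <- toupper(l$kind %||% "MM")
    mods <- as.character(unlist(l$modifiers))
    if (kind %in% c("MM", "MICHAELIS_MENTEN")) {
        mmLaw(vmax = .num1(l$vmax), km = .namedNum(l$km),
              vmaxr = .num1(l$vmaxr, 0), kmr = .namedNum(l$kmr),
              modifiers = mods)
    } else if (kind %in% c("GMA", "GENERALIZED_MASS_ACTION", "MASS_ACTION")) {
        gmaLaw(k = .num1(l$k), exponents = .namedNum(l$exponents),
               kr = .num1(l$kr, 0), rexponents = .namedNum(l$rexponents),
               modifiers = mods)
    } else stop("unknown rate-law kind '", l$kind, "'")
}

.lawToList <- function(law) {
    if (is(law, "MichaelisMentenLaw")) {
        out <- list(kind = "MM", vmax = law@vmax, km = as.list(law@km))
        if (law@vmaxr > 0) {
            out$vmaxr <- law@vmaxr
            out$kmr <- as.list(law@kmr)
        }
    } else {
        out <- list(kind = "GMA", k = law@k, exponents = as.list(law@exponents))
        if (law@kr > 0) {
            out$kr <- law@kr
            out$rexponents <- as.list(law@rexponents)
        }
    }
    if (length(law@modifiers)) out$modifiers <- as.list(law@modifiers)
    out
}

#' Read / write a kinetic model as structured text
#'
#' Models are interchanged as YAML documents with `compartments`, `species`,
#' `reactions` (stoichiometry plus rate law) sections; see the packaged
#' `srcm_model.yaml` for the schema. Numeric fields left null are read as
#' unassigned (`NA`) placeholders, to be filled from a [ParameterTable].
#'
#' @param path file path.
#' @return `readKineticModel()`: a [KineticModel].
#' @export
readKineticModel <- function(path) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$species) || is.null(doc$reactions))
        stop("model document needs species and reactions sections")
    cp <- do.call(rbind, lapply(doc$compartments, function(x)
        data.frame(id = x$id, label = x$label %||% x$id)))
    sp <- do.call(rbind, lapply(doc$species, function(x)
        data.frame(id = x$id, name = x$name %||% x$id,
                   compartment = x$compartment,
                   initial = .num1(x$initial, 0),
                   charge = as.integer(x$charge %||% 0L),
                   boundary = isTRUE(x$boundary), sink = isTRUE(x$sink))))
    rx <- lapply(doc$reactions, function(x) {
        st <- .namedNum(x$stoichiometry)
        reaction(id = x$id, name = x$name %||% x$id, stoichiometry = st,
                 rateLaw = .lawFromList(x$rateLaw),
                 reversible = isTRUE(x$reversible),
                 ecNumber = x$ec %||% NA_character_,
                 transporterClass = x$transporterClass %||% NA_character_)
    })
    kineticModel(name = doc$name %||% "model", compartments = cp, species = sp,
                 reactions = rx,
                 unitsNote = doc$units %||%
                     "concentrations mmol/ml; fluxes mmol/min/ml; time min")
}

#' @rdname readKineticModel
#' @param model a [KineticModel].
#' @return `writeKineticModel()`: `path`, invisibly.
#' @export
writeKineticModel <- function(model, path) {
    doc <- list(
        name = model@name,
        units = model@unitsNote,
        compartments = lapply(seq_len(nrow(model@compartments)), function(i)
            as.list(model@compartments[i, c("id", "label")])),
        species = lapply(seq_len(nrow(model@species)), function(i) {
            s <- model@species[i, ]
            list(id = s$id, name = s$name, compartment = s$compartment,
                 initial = s$initial, charge = s$charge,
                 boundary = s$boundary, sink = s$sink)
        }),
        reactions = lapply(model@reactions, function(r) {
            out <- list(id = r@id, name = r@name,
                        stoichiometry = as.list(r@stoichiometry),
                        rateLaw = .lawToList(r@rateLaw),
                        reversible = r@reversible)
            if (!is.na(r@ecNumber)) out$ec <- r@ecNumber
            if (!is.na(r@transporterClass)) out$transporterClass <- r@transporterClass
            out
        }))
    yaml::write_yaml(doc, path)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tidy export of a trajectory
#'
#' @param trajectory a [Trajectory].
#' @return data.frame in long format with columns `time`, `id`, `kind`
#'   (`"concentration"` or `"flux"`), `value`.
#' @export
trajectoryToDataFrame <- function(trajectory) {
    stopifnot(is(trajectory, "Trajectory"))
    tall <- function(m, kind) data.frame(
        time = rep(trajectory@time, ncol(m)),
        id = rep(colnames(m), each = nrow(m)),
        kind = kind, value = as.vector(m))
    rbind(tall(trajectory@conc, "concentration"), tall(trajectory@flux, "flux"))
}

#' Read / write a parameter table as a delimited file
#'
#' Tab-separated long format with columns `component`, `reaction`,
#' `parameter`, `species`, `value`; the schema mirrors a kinetic-parameter
#' assignment table (reaction, substrate, Km, Vmax, initial concentration).
#'
#' @param path file path.
#' @return `readParameterTable()`: a [ParameterTable].
#' @export
readParameterTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
    new("ParameterTable", table = tab,
        metadata = list(provenance = "synthetic", source = path))
}

#' @rdname readParameterTable
#' @param params a [ParameterTable].
#' @return `writeParameterTable()`: `path`, invisibly.
#' @export
writeParameterTable <- function(params, path) {
    stopifnot(is(params, "ParameterTable"))
    utils::write.table(params@table, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
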