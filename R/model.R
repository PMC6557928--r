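#' Build a reaction
#'
#' @param id,name identifiers.
#' @param stoichiometry named numeric, negative coefficients = consumed.
#' @param rateLaw a [RateLaw] from [mmLaw()] or [gmaLaw()].
#' @param reversible logical; reversible reactions evaluate a net law.
#' @param ecNumber,transporterClass optional annotations.
#' @return a [Reaction].
#' @export
reaction <- function(id, stoichiometry, rateLaw, name = id, reversible = FALSE,
                     ecNumber = NA_character_, transporterClass = NA_character_) {
    new("Reaction", id = id, name = name, stoichiometry = stoichiometry,
        rateLaw = rateLaw, reversible = reversible, ecNumber = ecNumber,
        transporterClass = transporterClass)
}

#' Build a kinetic model
#'
#' @param name model name.
#' @param compartments data.frame (`id`, `label`) or character vector of ids.
#' @param species data.frame with at least `id`, `compartment`, `initial`;
#'   missing `name`/`charge`/`boundary`/`sink` columns are filled with
#'   defaults (id, 0, FALSE, FALSE).
#' @param reactions list of [Reaction] objects.
#' @param unitsNote units annotation.
#' @return a validated [KineticModel].
#' @export
kineticModel <- function(name, compartments, species, reactions,
                         unitsNote = "concentrations mmol/ml; fluxes mmol/min/ml; time min") {
    if (is.character(compartments))
        compartments <- data.frame(id = compartments, label = compartments)
    species <- as.data.frame(species)
    n <- nrow(species)
    if (is.null(species$id)) species$id <- character(n)
    if (is.null(species$initial)) species$initial <- numeric(n)
    if (is.null(species$compartment)) species$compartment <- character(n)
    if (is.null(species$name)) species$name <- species$id
    if (is.null(species$charge)) species$charge <- rep(0L, n)
    if (is.null(species$boundary)) species$boundary <- rep(FALSE, n)
    if (is.null(species$sink)) species$sink <- rep(FALSE, n)
    species <- species[, c("id", "name", "compartment", "initial", "charge",
                           "boundary", "sink")]
    new("KineticModel", name = name, compartments = as.data.frame(compartments),
        species = species, reactions = reactions, unitsNote = unitsNote)
}

#' @describeIn kineticModel species id vector, in canonical order.
#' @param object a [KineticModel].
#' @export
setMethod("speciesIds", "KineticModel", function(object) object@species$id)

#' @describeIn kineticModel reaction id vector, in canonical order.
#' @export
setMethod("reactionIds", "KineticModel",
          function(object) vapply(object@reactions, function(r) r@id, character(1)))

#' @describeIn kineticModel the species table.
#' @export
setMethod("modelSpecies", "KineticModel", function(object) object@species)

#' @describeIn kineticModel the reaction list (named by reaction id).
#' @export
setMethod("modelReactions", "KineticModel", function(object) {
    rs <- object@reactions
    names(rs) <- reactionIds(object)
    rs
})

#' @describeIn kineticModel the compartment table.
#' @export
setMethod("modelCompartments", "KineticModel", function(object) object@compartments)

#' @describeIn kineticModel named vector of initial concentrations.
#' @export
setMethod("initialState", "KineticModel", function(object) {
    stats::setNames(object@species$initial, object@species$id)
})

.internalIds <- function(model) model@species$id[!model@species$boundary]

.reactionById <- function(model, id) {
    idx <- match(id, reactionIds(model))
    if (is.na(idx)) stop("no reaction with id '", id, "'")
    model@reactions[[idx]]
}

#' Stoichiometric matrix
#'
#' The m x n matrix S of the mass balance dx/dt = S v: rows are the internal
#' (non-boundary) species in declaration order, columns the reactions in
#' declaration order, entries the signed stoichiometric coefficients.
#' Boundary species are excluded from the balance.
#'
#' @param object a [KineticModel].
#' @return a base matrix with dimnames (species x reactions).
#' @export
setMethod("stoichiometricMatrix", "KineticModel", function(object) {
    ids <- .internalIds(object)
    rids <- reactionIds(object)
    S <- matrix(0, nrow = length(ids), ncol = length(rids),
                dimnames = list(ids, rids))
    for (j in seq_along(object@reactions)) {
        st <- object@reactions[[j]]@stoichiometry
        unknown <- setdiff(names(st), object@species$id)
        if (length(unknown))
            stop("reaction ", rids[j], " references unknown species: ",
                 paste(unknown, collapse = ", "))
        keep <- intersect(names(st), ids)
        S[keep, j] <- st[keep]
    }
    S
})

.clampBoundary <- function(model, state) {
    b <- model@species$boundary
    state[model@species$id[b]] <- model@species$initial[b]
    state
}

#' Evaluate all reaction fluxes
#'
#' Dispatches each reaction's rate law on the given state (mmol/ml), after
#' clamping boundary species to their fixed values. `activity` optionally
#' scales whole rate laws (enzyme-activity multipliers, used by flux control
#' analysis and by optimization decision variables).
#'
#' @param object a [KineticModel].
#' @param state named numeric over all species, or unnamed in species order.
#' @param activity optional named numeric of per-reaction multipliers.
#' @return named flux vector (mmol/min/ml), one entry per reaction.
#' @export
setMethod("evaluateFluxes", "KineticModel", function(object, state, activity = NULL) {
    ids <- object@species$id
    if (is.null(names(state))) {
        if (length(state) != length(ids))
            stop("state length must equal the number of species")
        names(state) <- ids
    }
    if (any(state[ids] < 0, na.rm = TRUE))
        stop("negative concentration in state")
    state <- .clampBoundary(object, state)
    rids <- reactionIds(object)
    v <- numeric(length(rids))
    names(v) <- rids
    for (j in seq_along(rids)) {
        a <- if (!is.null(activity) && rids[j] %in% names(activity))
            activity[[rids[j]]] else 1
        v[j] <- .evalLaw(object@reactions[[j]]@rateLaw, state, a)
        if (!object@reactions[[j]]@reversible && v[j] < 0) v[j] <- 0
    }
    v
})

#' Mass-balance right-hand side
#'
#' dx/dt = S v(x, u, theta) restricted to internal species; boundary species
#' have derivative zero (their clamped values are the input vector u).
#'
#' @param object a [KineticModel].
#' @param state named (or ordered) concentration vector.
#' @param t time (min); present for integrator signatures, the shipped laws
#'   are autonomous.
#' @param activity optional per-reaction activity multipliers.
#' @return named derivative vector over all species, mmol/ml/min.
#' @export
setMethod("odeRHS", "KineticModel", function(object, state, t = 0, activity = NULL) {
    v <- evaluateFluxes(object, state, activity = activity)
    S <- stoichiometricMatrix(object)
    dx <- stats::setNames(numeric(nrow(object@species)), object@species$id)
    dx[rownames(S)] <- as.numeric(S %*% v)
    dx
})

#' Validate a kinetic model
#'
#' Collects every invariant violation rather than stopping at the first:
#' dangling species/compartment references, missing or out-of-domain rate-law
#' parameters, negative initial concentrations, internal species that appear
#' in no reaction, and transporters that do not span exactly two
#' compartments. An empty report means the model is usable.
#'
#' @param object a [KineticModel].
#' @return data.frame with columns `kind`, `where`, `message`; zero rows when
#'   the model is valid.
#' @export
setMethod("validateModel", "KineticModel", function(object) {
    rep <- data.frame(kind = character(), where = character(),
                      message = character())
    note <- function(kind, where, message)
        rbind(rep, data.frame(kind = kind, where = where, message = message))
    sp <- object@species
    if (anyDuplicated(sp$id))
        rep <- note("structural", "species", "duplicated species ids")
    bad <- !sp$compartment %in% object@compartments$id
    if (any(bad))
        rep <- note("structural", paste(sp$id[bad], collapse = ","),
                    "unknown compartment")
    neg <- !is.na(sp$initial) & sp$initial < 0
    if (any(neg))
        rep <- note("domain", paste(sp$id[neg], collapse = ","),
                    "negative initial concentration")
    used <- character()
    comp <- stats::setNames(sp$compartment, sp$id)
    for (r in object@reactions) {
        rsp <- union(names(r@stoichiometry),
                     union(.lawSpecies(r@rateLaw), r@rateLaw@modifiers))
        unknown <- setdiff(rsp, sp$id)
        if (length(unknown))
            rep <- note("structural", r@id,
                        paste("unknown species:", paste(unknown, collapse = ", ")))
        used <- union(used, rsp)
        law <- r@rateLaw
        if (is(law, "MichaelisMentenLaw")) {
            if (is.na(law@vmax) || anyNA(law@km))
                rep <- note("parameter", r@id, "missing (unassigned) vmax/km")
            else {
                if (!is.finite(law@vmax) || law@vmax <= 0)
                    rep <- note("parameter", r@id, "vmax must be > 0")
                if (length(law@km) == 0 || any(!is.finite(law@km)) || any(law@km <= 0))
                    rep <- note("parameter", r@id, "km must be > 0")
            }
        } else if (is(law, "MassActionLaw")) {
            if (is.na(law@k))
                rep <- note("parameter", r@id, "missing (unassigned) rate constant")
            else if (!is.finite(law@k) || law@k < 0)
                rep <- note("parameter", r@id, "k must be >= 0")
            if (any(!is.finite(law@exponents[!is.na(law@exponents)])))
                rep <- note("parameter", r@id, "exponents must be finite")
        }
        if (!is.na(r@transporterClass)) {
            cps <- unique(comp[intersect(names(r@stoichiometry), sp$id)])
            cps <- cps[!is.na(cps)]
            if (length(cps) != 2L)
                rep <- note("structural", r@id,
                            sprintf("transporter spans %d compartments (needs 2)",
                                    length(cps)))
        }
    }
    orphan <- sp$id[!sp$boundary & !sp$id %in% used]
    if (length(orphan))
        rep <- note("structural", paste(orphan, collapse = ","),
                    "internal species appears in no reaction")
    rep
})

## ---- kinetic parameter access by flat id -----------------------------------
## Naming scheme: R5.vmax, R5.km.c_accoa, T1.k, T1.exp.m_ala, R1.vmaxr,
## R1.kmr.<sp>, T1.kr, T1.rexp.<sp>, init.<species>.

#' Flat named vector of all kinetic parameters and initial concentrations
#'
#' Parameter ids follow `<reaction>.vmax`, `<reaction>.km.<species>`,
#' `<reaction>.k`, `<reaction>.exp.<species>` (plus `vmaxr`/`kmr`/`kr`/`rexp`
#' for reverse parts) and `init.<species>`. These ids are the currency of
#' [fitParameters()], [localSensitivity()] and optimization decision
#' variables.
#'
#' @param object a [KineticModel].
#' @return named numeric vector.
#' @export
setMethod("modelParameters", "KineticModel", function(object) {
    out <- numeric(0)
    for (r in object@reactions) {
        law <- r@rateLaw
        if (is(law, "MichaelisMentenLaw")) {
            out[paste0(r@id, ".vmax")] <- law@vmax
            for (sp in names(law@km)) out[paste0(r@id, ".km.", sp)] <- law@km[[sp]]
            if (law@vmaxr > 0) {
                out[paste0(r@id, ".vmaxr")] <- law@vmaxr
                for (sp in names(law@kmr)) out[paste0(r@id, ".kmr.", sp)] <- law@kmr[[sp]]
            }
        } else {
            out[paste0(r@id, ".k")] <- law@k
            for (sp in names(law@exponents))
                out[paste0(r@id, ".exp.", sp)] <- law@exponents[[sp]]
            if (law@kr > 0) {
                out[paste0(r@id, ".kr")] <- law@kr
                for (sp in names(law@rexponents))
                    out[paste0(r@id, ".rexp.", sp)] <- law@rexponents[[sp]]
            }
        }
    }
    ini <- initialState(object)
    out[paste0("init.", names(ini))] <- unname(ini)
    out
})

#' Set kinetic parameters by flat id
#'
#' @param object a [KineticModel].
#' @param values named numeric; names as in [modelParameters()].
#' @return the updated model.
#' @export
setMethod("setModelParameters", "KineticModel", function(object, values) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
        stop("values must be a named numeric vector")
    rids <- reactionIds(object)
    for (nm in names(values)) {
        val <- values[[nm]]
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        if (parts[1] == "init") {
            sp <- paste(parts[-1], collapse = ".")
            i <- match(sp, object@species$id)
            if (is.na(i)) stop("unknown species in parameter id '", nm, "'")
            object@species$initial[i] <- val
            next
        }
        j <- match(parts[1], rids)
        if (is.na(j)) stop("unknown reaction in parameter id '", nm, "'")
        law <- object@reactions[[j]]@rateLaw
        what <- parts[2]
        sp <- if (length(parts) > 2) paste(parts[-(1:2)], collapse = ".") else NULL
        law <- switch(what,
            vmax  = { law@vmax <- val; law },
            vmaxr = { law@vmaxr <- val; law },
            km    = { law@km[[sp]] <- val; law },
            kmr   = { law@kmr[[sp]] <- val; law },
            k     = { law@k <- val; law },
            kr    = { law@kr <- val; law },
            exp   = { law@exponents[[sp]] <- val; law },
            rexp  = { law@rexponents[[sp]] <- val; law },
            stop("unknown parameter field '", what, "' in '", nm, "'"))
        object@reactions[[j]]@rateLaw <- law
    }
    validObject(object)
    object
})

setMethod("show", "KineticModel", function(object) {
    cen <- tryCatch(modelCensus(object), error = function(e) NULL)
    cat("KineticModel:", object@name, "\n")
    cat("  compartments:", paste(object@compartments$id, collapse = ", "), "\n")
    cat("  species:", nrow(object@species),
        sprintf("(%d boundary)", sum(object@species$boundary)), "\n")
    cat("  reactions:", length(object@reactions), "\n")
    if (!is.null(cen)) {
        for (cp in names(cen@reactions))
            cat(sprintf("    %s: %d intracellular / %d metabolites / %d transport\n",
                        cp, cen@reactions[[cp]], cen@metabolites[[cp]],
                        cen@transport[[cp]]))
    }
    cat("  units:", object@unitsNote, "\n")
    invisible(object)
})

setMethod("show", "Reaction", function(object) {
    st <- object@stoichiometry
    lhs <- st[st < 0]; rhs <- st[st > 0]
    fmt <- function(x) paste(ifelse(abs(x) == 1, names(x),
                                    paste(abs(x), names(x))), collapse = " + ")
    arrow <- if (object@reversible) "<->" else "->"
    cat(sprintf("%s: %s %s %s  [%s]\n", object@id, fmt(lhs), arrow, fmt(rhs),
                class(object@rateLaw)))
    invisible(object)
})
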