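## SBML Level 3 Version 1 interchange, written directly over xml2.
## Export covers the constructs this package produces (compartments, species
## with boundaryCondition flags, reactions with MathML kinetic laws and local
## parameters); import recognizes kinetic laws structurally as
## Michaelis-Menten products of saturations or generalized mass action and
## rejects anything else with a precise message.

.sbmlNS <- "http://www.sbml.org/sbml/level3/version1/core"
.annoNS <- "https://srcmkinetics.r-universe.dev/annotations"

.xmlMissing <- function(node) inherits(node, "xml_missing")

.xnum <- function(x) sprintf("%.17g", x)

.mathFactorMM <- function(sp, kmName) {
    sprintf("<apply><divide/><ci>%s</ci><apply><plus/><ci>%s</ci><ci>%s</ci></apply></apply>",
            sp, kmName, sp)
}

.mathFactorGMA <- function(sp, g) {
    if (g == 1) sprintf("<ci>%s</ci>", sp)
    else sprintf("<apply><power/><ci>%s</ci><cn>%s</cn></apply>", sp, .xnum(g))
}

.mathProduct <- function(constName, factors) {
    if (length(factors) == 0) return(sprintf("<ci>%s</ci>", constName))
    sprintf("<apply><times/><ci>%s</ci>%s</apply>", constName,
            paste(factors, collapse = ""))
}

.lawToMathML <- function(law) {
    if (is(law, "MichaelisMentenLaw")) {
        fwd <- .mathProduct("vmax", vapply(names(law@km), function(sp)
            .mathFactorMM(sp, paste0("km_", sp)), character(1)))
        if (law@vmaxr > 0) {
            rev <- .mathProduct("vmaxr", vapply(names(law@kmr), function(sp)
                .mathFactorMM(sp, paste0("kmr_", sp)), character(1)))
            fwd <- sprintf("<apply><minus/>%s%s</apply>", fwd, rev)
        }
        pars <- c(vmax = law@vmax,
                  stats::setNames(law@km, paste0("km_", names(law@km))))
        if (law@vmaxr > 0)
            pars <- c(pars, vmaxr = law@vmaxr,
                      stats::setNames(law@kmr, paste0("kmr_", names(law@kmr))))
    } else {
        fwd <- .mathProduct("k", vapply(names(law@exponents), function(sp)
            .mathFactorGMA(sp, law@exponents[[sp]]), character(1)))
        if (law@kr > 0) {
            rev <- .mathProduct("kr", vapply(names(law@rexponents), function(sp)
                .mathFactorGMA(sp, law@rexponents[[sp]]), character(1)))
            fwd <- sprintf("<apply><minus/>%s%s</apply>", fwd, rev)
        }
        pars <- c(k = law@k)
        if (law@kr > 0) pars <- c(pars, kr = law@kr)
    }
    list(math = sprintf("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">%s</math>", fwd),
         parameters = pars)
}

#' Export a model as SBML Level 3 Version 1
#'
#' Compartments (unit volume), species with `boundaryCondition` flags and
#' initial concentrations, and reactions with MathML kinetic laws whose
#' constants are local parameters. Charges, sink flags and transporter
#' classes travel in a package annotation namespace. Units are declared as
#' mmol, ml and min.
#'
#' @param model a validated [KineticModel]; unassigned (NA) rate-law
#'   parameters are an export error naming the reaction.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportSBML <- function(model, path) {
    stopifnot(is(model, "KineticModel"))
    for (r in model@reactions) {
        law <- r@rateLaw
        bad <- if (is(law, "MichaelisMentenLaw")) is.na(law@vmax) || anyNA(law@km)
               else is.na(law@k)
        if (bad)
            stop("export error: reaction ", r@id, " has unassigned parameters")
    }
    esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
    }
    out <- c(sprintf("<?xml version=\"1.0\" encoding=\"UTF-8\"?>"),
             sprintf("<sbml xmlns=\"%s\" level=\"3\" version=\"1\">", .sbmlNS),
             sprintf("<model id=\"%s\" name=\"%s\" timeUnits=\"min\" volumeUnits=\"ml\" substanceUnits=\"mmol\" extentUnits=\"mmol\">",
                     gsub("[^A-Za-z0-9_]", "_", model@name), esc(model@name)),
             "<listOfUnitDefinitions>",
             "<unitDefinition id=\"mmol\"><listOfUnits><unit kind=\"mole\" exponent=\"1\" scale=\"-3\" multiplier=\"1\"/></listOfUnits></unitDefinition>",
             "<unitDefinition id=\"ml\"><listOfUnits><unit kind=\"litre\" exponent=\"1\" scale=\"-3\" multiplier=\"1\"/></listOfUnits></unitDefinition>",
             "<unitDefinition id=\"min\"><listOfUnits><unit kind=\"second\" exponent=\"1\" scale=\"0\" multiplier=\"60\"/></listOfUnits></unitDefinition>",
             "</listOfUnitDefinitions>",
             "<listOfCompartments>")
    for (i in seq_len(nrow(model@compartments)))
        out <- c(out, sprintf("<compartment id=\"%s\" name=\"%s\" size=\"1\" spatialDimensions=\"3\" constant=\"true\"/>",
                              model@compartments$id[i],
                              esc(model@compartments$label[i])))
    out <- c(out, "</listOfCompartments>", "<listOfSpecies>")
    for (i in seq_len(nrow(model@species))) {
        s <- model@species[i, ]
        out <- c(out, sprintf(paste0(
            "<species id=\"%s\" name=\"%s\" compartment=\"%s\" initialConcentration=\"%s\"",
            " boundaryCondition=\"%s\" constant=\"%s\" hasOnlySubstanceUnits=\"false\">",
            "<annotation><srcm:info xmlns:srcm=\"%s\" charge=\"%d\" sink=\"%s\"/></annotation>",
            "</species>"),
            s$id, esc(s$name), s$compartment, .xnum(s$initial),
            tolower(s$boundary), tolower(s$boundary), .annoNS,
            as.integer(s$charge), tolower(s$sink)))
    }
    out <- c(out, "</listOfSpecies>", "<listOfReactions>")
    for (r in model@reactions) {
        st <- r@stoichiometry
        ml <- .lawToMathML(r@rateLaw)
        anno <- sprintf("<annotation><srcm:reaction xmlns:srcm=\"%s\"%s%s/></annotation>",
                        .annoNS,
                        if (!is.na(r@ecNumber)) sprintf(" ec=\"%s\"", r@ecNumber) else "",
                        if (!is.na(r@transporterClass))
                            sprintf(" transporterClass=\"%s\"", r@transporterClass) else "")
        out <- c(out, sprintf("<reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\">",
                              r@id, esc(r@name), tolower(r@reversible)), anno)
        react <- st[st < 0]; prod <- st[st > 0]
        if (length(react)) {
            out <- c(out, "<listOfReactants>",
                     sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                             names(react), .xnum(abs(react))),
                     "</listOfReactants>")
        }
        if (length(prod)) {
            out <- c(out, "<listOfProducts>",
                     sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
                             names(prod), .xnum(prod)),
                     "</listOfProducts>")
        }
        if (length(r@rateLaw@modifiers))
            out <- c(out, "<listOfModifiers>",
                     sprintf("<modifierSpeciesReference species=\"%s\"/>",
                             r@rateLaw@modifiers),
                     "</listOfModifiers>")
        out <- c(out, "<kineticLaw>", ml$math, "<listOfLocalParameters>",
                 sprintf("<localParameter id=\"%s\" value=\"%s\"/>",
                         names(ml$parameters), .xnum(ml$parameters)),
                 "</listOfLocalParameters>", "</kineticLaw>", "</reaction>")
    }
    out <- c(out, "</listOfReactions>", "</model>", "</sbml>")
    writeLines(out, path)
    invisible(path)
}

## ---- import ---------------------------------------------------------------

## Recursively convert a (namespace-stripped) MathML node to a nested list:
## list(op=..., args=list(...)) / list(ci=name) / list(cn=value)
.mathmlTree <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "math") {
        kids <- xml2::xml_children(node)
        if (length(kids) != 1L) stop("unsupported-construct error: empty math")
        return(.mathmlTree(kids[[1]]))
    }
    if (nm == "ci") return(list(ci = trimws(xml2::xml_text(node))))
    if (nm == "cn") return(list(cn = as.numeric(trimws(xml2::xml_text(node)))))
    if (nm == "apply") {
        kids <- xml2::xml_children(node)
        op <- xml2::xml_name(kids[[1]])
        args <- lapply(kids[-1], .mathmlTree)
        return(list(op = op, args = args))
    }
    stop("unsupported-construct error: MathML element <", nm, ">")
}

## Structural recognition of a product law part. Returns
## list(const = <name>, mm = named km-param map, gma = named exponent map)
.recognizeProduct <- function(tree, speciesIds, params, rid) {
    factors <- if (!is.null(tree$op) && tree$op == "times") tree$args else list(tree)
    const <- NULL; mm <- character(0); gma <- numeric(0)
    for (f in factors) {
        if (!is.null(f$ci)) {
            if (f$ci %in% speciesIds) {
                gma[f$ci] <- if (f$ci %in% names(gma)) gma[[f$ci]] + 1 else 1
            } else if (f$ci %in% names(params)) {
                if (!is.null(const))
                    stop("unsupported-construct error in ", rid,
                         ": more than one constant factor")
                const <- f$ci
            } else stop("unsupported-construct error in ", rid,
                        ": unknown symbol '", f$ci, "'")
        } else if (!is.null(f$op) && f$op == "power" &&
                   !is.null(f$args[[1]]$ci) && f$args[[1]]$ci %in% speciesIds &&
                   !is.null(f$args[[2]]$cn)) {
            gma[f$args[[1]]$ci] <- f$args[[2]]$cn
        } else if (!is.null(f$op) && f$op == "divide") {
            num <- f$args[[1]]; den <- f$args[[2]]
            ok <- !is.null(num$ci) && num$ci %in% speciesIds &&
                !is.null(den$op) && den$op == "plus" && length(den$args) == 2L
            if (ok) {
                terms <- den$args
                cis <- vapply(terms, function(a) a$ci %||% NA_character_, character(1))
                kmName <- cis[cis %in% names(params)][1]
                spName <- cis[cis == num$ci][1]
                ok <- !is.na(kmName) && !is.na(spName)
            }
            if (!ok) stop("unsupported-construct error in ", rid,
                          ": unrecognized saturation term")
            mm[num$ci] <- kmName
        } else stop("unsupported-construct error in ", rid,
                    ": unrecognized factor")
    }
    if (is.null(const))
        stop("unsupported-construct error in ", rid, ": no rate constant factor")
    if (length(mm) && length(gma))
        stop("unsupported-construct error in ", rid,
             ": mixed saturation and power-law factors")
    list(const = const, mm = mm, gma = gma)
}

.recognizeLaw <- function(tree, speciesIds, params, modifiers, rid) {
    fwdTree <- tree; revTree <- NULL
    if (!is.null(tree$op) && tree$op == "minus" && length(tree$args) == 2L) {
        fwdTree <- tree$args[[1]]; revTree <- tree$args[[2]]
    }
    fwd <- .recognizeProduct(fwdTree, speciesIds, params, rid)
    rev <- if (!is.null(revTree))
        .recognizeProduct(revTree, speciesIds, params, rid) else NULL
    if (length(fwd$mm) || (length(fwd$gma) == 0 && !is.null(rev) && length(rev$mm))) {
        km <- stats::setNames(params[unname(fwd$mm)], names(fwd$mm))
        if (length(fwd$gma))
            stop("unsupported-construct error in ", rid, ": mixed law")
        mmLaw(vmax = params[[fwd$const]], km = km,
              vmaxr = if (!is.null(rev)) params[[rev$const]] else 0,
              kmr = if (!is.null(rev))
                  stats::setNames(params[unname(rev$mm)], names(rev$mm))
              else numeric(),
              modifiers = modifiers)
    } else {
        gmaLaw(k = params[[fwd$const]], exponents = fwd$gma,
               kr = if (!is.null(rev)) params[[rev$const]] else 0,
               rexponents = if (!is.null(rev)) rev$gma else numeric(),
               modifiers = modifiers)
    }
}

#' Import an SBML Level 3 Version 1 document
#'
#' Reads compartments, species (honoring `boundaryCondition`) and reactions.
#' Kinetic laws must be structurally recognizable as a Michaelis-Menten
#' product of saturations or a generalized-mass-action power product (each
#' optionally minus a reverse part of the same shape), with rate constants
#' as local parameters; any other MathML shape, or a reaction without a
#' kinetic law, is rejected with an unsupported-construct error naming the
#' reaction. The resulting model is validated.
#'
#' @param path SBML file path.
#' @return a [KineticModel].
#' @export
importSBML <- function(path) {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    modelNode <- xml2::xml_find_first(doc, "./model")
    if (.xmlMissing(modelNode))
        stop("parse error: no <model> element")
    att <- function(node, a, default = NA_character_) {
        v <- xml2::xml_attr(node, a)
        if (is.na(v)) default else v
    }
    cps <- xml2::xml_find_all(modelNode, ".//listOfCompartments/compartment")
    cp <- data.frame(id = xml2::xml_attr(cps, "id"),
                     label = vapply(cps, function(n) att(n, "name", xml2::xml_attr(n, "id")),
                                    character(1)))
    sps <- xml2::xml_find_all(modelNode, ".//listOfSpecies/species")
    sp <- do.call(rbind, lapply(sps, function(n) {
        info <- xml2::xml_find_first(n, ".//annotation/*[local-name()='info']")
        data.frame(id = xml2::xml_attr(n, "id"),
                   name = att(n, "name", xml2::xml_attr(n, "id")),
                   compartment = xml2::xml_attr(n, "compartment"),
                   initial = as.numeric(att(n, "initialConcentration", "0")),
                   charge = if (!.xmlMissing(info))
                       as.integer(att(info, "charge", "0")) else 0L,
                   boundary = identical(att(n, "boundaryCondition", "false"), "true"),
                   sink = !.xmlMissing(info) &&
                       identical(att(info, "sink", "false"), "true"))
    }))
    speciesIds <- sp$id
    rxNodes <- xml2::xml_find_all(modelNode, ".//listOfReactions/reaction")
    reactions <- lapply(rxNodes, function(n) {
        rid <- xml2::xml_attr(n, "id")
        refs <- function(xp, sign) {
            rr <- xml2::xml_find_all(n, xp)
            if (!length(rr)) return(numeric(0))
            stats::setNames(sign * as.numeric(xml2::xml_attr(rr, "stoichiometry")),
                            xml2::xml_attr(rr, "species"))
        }
        st <- c(refs(".//listOfReactants/speciesReference", -1),
                refs(".//listOfProducts/speciesReference", +1))
        dup <- names(st)[duplicated(names(st))]
        for (d in dup) {  # same species on both sides: net coefficient
            tot <- sum(st[names(st) == d])
            st <- st[names(st) != d]
            if (tot != 0) st[d] <- tot
        }
        mods <- xml2::xml_attr(
            xml2::xml_find_all(n, ".//listOfModifiers/modifierSpeciesReference"),
            "species")
        klaw <- xml2::xml_find_first(n, ".//kineticLaw")
        if (.xmlMissing(klaw))
            stop("unsupported-construct error: reaction ", rid,
                 " has no kineticLaw")
        lp <- xml2::xml_find_all(klaw, ".//localParameter")
        params <- stats::setNames(as.numeric(xml2::xml_attr(lp, "value")),
                                  xml2::xml_attr(lp, "id"))
        mathNode <- xml2::xml_find_first(klaw, ".//math")
        if (.xmlMissing(mathNode))
            stop("unsupported-construct error: reaction ", rid, " has no math")
        law <- .recognizeLaw(.mathmlTree(mathNode), speciesIds, params,
                             as.character(mods), rid)
        info <- xml2::xml_find_first(n, ".//annotation/*[local-name()='reaction']")
        reaction(id = rid, name = att(n, "name", rid), stoichiometry = st,
                 rateLaw = law,
                 reversible = identical(att(n, "reversible", "false"), "true"),
                 ecNumber = if (!.xmlMissing(info))
                     att(info, "ec") else NA_character_,
                 transporterClass = if (!.xmlMissing(info))
                     att(info, "transporterClass") else NA_character_)
    })
    model <- kineticModel(name = att(modelNode, "name",
                                     att(modelNode, "id", "model")),
                          compartments = cp, species = sp, reactions = reactions)
    rep <- validateModel(model)
    rep <- rep[rep$kind != "parameter", , drop = FALSE]  # NA params allowed
    if (nrow(rep))
        stop("imported model failed validation:\n",
             paste(sprintf("  [%s] %s: %s", rep$kind, rep$where, rep$message),
                   collapse = "\n"))
    model
}
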