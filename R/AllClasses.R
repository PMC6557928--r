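#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib SRCMkinetics, .registration = TRUE
NULL

#' Rate laws
#'
#' `RateLaw` is the virtual parent of the two kinetic rate-law families used
#' throughout the package: `MichaelisMentenLaw` for intracellular enzymatic
#' reactions and `MassActionLaw` (generalized mass action, power-law kinetics
#' with possibly non-integer exponents) for transport steps.
#'
#' A `MichaelisMentenLaw` with several driving substrates evaluates as a
#' product of saturation terms, \eqn{v = V_{max} \prod_i s_i/(K_{m,i}+s_i)}.
#' An optional reverse part (`vmaxr`, `kmr`) turns it into a net law.
#' A `MassActionLaw` evaluates as \eqn{v = k \prod_i c_i^{g_i}}, minus an
#' optional reverse term \eqn{k_r \prod_i c_i^{h_i}}.
#'
#' Modifiers are species (typically enzymes at constant concentration) that
#' appear in the law's context but are not consumed; they scale activity only
#' through the assignment \eqn{V_{max} = k_{cat}\,[E]} made when parameters
#' are assembled, so the law itself stores them as annotations.
#'
#' @slot modifiers character vector of modifier species ids.
#' @slot vmax,km forward maximal rate (mmol/min/ml) and Michaelis constants
#'   (mmol/ml), `km` named by driving-substrate species id.
#' @slot vmaxr,kmr optional reverse part (0 / empty when irreversible).
#' @slot k,exponents forward rate constant and kinetic orders, `exponents`
#'   named by species id.
#' @slot kr,rexponents optional reverse rate constant and kinetic orders.
#'
#' @name RateLaw-classes
#' @aliases RateLaw MichaelisMentenLaw MassActionLaw
#' @exportClass RateLaw
#' @exportClass MichaelisMentenLaw
#' @exportClass MassActionLaw
setClass("RateLaw", representation("VIRTUAL", modifiers = "character"),
         prototype(modifiers = character()))

#' @rdname RateLaw-classes
setClass("MichaelisMentenLaw", contains = "RateLaw",
         representation(vmax = "numeric", km = "numeric",
                        vmaxr = "numeric", kmr = "numeric"),
         prototype(vmaxr = 0, kmr = numeric()))

## NA parameter values are permitted as placeholders for "not yet assigned";
## validateModel() reports them, evaluation refuses them.
setValidity("MichaelisMentenLaw", function(object) {
    msg <- character()
    if (length(object@vmax) != 1L ||
        (!is.na(object@vmax) && (!is.finite(object@vmax) || object@vmax <= 0)))
        msg <- c(msg, "vmax must be a single positive finite number (or NA)")
    if (length(object@km) < 1L || is.null(names(object@km)) || any(!nzchar(names(object@km))))
        msg <- c(msg, "km must be a named vector with one entry per driving substrate")
    km <- object@km[!is.na(object@km)]
    if (any(!is.finite(km)) || any(km <= 0))
        msg <- c(msg, "all km must be positive and finite")
    if (length(object@vmaxr) != 1L || object@vmaxr < 0)
        msg <- c(msg, "vmaxr must be a single number >= 0")
    if (object@vmaxr > 0 && (length(object@kmr) < 1L || any(object@kmr <= 0)))
        msg <- c(msg, "reverse part requires positive named kmr")
    if (length(msg)) msg else TRUE
})

#' @rdname RateLaw-classes
setClass("MassActionLaw", contains = "RateLaw",
         representation(k = "numeric", exponents = "numeric",
                        kr = "numeric", rexponents = "numeric"),
         prototype(kr = 0, rexponents = numeric()))

setValidity("MassActionLaw", function(object) {
    msg <- character()
    if (length(object@k) != 1L ||
        (!is.na(object@k) && (!is.finite(object@k) || object@k < 0)))
        msg <- c(msg, "k must be a single finite number >= 0 (or NA)")
    if (length(object@exponents) &&
        (is.null(names(object@exponents)) || any(!nzchar(names(object@exponents)))))
        msg <- c(msg, "exponents must be named by species id")
    if (any(!is.finite(object@exponents)))
        msg <- c(msg, "exponents must be finite")
    if (length(object@kr) != 1L || object@kr < 0)
        msg <- c(msg, "kr must be a single number >= 0")
    if (any(!is.finite(object@rexponents)))
        msg <- c(msg, "reverse exponents must be finite")
    if (length(msg)) msg else TRUE
})

#' Reaction
#'
#' One reaction of a kinetic network: a signed stoichiometry over species
#' (negative = consumed), a [RateLaw], a reversibility flag, and optional
#' EC number and transporter classification. Transport reactions carry one of
#' the membrane-transporter classes `DIFFUSION`, `SYMPORTER`,
#' `PROTON_TRANSLOCATION`, `ABC`, `FNT`, `AAPO`, `DAACS` and must connect
#' species in exactly two distinct compartments.
#'
#' @slot id,name identifiers (`id` unique within a model).
#' @slot stoichiometry named numeric, names are species ids.
#' @slot rateLaw a [RateLaw].
#' @slot reversible logical; reversible reactions evaluate their net law and
#'   may carry negative flux.
#' @slot ecNumber optional EC number (`NA` if none).
#' @slot transporterClass optional transporter class (`NA` for intracellular
#'   reactions).
#' @exportClass Reaction
setClass("Reaction",
         representation(id = "character", name = "character",
                        stoichiometry = "numeric", rateLaw = "RateLaw",
                        reversible = "logical", ecNumber = "character",
                        transporterClass = "character"),
         prototype(reversible = FALSE, ecNumber = NA_character_,
                   transporterClass = NA_character_))

.transporterClasses <- c("DIFFUSION", "SYMPORTER", "PROTON_TRANSLOCATION",
                         "ABC", "FNT", "AAPO", "DAACS")

setValidity("Reaction", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "reaction id must be a non-empty string")
    st <- object@stoichiometry
    if (length(st) < 1L || is.null(names(st)) || any(!nzchar(names(st))))
        msg <- c(msg, "stoichiometry must be a named numeric vector")
    if (!any(st != 0))
        msg <- c(msg, "stoichiometry needs at least one nonzero coefficient")
    if (!is.na(object@transporterClass) &&
        !object@transporterClass %in% .transporterClasses)
        msg <- c(msg, paste0("unknown transporter class '",
                             object@transporterClass, "'"))
    if (length(msg)) msg else TRUE
})

#' Compartmental kinetic model
#'
#' The central container: compartments, species (with initial concentrations
#' in mmol/ml, charges and boundary flags) and reactions with their rate laws.
#' Boundary species have clamped concentrations, are excluded from the mass
#' balance, and implement the model's input vector (substrate feeds, exported
#' gases, conserved cofactor pools held constant). Species flagged `sink` are
#' terminal accumulation pools that chemostat-style scenarios may clamp.
#'
#' Species and reaction declaration order is canonical: it fixes the row and
#' column ordering of the stoichiometric matrix and of all trajectory and
#' control-coefficient matrices.
#'
#' @slot name model name.
#' @slot compartments data.frame with columns `id`, `label`.
#' @slot species data.frame with columns `id`, `name`, `compartment`,
#'   `initial`, `charge`, `boundary`, `sink`.
#' @slot reactions list of [Reaction] objects.
#' @slot unitsNote free-text note on units (concentrations mmol/ml, fluxes
#'   mmol/min/ml, time min).
#' @exportClass KineticModel
setClass("KineticModel",
         representation(name = "character", compartments = "data.frame",
                        species = "data.frame", reactions = "list",
                        unitsNote = "character"),
         prototype(name = "model",
                   unitsNote = "concentrations mmol/ml; fluxes mmol/min/ml; time min"))

setValidity("KineticModel", function(object) {
    msg <- character()
    cp <- object@compartments
    sp <- object@species
    need <- c("id", "name", "compartment", "initial", "charge", "boundary", "sink")
    if (!all(c("id", "label") %in% names(cp)))
        msg <- c(msg, "compartments need columns id, label")
    if (!all(need %in% names(sp)))
        msg <- c(msg, paste("species table needs columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(sp$id)) msg <- c(msg, "species ids must be unique")
        if (any(!sp$compartment %in% cp$id))
            msg <- c(msg, "every species must reference an existing compartment")
        if (any(sp$initial < 0, na.rm = TRUE))
            msg <- c(msg, "initial concentrations must be >= 0")
    }
    if (anyDuplicated(cp$id)) msg <- c(msg, "compartment ids must be unique")
    rids <- vapply(object@reactions, function(r) r@id, character(1))
    if (anyDuplicated(rids)) msg <- c(msg, "reaction ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Simulation settings
#'
#' Controls for deterministic and stochastic time-course simulation. Output
#' is sampled on a regular grid `seq(0, tEnd, by = interval)`; the default
#' output spacing is 1.0 (minutes) and the internal step budget defaults to
#' 10,000, matching the batch simulation protocol the shipped model is run
#' under. `omega` (concentration-to-copy-number scale, copies per mmol/ml)
#' and `seed` are used by the stochastic simulator only.
#'
#' @slot tEnd simulation horizon, min.
#' @slot interval output spacing, min.
#' @slot maxInternalSteps integrator internal step budget.
#' @slot rtol,atol relative / absolute integration tolerances.
#' @slot seed RNG seed (stochastic).
#' @slot omega copies per unit concentration (stochastic).
#' @slot maxEvents cap on stochastic reaction firings.
#' @exportClass SimulationSettings
setClass("SimulationSettings",
         representation(tEnd = "numeric", interval = "numeric",
                        maxInternalSteps = "numeric", rtol = "numeric",
                        atol = "numeric", seed = "numeric", omega = "numeric",
                        maxEvents = "numeric"),
         prototype(interval = 1.0, maxInternalSteps = 10000, rtol = 1e-8,
                   atol = 1e-12, seed = NA_real_, omega = NA_real_,
                   maxEvents = 1e8))

setValidity("SimulationSettings", function(object) {
    msg <- character()
    if (length(object@tEnd) != 1L || !is.finite(object@tEnd) || object@tEnd <= 0)
        msg <- c(msg, "tEnd must be > 0")
    if (object@interval <= 0) msg <- c(msg, "interval must be > 0")
    if (object@rtol <= 0 || object@atol <= 0)
        msg <- c(msg, "tolerances must be > 0")
    if (!is.na(object@omega) && object@omega <= 0)
        msg <- c(msg, "omega must be > 0")
    if (length(msg)) msg else TRUE
})

#' Simulated time course
#'
#' Time grid with a concentration matrix (time x species, mmol/ml) and a flux
#' matrix (time x reactions, mmol/min/ml); flux rows are the rate laws
#' evaluated at the corresponding state. `clampedNegatives` counts
#' integrator outputs below zero that were projected back to zero.
#'
#' @exportClass Trajectory
setClass("Trajectory",
         representation(time = "numeric", conc = "matrix", flux = "matrix",
                        clampedNegatives = "integer"),
         prototype(clampedNegatives = 0L))

setValidity("Trajectory", function(object) {
    msg <- character()
    if (length(object@time) != nrow(object@conc) ||
        length(object@time) != nrow(object@flux))
        msg <- c(msg, "time grid and matrix rows disagree")
    if (is.unsorted(object@time, strictly = TRUE))
        msg <- c(msg, "time grid must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Steady state
#'
#' A root of the mass balance \eqn{S\,v(x) = 0} over the internal species,
#' with the eigenvalues of the Jacobian of the internal dynamic block and the
#' resulting linear-stability verdict (stable iff every eigenvalue has
#' negative real part).
#'
#' @exportClass SteadyState
setClass("SteadyState",
         representation(state = "numeric", flux = "numeric",
                        eigenvalues = "complex", stable = "logical",
                        residualNorm = "numeric"))

#' Metabolic control analysis results
#'
#' Scaled elasticities \eqn{\varepsilon_{j,i} = (x_i/v_j)\,\partial v_j /
#' \partial x_i} (reactions x species; `NA` where the scaling is degenerate)
#' and flux control coefficients \eqn{C^{J}_{e} = (e/J)\,\Delta J/\Delta e}
#' (target fluxes x enzymes) obtained by central finite differences on the
#' enzyme activities, together with the relative perturbation used.
#' `fccFlagged` marks entries whose half/double-step estimates disagree by
#' more than 5% or where a perturbed steady state could not be recovered.
#'
#' @exportClass ControlAnalysis
setClass("ControlAnalysis",
         representation(elasticities = "matrix", fcc = "matrix",
                        fccFlagged = "matrix", perturbation = "numeric"),
         prototype(elasticities = matrix(numeric(), 0, 0),
                   fcc = matrix(numeric(), 0, 0),
                   fccFlagged = matrix(logical(), 0, 0),
                   perturbation = NA_real_))

#' Kinetic parameter table
#'
#' Long-format table of per-reaction kinetic constants plus initial
#' concentrations: the synthetic stand-in for a full experimental parameter
#' assignment. Columns: `component` (`"kinetics"` or `"initial"`),
#' `reaction`, `parameter` (`vmax`, `km`, `k`, `exponent`, `initial`),
#' `species` (driving substrate / exponent species / metabolite), `value`.
#' Units follow the model convention (mmol, ml, min).
#'
#' @slot table the data.frame described above.
#' @slot metadata list; carries `seed`, `ranges` and a provenance note for
#'   generated tables (all shipped and generated tables are synthetic).
#' @exportClass ParameterTable
setClass("ParameterTable",
         representation(table = "data.frame", metadata = "list"),
         prototype(metadata = list(provenance = "synthetic")))

setValidity("ParameterTable", function(object) {
    need <- c("component", "reaction", "parameter", "species", "value")
    if (!all(need %in% names(object@table)))
        return(paste("parameter table needs columns:", paste(need, collapse = ", ")))
    if (any(!object@table$component %in% c("kinetics", "initial")))
        return("component must be 'kinetics' or 'initial'")
    TRUE
})

#' Substrate-constraint scenario
#'
#' Which amino-acid feed the medium supplies (glycine only, alanine only, or
#' the alanine-glycine pair), at what concentrations, and whether feeds and
#' terminal product sinks are clamped (chemostat-style boundary conditions)
#' or left free (batch mode, finite feed).
#'
#' @slot mode one of `"GLYCINE"`, `"ALANINE"`, `"PAIR"`.
#' @slot feed named numeric, mmol/ml, names among the medium amino-acid
#'   species.
#' @slot clampFeeds,clampSinks logical clamp flags.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
         representation(mode = "character", feed = "numeric",
                        clampFeeds = "logical", clampSinks = "logical"),
         prototype(clampFeeds = FALSE, clampSinks = FALSE))

setValidity("ScenarioSpec", function(object) {
    msg <- character()
    if (!object@mode %in% c("GLYCINE", "ALANINE", "PAIR"))
        msg <- c(msg, "mode must be GLYCINE, ALANINE or PAIR")
    if (any(object@feed < 0)) msg <- c(msg, "feed concentrations must be >= 0")
    if (object@mode == "PAIR") {
        gly <- object@feed[["glycine"]]
        ala <- object@feed[["alanine"]]
        if (is.null(gly) || is.null(ala) || gly <= 0 || ala <= 0)
            msg <- c(msg, "PAIR mode requires nonzero glycine and alanine feeds")
    }
    if (length(msg)) msg else TRUE
})

#' Flux-optimization objective
#'
#' Scalarized flux objective: maximize the summed flux through `maximize`
#' reactions (weight `wMax`) minus the summed flux through `minimize`
#' reactions (weight `wMin`), over box-bounded decision parameters. The
#' shipped default maximizes the methane-synthesis reaction while minimizing
#' the glycine/alanine catabolic reactions.
#'
#' @slot maximize,minimize disjoint reaction id sets.
#' @slot wMax,wMin scalarization weights.
#' @slot decision data.frame with columns `parameter`, `lower`, `upper`.
#' @exportClass ObjectiveSpec
setClass("ObjectiveSpec",
         representation(maximize = "character", minimize = "character",
                        wMax = "numeric", wMin = "numeric",
                        decision = "data.frame"),
         prototype(wMax = 1.0, wMin = 0.1))

setValidity("ObjectiveSpec", function(object) {
    msg <- character()
    if (length(intersect(object@maximize, object@minimize)))
        msg <- c(msg, "maximize and minimize sets must be disjoint")
    d <- object@decision
    if (nrow(d)) {
        if (!all(c("parameter", "lower", "upper") %in% names(d)))
            msg <- c(msg, "decision table needs parameter, lower, upper")
        else if (any(!is.finite(d$lower)) || any(!is.finite(d$upper)) ||
                 any(d$lower >= d$upper))
            msg <- c(msg, "decision bounds must be finite with lower < upper")
    }
    if (length(msg)) msg else TRUE
})

#' Flux-optimization result
#'
#' @slot par best decision-parameter vector found.
#' @slot value objective value at `par` (mmol/min/ml scale).
#' @slot fluxes matrix with rows `initial` and `optimized`: per-reaction flux
#'   distribution at the evaluation state.
#' @slot trace data.frame iteration log (evaluation index, objective,
#'   incumbent).
#' @slot seed seed used.
#' @exportClass OptimizationResult
setClass("OptimizationResult",
         representation(par = "numeric", value = "numeric", fluxes = "matrix",
                        trace = "data.frame", seed = "numeric"))

#' Parameter-estimation result
#'
#' @slot par fitted parameters.
#' @slot rss residual sum of squares at `par`.
#' @slot converged logical.
#' @slot message optimizer message.
#' @slot starts data.frame of multistart outcomes (start index, rss,
#'   converged).
#' @exportClass FitResult
setClass("FitResult",
         representation(par = "numeric", rss = "numeric",
                        converged = "logical", message = "character",
                        starts = "data.frame"))

#' Model census
#'
#' Per-compartment counts of intracellular reactions, metabolites and
#' transport reactions. Transport reactions are counted per membrane: each
#' transporter is attributed to every compartment it touches.
#'
#' @slot reactions,metabolites,transport named integer vectors (names =
#'   compartment ids).
#' @exportClass ModelCensus
setClass("ModelCensus",
         representation(reactions = "integer", metabolites = "integer",
                        transport = "integer"))

#' Synthetic observed time courses
#'
#' Noisy observations generated from a simulated trajectory, for parameter
#' estimation. Long format: `time`, `species`, `replicate`, `value`.
#'
#' @slot data the long-format data.frame.
#' @slot noiseCV multiplicative lognormal noise coefficient of variation.
#' @slot seed generating seed.
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(data = "data.frame", noiseCV = "numeric",
                        seed = "numeric"))
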