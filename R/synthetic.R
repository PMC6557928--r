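## Synthetic data generation: parameter tables, noisy observations.
## Everything here is explicitly synthetic stand-in data; generated tables
## carry a provenance marker in their metadata.

.logUniform <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate a synthetic kinetic-parameter table
#'
#' Draws a complete parameter assignment for a model: log-uniform Vmax and
#' Km for every Michaelis-Menten reaction (one Km per driving substrate),
#' log-uniform rate constants for mass-action reactions, and log-uniform
#' initial concentrations for metabolites. Enzyme modifier species are
#' assigned initial concentration 1.0 so that table Vmax values are the
#' effective activities. Identical seeds give identical tables.
#'
#' @param model a [KineticModel] (parameter values may be unassigned).
#' @param seed RNG seed.
#' @param ranges list with elements `km`, `vmax`, `k`, `initial`, each a
#'   `c(lower, upper)` range (defaults: Km in 0.01-10 mmol/ml, Vmax in
#'   0.1-10 mmol/min/ml, k in 0.01-10 per min, initials in 0.05-5 mmol/ml).
#' @return a [ParameterTable] covering every model reaction.
#' @export
generateParameterTable <- function(model, seed = 1L,
                                   ranges = list(km = c(0.01, 10),
                                                 vmax = c(0.1, 10),
                                                 k = c(0.01, 10),
                                                 initial = c(0.05, 5))) {
    for (nm in c("km", "vmax", "k", "initial")) {
        r <- ranges[[nm]]
        if (is.null(r) || length(r) != 2L || any(r <= 0) || r[1] >= r[2])
            stop("configuration error: range '", nm,
                 "' must be positive with lower < upper")
    }
    set.seed(seed)
    rows <- list()
    add <- function(component, reaction, parameter, species, value)
        rows[[length(rows) + 1L]] <<- data.frame(
            component = component, reaction = reaction, parameter = parameter,
            species = species, value = value)
    for (r in model@reactions) {
        law <- r@rateLaw
        if (is(law, "MichaelisMentenLaw")) {
            add("kinetics", r@id, "vmax", NA, .logUniform(1, ranges$vmax))
            for (sp in names(law@km))
                add("kinetics", r@id, "km", sp, .logUniform(1, ranges$km))
        } else {
            add("kinetics", r@id, "k", NA, .logUniform(1, ranges$k))
        }
    }
    enzymes <- unique(unlist(lapply(model@reactions,
                                    function(r) r@rateLaw@modifiers)))
    for (i in seq_len(nrow(model@species))) {
        sp <- model@species$id[i]
        val <- if (sp %in% enzymes) 1.0 else .logUniform(1, ranges$initial)
        add("initial", NA, "initial", sp, val)
    }
    new("ParameterTable", table = do.call(rbind, rows),
        metadata = list(provenance = "synthetic", seed = seed, ranges = ranges))
}

#' Generate noisy synthetic observations
#'
#' Simulates the model deterministically and applies independent
#' multiplicative lognormal noise with coefficient of variation `noiseCV`
#' to every observed point and replicate (mean-preserving: the noise
#' multiplier has expectation 1). Concentrations stay non-negative by
#' construction. `noiseCV = 0` returns the trajectory exactly; identical
#' seeds give identical datasets.
#'
#' @param model a validated [KineticModel].
#' @param settings a [SimulationSettings].
#' @param noiseCV coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param replicates number of replicate series.
#' @param seed RNG seed.
#' @param species species ids to observe (default: all non-boundary).
#' @return a [SyntheticDataset].
#' @export
generateObservations <- function(model, settings, noiseCV = 0.05,
                                 replicates = 1L, seed = 1L, species = NULL) {
    if (noiseCV < 0) stop("noiseCV must be >= 0")
    tr <- simulateDeterministic(model, settings)
    if (is.null(species))
        species <- model@species$id[!model@species$boundary]
    conc <- concMatrix(tr)[, species, drop = FALSE]
    times <- timeGrid(tr)
    sigma <- sqrt(log(1 + noiseCV^2))
    set.seed(seed)
    out <- list()
    for (r in seq_len(replicates)) {
        noise <- if (noiseCV == 0) 1 else
            exp(stats::rnorm(length(conc), -sigma^2 / 2, sigma))
        vals <- pmax(as.vector(conc) * noise, 0)
        out[[r]] <- data.frame(
            time = rep(times, length(species)),
            species = rep(species, each = length(times)),
            replicate = r, value = vals)
    }
    new("SyntheticDataset", data = do.call(rbind, out), noiseCV = noiseCV,
        seed = as.numeric(seed))
}

setMethod("show", "SyntheticDataset", function(object) {
    cat(sprintf("SyntheticDataset: %d observations, %d species, %d replicate(s), noise CV %g, seed %g\n",
                nrow(object@data), length(unique(object@data$species)),
                max(object@data$replicate), object@noiseCV, object@seed))
    invisible(object)
})

setMethod("show", "ParameterTable", function(object) {
    k <- object@table
    cat(sprintf("ParameterTable: %d kinetic values over %d reactions, %d initial concentrations\n",
                sum(k$component == "kinetics"),
                length(unique(k$reaction[k$component == "kinetics"])),
                sum(k$component == "initial")))
    if (!is.null(object@metadata$provenance))
        cat("  provenance:", object@metadata$provenance, "\n")
    invisible(object)
})
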