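#' Simulation settings
#'
#' @param tEnd horizon, min.
#' @param interval output spacing, min (default 1.0).
#' @param maxInternalSteps internal integrator step budget (default 10,000).
#' @param rtol,atol integration tolerances (defaults 1e-8, 1e-12).
#' @param seed RNG seed for stochastic simulation.
#' @param omega concentration-to-copy-number scale for stochastic simulation
#'   (copies = concentration x omega).
#' @param maxEvents stochastic event budget.
#' @return a [SimulationSettings].
#' @export
simulationSettings <- function(tEnd, interval = 1.0, maxInternalSteps = 10000,
                               rtol = 1e-8, atol = 1e-12, seed = NA,
                               omega = NA, maxEvents = 1e8) {
    new("SimulationSettings", tEnd = tEnd, interval = interval,
        maxInternalSteps = maxInternalSteps, rtol = rtol, atol = atol,
        seed = as.numeric(seed), omega = as.numeric(omega),
        maxEvents = maxEvents)
}

## Precompute the compact law encoding consumed by the C++ evaluator.
## Species indices are 0-based positions in the canonical species order.
.compileModel <- function(model) {
    ids <- model@species$id
    pos <- function(x) {
        i <- match(x, ids)
        if (anyNA(i)) stop("rate law references unknown species: ",
                           paste(x[is.na(i)], collapse = ", "))
        i - 1L
    }
    laws <- lapply(model@reactions, function(r) {
        law <- r@rateLaw
        if (is(law, "MichaelisMentenLaw")) {
            if (is.na(law@vmax) || anyNA(law@km))
                stop("configuration error: reaction ", r@id,
                     " has unassigned parameters")
            list(kind = 0, p1 = law@vmax, idx = pos(names(law@km)),
                 p2 = unname(law@km), rp1 = law@vmaxr,
                 ridx = pos(names(law@kmr)), rp2 = unname(law@kmr),
                 rev = r@reversible)
        } else {
            if (is.na(law@k))
                stop("configuration error: reaction ", r@id,
                     " has unassigned parameters")
            list(kind = 1, p1 = law@k, idx = pos(names(law@exponents)),
                 p2 = unname(law@exponents), rp1 = law@kr,
                 ridx = pos(names(law@rexponents)),
                 rp2 = unname(law@rexponents), rev = r@reversible)
        }
    })
    S <- stoichiometricMatrix(model)
    boundary <- model@species$boundary
    list(laws = laws, S = S, ids = ids, rids = reactionIds(model),
         boundary = boundary,
         boundaryValues = model@species$initial[boundary],
         internal = match(rownames(S), ids))
}

.fluxAt <- function(cm, state, activity) {
    v <- rate_eval(state, cm$laws, activity)
    names(v) <- cm$rids
    v
}

.activityVector <- function(cm, activity) {
    a <- rep(1, length(cm$rids))
    if (!is.null(activity)) {
        i <- match(names(activity), cm$rids)
        if (anyNA(i)) stop("unknown reaction id in activity vector")
        a[i] <- unname(activity)
    }
    a
}

#' Deterministic time-course simulation
#'
#' Integrates the mass balance dx/dt = S v(x, u, theta) from the model's
#' initial concentrations with a stiffness-switching adaptive integrator
#' (`deSolve::lsoda`), sampling output on the regular interval grid.
#' Boundary species are held at their clamped values. Output concentrations
#' marginally below zero (within integrator tolerance) are projected to zero;
#' the number of projected entries is recorded on the returned object.
#'
#' @param model a validated [KineticModel].
#' @param settings a [SimulationSettings].
#' @param activity optional named per-reaction activity multipliers.
#' @return a [Trajectory].
#' @examples
#' decay <- kineticModel("decay", "CELL",
#'     data.frame(id = "x", compartment = "CELL", initial = 1),
#'     list(reaction("deg", c(x = -1), gmaLaw(k = 0.1, exponents = c(x = 1)))))
#' tr <- simulateDeterministic(decay, simulationSettings(tEnd = 10))
#' concMatrix(tr)[11, "x"]   # ~ exp(-1)
#' @export
simulateDeterministic <- function(model, settings, activity = NULL) {
    stopifnot(is(model, "KineticModel"), is(settings, "SimulationSettings"))
    validObject(settings)
    cm <- .compileModel(model)
    act <- .activityVector(cm, activity)
    x0 <- initialState(model)
    times <- seq(0, settings@tEnd, by = settings@interval)
    if (times[length(times)] < settings@tEnd)
        times <- c(times, settings@tEnd)
    intIdx <- cm$internal
    rhs <- function(t, y, parms) {
        full <- x0
        full[intIdx] <- pmax(y, 0)
        v <- rate_eval(full, cm$laws, act)
        list(as.numeric(cm$S %*% v))
    }
    sol <- try(deSolve::lsoda(y = unname(x0[intIdx]), times = times,
                              func = rhs, parms = NULL,
                              rtol = settings@rtol, atol = settings@atol,
                              maxsteps = settings@maxInternalSteps), silent = TRUE)
    if (inherits(sol, "try-error"))
        stop("simulation error: integrator failure: ", attr(sol, "condition")$message)
    if (nrow(sol) < length(times)) {
        stop("simulation error: integrator stopped at t = ",
             sol[nrow(sol), 1], " (of ", settings@tEnd, ")")
    }
    conc <- matrix(rep(x0, each = nrow(sol)), nrow = nrow(sol),
                   dimnames = list(NULL, cm$ids))
    conc[, intIdx] <- sol[, -1, drop = FALSE]
    nneg <- sum(conc < 0)
    if (nneg > 0) conc[conc < 0] <- 0
    flux <- matrix(0, nrow(conc), length(cm$rids),
                   dimnames = list(NULL, cm$rids))
    for (i in seq_len(nrow(conc)))
        flux[i, ] <- rate_eval(conc[i, ], cm$laws, act)
    new("Trajectory", time = sol[, 1], conc = conc, flux = flux,
        clampedNegatives = as.integer(nneg))
}

#' Stochastic time-course simulation (next-reaction method)
#'
#' Exact-in-structure stochastic simulation using the Gibson-Bruck
#' next-reaction variant of the Gillespie algorithm: one putative firing
#' time per reaction kept in an indexed priority queue, updated through a
#' precomputed dependency graph after each firing; exact ties fire the
#' lowest reaction index first. Copy numbers are `round(concentration *
#' omega)`; propensities are the macroscopic rate laws evaluated at `n/omega`
#' and scaled by `omega` (for Michaelis-Menten laws this is the standard
#' mean-field approximation of the propensity). Output is converted back to
#' concentration units. Identical seed and settings give an identical
#' trajectory.
#'
#' @param model a validated [KineticModel] with integer stoichiometric
#'   coefficients and irreversible rate laws.
#' @param settings a [SimulationSettings] with `seed` and `omega` set.
#' @return a [Trajectory] (concentrations piecewise constant between events,
#'   sampled on the interval grid).
#' @export
simulateStochastic <- function(model, settings) {
    stopifnot(is(model, "KineticModel"), is(settings, "SimulationSettings"))
    validObject(settings)
    if (is.na(settings@omega))
        stop("configuration error: stochastic simulation requires omega")
    if (is.na(settings@seed))
        stop("configuration error: stochastic simulation requires a seed")
    cm <- .compileModel(model)
    for (r in model@reactions) {
        if (any(r@stoichiometry != round(r@stoichiometry)))
            stop("configuration error: non-integer stoichiometry in ", r@id)
        if (r@reversible)
            stop("configuration error: stochastic simulation requires irreversible laws (",
                 r@id, ")")
    }
    ids <- cm$ids
    x0 <- initialState(model)
    copies <- round(x0 * settings@omega)
    times <- seq(0, settings@tEnd, by = settings@interval)
    if (times[length(times)] < settings@tEnd)
        times <- c(times, settings@tEnd)
    # per-reaction state updates restricted to internal species
    internalSet <- ids[!cm$boundary]
    stIdx <- list(); stDel <- list()
    for (j in seq_along(model@reactions)) {
        st <- model@reactions[[j]]@stoichiometry
        st <- st[names(st) %in% internalSet & st != 0]
        stIdx[[j]] <- match(names(st), ids) - 1L
        stDel[[j]] <- as.integer(st)
    }
    # dependency graph: j must be refreshed when a species its law reads changes
    lawSpp <- lapply(model@reactions, function(r) .lawSpecies(r@rateLaw))
    dep <- lapply(seq_along(model@reactions), function(i) {
        changed <- ids[stIdx[[i]] + 1L]
        affected <- which(vapply(lawSpp, function(s) any(s %in% changed), logical(1)))
        sort(unique(c(i, affected))) - 1L
    })
    set.seed(settings@seed)
    res <- nrm_run(unname(copies), cm$laws, stIdx, stDel, dep,
                   times, settings@omega, settings@maxEvents)
    conc <- res$copies
    colnames(conc) <- ids
    act <- rep(1, length(cm$rids))
    flux <- matrix(0, nrow(conc), length(cm$rids),
                   dimnames = list(NULL, cm$rids))
    for (i in seq_len(nrow(conc)))
        flux[i, ] <- rate_eval(conc[i, ], cm$laws, act)
    new("Trajectory", time = times, conc = conc, flux = flux)
}

#' @describeIn simulateDeterministic time grid accessor.
#' @param object a [Trajectory].
#' @export
setMethod("timeGrid", "Trajectory", function(object) object@time)

#' @describeIn simulateDeterministic concentration matrix accessor
#'   (time x species, mmol/ml).
#' @export
setMethod("concMatrix", "Trajectory", function(object) object@conc)

#' @describeIn simulateDeterministic flux matrix accessor
#'   (time x reactions, mmol/min/ml).
#' @export
setMethod("fluxMatrix", "Trajectory", function(object) object@flux)

setMethod("show", "Trajectory", function(object) {
    cat(sprintf("Trajectory: %d time points (0..%g min), %d species, %d reactions\n",
                length(object@time), max(object@time), ncol(object@conc),
                ncol(object@flux)))
    if (object@clampedNegatives > 0)
        cat("  note:", object@clampedNegatives,
            "marginally negative outputs projected to zero\n")
    invisible(object)
})
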