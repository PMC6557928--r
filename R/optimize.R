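#' Flux-objective specification
#'
#' @param maximize reaction ids whose flux is maximized.
#' @param minimize reaction ids whose flux is penalized.
#' @param wMax,wMin scalarization weights (defaults 1.0 and 0.1; the source
#'   protocol states no weights, so they are configuration-exposed).
#' @param decision data.frame with columns `parameter`, `lower`, `upper`:
#'   the box-bounded decision variables (flat parameter ids, typically
#'   `vmax`/`k` enzyme activities).
#' @return an [ObjectiveSpec].
#' @export
objectiveSpec <- function(maximize, minimize = character(), wMax = 1.0,
                          wMin = 0.1,
                          decision = data.frame(parameter = character(),
                                                lower = numeric(),
                                                upper = numeric())) {
    new("ObjectiveSpec", maximize = maximize, minimize = minimize,
        wMax = wMax, wMin = wMin, decision = decision)
}

#' Shipped methane-maximization objective for the SRCM model
#'
#' Maximize the methane-synthesis flux (R13) while penalizing the
#' glycine/alanine catabolic fluxes (R1-R3). Decision variables are the
#' maximal activities of the glycine-reductase branch (R3), the
#' acetate-synthesis step (R5), CO dehydrogenase (R9), the first
#' methyltransfer step (R11) and methyl-CoM reductase (R13), each bounded
#' to [0.2x, 5x] its current value.
#'
#' @param model the SRCM [KineticModel] the bounds are scaled from.
#' @return an [ObjectiveSpec].
#' @export
srcmObjective <- function(model) {
    pars <- paste0(c("R3", "R5", "R9", "R11", "R13"), ".vmax")
    base <- modelParameters(model)[pars]
    objectiveSpec(maximize = "R13", minimize = c("R1", "R2", "R3"),
                  wMax = 1.0, wMin = 0.1,
                  decision = data.frame(parameter = pars,
                                        lower = 0.2 * unname(base),
                                        upper = 5.0 * unname(base)))
}

## Objective-evaluation state: integrate the candidate to the horizon; when
## the system converges on the way (clamped-feed chemostat) the end state is
## its steady state, otherwise it is the end-of-horizon state of the
## pre-steady-state batch protocol. One ODE solve per candidate keeps the
## derivative-free search affordable.
.objectiveState <- function(model, settings) {
    tr <- simulateDeterministic(model, settings)
    fluxMatrix(tr)[nrow(fluxMatrix(tr)), ]
}

#' Maximize a flux objective over bounded enzyme activities
#'
#' Scalarizes the multi-objective (maximize methane-synthesis flux, minimize
#' amino-acid catabolic fluxes) as \eqn{J = w_{max}\sum v_{max-set} -
#' w_{min}\sum v_{min-set}}, each candidate parameterization being evaluated
#' at its steady state, or at the end-of-horizon state of a batch
#' integration when no steady state exists. The search is derivative-free:
#' multistart Nelder-Mead on a sine-transformed box, seeded deterministically;
#' the reported optimum is never worse than the starting point, whose
#' evaluation is always included.
#'
#' @param model a validated [KineticModel] (scenario already applied).
#' @param objective an [ObjectiveSpec].
#' @param seed RNG seed for the multistart draws.
#' @param settings horizon used for end-of-horizon evaluation (default
#'   `simulationSettings(tEnd = 200, interval = 10)`).
#' @param nStarts number of Nelder-Mead starts (first = current values).
#' @param maxit Nelder-Mead iterations per start.
#' @return an [OptimizationResult].
#' @export
optimizeFlux <- function(model, objective, seed = 1L, settings = NULL,
                         nStarts = 2L, maxit = 300L) {
    stopifnot(is(objective, "ObjectiveSpec"))
    validObject(objective)
    rids <- reactionIds(model)
    missing <- setdiff(c(objective@maximize, objective@minimize), rids)
    if (length(missing))
        stop("objective references unknown reactions: ",
             paste(missing, collapse = ", "))
    if (is.null(settings))
        settings <- simulationSettings(tEnd = 200, interval = 10,
                                       rtol = 1e-6, atol = 1e-9)
    d <- objective@decision
    scalarize <- function(flux) {
        objective@wMax * sum(flux[objective@maximize]) -
            objective@wMin * sum(flux[objective@minimize])
    }
    evalCount <- 0L
    trace <- list()
    evalPar <- function(p) {
        m <- setModelParameters(model, stats::setNames(p, d$parameter))
        flux <- tryCatch(suppressWarnings(.objectiveState(m, settings)),
                         error = function(e) NULL)
        evalCount <<- evalCount + 1L
        if (is.null(flux)) return(list(J = -Inf, flux = NULL))
        J <- scalarize(flux)
        trace[[length(trace) + 1L]] <<- data.frame(eval = evalCount, objective = J)
        list(J = J, flux = flux)
    }
    initFlux <- .objectiveState(model, settings)
    if (nrow(d) == 0L) {
        return(new("OptimizationResult",
                   par = stats::setNames(numeric(0), character(0)),
                   value = scalarize(initFlux),
                   fluxes = rbind(initial = initFlux, optimized = initFlux),
                   trace = data.frame(eval = integer(), objective = numeric(),
                                      incumbent = numeric()),
                   seed = as.numeric(seed)))
    }
    p0 <- modelParameters(model)[d$parameter]
    lo <- d$lower; hi <- d$upper
    toZ <- function(p) asin(pmin(pmax(2 * (p - lo) / (hi - lo) - 1, -1), 1))
    toP <- function(z) lo + (hi - lo) * (sin(z) + 1) / 2
    best <- list(p = unname(p0), J = evalPar(unname(p0))$J)
    set.seed(seed)
    starts <- list(unname(p0))
    if (nStarts > 1L)
        for (i in seq_len(nStarts - 1L))
            starts[[i + 1L]] <- lo + (hi - lo) * stats::runif(length(lo))
    fn <- function(z) {
        r <- evalPar(toP(z))
        if (!is.finite(r$J)) 1e10 else -r$J
    }
    # Brent for one decision variable (bounded 1-D), Nelder-Mead otherwise
    runOpt <- function(z0) {
        if (length(lo) == 1L)
            stats::optim(z0, fn, method = "Brent", lower = -pi / 2,
                         upper = pi / 2, control = list(maxit = maxit))
        else stats::optim(z0, fn, method = "Nelder-Mead",
                          control = list(maxit = maxit))
    }
    for (s in starts) {
        opt <- runOpt(toZ(s))
        pOpt <- toP(opt$par)
        JOpt <- -opt$value
        if (is.finite(JOpt) && JOpt > best$J) best <- list(p = pOpt, J = JOpt)
    }
    # restart from the incumbent with a fresh simplex to tighten convergence
    polish <- runOpt(toZ(best$p))
    if (is.finite(-polish$value) && -polish$value > best$J)
        best <- list(p = toP(polish$par), J = -polish$value)
    bestEval <- evalPar(best$p)
    tr <- do.call(rbind, trace)
    tr$incumbent <- cummax(tr$objective)
    new("OptimizationResult",
        par = stats::setNames(best$p, d$parameter), value = best$J,
        fluxes = rbind(initial = initFlux, optimized = bestEval$flux),
        trace = tr, seed = as.numeric(seed))
}

setMethod("show", "OptimizationResult", function(object) {
    cat(sprintf("OptimizationResult: objective %.4f after %d evaluations (seed %g)\n",
                object@value, nrow(object@trace), object@seed))
    if (length(object@par)) {
        cat("  decision parameters:\n")
        for (nm in names(object@par))
            cat(sprintf("    %s = %.4g\n", nm, object@par[[nm]]))
    }
    invisible(object)
})

#' Fit kinetic parameters to observed time courses
#'
#' Least-squares estimation of selected kinetic parameters from (synthetic)
#' observed concentration time courses: the model is simulated at each
#' candidate parameterization and the concentration residuals at the
#' observation times minimized with bounded Levenberg-Marquardt
#' (`minpack.lm::nls.lm`), optionally after log transformation. Multistart:
#' the first start is the model's current values, further starts are drawn
#' uniformly inside the bounds under the given seed. Candidates on which the
#' integrator fails are rejected with a large penalty and logged in the
#' per-start table.
#'
#' @param model a validated [KineticModel].
#' @param observed a [SyntheticDataset] or a data.frame with columns `time`,
#'   `species`, `value` (optionally `replicate`).
#' @param free data.frame with columns `parameter`, `lower`, `upper`.
#' @param seed RNG seed for multistart draws.
#' @param nStarts number of starts (default 1: start at current values).
#' @param logScale fit on log1p-transformed concentrations.
#' @param rtol,atol integration tolerances used during fitting.
#' @return a [FitResult].
#' @export
fitParameters <- function(model, observed, free, seed = 1L, nStarts = 1L,
                          logScale = FALSE, rtol = 1e-8, atol = 1e-10) {
    obs <- if (is(observed, "SyntheticDataset")) observed@data else observed
    stopifnot(all(c("time", "species", "value") %in% names(obs)))
    stopifnot(all(c("parameter", "lower", "upper") %in% names(free)))
    theta <- modelParameters(model)
    unknown <- setdiff(free$parameter, names(theta))
    if (length(unknown))
        stop("unknown free parameters: ", paste(unknown, collapse = ", "))
    times <- sort(unique(c(0, obs$time)))
    cmBase <- .compileModel(model)
    spIdx <- match(obs$species, cmBase$ids)
    if (anyNA(spIdx))
        stop("observed species not in model: ",
             paste(unique(obs$species[is.na(spIdx)]), collapse = ", "))
    tIdx <- match(obs$time, times)
    tf <- if (logScale) function(x) log1p(x) else identity
    simulateAt <- function(p) {
        m <- setModelParameters(model, stats::setNames(p, free$parameter))
        cm <- .compileModel(m)
        x0 <- initialState(m)
        act <- rep(1, length(cm$rids))
        rhs <- function(t, y, parms) {
            full <- x0
            full[cm$internal] <- pmax(y, 0)
            list(as.numeric(cm$S %*% rate_eval(full, cm$laws, act)))
        }
        sol <- deSolve::lsoda(unname(x0[cm$internal]), times, rhs, NULL,
                              rtol = rtol, atol = atol)
        if (nrow(sol) < length(times)) stop("integrator failure")
        conc <- matrix(rep(x0, each = nrow(sol)), nrow = nrow(sol),
                       dimnames = list(NULL, cm$ids))
        conc[, cm$internal] <- pmax(sol[, -1, drop = FALSE], 0)
        conc
    }
    failures <- 0L
    residFun <- function(p) {
        conc <- tryCatch(suppressWarnings(simulateAt(p)),
                         error = function(e) NULL)
        if (is.null(conc)) {
            failures <<- failures + 1L
            return(rep(1e3, nrow(obs)))
        }
        tf(obs$value) - tf(conc[cbind(tIdx, spIdx)])
    }
    set.seed(seed)
    p0 <- unname(theta[free$parameter])
    starts <- list(p0)
    if (nStarts > 1L) {
        # log-uniform draws when the box is positive (kinetic constants span
        # decades), plain uniform otherwise
        logOK <- all(free$lower > 0)
        for (i in seq_len(nStarts - 1L))
            starts[[i + 1L]] <- if (logOK)
                exp(log(free$lower) +
                    (log(free$upper) - log(free$lower)) * stats::runif(nrow(free)))
            else free$lower + (free$upper - free$lower) * stats::runif(nrow(free))
    }
    fits <- lapply(starts, function(s)
        tryCatch(minpack.lm::nls.lm(par = s, lower = free$lower,
                                    upper = free$upper, fn = residFun,
                                    control = minpack.lm::nls.lm.control(maxiter = 200)),
                 error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("all fit starts failed")
    rss <- vapply(fits, function(f) if (is.null(f)) Inf else sum(f$fvec^2),
                  numeric(1))
    bestIdx <- which.min(rss)
    best <- fits[[bestIdx]]
    startTab <- data.frame(start = seq_along(fits), rss = rss,
                           converged = vapply(fits, function(f)
                               !is.null(f) && f$info %in% 1:4, logical(1)))
    new("FitResult", par = stats::setNames(best$par, free$parameter),
        rss = sum(best$fvec^2), converged = best$info %in% 1:4,
        message = paste0(best$message,
                         if (failures > 0)
                             sprintf(" [%d candidate(s) rejected on integrator failure]",
                                     failures) else ""),
        starts = startTab)
}

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult: RSS %.4g, %s\n", object@rss,
                if (object@converged) "converged" else "not converged"))
    for (nm in names(object@par))
        cat(sprintf("  %s = %.6g\n", nm, object@par[[nm]]))
    invisible(object)
})
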