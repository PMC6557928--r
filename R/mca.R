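## Steady states, linear stability, elasticities, flux control coefficients
## and local parameter sensitivity.

## Finite-difference Jacobian of the internal mass balance at y (internal
## dynamic species). Step per coordinate: max(1e-8, 1e-6 * |x_i|), central.
.fdJacobian <- function(fun, y) {
    n <- length(y)
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
        h <- max(1e-8, 1e-6 * abs(y[i]))
        yp <- y; ym <- y
        yp[i] <- y[i] + h
        ym[i] <- max(y[i] - h, 0)
        J[, i] <- (fun(yp) - fun(ym)) / (yp[i] - ym[i])
    }
    J
}

.internalRHS <- function(model, activity = NULL) {
    cm <- .compileModel(model)
    act <- .activityVector(cm, activity)
    x0 <- initialState(model)
    intIdx <- cm$internal
    list(
        cm = cm, act = act, intIdx = intIdx, x0 = x0,
        f = function(y) {
            full <- x0
            full[intIdx] <- pmax(y, 0)
            as.numeric(cm$S %*% rate_eval(full, cm$laws, act))
        },
        fluxes = function(y) {
            full <- x0
            full[intIdx] <- pmax(y, 0)
            stats::setNames(as.numeric(rate_eval(full, cm$laws, act)), cm$rids)
        })
}

## Damped Newton with non-negativity projection and a long-time-integration
## fallback; returns list(y, residual) or signals a convergence error.
.solveSteady <- function(model, y0, activity = NULL, tol = 1e-9,
                         maxIter = 100L, fallback = TRUE) {
    ir <- .internalRHS(model, activity)
    y <- pmax(y0, 0)
    best <- list(y = y, res = sqrt(sum(ir$f(y)^2)))
    newton <- function(y) {
        for (it in seq_len(maxIter)) {
            fy <- ir$f(y)
            res <- sqrt(sum(fy^2))
            if (res < best$res) best <<- list(y = y, res = res)
            if (res < tol) return(y)
            J <- .fdJacobian(ir$f, y)
            dy <- tryCatch(solve(J, -fy), error = function(e) NULL)
            if (is.null(dy)) dy <- -as.numeric(pracma::pinv(J) %*% fy)
            lambda <- 1
            improved <- FALSE
            while (lambda > 1e-6) {
                yn <- pmax(y + lambda * dy, 0)
                rn <- sqrt(sum(ir$f(yn)^2))
                if (rn < res) { y <- yn; improved <- TRUE; break }
                lambda <- lambda / 2
            }
            if (!improved) return(NULL)
        }
        NULL
    }
    out <- newton(y)
    if (is.null(out) && fallback) {
        # integrate toward the attractor, then polish
        for (tEnd in c(100, 1000, 10000)) {
            tr <- try(suppressWarnings(simulateDeterministic(model,
                          simulationSettings(tEnd = tEnd, interval = tEnd / 10),
                          activity = activity)), silent = TRUE)
            if (inherits(tr, "try-error")) next
            yT <- concMatrix(tr)[nrow(concMatrix(tr)), ir$cm$ids[ir$intIdx]]
            out <- newton(pmax(unname(yT), 0))
            if (!is.null(out)) break
        }
    }
    if (is.null(out))
        stop(sprintf("convergence error: no steady state found (best residual %.3g)",
                     best$res))
    list(y = out, residual = sqrt(sum(ir$f(out)^2)), ir = ir)
}

#' Find a steady state
#'
#' Solves the internal mass balance S v(x) = 0 by damped Newton iteration
#' (finite-difference Jacobian, backtracking line search, non-negativity
#' projection) with a fallback to long-time integration followed by a Newton
#' polish. The returned object carries the Jacobian eigenvalues at the root
#' and the linear-stability verdict.
#'
#' @param model a validated [KineticModel].
#' @param initialGuess optional named (or internal-species-ordered) starting
#'   state; defaults to the model's initial concentrations.
#' @param tol residual-norm tolerance (default 1e-9).
#' @param activity optional per-reaction activity multipliers.
#' @return a [SteadyState].
#' @export
findSteadyState <- function(model, initialGuess = NULL, tol = 1e-9,
                            activity = NULL) {
    cm <- .compileModel(model)
    intIds <- cm$ids[cm$internal]
    y0 <- if (is.null(initialGuess)) {
        unname(initialState(model)[intIds])
    } else if (!is.null(names(initialGuess))) {
        unname(initialGuess[intIds])
    } else initialGuess
    sol <- .solveSteady(model, y0, activity = activity, tol = tol)
    full <- initialState(model)
    full[intIds] <- sol$y
    eig <- jacobianEigenvalues(model, full, activity = activity)
    new("SteadyState", state = full, flux = sol$ir$fluxes(sol$y),
        eigenvalues = eig$values, stable = eig$stable,
        residualNorm = sol$residual)
}

#' Jacobian eigenvalues and linear stability
#'
#' Central finite-difference Jacobian of the internal mass balance
#' (step `max(1e-8, 1e-6 |x_i|)` per species), eigenvalues of the internal
#' block, and the stability verdict (all real parts negative).
#'
#' @param model a validated [KineticModel].
#' @param state named concentration vector over all species.
#' @param activity optional per-reaction activity multipliers.
#' @return list with `values` (complex eigenvalues, sorted by decreasing real
#'   part) and `stable` (logical).
#' @export
jacobianEigenvalues <- function(model, state, activity = NULL) {
    ir <- .internalRHS(model, activity)
    y <- unname(state[ir$cm$ids[ir$intIdx]])
    if (anyNA(y)) stop("state must cover all internal species")
    J <- .fdJacobian(ir$f, y)
    if (any(!is.finite(J)))
        stop("numerical error: non-finite rate evaluations in the Jacobian")
    ev <- as.complex(eigen(J, only.values = TRUE)$values)
    ev <- ev[order(-Re(ev))]
    list(values = ev, stable = all(Re(ev) < 0))
}

#' Scaled elasticity coefficients
#'
#' The elasticity of reaction j with respect to species i is the scaled
#' local sensitivity \eqn{\varepsilon_{j,i} = (x_i/v_j)\,\partial v_j/
#' \partial x_i}, a property of the individual enzyme, computed here by
#' analytic differentiation of the Michaelis-Menten and mass-action laws:
#' for an irreversible MM law it is \eqn{K_m/(K_m+S)}; for a pure power law
#' it equals the kinetic-order exponent, independent of state. Entries for
#' species absent from a reaction's rate law are exactly zero; entries where
#' the reaction rate is zero (scaling degenerate) are `NA`.
#'
#' @param model a validated [KineticModel].
#' @param state named concentration vector (a steady state, typically).
#' @return a [ControlAnalysis] with the elasticity matrix filled
#'   (reactions x species).
#' @export
elasticityMatrix <- function(model, state) {
    ids <- model@species$id
    rids <- reactionIds(model)
    state <- .clampBoundary(model, state[ids])
    E <- matrix(0, length(rids), length(ids), dimnames = list(rids, ids))
    v <- evaluateFluxes(model, state)
    for (j in seq_along(rids)) {
        e <- .lawElasticities(model@reactions[[j]]@rateLaw, state, v[[j]])
        if (length(e)) E[j, names(e)] <- unname(e)
    }
    new("ControlAnalysis", elasticities = E, perturbation = NA_real_)
}

#' Flux control coefficients
#'
#' The control coefficient of enzyme e over flux J is the scaled global
#' sensitivity \eqn{C^J_e = (e/J)\,\Delta J/\Delta e}. Each enzyme's
#' activity (the whole rate law, equivalent to `vmax`/`k` scaling under
#' \eqn{V_{max} = k_{cat}[E]}) is scaled by \eqn{(1 \pm \delta)}, the steady
#' state re-solved from the unperturbed root, and the target fluxes
#' differenced centrally. With `stepCheck` the estimate is recomputed at
#' half and double step and the entry flagged when the two disagree by more
#' than 5% (or when a perturbed steady state cannot be recovered). For an
#' unbranched pathway the coefficients along the flux sum to 1 (summation
#' theorem), a property used in the package's tests.
#'
#' @param model a validated [KineticModel].
#' @param steadyState a [SteadyState] from [findSteadyState()].
#' @param perturbation relative activity perturbation (default 0.01).
#' @param targets reaction ids whose flux is the controlled variable
#'   (default: all reactions).
#' @param enzymes reaction ids whose activity is perturbed (default: all).
#' @param stepCheck verify step-size robustness (default TRUE).
#' @return a [ControlAnalysis] with `fcc` (targets x enzymes) and
#'   `fccFlagged` filled.
#' @export
fluxControlCoefficients <- function(model, steadyState, perturbation = 0.01,
                                    targets = NULL, enzymes = NULL,
                                    stepCheck = TRUE) {
    stopifnot(is(steadyState, "SteadyState"))
    rids <- reactionIds(model)
    if (is.null(targets)) targets <- rids
    if (is.null(enzymes)) enzymes <- rids
    cm <- .compileModel(model)
    intIds <- cm$ids[cm$internal]
    y0 <- unname(steadyState@state[intIds])
    J0 <- steadyState@flux[targets]
    fccAt <- function(e, delta) {
        up <- stats::setNames(1 + delta, e)
        dn <- stats::setNames(1 - delta, e)
        sp <- .solveSteady(model, y0, activity = up, fallback = FALSE)
        sm <- .solveSteady(model, y0, activity = dn, fallback = FALSE)
        (sp$ir$fluxes(sp$y)[targets] - sm$ir$fluxes(sm$y)[targets]) /
            (2 * delta * J0)
    }
    C <- matrix(NA_real_, length(targets), length(enzymes),
                dimnames = list(targets, enzymes))
    flag <- matrix(FALSE, length(targets), length(enzymes),
                   dimnames = list(targets, enzymes))
    for (e in enzymes) {
        est <- tryCatch(fccAt(e, perturbation), error = function(err) NULL)
        if (is.null(est)) { flag[, e] <- TRUE; next }
        C[, e] <- est
        if (stepCheck) {
            lo <- tryCatch(fccAt(e, perturbation / 2), error = function(err) NULL)
            hi <- tryCatch(fccAt(e, perturbation * 2), error = function(err) NULL)
            if (is.null(lo) || is.null(hi)) { flag[, e] <- TRUE; next }
            denom <- pmax(abs(est), 1e-8)
            flag[, e] <- abs(lo - hi) / denom > 0.05
        }
    }
    new("ControlAnalysis", fcc = C, fccFlagged = flag,
        perturbation = perturbation)
}

#' @describeIn elasticityMatrix elasticity matrix accessor.
#' @param object a [ControlAnalysis].
#' @export
setMethod("elasticities", "ControlAnalysis", function(object) object@elasticities)

#' @describeIn fluxControlCoefficients FCC matrix accessor.
#' @param object a [ControlAnalysis].
#' @export
setMethod("fluxControl", "ControlAnalysis", function(object) object@fcc)

#' @describeIn findSteadyState stability accessor.
#' @param object a [SteadyState].
#' @export
setMethod("isStable", "SteadyState", function(object) object@stable)

setMethod("show", "SteadyState", function(object) {
    cat(sprintf("SteadyState: residual %.3g, %s (max Re(eig) = %.3g)\n",
                object@residualNorm,
                if (object@stable) "stable" else "not stable",
                max(Re(object@eigenvalues))))
    invisible(object)
})

setMethod("show", "ControlAnalysis", function(object) {
    cat("ControlAnalysis\n")
    if (length(object@elasticities))
        cat(sprintf("  elasticities: %d x %d\n", nrow(object@elasticities),
                    ncol(object@elasticities)))
    if (length(object@fcc))
        cat(sprintf("  flux control coefficients: %d x %d (perturbation %g, %d flagged)\n",
                    nrow(object@fcc), ncol(object@fcc), object@perturbation,
                    sum(object@fccFlagged)))
    invisible(object)
})

#' Time-resolved local parameter sensitivity
#'
#' Central finite-difference sensitivity of every species trajectory to one
#' kinetic parameter: the model is simulated at \eqn{\theta(1\pm\delta)} and
#' the trajectories differenced, giving \eqn{\partial x(t)/\partial\theta}.
#' The area under \eqn{|\partial x/\partial\theta|} summarizes each
#' species' overall sensitivity.
#'
#' @param model a validated [KineticModel].
#' @param settings a [SimulationSettings].
#' @param parameter a flat parameter id (see [modelParameters()]).
#' @param perturbation relative perturbation (default 0.01).
#' @return list with `time`, `sensitivity` (time x species matrix of
#'   \eqn{\partial x/\partial\theta}) and `auc` (named numeric).
#' @export
localSensitivity <- function(model, settings, parameter, perturbation = 0.01) {
    theta <- modelParameters(model)
    if (!parameter %in% names(theta))
        stop("parameter '", parameter, "' does not exist")
    t0 <- theta[[parameter]]
    h <- perturbation * max(abs(t0), 1e-8)
    up <- setModelParameters(model, stats::setNames(t0 + h, parameter))
    dn <- setModelParameters(model, stats::setNames(max(t0 - h, 0), parameter))
    step <- (t0 + h) - max(t0 - h, 0)
    trp <- simulateDeterministic(up, settings)
    trm <- simulateDeterministic(dn, settings)
    internal <- model@species$id[!model@species$boundary]
    sens <- (concMatrix(trp)[, internal, drop = FALSE] -
             concMatrix(trm)[, internal, drop = FALSE]) / step
    auc <- apply(abs(sens), 2L, function(col) pracma::trapz(timeGrid(trp), col))
    list(time = timeGrid(trp), sensitivity = sens, auc = auc)
}
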