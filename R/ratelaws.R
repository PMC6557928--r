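#' Michaelis-Menten rate
#'
#' Irreversible single-substrate Michaelis-Menten kinetics
#' \eqn{v = V_{max} S / (K_m + S)}: the rate law used for every intracellular
#' enzymatic reaction in the shipped model. At \eqn{S = K_m} the rate is half
#' of \eqn{V_{max}}; the flux is bounded above by \eqn{V_{max}}.
#'
#' @param vmax maximal rate, mmol/min/ml (> 0).
#' @param km Michaelis constant, mmol/ml (> 0).
#' @param s substrate concentration, mmol/ml (>= 0); vectorized.
#' @return flux in mmol/min/ml.
#' @examples
#' mmRate(2, 0.5, 0.5)   # half-saturation: 1
#' @export
mmRate <- function(vmax, km, s) {
    if (!is.numeric(vmax) || any(!is.finite(vmax)) || any(vmax <= 0))
        stop("mmRate: vmax must be positive and finite")
    if (!is.numeric(km) || any(!is.finite(km)) || any(km <= 0))
        stop("mmRate: km must be positive and finite")
    if (!is.numeric(s) || any(!is.finite(s)) || any(s < 0))
        stop("mmRate: substrate concentration must be >= 0")
    vmax * s / (km + s)
}

#' Generalized mass-action rate
#'
#' Power-law kinetics \eqn{v = k \prod_i c_i^{g_i}} with possibly non-integer
#' kinetic orders: the rate law used for transport reactions. A zero
#' concentration with positive order gives zero flux; a zero concentration
#' with negative order is a singularity and is rejected.
#'
#' @param k rate constant (>= 0).
#' @param concentrations numeric vector of concentrations, mmol/ml (>= 0).
#' @param exponents kinetic orders, same length as `concentrations`.
#' @return flux in mmol/min/ml.
#' @examples
#' gmaRate(2, 3, 1)            # first order: 6
#' gmaRate(1, 4, 0.5)          # fractional order: 2
#' @export
gmaRate <- function(k, concentrations, exponents) {
    if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
        stop("gmaRate: k must be a single finite number >= 0")
    if (any(!is.finite(concentrations)) || any(concentrations < 0))
        stop("gmaRate: concentrations must be >= 0")
    if (length(concentrations) != length(exponents))
        stop("gmaRate: concentrations and exponents differ in length")
    zero <- concentrations == 0
    if (any(zero & exponents < 0))
        stop("gmaRate: zero concentration raised to a negative exponent")
    if (any(zero & exponents > 0)) return(0)
    k * prod(concentrations[!zero | exponents != 0]^exponents[!zero | exponents != 0])
}

## Net evaluation of one rate law at a named state. `activity` is the enzyme
## activity multiplier (FCC perturbations scale the whole law, forward and
## reverse, consistent with vmax = kcat * [E]).
.evalLaw <- function(law, state, activity = 1) {
    if (is(law, "MichaelisMentenLaw")) {
        if (is.na(law@vmax) || anyNA(law@km))
            stop("configuration error: rate law has unassigned (NA) parameters")
        s <- state[names(law@km)]
        if (anyNA(s)) stop("rate law references unknown species: ",
                           paste(names(law@km)[is.na(s)], collapse = ", "))
        v <- law@vmax * prod(s / (law@km + s))
        if (law@vmaxr > 0) {
            p <- state[names(law@kmr)]
            v <- v - law@vmaxr * prod(p / (law@kmr + p))
        }
        return(activity * v)
    }
    if (is(law, "MassActionLaw")) {
        if (is.na(law@k))
            stop("configuration error: rate law has unassigned (NA) parameters")
        cf <- state[names(law@exponents)]
        if (anyNA(cf)) stop("rate law references unknown species: ",
                            paste(names(law@exponents)[is.na(cf)], collapse = ", "))
        v <- gmaRate(law@k, unname(cf), unname(law@exponents))
        if (law@kr > 0) {
            cr <- state[names(law@rexponents)]
            v <- v - gmaRate(law@kr, unname(cr), unname(law@rexponents))
        }
        return(activity * v)
    }
    stop("unknown rate-law class: ", class(law))
}

## Analytic scaled elasticities of one law wrt every species it references.
## Returns named numeric; NA where v = 0 makes the scaling degenerate.
.lawElasticities <- function(law, state, v) {
    out <- numeric(0)
    if (is(law, "MichaelisMentenLaw")) {
        for (sp in names(law@km)) {
            s <- state[[sp]]
            ef <- law@km[[sp]] / (law@km[[sp]] + s)   # d ln(sat)/d ln s
            if (law@vmaxr == 0) {
                out[sp] <- ef
            } else {
                vf <- law@vmax * prod(state[names(law@km)] / (law@km + state[names(law@km)]))
                out[sp] <- if (v == 0) NA_real_ else vf * ef / v
            }
        }
        if (law@vmaxr > 0) {
            vr <- law@vmaxr * prod(state[names(law@kmr)] / (law@kmr + state[names(law@kmr)]))
            for (sp in names(law@kmr)) {
                p <- state[[sp]]
                er <- law@kmr[[sp]] / (law@kmr[[sp]] + p)
                prev <- if (sp %in% names(out)) out[[sp]] else 0
                out[sp] <- if (v == 0) NA_real_ else prev - vr * er / v
            }
        }
        return(out)
    }
    if (is(law, "MassActionLaw")) {
        if (law@kr == 0) {
            # pure power law: elasticity equals the kinetic order, state-free
            return(law@exponents)
        }
        vf <- gmaRate(law@k, unname(state[names(law@exponents)]), unname(law@exponents))
        vr <- gmaRate(law@kr, unname(state[names(law@rexponents)]), unname(law@rexponents))
        sps <- union(names(law@exponents), names(law@rexponents))
        for (sp in sps) {
            g <- if (sp %in% names(law@exponents)) law@exponents[[sp]] else 0
            h <- if (sp %in% names(law@rexponents)) law@rexponents[[sp]] else 0
            out[sp] <- if (v == 0) NA_real_ else (g * vf - h * vr) / v
        }
        return(out)
    }
    stop("unknown rate-law class: ", class(law))
}

.lawSpecies <- function(law) {
    if (is(law, "MichaelisMentenLaw"))
        return(union(names(law@km), names(law@kmr)))
    union(names(law@exponents), names(law@rexponents))
}

#' Rate-law constructors
#'
#' `mmLaw()` builds a [MichaelisMentenLaw] (product-of-saturations form when
#' `km` has several named entries); `gmaLaw()` builds a [MassActionLaw].
#'
#' @param vmax,km forward Michaelis-Menten parameters; `km` must be named by
#'   driving-substrate species id.
#' @param vmaxr,kmr optional reverse part.
#' @param k,exponents forward mass-action parameters; `exponents` named by
#'   species id.
#' @param kr,rexponents optional reverse part.
#' @param modifiers modifier species ids.
#' @return a [RateLaw].
#' @examples
#' mmLaw(vmax = 2, km = c(glucose = 0.5))
#' gmaLaw(k = 0.1, exponents = c(acetate = 1))
#' @export
mmLaw <- function(vmax, km, vmaxr = 0, kmr = numeric(), modifiers = character()) {
    new("MichaelisMentenLaw", vmax = vmax, km = km, vmaxr = vmaxr, kmr = kmr,
        modifiers = modifiers)
}

#' @rdname mmLaw
#' @export
gmaLaw <- function(k, exponents = numeric(), kr = 0, rexponents = numeric(),
                   modifiers = character()) {
    new("MassActionLaw", k = k, exponents = exponents, kr = kr,
        rexponents = rexponents, modifiers = modifiers)
}
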