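---
title: "Kinetic modeling of Stickland-reaction-coupled methanogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modeling of Stickland-reaction-coupled methanogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SRCMkinetics)
```

## The system and the model

Protein-rich waste streams are degraded anaerobically in two trophic stages:
an acidogenic *Clostridium* (here abbreviated CAC) hydrolyzes gelatin and
ferments the released amino acids — glycine and alanine dominating, coupled
pairwise as Stickland donor/acceptor — to acetate, ammonia, formate and CO2;
an aceticlastic *Methanosarcina* (MAC) then converts the excreted acetate to
methane. Neither organism performs the full conversion alone: the two cells
plus the shared medium form an obligate syntrophy.

The package represents this as a compartmental kinetic model. The state
vector x(t) collects all metabolite concentrations (mmol/ml); its dynamics
are the mass balance

$$\frac{dx}{dt} = S\,v(x(t), u(t), \theta),$$

with S the stoichiometric matrix over the *internal* species, v the reaction
rates, u(t) the clamped boundary species and theta the kinetic parameters.
Two rate-law families cover every reaction:

* **Michaelis–Menten** for intracellular enzymatic steps,
  $v = V_{max}\,S/(K_m+S)$, extended to multiple driving substrates as a
  product of saturation terms. This presumes enzyme << substrate and rapid
  equilibrium binding; co-substrates held constant (see boundary species) are
  absorbed into $V_{max}$.
* **Generalized mass action** (power law, possibly non-integer orders) for
  membrane transport, $v = k \prod_i c_i^{g_i}$. The shipped transporters are
  first order in their source-side substrate.

Reactions are irreversible by default (flux floored at zero); a reaction
declared reversible evaluates a net two-term law and may carry negative flux.

### Compartments, units, boundary and sink species

All compartments have unit volume, so concentration balance and amount
balance coincide; concentrations are mmol/ml, fluxes mmol/min/ml, time in
minutes, the unit convention used throughout. Three species
roles matter:

* **boundary** species are clamped at their initial value and excluded from
  the mass balance. They implement the input vector u(t): the gelatin-derived
  feed when run as a chemostat, dissolved H2 in the medium, and the conserved
  cofactor pools (NAD(H), CoA, ATP/ADP, thioredoxin, ferredoxin, F420) and
  enzyme species, for which no synthesis/turnover kinetics are available.
  Enzymes enter rate laws only through $V_{max} = k_{cat}[E]$; they are
  carried as explicit modifier species at constant concentration so the
  census and the SBML export see them.
* **sink** species are terminal accumulation pools (exported CH4, CO2, CO,
  ammonia, pyruvate overflow). In batch mode they accumulate freely; a
  chemostat-style scenario clamps them, which removes the zero eigenvalues
  they would otherwise contribute and makes a steady state well defined.
* everything else is an ordinary internal state variable.

### The shipped SRCM network

`srcmModelPath()` points to the packaged YAML definition of the network:
7 CAC reactions with 24 CAC metabolites, 11 MAC reactions with 37 MAC
metabolites, and 6 transport reactions on each membrane. The reaction-id map
anchors the well-established steps (R1
alanine route, R2/R3 glycine routes, R5/R6 acetate synthesis, R8 acetyl-CoA,
R9 CO/CO2, R13 methane synthesis, R14 heterodisulfide reduction, M15
coenzyme M); the remaining assignments (R4 pyruvate dehydrogenase, R7
pyruvate formate-lyase, R10–R12 methyl transfer, M16–M18 ancillary
electron/energy steps) are inferred and flagged as such in the model file.
Two deliberate choices deserve emphasis:

* **Glycine reductase stoichiometry.** Reduced thioredoxin and ATP are the
  redox/energy partners of this step, but the coefficients had to be
  chosen. R3 is modeled as glycine + Pi + Trx(red) -> acetyl
  phosphate + NH3 + Trx(ox), with acetate kinase (R6) completing the
  substrate-level phosphorylation — the textbook selenoprotein mechanism.
* **CO dehydrogenase direction.** "CO/CO2 handling" is ambiguous about
  direction. R9 is modeled in the CO2-reducing direction,
  CO2 + H2 -> CO + H2O, so that it draws on the same H2/electron budget as
  heterodisulfide reduction (R14) and the F420-reducing hydrogenase (M16).
  This couples CO handling to methanogenesis through an explicit resource
  competition: pushing flux toward methane starves R9 of H2. That competition
  is the mechanism behind the optimization result below, rather than any
  assigned outcome.

The census convention counts transport reactions per membrane (each
transporter belongs to both compartments it connects, hence "6 per
compartment" for the two cellular compartments), counts medium-owned shared
metabolites in the medium only, and counts constant-concentration enzyme
species toward their compartment's metabolite tally. Proline, released from
gelatin but not catabolized in this network, is a boundary dead end in the
medium.

### Parameters

No experimentally measured kinetic-parameter set exists for this
co-culture, so the package ships a clearly synthetic stand-in
(`defaultParameterTable()`): Michaelis constants 0.2–2 mmol/ml and maximal
rates 0.05–2.5 mmol/min/ml for the enzymatic steps, first-order transport
constants 0.02–0.5 per minute, and initial pools of 0.01–1 mmol/ml for
intermediates with carrier pools (H4SPT, corrinoid, CoM, CoB) around
0.5–1 mmol/ml. These were chosen once, as physiologically plausible orders
of magnitude that put the simulated methane-synthesis flux in the 0.1–0.2
mmol/min/ml range, and are not tuned thereafter. Every numeric result that
depends on them is therefore a property of this synthetic parameterization,
not a measurement of the real co-culture.

## Simulation

`simulateDeterministic()` integrates the mass balance with a
stiffness-switching adaptive method (`deSolve::lsoda`), output sampled on a
regular grid with default spacing 1.0 min and an internal step budget of
10,000 — the batch protocol the network is meant to be run under. Default
tolerances are rtol 1e-8, atol 1e-12; trajectories are invariant to 1e-6
under tolerance halving (tested). Outputs marginally below zero are projected
to zero and counted on the returned object.

`simulateStochastic()` implements the Gibson–Bruck next-reaction method in
compiled code: one putative firing time per reaction in an indexed binary
heap, propensities refreshed through a precomputed dependency graph, exact
ties resolved toward the lowest reaction index for reproducibility. Copy
numbers are `round(concentration * omega)`; propensities reuse the
macroscopic laws evaluated at n/omega and scaled by omega — exact for
elementary mass action, the standard mean-field approximation for
Michaelis–Menten laws. Reversible net laws are rejected (a net two-term law
is not a propensity). One RNG stream derives from the seed; replicate r of a
replicate study uses seed + r. Identical seed and settings give bit-identical
trajectories.

## Steady states and metabolic control analysis

`findSteadyState()` solves S v(x) = 0 by damped Newton iteration
(finite-difference Jacobian with per-coordinate step max(1e-8, 1e-6|x|),
backtracking line search, non-negativity projection), falling back to
long-time integration plus a Newton polish; the accepted residual norm is
1e-9. Stability is the eigenvalue criterion on the internal Jacobian block.

Elasticities are computed analytically: Km/(Km+S) per saturation factor for
MM laws, the kinetic order for pure power laws, flux-weighted combinations
for net reversible laws. A scaled elasticity at zero flux is reported as NA
rather than silently zeroed, because the scaling x/v is degenerate there.
Flux control coefficients perturb whole enzyme activities (both directions
of a reversible law scale together, consistent with Vmax = kcat [E]) by a
relative 1% by default, re-solve the steady state, and difference centrally;
each entry is re-estimated at half and double step and flagged when the two
disagree by more than 5%. The summation and connectivity theorems on closed-
form toys serve as correctness oracles in the test suite. The 1% step is a
documented choice — the original protocol does not state one — so
control-coefficient claims in this package are property-based (theorems,
signs), not value-based.

## Flux optimization

The optimization objective scalarizes "maximize methane synthesis, minimize
glycine/alanine catabolism" as

$$J = w_{max} \sum_{j \in max} v_j - w_{min} \sum_{j \in min} v_j$$

with default weights 1.0 and 0.1 (there is no principled unique choice;
both are configuration-exposed). The shipped decision variables are the
maximal activities of R3, R5, R9, R11 and R13, each bounded to [0.2x, 5x]
its table value. Each candidate is evaluated "with the ODE": the model is
integrated under the clamped alanine–glycine pair scenario to a 200-min
horizon, and the objective reads the fluxes at the end state — the steady
state when the candidate converges, the pre-steady-state batch snapshot when
some step is saturated and pools still grow. No FBA-style LP is involved;
the model is kinetic, not constraint-based. The search is derivative-free
bounded multistart Nelder–Mead on a sine-transformed box with a final
restart from the incumbent, deterministically seeded, and the reported
optimum is never worse than the starting point. Under this setup the
optimizer raises the methane-synthesis flux while the glycine-reductase flux
falls (its activity is penalized and its carbon cannot reach methane past
the saturated downstream steps) and the CO-dehydrogenase flux falls (it
loses the competition for H2 against heterodisulfide reduction) — the
qualitative robustness pattern the model family is known for.

## Parameter estimation

`fitParameters()` minimizes concentration residuals at the observation times
with bounded Levenberg–Marquardt (`minpack.lm`), optionally on log1p scale.
Multistart matters: the classic single-substrate MM recovery problem has a
correlated Vmax/Km valley ending in a boundary local minimum, and a lone
start from a distant guess lands there. Starts beyond the first are drawn
log-uniformly over the (positive) bounds — kinetic constants live on decade
scales — which makes recovery robust across seeds; with six starts the
noiseless MM toy is recovered to better than 1e-3 relative error, and under
5% multiplicative noise — fitted with log-scale residuals, the natural
likelihood for that noise model, which re-weights the informative
low-concentration tail — the median relative error over replicate fits stays
below 10% (both tested). Candidates on which the integrator fails are
rejected with a large penalty and logged.

## Synthetic data

`generateParameterTable()` draws complete parameter assignments log-uniformly
(Km in 0.01–10 mmol/ml, Vmax in 0.1–10 mmol/min/ml, transport k in 0.01–10
per min, initials in 0.05–5 mmol/ml; enzymes fixed at 1 so table Vmax values
are effective activities). `generateObservations()` adds independent
multiplicative lognormal noise with a given coefficient of variation,
mean-preserving, truncated at zero — the standard error model for positive
concentrations spanning decades; additive Gaussian noise would produce
negative values and overweight large pools.

What the generator emulates: per-reaction kinetic constants in the model's
units, a gelatin-hydrolysate feed with the fixed glycine/proline/alanine
composition (21.4/12.4/8.9% of amino-acid units), and replicate noisy time
courses for estimation studies. What it does not emulate: real digester
measurement error structure (autocorrelation, batch effects, detection
limits), gas–liquid partitioning of CH4/CO2, and biomass growth. Passing
recovery tests on these data therefore demonstrates the estimator's
correctness, not field-data performance.

One limitation surfaced by the generator is worth stating plainly: under the
ranges above, a randomly parameterized SRCM network run as a clamped-feed
chemostat almost always has at least one saturated step, so pools grow
without bound and no stable steady state exists. The seed-panel test
accordingly asserts the property that does hold — batch integration
completes with finite, non-negative trajectories on the whole panel — and
steady-state analysis is reserved for the shipped parameterization and for
toys.

## Problem sizes and numerical choices used in the tests

The test suite and the acceptance script use: closed-form toys of 1–3
species; 100 stochastic replicates at omega = 1e5 (two-step chain) and 1000
replicates of the pure death process for moment checks; 50-point MM time
courses with a 12-start noiseless fit and 20 replicate noisy fits at 6
starts each; and the full 72-
species, 30-reaction SRCM network for census, round-trip, time-course and
optimization runs (200-min horizon, about 900 objective evaluations). These
sizes give stable verdicts for every stochastic check while keeping a full
run in the minutes range.

## Known limitations

* The network is a curated reconstruction: reaction ids beyond the anchored
  subset and all parameter values are documented inferences, since no
  authoritative reaction or parameter tables exist for this co-culture.
  Quantitative flux values measured on the real system are consequently out
  of reach; the package fixes the structure exactly and reproduces dynamic
  behavior qualitatively.
* Michaelis–Menten propensities in the stochastic simulator are a mean-field
  approximation; at very small copy numbers of an enzyme-bound intermediate
  the next-reaction trajectories are exact only for the mass-action subset.
* No thermodynamic feasibility checking, no biomass/growth coupling, no
  aspartate/glutamate catabolism branch, and no COPASI/CellDesigner file
  parsing (SBML L3V1 is the interchange route).
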