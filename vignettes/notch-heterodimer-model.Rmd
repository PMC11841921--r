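---
title: "Models and methods: DLL4/JAG1 competition, Notch-VEGF feedback, and tip/stalk patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(notchsim)
```

## The biological question

During sprouting angiogenesis, endothelial cells at the vascular front
differentiate into migratory tip cells and trailing stalk cells. Two
Notch ligands steer this decision in opposite directions: DLL4 restrains
sprouting while JAG1 promotes it. `notchsim` implements a mechanistic
explanation built on two biochemical asymmetries between the ligands:

1. **Trans asymmetry.** DLL4 presented by a neighbouring cell activates
   Notch1 efficiently; JAG1 does so only weakly. The model carries this
   as the affinity ratio `alpha` multiplying every trans-JAG1 term
   (`alpha = 1e-4` at baseline; `alpha = 0` makes trans-JAG1 inert,
   `alpha = 1` makes the ligands equivalent).
2. **Cis asymmetry.** Cis-inhibition of Notch1 is carried out by DLL4
   *homodimers* (species `C`). JAG1 cannot homodimerize, but binds DLL4
   monomers into an inactive DLL4–JAG1 heterodimer at rate `khe`. JAG1
   therefore depletes the pool from which the inhibitory homodimer is
   built: it antagonizes DLL4 without touching the receptor.

## Model variants

All variants use mass-action kinetics in molecules per cell and hours.

* **Ligand-competition model** (`rhs_model1`): species `D, J, C, N, S`.
  Production at constant rates `bD, bJ, bN`; first-order decay at `beta`
  (`betaS` for the signal `S`); homodimerization removes two `D` per
  `C` formed; heterodimerization removes one `D` and one `J` (the
  complex is inert and is not tracked); trans-binding consumes ligand
  and receptor and releases Notch activity `S`.
* **Notch–VEGF model** (`rhs_model2`): adds VEGFR2 `R` and VEGFR2
  activity `V`. Local free VEGF binds `R` at rate `kv`, producing `V`;
  `V` upregulates DLL4 production through
  `H(V; theta_D = 200, lam_D = 10, n_D = 2)` and Notch activity
  suppresses VEGFR2 production through
  `H(S; theta_R = 30, lam_R = 0, n_R = 2)` — a complete shutdown at
  saturating `S`, which closes the lateral-inhibition loop. With
  `bR = 0` and `R(0) = V(0) = 0` the model reduces exactly to the
  ligand-competition model (tested to 1e-9 per step).
* **Reversible heterodimer variant** (`rhs_reversible`): tracks the
  complex `DJ` explicitly with association/dissociation rates
  `kplus`/`kminus` and decay `beta`. Its ligand steady state coincides
  with the irreversible model at the effective rate
  `khe = beta * kplus / (beta + kminus)`
  (`reversible_equivalent_khe()`), which the tests verify over random
  rate pairs. The irreversible models are therefore not a loss of
  generality at steady state.

One printed-model discrepancy had to be resolved: the ligand-competition
model's `S` equation is written in one place with decay proportional to
`N` and in the VEGF model with decay proportional to `S`. We use
`-betaS * S` in both variants: `S` is a decaying readout of cleavage
events, and a decay proportional to `N` has no biochemical reading here.

## Steady-state analysis

At steady state the `D`/`J` balances close onto a monic cubic in the
steady free-DLL4 level (`ligand_cubic()`), with composites
`A1 = (beta + kt*Next)/(2*kho)`, `B1 = (beta + alpha*kt*Next)/khe`,
`A2 = (beta + kt*Next)/khe`, `B2 = 2*kho/khe^2`, and a mirror cubic in
JAG1. `solve_ligand_steady_state()` finds the roots via
companion-matrix eigenvalues followed by a Newton polish — closed-form
cubic formulas lose precision when the coefficients span several orders
of magnitude, as they do here. JAG1 is recovered from its own linear
balance, and the pair must zero both original equations to within
`1e-6 * max(bD, bJ)`. When more than one nonnegative root qualifies,
the root reached by integrating the dynamics from the empty state breaks
the tie; the implicit-function analysis guarantees a consistent branch
but does not by itself exclude multiple positive cubic roots, so the
dynamical tie-break is our construction. At `khe = 0` the ligands
decouple and the quadratic/linear solutions are used directly (the
cubic is undefined there).

Two closed-form limits anchor the analysis. For
`khe >> max(beta + kt*Next, kho)` the ligands mutually inactivate:
if `bD > bJ` then `Jbar = 0` and
`Dbar = sqrt((p/(4 kho))^2 + (bD-bJ)/(2 kho)) - p/(4 kho)` with
`p = beta + kt*Next`; if `bJ > bD` then `Dbar = 0` and
`Jbar = (bJ - bD)/(beta + alpha*kt*Next)`. At the finite rate
`khe = 0.1` used in the strong-heterodimerization scenarios the limit
is close but not exact: with `(bD, bJ) = (100, 50)` the surviving DLL4
sits at 309.7 vs the limit's 309.0, while the "extinguished" JAG1
retains 1.61 molecules (`bJ/(beta + khe*Dbar)`), not 0. The package
reports these finite-rate values; the limit formulas are exposed
separately as `strong_het_limit()`.

Monotonicity of the steady ligands in the production rates — each
ligand rises with its own rate and falls with the other's, the sign
pattern `(+, -, -, +)` — follows from the implicit function theorem and
is checked numerically by central differences
(`ligand_monotonicity()`), with a noise floor below which a sign is
reported as indeterminate rather than guessed.

## Numerical integration

All trajectories use the classical fixed-step fourth-order Runge–Kutta
scheme. Defaults: `h = 0.01` h, `t_end = 1000` h, steady-state
detection at `max |dx/dt| < 1e-6` molecules/h checked every 100 steps.
The fastest baseline rate is `kv * Vext = 0.125`/h, so `h = 0.01`
resolves every timescale with a wide margin; the order-4 convergence of
the integrator is verified against the exponential closed form.
Floating-point negative excursions above `-1e-9` are clipped to zero;
anything more negative, or any NaN/Inf, aborts with the failure time —
clipping must not mask a genuine blow-up. Clamped species
(`clamps` argument) are reset after every step, which implements the
fixed-sender/fixed-receiver assay configurations.

Single- and two-cell work uses the R integrator (`rk4_integrate`),
which accepts arbitrary derivative closures; lattice simulations use a
compiled stepper with identical arithmetic (the two paths agree to
1e-8 on the same problem, which is tested). Trans inputs are recomputed
at every RK4 *stage* from the stage state, so the coupled system is
integrated consistently at O(h^4) rather than with per-step frozen
coupling.

## Multicellular geometry and the VEGF field

Cells tile a pointy-top hexagonal lattice of side 1, odd rows offset by
half a cell (row spacing 1.5, column spacing sqrt(3)); the geometry
fixes only regular hexagons of side 1, and this layout satisfies it.
Free VEGF decays exponentially behind the front row:
`V(y) = Vext * exp(-a (y - y0))` with `Vext = 2500` molecules and
sharpness `a = 1` by default; a line of cells represents the front
itself and sees uniform `Vext`. The gradient-sharpness scenario
(`s6_gradient_sharpness`) defaults to `a in {1/2, 1/5, 1/35}` — values
below 1 probe progressively shallower fields; the exact values drawn in
the corresponding supplementary panels are ambiguous in the source
text, so they are exposed as configuration rather than fixed.

Trans inputs are neighbour averages. The default `"slots"` rule reads
the Dirichlet-0 boundary literally: every cell divides by its full slot
count (6 for hexagons, 2 for a line) and off-lattice slots contribute
zero ligand, so edge cells genuinely see less trans input. The
alternative `"truncate"` rule divides by the realized neighbour count;
both are implemented because the published description admits either
reading. Note that only `"truncate"` preserves a perfectly uniform
state on a finite sheet — under `"slots"` the boundary itself breaks
the symmetry, which is intended. Two-cell analyses use pure pairwise
exchange (each cell's trans input is the other cell's level), the
1-neighbour case of the same rule.

Initial states are drawn independently per cell and species from
U(0, 100) molecules with a mandatory seed: the published setup says
only "random", and a uniform draw at the scale of the fastest-equilibrating
species is the conventional choice. Identical `(lattice, parameters,
seed)` triples are bit-reproducible, which the tests enforce.

Tip/stalk classification thresholds VEGFR2 activity at the population
midpoint `(min V + max V)/2`; when the population range is under 5% of
the maximum the state is called uniform and no tips are reported. The
front-alternation index is the fraction of adjacent front-row pairs
with differing labels (1 = perfect salt-and-pepper, 0.5 = coin-flip
expectation, 0 = uniform front).

## Two-cell equilibria and continuation

`find_equilibria()` is a multistart damped-Newton solver with
finite-difference Jacobians: starts are the forward-integrated
attractor from the empty state, the homogeneous equilibrium solved on
the symmetric subspace, symmetry-broken perturbations of it, and seeded
random states; converged roots are merged at 1e-4 relative distance,
classified stable/unstable/marginal by Jacobian eigenvalue real parts
(margin 1e-6/h), and homogeneous/heterogeneous at 1e-6 relative
cell-block difference. Because the coupled system is exchange-symmetric,
the cell-swap of every root is added explicitly, so heterogeneous
equilibria always appear as swap pairs with identical spectra.

`continue_branch()` is natural-parameter continuation: a parameter
grid, Newton warm-started from the previous grid point's equilibria,
plus fresh multistarts to catch branch births; intervals where the
stable-equilibrium count changes are recorded as events. Pseudo-
arclength continuation was deliberately not implemented: over the
parameter ranges analysed the branches are single-valued in the swept
parameter, and the multistart sweeps recover coexisting attractors
without fold-following. This is a known limitation for general use.

The measured bifurcation structure of the two-cell Notch–VEGF system
without heterodimerization is richer than a single bistable window: a
narrow low-`bD` window with a stable heterogeneous pair (homogeneous
state unstable), a monostable stretch, then a broad window in which the
stable heterogeneous pair coexists with one — and in part of the range
two, via a homogeneous fold — stable homogeneous states, closing to a
single homogeneous attractor at very high `bD`. With `khe = 0` this
entire diagram is independent of the JAG1 production rate (verified
identically across `bJ`); with heterodimerization on, the window edges
move with `bJ` — the ligand coupling is what lets JAG1 tune the
patterning regime.

`phase_diagram()` reduces each `(Jext, alpha)` pair to a Boolean:
does a stable heterogeneous equilibrium exist? That is the operational
definition of "patterning" used for the trans-JAG1/affinity phase
diagram; at `alpha = 0` the external JAG1 column is provably inert
(it enters the equations only as `alpha * kt * Jext`).

## Scenario registry

Every in-silico experiment is a named, seeded, configuration-overridable
scenario (see `list_scenarios()`), writing CSV tables (doubles at 17
significant digits, so files round-trip exactly), a JSON summary and
the resolved configuration. Quantities that the experimental setups fix
only qualitatively are exposed as configuration with documented
defaults rather than hard-coded:

* the clamped sender-ligand level and dose ranges of the cis/trans
  assays (`dext = 1000`; production sweeps to 2000 molecules/h — the
  cis-inhibition assay needs several-fold-over-baseline DLL4 production
  before homodimer inhibition dominates, and the assay is about the
  inhibited regime);
* the receiver clamp of the trans assays (Notch fixed at its solo
  steady level `bN/beta = 5000`);
* the mutant-group multipliers of the line-of-cells comparison
  (0.5x, 1x, 4x on the ligand production rate for the loss-of-function,
  wild-type and overexpression groups — the source labels regions of a
  continuous ramp without printing values);
* the stripe geometry of the external-ligand experiment (two
  contiguous stripes, each a fifth of the line, additions ramping
  linearly 0 to 200 molecules along the stripe).

## Problem sizes and what the tests show

The shipped tests and scenarios use a 10 x 10 hexagonal sheet, lines of
8–20 cells, 16–21-point continuation grids and 100-draw random
parameter panels; these sizes are where the patterning statistics and
branch structure are already stable, and they keep a full run on a
single CPU comfortable. The simulations are deterministic ODE systems
with seeded random initial conditions: they emulate the signalling
logic of an idealized endothelial sheet, not cell migration,
proliferation, rearrangement, VEGF transport dynamics (the field is a
static exponential profile) or molecular noise. Passing tests therefore
validate the model's internal structure — its steady states, stability
boundaries and patterning logic — and its agreement with the analytic
limits; they do not by themselves certify quantitative agreement with
any particular tissue.
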