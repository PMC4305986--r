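---
title: "Designing genetic lysis circuits for population density control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing genetic lysis circuits for population density control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glcdesign)
```

## The problem

A genetic lysis circuit couples an inducible promoter-RBS component to a
lysis gene so that the expression level of the lysis protein — and through
it the death rate of the host population — becomes a function of an
external inducer dose. Given a library of characterized promoter-RBS
components, the design question is combinatorial: which (constitutive,
regulated) pair, over which inducer range, makes the steady-state culture
density follow a user-prescribed density-versus-inducer curve?

`glcdesign` answers this with a mechanistic steady-state model, a
Monte-Carlo account of parameter uncertainty, and a genetic-algorithm (GA)
search over the component index pairs, with an exhaustive search as the
ground-truth oracle.

## Model and assumptions

The circuit has two expression stages and one population state:

* **Stage 1** — a constitutive component of strength $P_{u,i}$ expresses
  the regulator (a repressor, or an activator such as LuxR).
* **Stage 2** — a regulated component expresses the lysis protein with
  Hill-function activity between a basal strength $P_l$ and a maximal
  strength $P_u$, driven by the *effective* regulator: the inducer
  sequesters a repressor ($x^* = x/(1+I/K_I)$) or is required by an
  activator to form the active complex ($x^* = x/(1+K_I/I)$).
* **Population** — logistic growth at rate $k$ toward carrying capacity
  $N_{max}$, minus a first-order kill term $\gamma_N N x_{l2}$.

Transcription and translation are lumped into one kinetic strength per
component, as promoter-RBS pairs are characterized as units; there is no
mRNA intermediate, no division-event stochasticity, and the same $k$ both
grows cells and dilutes intracellular protein (one shared rate). Setting
derivatives to zero yields the closed-form steady state used throughout
design, ending in $N_{ss} = N_{max}(1 - (\gamma_N/k)\,x_{l2,ss})$. The raw
formula can go negative when lysis outpaces growth; since a density cannot
be negative, `steady_state()` clamps to zero and flags the row (`clamped`),
and the clamp is applied after any steady-state noise term.

Degenerate inputs are defined by continuous limits: at $I_2 = 0$ the active
complex is zero and an activated promoter sits at its basal strength $P_l$;
a fully de-repressed promoter sits at $P_u$.

## Units and default rates

Concentrations are in nM, time in minutes, strengths in nM/min, density in
O.D. 600 — consistent with nM-range quorum-sensing inducers. No global rate
set comes with the component libraries, so the package fixes a nominal
slow-growing *E. coli* template (`circuit_template()`):

| parameter | default | meaning |
|---|---|---|
| `k` | 0.02 /min | growth & dilution rate (doubling ~35 min) |
| `gamma_reg`, `gamma_lys` | 0.01 /min | protein degradation (half-life ~70 min) |
| `Nmax` | 1 O.D. | carrying capacity |
| `gamma_N` | 5e-4 /(nM·min) | lysis rate per nM of lysis protein |

With these, densities between 0.1 and 0.7 O.D. correspond to lysis-protein
levels of a few tens of nM — a realistic expression range.

## Simulation

`simulate_circuit()` integrates the three-state model on a fixed grid:
classical RK4 when deterministic, Euler–Maruyama with additive Gaussian
increments when process noise is enabled. A fixed shared grid was chosen
deliberately so deterministic and stochastic paths are directly comparable;
an adaptive solver (deSolve) serves as an independent cross-check in the
test suite, as does the closed-form steady state (terminal states agree to
1e-6 relative over randomized circuits). States are clipped at zero after
every step, which keeps concentrations and density physical under noise.
Halving the step size moves terminal densities by less than 1e-4, so the
default `dt = 0.1` min is comfortably converged; long-horizon convergence
runs in the tests use `dt = 0.5` min and a horizon of 40 time constants of
the slowest mode.

The steady-state noise terms $v_1, v_2, v_3$ enter additively on the three
steady-state quantities. Their nominal unit variance would dwarf an O.D.
scale bounded by 1, so the package default is deliberately small
(`noise_spec()`: 0.5 nM on the protein levels, 0.01 O.D. on density) and
fully configurable — a documented deviation from a literal unit-variance
reading.

## Parameter uncertainty

Kinetic parameters in vivo fluctuate. `perturb()` replaces each parameter
$p$ by $p(1 + f z)$ with standard-normal $z$ and fractional deviation
$f = 0.05$ by default, so each parameter's SD is 5% of nominal. One noise
source is shared per expression stage and per draw — stage-1 strength with
regulator degradation, stage-2 strengths with lysis-protein degradation,
growth rate with lysis rate — so a draw is a coherent realization of
stage-wise expression noise rather than seven independent dials. Draws
whose multipliers are not all positive are rejected and redrawn, keeping
rates physical; at $f = 0.05$ the rejection region is ~20 SDs out, so the
truncation is immaterial (a warning flags $f \ge 1$, where it is not).

## The design search

The tracking cost integrates the squared deviation between $N_{ss}(S, I)$
and the prescribed response $N_{ref}(I)$ over the feasible inducer range
(default $[0.1, 10]$ nM) and averages it over the perturbation ensemble.
Numerical choices: a 25-point log-spaced grid with the trapezoidal rule on
linear $I$ (inducer responses live on a log axis; doubling the grid moves
costs negligibly), 100 draws by default, and **common random numbers** —
all candidates in one search share the same perturbation draws, so cost
differences reflect the candidates, not the Monte Carlo, and the cost is
invariant to evaluation order.

The GA encodes a candidate as its index pair, with fitness-proportional
reproduction, single-index crossover (probability 0.7), per-index uniform
mutation (0.1), and one elite. Population 20 and a 100-generation cap are
defaults chosen for libraries up to a few hundred pairs; the operators are
the standard trio, and hyperparameters were fixed once at conventional
values. Ties in the rankings break toward the lowest constitutive then
regulated index, making results stable. Fitness is regularized as
$F = 1/(J + 10^{-12})$ because $1/J$ is undefined at a perfect fit. On any
enumerable library the exhaustive search is the oracle; the tests require
the GA to attain its optimum across randomized libraries.

The inducer range is an input and the point-dose choice is closed-form:
`recommend_inducer()` inverts the reference family exactly and reports the
attainable density interval when a target is out of reach.

## The synthetic library generator and calibration

Real component libraries come from reporter-based characterization; none
ships with the package, so `generate_library()` emulates one: strengths
log-uniform across decades (default 0.05–50 nM/min), basal strengths
0.1–10% of maximal, affinities $K$ log-uniform 1–100 nM, cooperativities
uniform 1–4, inducer dissociation constants log-uniform 0.1–10 nM. These
ranges are the generator's definition of a realistic spread of weak-to-
strong parts and are fixed defaults, not tuning knobs. What the generator
does **not** emulate: correlations between promoter strength and leakiness
in real parts, context effects of assembly, extrinsic noise structure, or
measurement error in the characterization itself — so green tests certify
the method's internal consistency on libraries of this form, not bench
performance of any specific part.

`calibrate_demo_library()` plants a known-correct answer for end-to-end
validation. The key observation: with an activated component whose $K_I$
sits far above the working inducer range, the active complex is nearly
proportional to the dose, and the stage-2 Hill function in the complex
collapses to a Hill function in $I$ itself — exactly the prescribed
response family. Floor, span and midpoint matching give analytic $P_l$,
$P_u$, $K$; Nelder–Mead then minimizes the maximum relative tracking error
on a dense log grid (the planted pair lands ~4 parts in $10^5$ from the
target curve, well inside the 2% construction tolerance). The construction
is rejected and redrawn if any other pair in the random remainder comes
within 10× of the planted pair's deterministic cost, so searches against
the demo library have an unambiguous optimum.

`fit_component()` closes the characterization loop: least squares against
the matching regulation function, with $P_u$, $K$, $K_I$ fitted on the log
scale, $P_l$ as a logistic fraction of $P_u$, cooperativity bounded to
$[0.5, 6]$, and a small multi-start over affinity decades — standard
identifiability practice for Hill fits. Noise-free curves are recovered to
better than 1%; flat curves are rejected as non-identifiable.

## Problem sizes

The shipped tests run the dynamics-versus-closed-form oracle on 50
randomized circuits, the GA-versus-exhaustive identity on 20 randomized
libraries of up to 100 pairs, perturbation moments at 10,000 draws, and
monotonicity sweeps over 30 randomized circuits — sizes at which every
Monte-Carlo bound in the suite is comfortably resolved.

## Known limitations

* The steady state is the model's closed form, not a root-find of the full
  ODE: multistability or slow transients outside the logistic regime are
  out of scope (none arise in this model class).
* Additive Gaussian process noise is a coarse stand-in for intrinsic
  copy-number noise; no division events are simulated.
* Components are purely kinetic entries; no sequence-level design.
* The density equation is clamped at zero; near-extinction behavior below
  the clamp is not modeled.
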