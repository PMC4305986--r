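# glcdesign

Systematic design of synthetic **genetic lysis circuits** that hold an
*Escherichia coli* population at a prescribed density. A lysis gene placed
behind an inducible promoter-RBS component kills cells in proportion to the
lysis-protein level, so the steady-state optical density of a culture becomes
a tunable function of an external inducer dose (e.g. AHL acting through
LuxR). `glcdesign` is for synthetic biologists who want to pick, from
characterized promoter-RBS component libraries, the component pair whose
circuit best realizes a desired density-versus-inducer response — before
building anything at the bench.

## The model

Two-stage circuit, two topologies. Stage 1 is a constitutive promoter-RBS
component expressing a regulator (repressor `x_r1` or activator `x_a1`);
stage 2 is a regulated component expressing the lysis protein `x_l2`:

```
dx_reg/dt = P_c1              - (γ_reg + k) x_reg
dx_l2/dt  = P_2(x_reg*, I)    - (γ_l2  + k) x_l2
dN/dt     = k N (1 - N/Nmax)  - γ_N N x_l2
```

with Hill regulation functions

```
repressor:  P_r2 = Pl + (Pu - Pl) / (1 + (x_r1*/K)^n),  x_r1* = x_r1 / (1 + I1/KI1)
activator:  P_a2 = Pl + (Pu - Pl) / (1 + (K/x_a1*)^n),  x_a1* = x_a1 / (1 + KI2/I2)
```

Setting derivatives to zero gives closed-form steady states, ending in
`N_ss = Nmax (1 - (γ_N / k) x_l2ss)`. Design works against a prescribed
response `N_ref(I) = base + amplitude / (1 + scale · I^exponent)` (default
`0.1 + 0.6 / (1 + 2 I²)`): the tracking cost

```
J(S) = E ∫ (N_ss(S, I) - N_ref(I))² dI ,   I ∈ [0.1, 10] nM
```

is averaged over a Monte-Carlo ensemble in which every kinetic parameter
fluctuates with a 5% standard deviation, and a genetic algorithm (fitness
`F = 1/J`; reproduction, crossover, mutation, elitism over component index
pairs) searches the library for the minimizing pair `S`. An
exhaustive-search oracle, a fixed-step RK4 / Euler-Maruyama simulator, a
synthetic library generator, and characterization-curve fitting round out
the toolchain.

## Worked example

```r
library(glcdesign)

lib <- demo_library(seed = 1)       # calibrated library with a planted optimum
attr(lib, "planted")
#> constitutive    activated
#>         "C1"         "A2"

des <- ga_search(lib, demo_template(), reference_response(),
                 frac = 0.05, draws = 100,
                 settings = ga_settings(generations = 60, seed = 42))
glance(des)
#> # A tibble: 1 × 7
#>   method n_evaluated constitutive regulated best_cost best_fitness generations
#> 1 ga              27 C1           A2           0.0195         51.3          60
```

The GA evaluated 27 of the 36 possible pairs and selected `C1`/`A2` — the
pair the calibration planted. `best_cost` is the expected integrated squared
tracking error under 5% parameter fluctuations; its reciprocal is the GA
fitness. The selected circuit tracks the prescribed response to within a few
parts in 10⁵ at nominal parameters:

```r
tracking_table(des)[c(1, 13, 25), ]
#>   inducer  N_ss N_ref rel_error
#> 1     0.1 0.688 0.688 0.0000400
#> 2     1   0.300 0.3   0.0000274
#> 3    10   0.103 0.103 0.0000400
```

Dosing the built circuit: inverting the prescribed response gives the
inducer concentration for a target density, and the steady-state model
confirms the circuit lands there:

```r
recommend_inducer(reference_response(), target = 0.5)   # 0.5 nM
recommend_inducer(reference_response(), target = 0.3)   # 1 nM
steady_state(demo_circuit(lib), I = c(0.5, 1))
#>   inducer x_reg_ss x_lys_ss  N_ss clamped
#> 1     0.5       30     20.0 0.500 FALSE
#> 2     1         30     28.0 0.300 FALSE
```

A density of 0.5 O.D. 600 calls for 0.5 nM of inducer, 0.3 O.D. for 1 nM; an
observed density of 0.487 at 0.5 nM would be a `percent_error(0.487, 0.5)` =
2.6% miss. `autoplot(des)` draws the tracking curve,
`simulate_circuit()` / `inducer_sweep()` produce time-domain (optionally
stochastic) trajectories, and the `run_*()` workflows plus the `inst/cli/glc`
script drive everything from YAML configs on the command line.

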