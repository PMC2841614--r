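---
title: "The active-layer model: methods, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The active-layer model: methods, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what `activelayer` computes, the assumptions built
into its defaults, and the numerical decisions behind the implementation.
Code chunks are shown but not evaluated; the quantitative behavior of the
model is exercised by the test suite and by `scripts/acceptance.R`, which
recompute every number the package claims.

## 1. The model

`activelayer` is a two-dimensional individual-based model of a growing cell
group — a biofilm cross-section, a colony edge, or any dense cell
collective fed by diffusion — coupled to steady-state reaction–diffusion
fields for a growth substrate and an optional secreted enzyme.

**Agents.** Cells are circles with biomass `m` [fg] at areal density
`rho_area = rho * slice`, so `radius = sqrt(m / (rho_area * pi))`. Each
iteration a cell grows by one explicit Euler step `m <- m * (1 + mu * dt)`,
divides into two daughters of exactly `m/2` when its radius reaches
`r_div`, and is then pushed apart from its neighbors by hard-sphere shoving
(each overlapping pair moves half the overlap along the centre line, in
randomized sweeps, until the largest overlap is below `relax_tol`). The
domain is periodic laterally with a solid floor (`surface` condition) or
fully open (`radial` condition).

**Fields.** Substrate `G` and enzyme `E` obey steady-state
reaction–diffusion on a node-centred lattice:

```
D_G lap(G) - A * G / (K_G + G) = 0       A = sum_strains mu_max (1 - C R_E) b(E) X / Y
D_E lap(E) + sum_coop R_E * X = 0
```

with `X` the rasterized biomass concentration. The quasi-steady-state
assumption is the standard one for microbial collectives: solute diffusion
equilibrates in seconds while biomass doubles in hours, so the fields are
re-solved to steady state after every growth step. Above the group sits a
diffusion boundary layer of height `h`; beyond it the liquid is assumed
perfectly mixed, giving a Dirichlet condition `G = G_bulk` (and `E = 0`:
the bulk is an infinite enzyme sink).

**Kinetics.** Growth follows
`mu = mu_max * (1 - C*R_E) * b(E) * G / (K_G + G)`. Cooperators secrete
enzyme constitutively at specific rate `R_E`, paying the fold cost
`C * R_E` unconditionally; *any* cell whose local enzyme reaches the
threshold `tau` receives the benefit factor `b = 1 + B` (a config switch
`benefit_mode = "times_b"` gives the literal `b = B`). Cost private,
benefit shared: that asymmetry is what makes exploitation possible.

**The active-layer number.** Growth is confined to a band of depth
`~ h * delta` below the front, where

```
delta = (1/h) * sqrt(G_bulk * D_G * Y / (mu_max * rho))
```

is the inverse Thiele modulus of the group: the square of `delta` is the
coefficient of the dimensionless Laplacian after normalizing substrate by
`G_bulk`, biomass by `rho`, and length by `h`. Large `delta` (deep active
layer) means everyone grows and lineages mix; small `delta` means only a
thin front grows, lineages segregate into clonal sectors, and the front
fingers into towers. `realize_delta()` retargets `delta` by scaling
`G_bulk`, `mu_max`, or `D_G`; the model's statistics depend on `delta`,
not on which constituent realizes it (this collapse is one of the
acceptance checks).

**Metrics.** `segregation_index()` scores every metabolically active focal
cell by the activity-weighted frequency of same-color cells within
`10 * 2 * r_div` (20 um), then averages: 1 is complete segregation at the
neighborhood scale, and the quantity is a spatial relatedness coefficient
in the sense of Hamilton's rule. `front_roughness()` gives the standard
deviation of per-column front heights plus the count of empty interior
columns (tower gaps). `strain_fitness()` is `log2(N_end/N_start)/t` —
division rounds per hour — and `relative_fitness()` its ratio between
competitors.

## 2. Parameters: units, defaults, rationale

All quantities use g/L, micrometres, hours, femtograms; conveniently
1 g/L = 1 fg/um^3, so no unit conversions appear anywhere.

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `rho` | 200 | g/L | wet biomass density of a dense cell packing |
| `Y` | 0.5 | — | typical heterotroph yield, biomass per substrate |
| `mu_max` | 1 | 1/h | ~40 min doubling at saturation |
| `D_G` | 1e5 | um^2/h | small solute, matrix-hindered (~0.3e-9 m^2/s) |
| `D_E` | 2e4 | um^2/h | enzyme ~5x slower than substrate (macromolecule) |
| `h` | 6 | um | boundary layer a few cell diameters thick |
| `K_G` | 0.0035 | g/L | `K_G << G_bulk` at the default condition (ratio > 4000), making `delta = 10` genuinely saturating |
| `G_bulk` | 14.4 | g/L | realizes `delta = 10`; `G_bulk = 0.144 * delta^2` |
| `r_div` | 1 | um | division at 2 um cell diameter |
| `slice`, `spacing` | 1, 2 | um | lattice cell of one division diameter |
| `width`, `height` | 100, 112 | um | study domain; height leaves room for growth to 100 um plus the boundary layer |
| `dt_frac` | 0.05 | — | at most 5% biomass growth per Euler step |
| `tau` | 0.1 | g/L | see below |
| `B`, `C` | 3, 0.3 | — | benefit fold factor and cost scale of the social module |

**Calibration of `tau`.** The benefit threshold is set against the default
geometry: a pure-cooperator film secreting at `R_E = 1` holds roughly
2.4 g/L of enzyme throughout its active layer, so any `tau` well below
that satisfies the design rule that a cooperative group can reach its own
threshold. The default takes a few percent of that level (0.1 g/L) so that
a *single clonal sector* — secreting over only ~1/6 of the domain width,
at rates down to `R_E = 0.5`, losing enzyme laterally to the bulk sink —
can still trip its own benefit during early tower growth. A threshold near
the film-wide level (for example 1.2 g/L) is never reached by a minority
lineage in a mixed group and turns the social module off in competition.

**Founders.** Study experiments seed `n_cells = 6` founders on the 100-um
domain (~17 um apart, more than twice the `delta = 1` active-layer depth).
Sparse founding lets the low-`delta` regime express separated monoclonal
towers, inter-tower gaps, and founder-effect variance; a space-filling
lawn can only produce merged fronts.

**Competition design.** Competitions start from a 1:1 cooperator:exploiter
mixture of six founders. The focal low-`delta` secretion cell
(`delta = 1`, `R_E = 0.5`) races to 100 um, because the cooperator's
advantage builds during the tower-overtopping phase, which develops well
past the monolayer stage. The `delta = 10` arm stops at 50 um, where its
well-mixed, cost-driven outcome is already asymptotic and further growth
only moves relative fitness away from 1 (the truncation is conservative
for the expected cooperator loss). The remaining `delta = 1` cells, which
carry no headline claim, stop at 30 um to bound compute; the
`stop_heights` argument of `run_competition()` exposes all of this.

## 3. Numerical choices

* **Steady-state solver.** Damped Gauss–Seidel/SOR with Picard
  linearization of the Michaelis–Menten sink. Grids are at most a few
  thousand nodes, and warm starts from the previous iteration make SOR
  converge in a handful of sweeps, so multigrid would add complexity
  without benefit. The contract is the residual: the relative residual of
  the returned field must be below `solve_tol` (1e-6), and tests recompute
  it independently. `sor_omega = 1.92` is near-optimal for the default
  grid; it changes only the sweep count, not the solution.
* **Dirichlet at the bulk face.** The bulk value is imposed at the cell
  face between an interior node and a bulk node via the ghost value
  `2*b - C`. Face-centred Dirichlet keeps the 5-point scheme second-order
  (verified against the closed-form slab; node-centred placement degrades
  to first order by shifting the boundary half a spacing).
* **Boundary-layer geometry (`bulk_rule`).** Three constructions of "where
  the mixed liquid begins" are provided. The default `"plane"` puts the
  bulk on the horizontal plane `h` above the tallest column, so columns
  that fall behind sit farther from the source — the geometry that lets
  differential growth amplify a rough front into towers. `"contour"`
  follows each column's own front (laterally min-smoothed over `+/- h`)
  and therefore feeds troughs and crests equally, actively smoothing the
  front; `"distance"` (a dilation of the biomass by `h`) sits in between.
  The choice is a model convention, not physics; it matters most exactly
  in the low-`delta` regime the package is designed to study.
* **Conservative growth sampling.** Cells take their local `G` and `E`
  from the grid node containing their centre — the same mapping that
  deposits their biomass — so the biomass an agent adds is drawn from
  exactly the field cell whose sink represents it, and total biomass gain
  equals `Y` times field-side consumption to machine precision (tested).
  Bilinear interpolation (`sample_concentration()`) remains the
  analysis-side sampler; using it for growth leaves a small systematic
  surplus at low `delta`, because front cells interpolate richer substrate
  from above the interface than their sink consumes. Within an iteration
  the enzyme field is solved before the substrate field so the substrate
  sink capacity uses the same enzyme the cells then sample.
* **Shoving details.** Overlaps are resolved pairwise (half the overlap
  each), sweeping in randomized order with spatial binning; convergence is
  declared only after a clean full scan below `relax_tol`. Cells pushed
  under the floor are projected onto `y = radius`: exact reflection lets a
  vertically stacked floor pair cancel its own resolution and stall the
  sweep just above tolerance.
* **Time stepping.** The global step is `dt = dt_frac / max(mu)`, so the
  fastest cell grows 5% per iteration; division then resolves at better
  than one-tenth of a division time. Divisions place daughters at
  `r_child * (1 - eps_overlap)` separation along a uniform-random axis.
* **Seeding.** `replicate_seed(base, condition, replicate)` folds
  condition and replicate indices into the base seed (always below
  `2^31`), so sweeps are reproducible run-by-run and bit-identical under a
  fixed base seed (tested).

## 4. Worked example

```{r}
library(activelayer)

# the tower regime: delta = 1, six founders, grow to 50 um
p <- realize_delta(param_set(), 1)
cfg <- scenario_config(params = p, n_cells = 6, stop_height = 50)
tr <- run_simulation(cfg, seed = 1)
tr$summary$seg_index   # lineage segregation at the end of the run
tr$summary$gaps        # empty channels between towers

# the full delta sweep and the competition grid (minutes of compute)
sweep <- run_segregation_sweep(scenario_config(metrics_every = 1e9))
comp <- run_competition(scenario_config(metrics_every = 1e9))
```

## 5. Assumptions and limitations

* Two-dimensional mechanics and diffusion: quantitative values (for
  example segregation indices) will differ from 3-D systems, though the
  `delta`-controlled regimes are the same phenomenon.
* Quasi-steady fields: no transient nutrient dynamics; not suitable for
  pulse-feeding questions without modification.
* The enzyme benefit is a threshold on concentration, not an explicit
  substrate-liberating reaction: the public good raises the growth rate
  directly rather than converting a polymer into `G`.
* No death, lysis, detachment, or EPS matrix mechanics; "stalled" runs
  (no cell above the growth floor) end rather than shrink.
* Hard-sphere shoving is a mechanical relaxation, not a force model:
  positions have no inertia and the method gives packing, not stresses.
* The bulk boundary layer is a geometric convention (see `bulk_rule`
  above); all three variants are implemented, and conclusions that depend
  on the choice should be checked against more than one.
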