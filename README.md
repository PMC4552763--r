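# hemoflow

Particle-based blood flow in microvessels with **open inflow/outflow
boundary conditions**, in R (compiled Rcpp core).

Blood in arterioles is a dense suspension: red blood cells (RBCs) deform,
migrate toward the vessel center, and partition unevenly between the
branches of a bifurcation (*plasma skimming* — at high enough flow-rate
ratio the low-flow branch receives plasma only). Simulating this with
particle methods is easy under periodic boundary conditions and hard in
real, branched geometries: you cannot periodically wrap a bifurcation, and
you cannot trivially insert or remove whole deformable cells at open ends.

hemoflow implements a general open-boundary framework for multiphase
particle flows:

* **Fluid** — dissipative particle dynamics (DPD): pairwise
  `F = [a(1 - r/r_c) - γ w_D(r)(ê·v_ij) + σ w_R(r) ξ Δt^(-1/2)] ê`,
  with generalized dissipative weight `w_D = (1 - r/r_c)^s`,
  `w_R = w_D^(1/2)`, `σ² = 2γk_BT`. Reference plasma parameters:
  `a = 4, γ = 30, r_c = 1.5, k_BT = 0.0945, n = 2.96, s = 0.5`, body force
  `g = 0.1` per particle.
* **Cells** — closed triangulated membranes with worm-like-chain elasticity
  (plus the per-triangle repulsion that makes the relaxed network stress
  free), dihedral bending `k_b[1 - cos(θ - θ₀)]`, global area/volume
  constraints, and membrane viscosity with its fluctuation–dissipation
  random counterpart.
* **Walls** — frozen particles cut from an equilibrated fluid cloud plus
  bounce-back reflection (no-slip).
* **Open boundaries** — a small periodic *generating region* runs a fully
  developed pilot flow; everything crossing its downstream face (the *copy
  border*) is duplicated into the main domain (whole cells by
  center-of-mass crossing, slaved to the original until fully inside);
  ghost zones close the pilot periodically; coupling across the border is
  one-way. Each outlet carries an adaptive probabilistic membrane: crossing
  particles are reflected with probability `P` and removed otherwise, with
  `P` updated by `dP = h|ρ - ρ_t|/ρ_t` (gain `h = 0.05`) to hold the
  main-domain density at target. Cells are dissolved into fluid (in place)
  once fully inside a per-outlet deletion region; exits per branch give the
  RBC *recovery efficiency*.

All quantities are in reduced DPD units. See `vignettes/hemoflow-methods.Rmd`
for the models, parameter choices, numerical details and desk-scale caveats.

## Worked example

A scaled-down single-phase validation: develop a periodic pilot flow,
embed it as the generating region of an open tube, and check the
Poiseuille profile and the density controller.

```r
library(hemoflow)

pilot <- run_pilot(d = 8, L = 8, fluid = dpd_params(), seed = 1,
                   chunk = 4000, sample_every = 10, tol = 0.25, bins = 8)
sim <- obc_tube_simulation(pilot, main_tiles = 2, rho_target = 2.96)
sim_run(sim, 6000)                  # controller transient
sim_reset_stats(sim)
sim_run(sim, 5000, sample_every = 10)
stt <- sim_stats(sim)

mean(stt$rho)                       # main-domain number density
#> [1] 2.917477
tail(stt$P[, 1], 1)                 # outflow reflection probability
prof <- profile_from_samples(stt$profile, seq(0, 4, length.out = 9))
fit_poiseuille(prof$centers, prof$mean, d = 8, ng = 2.96 * 0.1)
```

The density sits within ~1–2% of the 2.96 target (the controller holds it
there; `P` is the adaptive reflection probability), and the fitted profile
returns the centerline velocity, apparent viscosity and R² of the
parabola. A bifurcation example:

```r
set.seed(1)
tmpl <- build_rbc_mesh(42, radius = 1.3)          # coarse RBC mesh
pilot <- run_pilot(d = 6, L = 6, hematocrit = 0.15, template = tmpl,
                   fluid = dpd_params(g = 3), seed = 301,
                   chunk = 2500, tol = 0.25)
spec <- bifurcation_spec(6, 5, theta = 70, parent_length = 8,
                         daughter_length = 6)
sim <- obc_bifurcation_simulation(pilot, spec, gfactors = c(1, 1, 1))
sim_run(sim, 30000, sample_every = 50)
recovery_efficiency(sim_stats(sim)$exits, n_branches = 2,
                    fluid_removed = sim_stats(sim)$removed_fluid)
#> <recovery_record> cells exited; fractions per branch; measured phi_d
```

There is also a thin command-line driver (`inst/cli/hemoflow`):
`hemoflow run config.json`, `hemoflow validate-poiseuille`,
`hemoflow sweep --param angle --values 50,80 config.json`, with JSON
scenario configs (`fluid:` block keys `a, gamma, r_c, kBT, s, n, g`).

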