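# gelrelease

Release kinetics of small nonionic molecules from collapsed spherical
microgels, by dynamical density functional theory (DDFT) and by
closed-form mean-first-passage-time (MFPT) theory.

Collapsed thermoresponsive microgels (e.g. PNIPAM above its volume
transition) are dense polymer spheres that transport small molecules by
the solution–diffusion mechanism. Three parameters control how fast an
encapsulated drug, reactant or probe leaves the particle: the microgel
radius *b*, the in-gel diffusion coefficient *D\** (set by the molecule's
size and shape), and the water-to-gel transfer free energy ΔG (set by its
chemistry; negative = retained). `gelrelease` is for soft-matter and drug
delivery modelers who want either the full spatiotemporal picture or a
fast analytic estimate of the release time.

The package provides:

* **Molecule parameterization** — relative shape anisotropy
  κ ∈ [0,1] from gyration-tensor eigenvalues (0 spherical, 0.25 planar,
  1 linear); the exponential size law *D\** = D₀(κ)·exp(−a_w/λ(κ));
  Stokes–Einstein conversion; the surface-area transfer-free-energy model
  ΔG = ΔG₀ + γ₀·4π(a_w + 0.233 nm)²; and a packaged registry of 15
  reference molecules (He … nitrophenol) with tabulated κ, βΔG, D\*/D_w.
* **A DDFT solver** — conservative finite-volume integration of
  ∂ρ/∂t = −(1/r²)∂(r²J)/∂r with
  J = −D_eff(r)[∂ρ/∂r + ρ∂(βu_eff)/∂r + ρ∂(βμ_ex)/∂r] on a nonuniform
  radial grid, with Carnahan–Starling excluded volume, explicit or
  implicit stepping, absorbing or reflecting outer boundary, and release
  observables f_rel(t), τ₁/₂, τ̄.
* **Analytic predictors** — the MFPT quadrature and its sharp-interface
  closed forms, culminating in the escape time
  τ̄ = b²/(15D\*) + b²·e^(−βΔG)/(3D_w) and the half-release time
  τ₁/₂ ≈ 0.497·τ̄, plus Weibull master-curve utilities
  (f = 1 − exp[−χ(t/t_s)^ν]) and a pooled-curve fitter for (χ, ν).
* **A CLI** (`inst/cli/gelrelease.R`) with `run`, `predict`, `sweep` and
  `molecules` subcommands driven by YAML configs.

## A worked example

```r
library(gelrelease)

gel  <- microgel_spec(b = 50, delta = 1)   # collapsed 50 nm particle
traj <- run_release(gel, "Me",             # methane, from the registry
                    config = solver_config("implicit"))

half_release_time(traj)
#> [1] 15548.6          # tau0 units (tau0 = 1 nm^2 / D_w)
half_release_time(traj, units = "ns")
#> [1] 2993.7           # methane's Stokes radius is tabulated, so ns work
analytic_half_release_time(50, D_star = 71e-4, D_w = 1, beta_dG = -1.88)
#> [1] 14384.4          # closed-form estimate, ~8% from the simulation
escape_time(50, D_star = 71e-4, D_w = 1, beta_dG = -1.88)
#> <MFPT (closed_form): tau = 28935.4 = 23474.2 (interior) + 5461.25 (barrier) + 0 (exterior)>
```

The numbers say: half of the loaded methane leaves the 50 nm particle
after ~1.6×10⁴ diffusion times (≈3 µs in water at 340 K); the escape-time
decomposition shows the release is diffusion-limited (interior term ~4×
the barrier term), so shrinking the particle or raising D\* matters more
than tuning ΔG.

From a shell:

```sh
Rscript inst/cli/gelrelease.R run inst/extdata/example_run.yaml out/
Rscript inst/cli/gelrelease.R predict 50 -1.88 0.0071 1
Rscript inst/cli/gelrelease.R molecules
```

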