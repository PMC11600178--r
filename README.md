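# microrheo

Passive-probe **computational microrheology** for biomolecular condensates
and other soft matter simulated at coarse-grained resolution.

Biomolecular condensates formed by intrinsically disordered proteins (IDPs)
behave as viscoelastic fluids, and their frequency-dependent elastic modulus
G'(ω) and viscous modulus G''(ω) encode how sequence changes (charge
patterning, aromatic composition) reshape condensate dynamics. In a passive
microrheology simulation a rough spherical probe is embedded in the dense
phase, its Brownian trajectory is recorded, and continuum mechanics converts
that motion into the medium's moduli. This package implements the complete
analysis chain for such simulations, plus the independent bulk (Green–Kubo)
route used to validate it, for users of residue-level hydropathy-scale (HPS)
models and similar coarse-grained force fields.

## What it computes

1. **MSD** — time-origin-averaged, multi-probe mean-square displacement
   (FFT-based, identical to the O(N²) estimator), in 3-d or restrained 2-d
   mode for spatially resolved measurements.
2. **Analytic MSD parametrization** — a BSW-style power-law relaxation
   parametrization on a fixed grid of relaxation times τ_j with fitted
   exponents α_j, anchored by the ballistic coefficient C (MSD → Ct²) and the
   diffusion coefficient D (MSD → 2dDt), with a closed-form one-sided Fourier
   transform `MSD(ω) = ∫ MSD(t) e^{-iωt} dt`.
3. **IGSER inversion** — the inertial generalized Stokes–Einstein relation:
   friction `Z*(ω) = 2 d k_B T/((iω)² MSD(ω)) − iω m_eff`, then the force
   balance `Z* = 6πR_h G*/(iω) + 6πR_h² (ρ G*)^{1/2}` solved for
   `G* = G' + iG''` (generalized Stokes drag + Basset force; probe and
   added medium inertia in `m_eff = m_bare + (2/3)πR_h³ρ`).
4. **Scalar rheology** — crossover frequency ω_c (G' = G''), relaxation time
   τ = 1/ω_c, terminal viscosity η = G''/ω with an enforced terminal-slope
   check.
5. **Green–Kubo route** — shear relaxation modulus G(t) from pressure-tensor
   autocorrelations (off-diagonal + normal-stress-difference estimator),
   Maxwell-mode fits (4 log-equidistant modes), hybrid η_GK integral, and
   closed-form moduli.
6. **Probe design** — FCC rough-sphere builder (2.12 Å lattice spacing →
   1.5 Å touching beads), gyration radius / shape anisotropy, hydrodynamic
   radius from the first probe–residue RDF peak, no-slip velocity-profile
   diagnostics, the mesh-size criterion R_h ≥ 1.5ξ (ξ from the overlap
   concentration) and the interaction window 1 ≤ ε/ε_HPS ≤ 1.5.
7. **HPS utilities** — bonded/vdW (Ashbaugh–Hatch)/Debye–Hückel pair
   energies, Kapcha–Rossky and Urry hydropathy tables, and the normalized
   sequence charge decoration (nSCD ∈ [0,1], 0 = alternating, 1 = diblock).
8. **Synthetic ground truth** — a generalized-Langevin (GLE) generator with
   exponential memory kernels integrated by an exact Gaussian one-step
   propagator, plus matched Ornstein–Uhlenbeck pressure-tensor series, so the
   whole chain can be validated against analytically known G*, τ and η.

Units are MD "real" units throughout: Å, kcal/mol, g/mol, K, ns; moduli in
kcal/(mol·Å³) (1 kcal/(mol·Å³) ≈ 6.95 GPa), frequencies in 1/ns.

## Worked example

Simulate probes in a synthetic Maxwell condensate with known rheology
(plateau G₀ = 0.01 kcal/(mol·Å³), relaxation time τ_M = 1 ns, plus a fast
solvent friction), then recover the rheology from probe motion alone:

```r
library(microrheo)

R_h <- 10                                   # hydrodynamic radius, A
model <- gle_model(
  kernel = list(type = "maxwell", zeta0 = 6 * pi * R_h * 0.01,
                tau_M = 1, zeta_n = 0.2),
  m = 1.7e5, T = 300, dt = 0.01, n_steps = 2e6, seed = 123,
  R_h_nominal = R_h, n_probes = 8)
traj <- simulate_gle(model)

cm <- compute_msd(traj)                      # 8-probe averaged MSD
keep <- cm$t <= 500
cm$t <- cm$t[keep]; cm$msd <- cm$msd[keep]
cm <- fit_limits(cm, ballistic_window = c(0.005, 0.035),
                 diffusive_window = c(20, 200))
spec <- bsw_fit(cm, n_max = 12, tau_grid = "adaptive", anchor_C = "first_lag")

omega <- 10^seq(-3, 1.5, by = 1/16)
Z   <- friction_from_msd(bsw_fourier(spec, omega), omega,
                         d = 3, T = 300, m_eff = model$m)
mod <- modulus_from_friction(Z, probe_spec(R_h, m_bare = model$m),
                             medium_spec(0, 300))
crossover(mod)$tau                           # 0.774 ns   (analytic: 0.767)
terminal_viscosity(mod, c(1e-3, 4e-3))       # 0.011085 kcal ns/(mol A^3)
gle_ground_truth(model, omega)$eta_true      # 0.011061   (exact)
```

The recovered relaxation time and viscosity agree with the analytically
known values within a few percent; the same pipeline applied to a condensate
trajectory (read with `read_trajectory()` from a LAMMPS text dump, XYZ or
CSV) yields the condensate's G'(ω), G''(ω), τ and η.

Probe design before a production run:

```r
res <- cmd_probe(list(R_b = 8, R_h = 10.6, xi = 7, eps_ratio = 1))
res$geometry$min_interbead        # 1.499 A  (2.12/sqrt(2): beads just touching)
res$criteria$size$status          # "ok"     (R_h/xi = 1.51 >= 1.5)
res$criteria$interaction$status   # "optimal"
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/microrheo` (subcommands `microrheo`, `gk`, `probe`, `synth`, YAML
configs, JSON run manifests).

## Scope

The package analyzes trajectories and stress series; it does not run
condensate MD itself (HOOMD/LAMMPS do that), does not generate NEMD velocity
profiles (it only analyzes them), and reads text formats only (LAMMPS dump,
XYZ, CSV/TSV, FASTA; no GSD).
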