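---
title: "Passive-probe microrheology of condensates: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive-probe microrheology of condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

A probe sphere embedded in a viscoelastic medium obeys a generalized
Langevin equation (GLE): its momentum change balances a memory-friction
integral over its past velocity plus a Brownian force tied to the friction
kernel by the fluctuation–dissipation theorem. In the frequency domain
(one-sided transform with kernel $e^{-i\omega t}$, used consistently
throughout the package) the friction a probe experiences in a medium of
dynamic modulus $G^*(\omega) = G'(\omega) + iG''(\omega)$ is

$$
Z^*(\omega) \;=\; \frac{6\pi R_h\,G^*}{i\omega}
\;+\; 6\pi R_h^2 \sqrt{\rho\, G^*},
$$

the generalized Stokes drag plus the Basset force from the medium's
inertia, with the added-mass part of that inertia absorbed into the
effective probe mass $m_{\rm eff} = m_{\rm bare} + \tfrac{2}{3}\pi R_h^3\rho$
(half the displaced medium mass, the unsteady-Stokes result). The friction
itself follows from the probe's mean-square displacement,

$$
Z^*(\omega) \;=\; \frac{2 d\, k_B T}{(i\omega)^2\, \widehat{\rm MSD}(\omega)}
\;-\; i\omega\, m_{\rm eff},
$$

where $d$ is the number of tracked dimensions (3, or 2 for spatially
restrained probes) and $\widehat{\rm MSD}$ the one-sided transform of the
MSD. Solving the force balance for $G^*$ — a quadratic in $\sqrt{G^*}$ when
the Basset term is present, with the $\mathrm{Re}\,\sqrt{G^*}>0$ branch
selected for passivity — is the inertial generalized Stokes–Einstein
relation (IGSER). In the inertialess Newtonian limit the chain collapses to
the Einstein relation $Z = k_BT/D$ and $G'' = \eta\omega$, which the tests
assert exactly.

Checks built into the workflow: for `rho = 0` the Basset term is dropped;
frequencies without an admissible root are masked and counted, never
silently removed.

## From trajectory to $\widehat{\rm MSD}(\omega)$

The MSD is averaged over all time origins (FFT algorithm, identical to the
direct double loop to floating-point accuracy — an invariant of the test
suite) and over probes with equal weight. Numerical transformation of a
noisy MSD is ill-conditioned, so the package fits an analytic
parametrization and transforms it in closed form, in the spirit of
power-law relaxation-spectrum (BSW-type) fits: on a fixed grid of
relaxation times $\tau_0 < \dots < \tau_{\max}$ the curve is represented as
a continuous piecewise power law

$$
{\rm MSD}(t) =
\begin{cases}
C\,t^2 & t \le \tau_0\\
g_j\,t^{\alpha_j} & \tau_{j-1}\le t \le \tau_j\\
2 d D\, t & t \ge \tau_{\max},
\end{cases}
$$

with the exponents $\alpha_j \in [0.05, 2]$ (local log–log slopes; the
ballistic slope 2 is the physical ceiling) sought numerically by minimizing
the $\chi^2$ of relative residuals on a log-spaced lag grid, so every
decade counts equally. The weights are not free: $g_1 = C\tau_0^{2-\alpha_1}$
ties the first window to the ballistic coefficient, each
$g_{j+1} = g_j \tau_j^{\alpha_j - \alpha_{j+1}}$ enforces continuity, and
the terminal diffusive amplitude coincides with the last window at
$\tau_{\max}$ exactly. When the curve carries a measured diffusion
coefficient (`fit_limits()`), the default *two-sided anchoring* makes the
last exponent dependent so the model lands exactly on $2dD t$ — the
terminal viscosity then inherits the accuracy of the D estimate rather
than of the spectral fit.

The closed-form one-sided transform of each power-law piece is an upper
incomplete gamma function of complex argument, evaluated by a Kummer
series for $|z|\le 15$ and the optimally truncated asymptotic series
beyond (both validated against arbitrary-precision references). Two
numerical choices matter:

* the diffusive asymptote $2dDt$ is transformed analytically over the whole
  half-line ($-2dD/\omega^2$) and only the compactly supported remainder is
  assembled from window integrals — otherwise the Abel-regularized tail
  ($\sim D\tau_{\max}/\omega$, orders of magnitude above the result)
  cancels against the finite windows catastrophically;
* there are no removable singularities anywhere in $\alpha\in(0,2]$ in this
  arrangement, so no series switchovers are needed.

Knot placement: the default grid is log-equidistant from the shortest lag
to half the longest; the `"adaptive"` option concentrates knots where the
smoothed log–log curvature of the data is largest (the ballistic-to-caged
elbow), which is what the validation pipeline uses. The first window opens
at the shortest lag itself so the pure-ballistic closed form never competes
with data it cannot represent.

Anchors: when the save interval resolves the ballistic regime, $C$ comes
from the least-squares ballistic fit; when the probe velocity decorrelates
within one save interval (the usual situation for Langevin-dynamics probes)
the first-lag value anchor $C=\mathrm{MSD}(t_1)/t_1^2$ is used instead
(`anchor_C = "first_lag"`).

## Scalar observables

The crossover $\omega_c$ is located on the log–log grid by a local linear
fit of $\log(G'/G'')$ around the sign change (exact for Maxwell behavior,
where that ratio is $\log \omega\tau$; it averages out parametrization
ripple otherwise); $\tau = 1/\omega_c$; absence of a crossing is reported
as no dominant elastic response, as expected for short-chain condensates.
The terminal viscosity is the mean of $G''/\omega$ over a window that must
pass a terminal-slope check ($|d\log G''/d\log\omega - 1| < 0.05$); the
default window is the lowest reliable decade.

## The Green–Kubo route

The independent bulk route estimates the shear relaxation modulus from
pressure-tensor fluctuations with the five-component symmetric-traceless
estimator,

$$
G(t) = \frac{V}{k_BT}\Big[\tfrac{1}{5}\textstyle\sum_{ab}\langle
P_{ab}(0)P_{ab}(t)\rangle + \tfrac{1}{30}\sum_{ab}\langle
N_{ab}(0)N_{ab}(t)\rangle\Big],
\qquad N_{ab} = P_{aa}-P_{bb},
$$

(off-diagonal pairs $xy, xz, yz$), which reduces to
$V\langle P_{xy}P_{xy}\rangle/k_BT$ for an isotropic equilibrium fluid with
much better statistics. The noisy tail is fitted with four non-negative
Maxwell modes log-equidistant in time (small active-set non-negative least
squares), and the viscosity is the hybrid integral: trapezoidal up to
$t_{\rm switch}$ (default: where $G$ falls below 5% of $G(0)$), analytic
mode integrals beyond.

## The synthetic ground-truth generator

`gle_model()`/`simulate_gle()` integrate the passive GLE with an
exponential (multi-Maxwell) kernel by Markovian embedding: one auxiliary
Ornstein–Uhlenbeck force per mode, whose stationary autocorrelation
$k_BT\,c_j e^{-t/\tau_j}$ realizes the fluctuation–dissipation theorem by
construction. The embedded system is linear, so the one-step propagator is
computed *exactly* (matrix exponential for the drift, Van Loan block
exponential for the one-step noise covariance) — the discretization is
exact in distribution at any step, and the spec-level bound
$dt \le \tau_M/50$ is kept as a sampling-resolution constraint. Ground
truth is analytic: $G^*(\omega) = i\omega\,\zeta^*(\omega)/(6\pi R_h)$,
$\eta = \zeta^*(0)/(6\pi R_h)$, and the exact MSD/VACF by partial-fraction
inversion of the rational Laplace transforms.

**What the generator emulates, and what it does not.** The standard fixture
(`maxwell_fixture_model()`: $G_0 = 0.01$ kcal/(mol·Å³), $\tau_M = 1$ ns,
$R_h = 10$ Å, $T = 300$ K, probe mass $1.7\times10^5$ g/mol, background
friction $\zeta_n = 0.2$ kcal·ns/(mol·Å²), $dt = \tau_M/100$,
$2\times10^6$ steps, 8 probes) mirrors a Langevin-dynamics probe in a
single-relaxation-time condensate: the plateau modulus and relaxation time
are of the order seen in coarse-grained charge-patterned IDP condensates,
and the background friction plays the role of the thermostat/solvent drag
that keeps the caged probe overdamped — without it a probe this light would
ring in its elastic cage, something never observed in condensate
simulations. Because $m/\zeta_n$ is shorter than the save interval, the
ballistic regime is represented by the first-lag anchor, exactly as in
practice. The generator does **not** emulate: multi-probe hydrodynamic
coupling (probes are independent copies, consistent with the observation
that multi-probe and single-probe MSDs coincide at volume fractions below
0.1), medium-inertia (Basset) effects on the probe (the kernel absorbs all
drag; the Basset-bearing inversion is exercised by separate algebraic
fixtures), heterogeneity, or aging. Passing the synthetic recovery
therefore shows the *analysis chain* is unbiased at realistic statistics —
not that any particular force field reproduces experimental rheology.

## Validation pipeline and problem sizes

The acceptance workflow simulates the standard fixture ($2\times10^6$
steps, 8 probes), computes the 8-probe MSD on a 30-points/decade log grid,
keeps lags up to 500 ns (a quarter of the run, before origin-averaging
statistics degrade), anchors $C$ at the first lag and $D$ on the 20–200 ns
window, fits 12 adaptive modes, inverts on
$\omega \in [10^{-3}, 10^{1.5}]$ 1/ns, and compares $\tau$, $\eta$ and the
plateau modulus (read at $5\omega_c$, where the Maxwell plateau is ~96%
developed) against the analytic truth; all three recover within 10%. The
matched Green–Kubo fixture represents the background friction as a fast
Maxwell mode ($\tau = 0.05$ ns) so both routes describe the same fluid;
$\eta_{GK}$ recovers within 15% at $10^6$ samples and the cross-route ratio
stays within [0.75, 1.25]. These sizes keep the whole validation suite in
the minutes range on one core.

## Design decisions taken where the design was open

* **Transform convention** fixed once: $e^{-i\omega t}$, so
  $\widehat{6Dt} = -6D/\omega^2$ and $\widehat{Ct^2} = +2iC/\omega^3$; all
  branch choices (Basset square root, passivity) are derived from it.
* **$\chi^2$ weighting**: relative residuals on log-spaced lags — the MSD
  spans many decades and absolute residuals would see only the diffusive
  tail.
* **Piecewise power law rather than a smooth mode superposition**: each
  window's exponent is directly the local slope, which keeps the fit
  deterministic, bounded, and interpretable; the cost is $C^0$ kinks whose
  transform ripple is handled by the local-fit crossover extraction.
* **Orthorhombic boxes only**, coordinates treated as free-space after
  `unwrap()`; wrapping exists only at I/O boundaries.
* **Histidine charge 0** by default (configurable), charges E/D = −1,
  K/R = +1; nSCD normalization by the alternating/diblock extremal
  arrangements of the same composition (verified extremal by exhaustive
  enumeration for short sequences).
* **vdW truncation without shift** at $4\sigma$ — the model definition's
  plain truncation; the discontinuity at the cutoff is intentional.
* **Mass bookkeeping**: Å/kcal·mol⁻¹/g·mol⁻¹/ns units are mutually
  inconsistent, so every dynamical formula converts masses to
  kcal·ns²/(mol·Å²) ($1\ \mathrm{g/mol} = 10^{-5}/4184$ of these); friction
  is carried in kcal·ns/(mol·Å²) with a converter to g/(mol·ns).

## Known limitations

* The piecewise parametrization cannot represent non-monotone (ringing)
  MSDs of strongly underdamped probes; such probes are outside the method's
  intended regime (and the no-slip/overdamped conditions of condensate
  simulations).
* $G'$ recovered far above the crossover degrades faster than $G''$ (it is
  the small difference-sensitive part of $G^*$); scalar observables are
  extracted near or below the crossover where both are accurate.
* The Green–Kubo mode fit assumes a completely monotone tail; oscillatory
  stress correlations (glassy or crystalline media) need a different basis.
* Trajectory readers are text-only (LAMMPS dump, XYZ, CSV); binary GSD
  files must be converted upstream.
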