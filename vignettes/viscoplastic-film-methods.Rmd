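---
title: "Models and numerics for surfactant-laden viscoplastic films in tubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerics for surfactant-laden viscoplastic films in tubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vpfilm)
```

## The physical problem

A liquid film lining the interior of a small tube is unstable to the
capillary (Rayleigh–Plateau) mechanism: axial undulations of the gas–liquid
interface lower surface energy, fluid drains into the growing lobe, and if
the film is thick enough the lobe bridges the tube and forms an occluding
liquid plug. In small human airways the lining liquid is mucus — a
yield-stress (Bingham) fluid — coated by a pulmonary surfactant monolayer.
`vpfilm` simulates this system with two reduced models of axisymmetric
Stokes flow and studies how the yield stress and the surfactant jointly
suppress or delay plug formation.

Two dimensionless groups control the liquid: the **capillary Bingham
number** $\mathcal{B} = a\tau_y/\sigma_0$ (yield stress $\tau_y$, tube
radius $a$, base surface tension $\sigma_0$) and the **Marangoni number**
$\mathcal{M} = K\Gamma_0/\sigma_0$, the relative sensitivity of surface
tension to the insoluble surfactant concentration $\Gamma$ through the
linear equation of state $\sigma = 1 + \mathcal{M}(1-\Gamma)$. Lengths are
in tube radii and times in capillary units $a\eta/\sigma_0$.

## The two models

**Long-wave model** (`long_wave_params()`, arbitrary thickness ratio
$\epsilon$): the interface radius $R(z,t)$ and concentration $\Gamma(z,t)$
evolve by
$$R_t = Q_z/R, \qquad (R\Gamma)_t + (w_s R \Gamma)_z = 0,$$
where the flux $Q$ and surface velocity $w_s$ follow from the annular
velocity profile of a Bingham fluid driven by the capillary pressure
$p = -\kappa\,[1+\mathcal{M}(1-\Gamma)]$ (with the exact curvature
$\kappa$) and the Marangoni traction $\mathcal{M}\Gamma_z$. The film
cross-section splits into fully-yielded shear layers and a plug-like region
bounded by two yield surfaces $\Psi_\pm(z,t)$; each axial station is one of
five yielding types (I internal pseudo-plug, II surface pseudo-plug, III
fully yielded, IV near-wall plug, V rigid; see `regime_map()`). Plug
formation is declared when $\min_z R \le 0.3$ and the stopping time is the
plugging time $\tilde t_p$.

**Thin-film model** (`thin_film_params()`, $\epsilon \ll 1$): with
$R = 1-\epsilon H$, times rescaled as $\tilde t = \epsilon^3 t$ and the
rescaled groups $B = \mathcal{B}/\epsilon^2$, $M = \mathcal{M}/\epsilon^2$,
the system reduces to
$$H_{\tilde t} + q_z = 0, \qquad \Gamma_{\tilde t} + (\tilde w_s\Gamma)_z = 0,$$
with the linearised pressure gradient $\tilde p_z = -H_z - H_{zzz}$ and
yield surfaces $Y_\pm = \mathrm{clip}(H + M\Gamma_z/\tilde p_z \pm
B/|\tilde p_z|)$. Plugs cannot form here, but the model exposes the
asymptotic structure: unstable runs with $2M \ge BL$ approach a
marginally-yielded static profile $H_0$ satisfying
$H_0(H_{0,z}+H_{0,zzz}) = 2B$ together with the linear static surfactant
profile $M\Gamma_0 = M - BL/2 + Bz$, with $O(1/\tilde t)$ corrections. For
asymptotically strong surfactant the interface immobilises and the dynamics
reduce to the surfactant-free dynamics with $B$ doubled and time slowed
four-fold (`evolve(..., large_M = TRUE)`); `tidy()` time series of the two
routes overlay to a few parts in $10^3$.

Both flux laws were verified against an independent oracle: direct
quadrature of the piecewise Bingham velocity profile across hundreds of
random parameter draws covering every branch, and the long-wave
flux/velocity/stress reduce to $\epsilon^4 q$, $\epsilon^3\tilde w_s$,
$\epsilon^2\tilde\tau_w$ with $O(\epsilon)$ error (tested at
$\epsilon = 10^{-3}$).

## Defaults and what they mean

| Parameter | Default | Meaning |
|---|---|---|
| `L` | $2\pi$ | domain half-wavelength; admits exactly one unstable mode |
| `N` | 200 (grids); 64–100 for long-wave production runs | nodes including both ends |
| `A` | 0.2 | initial interface perturbation amplitude |
| `Y_min` | $10^{-8}$ | yield-surface regularisation floor |
| `plug_threshold` | 0.3 | $\min_z R$ at which a plug is imminent |
| `t_end` | $10^4$ | horizon in thin-film time units |
| `rtol`, `atol` | $10^{-8}$, $10^{-10}$ | integration tolerances |

The initial conditions are a single-mode cosine perturbation with uniform
surfactant; the long-wave version carries a constant offset so the liquid
volume is independent of `A`. These generators are also the package's
synthetic-data surface: every test builds states from them or from
manufactured profiles, so the tests exercise exactly the conditions of the
study — symmetric single-mode perturbations of uniform films. They do not
emulate irregular real airway geometry, soluble surfactant, gravity or air
flow, so passing tests speak to the model equations, not to those effects.

## Numerical design

**Spatial discretisation.** Fields live on a uniform node grid including
both endpoints; symmetry (even ghost) extension enforces $H_z = 0$ and
matches periodic dynamics. The evolution operator is a *staggered
conservative flux form*: fluxes are evaluated at cell faces from compact
second-order differences and face averages and then differenced, with zero
boundary fluxes. Two reasons: the face form conserves
$\int H$, $\int\Gamma$, $\int(1-R^2)$ and $\int R\Gamma$ to round-off under
trapezoidal quadrature, and — unlike a collocated wide-stencil central
divergence, whose response to the $2\Delta z$ mode vanishes (odd–even
decoupling) — it damps grid-scale noise, which matters because yield-surface
switching can pump a neutrally stable checkerboard mode. The surfactant
advection uses a minmod-limited second-order upwind face value: the
concentration gradient steepens into travelling near-shocks, and an
unlimited centred average traps dispersive undershoots there (the model has
no surfactant diffusion to remove them).

**Time integration.** The stacked state (`(H, Γ)` or `(R, RΓ)`) is advanced
by the stiff BDF solver `lsodes` with an explicitly supplied band-block
sparsity pattern (the pattern auto-detected at the uniform initial state
misses couplings and causes chronic corrector failures). Trial states
outside the physical range are clamped inside the right-hand side so the
step-size controller can recover rather than abort. When the Marangoni
number is zero the surfactant is dynamically inert and is *not* evolved:
its passive advection steepens into a genuine tracer shock that stalls the
integrator while having no effect on the flow. Long-wave runs integrate in
unscaled time and report $\tilde t = \epsilon^3 t$; the identity
$t^\ast = \tilde t\, a\eta/(\sigma_0\epsilon^3)$ fixes this convention
against the dimensional plugging times (1.7 s and 13 s for a
12th-generation airway).

A linearly-implicit Rosenbrock (W-method) marcher was prototyped as an
alternative; it steps robustly through the flux kinks but systematically
retards the delicate marginally-yielded creep phase unless run at
tolerances where it is no faster than BDF, so BDF was kept.

**Plug events.** The run is advanced output-by-output and stopped at the
first output with $\min_z R$ below threshold; the crossing is then located
by recursive re-integration of the bracketing interval and a final short
integration lands the reported state on the trajectory at $\tilde t_p$.

**Problem sizes.** Long-wave production runs use $N = 64$–$100$: the
plugging time of the reference surfactant-free configuration is identical
at $N = 100/128/150$ to four digits and changes by only 0.5% from
$N = 64$, and the weak-surfactant reference changes by 0.3% between
$N = 64$ and $N = 100$, while the cost of finer grids grows steeply
because yield fronts crossing nodes throttle the BDF step size.
Thin-film diagnostic runs use $N = 48$–$100$ depending on the horizon.
Tests use small grids ($N = 32$–$64$) and short horizons; the acceptance
script states the sizes it uses.

**Sensitivity near the critical thickness.** The plugging time is extremely
steep in $\mathcal{B}$ near the critical thickness: at
$\epsilon = 0.14, A = 0.2$, changing $\mathcal{B}$ from 0.0008 to 0.0015
moves $\tilde t_p$ from 25 to 60. Quantitative plugging times in this
regime therefore amplify small modelling or discretisation differences,
and cross-implementation agreement should be judged with that lever arm in
mind.

## The static family and its closure

The marginally-yielded static equation has a subtle structure on the
default domain: the neutral curvature mode $\cos z$ solves the linearised
problem exactly (so $H = 1 - A\cos z$ with $B = 0$ satisfies every side
condition for any $A$), and along the volume-constrained family of smooth
shooting solutions the end-slope defect equals $-12\pi B^2$ exactly — there
is *no smooth solution* with $B > 0$. The physical profile instead carries
a localised corner that absorbs the defect. `solve_static_profile()`
therefore solves the discrete face form used by the evolution operator
(marginal yield $H_f\,\tilde p_{z,f} = -2B$ on every face), assigns the
corner to the boundary face — consistent with the $O(1/\tilde t)$
correction fields vanishing at $z = 0$ — and closes the system with
orthogonality to the neutral mode. The resulting $B(A)$ is grid-independent
and reproduces the linearised limit $B \to A/(2\pi)$ to 0.1% at
$A = 0.005$; `bm_of_A()` tabulates it. The continuation as implemented
tracks the near-flat (lower) branch, the one that sets the minimum
perturbation needed to yield and hence the stability thresholds
$B_c \approx B_m$ (strong surfactant) and $B_c \approx 2B_m$
(surfactant-free); strongly deformed static shapes are obtained dynamically
as late-time attractors rather than by this continuation.

The $O(1/\tilde t)$ correction fields (`late_time_correction()`) are
extracted from a late-time simulation through their defining scaling
($[H-H_0]B\tilde t$, $Y_- B\tilde t$, $\tilde w_s (B\tilde t)^2$, …)
rather than by solving the coupled correction equations algebraically: the
algebraic system is homogeneous (zero is always a solution) and its
nonzero root resisted Newton iteration at useful tolerances.
`validate_late_time()` checks the $1/\tilde t$ scaling by comparing the
scaled residuals at two times.

## Tunables that matter

- `Y_min` regularises rigid regions with a creeping film of that thickness
  against the wall; halving it changes late-time peak heights at the
  $10^{-6}$ level. Not a physical parameter.
- `plug_threshold` (0.3) is the community convention for "a plug is about
  to form"; the long-wave model itself loses validity just beyond it.
- `rtol/atol`: the marginally-yielded creep phase needs tight tolerances;
  loosening to $10^{-4}$ visibly retards growth (tested), so the defaults
  should not be relaxed for production runs.
- Bisection tolerances in `epsilon_crit_search()`: the full protocol
  (±0.001 at $\tilde t = 10^4$) is hours of compute; the desk-scale
  coarsening (±0.005 at $\tilde t = 2\times10^3$, smaller `N`) preserves
  the ordering and approximate levels of the critical-thickness curves.

## Known limitations

- Plugging times in the near-critical regime are reproduced with
  $O(10\%)$-level fidelity at desk scale, limited by the sensitivity
  discussed above, and the surfactant-laden plugging times are shorter than
  the reference values (the Marangoni delay is under-expressed at
  affordable resolution; see the README's reproduction notes).
- The upper static branch and the fold of the $(A, B)$ diagram are not
  produced by the static continuation.
- Post-coalescence dynamics, wall elasticity, soluble surfactant, gravity
  and core gas flow are out of scope.
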