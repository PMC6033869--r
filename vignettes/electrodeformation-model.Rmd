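---
title: "Modelling red blood cell electrodeformation under amplitude-modulated DEP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling red blood cell electrodeformation under amplitude-modulated DEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edeform)
```

## The physical problem

A red blood cell (RBC) suspended in a low-conductivity buffer over an
interdigitated electrode array experiences a dielectrophoretic (DEP) force
when a high-frequency field (1.58 MHz here) is applied: the cell polarises
relative to the medium and is pulled toward high-field regions at the
electrode edges, where it is trapped and stretched uniaxially. Modulating
the carrier amplitude (amplitude shift keying, ASK) shapes the load over
time — sudden steps, staircases, triangular ramps, or half-sine envelopes —
so the membrane can be probed at controlled strain rates.

`edeform` implements the full modelling chain for this experiment:

1. **Dielectrics** — the single-shell ellipsoid model of the cell
   (membrane shell + cytoplasm core) giving the complex Clausius-Mossotti
   factor $f_{CM}$ along each principal axis.
2. **Field** — a finite-difference solution of the electrode array's
   $\nabla E^2_{rms}$ map, and the effective-dipole-moment (EDM) force
   $F = 2\pi abc\,\varepsilon_m \mathrm{Re}(f_{CM}) \nabla E^2_{rms}$.
3. **Loading** — ASK envelope profiles and the empirical quadratic map
   from envelope voltage to membrane shear stress.
4. **Viscoelasticity** — a nonlinear Kelvin-Voigt model of the membrane
   driven by the stress history.
5. **Inverse fitting** — recovery of the material laws from cell-track
   time series.
6. **Energy** — dissipated energy per load-unload cycle from the
   stress-strain hysteresis loop.
7. **Synthetic data** — noisy track generation so the whole inverse chain
   can be validated end-to-end without measurements.

## The Kelvin-Voigt membrane model

The deformed cell is described by the extension ratio
$\lambda(t) = b_0/b(t)$ of the initial to the transient in-plane minor
semi-axis. Membrane shear stress (in N/m — a 2-D membrane stress) is the
stretching half of the DEP force averaged over the minor axis,
$\sigma = F/(4b)$, and shear strain is
$\varepsilon = (\lambda^2 - \lambda^{-2})/2$. The spring-and-dashpot
balance reads

$$\frac{\sigma(t)}{2\mu(\lambda)} =
  \frac{\lambda^2 - \lambda^{-2}}{4} +
  t_c \frac{\partial \ln\lambda}{\partial t},$$

with $\mu(\lambda)$ the shear modulus, $t_c \equiv \eta/\mu$ the recovery
characteristic time, and $\eta$ the membrane viscosity. The
characterised mean-cell parameters used as defaults are:

| parameter | default | units | meaning |
|---|---|---|---|
| `mu_small` | 3.02 | uN/m | shear modulus for $\lambda \le 1.4$ |
| `mu_exp_amp`, `mu_exp_rate`, `mu_exp_offset` | 0.21, 2.06, 0.25 | uN/m, 1/$\lambda$, uN/m | $\mu = 0.21\,e^{2.06\lambda} - 0.25$ for $\lambda > 1.4$ |
| `lambda_break` | 1.4 | — | branch boundary |
| `t_c` | 0.14 | s | recovery time; $\eta = t_c\,\mu(\lambda)$ |
| stress law | $3.65 V^2 - 2.63 V + 0.71$ | uN/m | fitted on 0.5–3 V$_{rms}$ |

The stress law's fitted polynomial has a nonzero intercept, yet zero field
must give zero stress. The default `"bridge"` closure keeps the polynomial
on its fitted domain ($V \ge 0.5$) and replaces it below with a quadratic
through the origin matched continuously at 0.5 V$_{rms}$. The `"raw_poly"`
option evaluates the polynomial everywhere; with it, the simulated cell is
pre-stressed at zero field, which inflates low-voltage hysteresis areas by
several-fold — the bridge is the physically sensible default, and the
choice is the dominant ambiguity in the energy results.

## Numerical choices

**Integration variable.** The balance is integrated in $\ln\lambda$, so
$\lambda > 0$ holds for any step size. `deSolve::lsoda` with
`rtol = 1e-9` does the stepping.

**The modulus discontinuity.** The fitted two-branch law jumps from 3.02
to ~3.51 uN/m at $\lambda = 1.4$. For stresses between the two branch
thresholds both branches push $\lambda$ toward the break — a Filippov
sliding mode on which any adaptive solver chatters indefinitely. Inside
the ODE right-hand side only, $\mu$ is therefore interpolated linearly
across a $\pm 10^{-4}$-wide window in $\lambda$ at the break: the sliding
mode becomes an ordinary (stiff) stable equilibrium, and the induced error
in $\lambda$ is bounded by the window width. `shear_modulus()` itself
always evaluates the exact left-closed discontinuous law. A coarser
`mu_continuity = "blend"` variant (linear over $\lambda \in [1.38, 1.42]$)
is available when a continuous constitutive law is preferred outright.
Equilibrium stresses inside the jump gap pin $\lambda$ exactly at the
break, which `equilibrium_lambda()` reports.

**Elastic limit.** `t_c = 0` removes the dashpot; `simulate_deformation()`
then returns the instantaneous equilibrium response rather than dividing
by zero.

**Depolarization factors.** The elliptic integral
$A_i = \tfrac{abc}{2}\int_0^\infty ds/((s+a_i^2)B(s))$ is mapped onto
$(0,1)$ by $s = a_i^2 u/(1-u)$ (the integrand decays as $s^{-5/2}$, so the
substitution avoids truncating an infinite tail) and evaluated by adaptive
quadrature at relative tolerance $10^{-10}$; semi-axes are rescaled to
unit geometric mean first, which the factors are invariant to.

**Field solver.** One spatial period of the array (two strips at
$\pm V/2$) is solved with a five-point stencil, periodic lateral
boundaries, and mirrored-ghost Neumann conditions on the floor gaps and
ceiling; the sparse system is solved directly. The Dirichlet–Neumann
transition at the electrode edge carries a square-root field singularity
that degrades pointwise convergence to roughly first order in the grid
spacing, so the solver also solves the doubled spacing and sampling
returns the first-order Richardson extrapolation $2v_h - v_{2h}$, which
restores sub-percent grid convergence at cell positions. The nominal cell
position defaults to 4 um into the gap from the trapping edge (about one
undeformed cell radius — where the trapped cell's centre sits, and away
from the singular edge) at half the cell thickness (1.3 um) above the
floor. The solver deliberately omits the cell's own perturbation of the
field; force calibrations from full finite-element Maxwell-stress
computations can be injected through `read_force_table()` instead, and the
default stress law already encodes such a calibration.

**Hysteresis energy.** $W = \oint \sigma\, d\varepsilon$ by the
trapezoidal rule at a sampling interval of $\min(5\,\mathrm{ms}, t_c/20)$,
which keeps the discretisation error of the loop area under 1% (verified
by halving the interval in the test suite). The cycle is the waveform's
natural period (20 s triangle, 5 s half-sine), simulated from rest: the
first-cycle convention. At cycle end the membrane is still recovering
slightly, so the loop is open by ~1–2% of the strain range; the integral
closes it with a chord (at cycle end the stress is zero at both chord
ends, so the chord contributes almost nothing) and warns.

**Recovery-time fit.** After release, $t_c$ solves
$\exp(-t/t_c) = \frac{(SR - SR_\infty)(SR_0 + SR_\infty)}
{(SR + SR_\infty)(SR_0 - SR_\infty)}$ with $SR = a/b$. $SR_\infty$ is
first estimated from the trailing 10% of samples and the slope of the
logged right-hand side gives a starting $t_c$; because the tail mean
slightly overestimates $SR_\infty$ on a still-decaying trace (a ~2% bias
on $t_c$), both parameters are then refined jointly by Nelder-Mead on the
direct $SR$ residuals. Non-decaying traces are rejected.

**Plateau detection.** A hold is summarised over its trailing 20%; the
equilibration rate is the regression slope over the trailing half of that
window (the approach is exponential, so a full-window slope overestimates
the end rate). The flag threshold is $5\times10^{-3}$ s$^{-1}$: with
$t_c = 0.14$ s, 1 s holds end with residual rates around $10^{-3}$
s$^{-1}$ while 0.25 s holds sit at $10^{-2}$ s$^{-1}$ and above, so this
threshold separates the two regimes the staircase experiments contrast.

**Modulus-law fitting.** The offset exponential $A e^{B\lambda} - C$ is
only weakly identified on noisy data; `fit_mu_lambda()` uses bounded
multi-start Levenberg-Marquardt and keeps the best of three starts.
Modulus samples are fitted unbinned. Aggregation across cells is the
arithmetic mean (medians available).

## What the synthetic generator does and does not emulate

`generate_track()` runs the forward model under a profile, maps
$\lambda$ to axes by $b = b_0/\lambda$ and $a = a_0\lambda$, samples at
100 frames/s, and adds i.i.d. Gaussian noise per frame and axis (default
sd 1% of $b_0$), seeded and reproducible. The $a$-axis coupling is a
one-parameter simplification — real cells deform with independently
measured $a$ and $b$, and only $b$ enters the constitutive model — so the
generator validates the $b$-based inverse chain, not $a$-axis physics.
Not modelled: motion blur, tracking dropouts, tank-treading, tip
formation at large stretch, cytoplasmic viscosity, or optics. Passing the
recovery loop on these tracks therefore demonstrates correctness of the
inverse procedures under the model's own assumptions, not robustness to
every artefact of real video microscopy. The undeformed cell is taken as
$a_0 = b_0 = 3.9$ um with fixed out-of-plane semi-axis $c = 1.3$ um, a
typical discocyte footprint.

The moments-based `ellipse_from_mask()` (equivalent-ellipse convention,
with a 1/12-pixel-variance footprint term) stands in for the original
image-processing step on binary masks only.

## Dielectric defaults and a caution

The stored layer properties are $\varepsilon_{mem} = 4.44$,
$\sigma_{mem} = 10$ S/m, $\varepsilon_{cyto} = 59$,
$\sigma_{cyto} = 0.31$ S/m, membrane thickness 4.5 nm, medium
$\sigma = 0.018$ S/m at 1.58 MHz. The medium's relative permittivity is
not part of the characterised set; 78 (aqueous sucrose buffer) is the
configurable default. A membrane conductivity of 10 S/m is orders of
magnitude above typical lipid-membrane values (~$10^{-6}$ S/m) and is
kept only because it is the documented source value; every dielectric
parameter is overridable, and nothing downstream of the stress law
depends on $f_{CM}$ at these defaults.

## Worked example

```{r example, eval = FALSE}
mat <- material_model()
law <- stress_law()

# sudden 2 V_rms load for 1 s, then release
sim <- simulate_cell(mat, make_step_profile(2, 1, 1), law)
plateau_summary(sim$time, sim$lambda, make_step_profile(2, 1, 1))

# hysteresis energies over the two waveforms
energy_table(mat, law, peaks = c(1, 2, 2.5))

# synthetic tracks in, material model out
tracks <- lapply(1:20, function(k)
  generate_track(mat, make_step_profile(c(0.5, 1, 2)[1 + k %% 3], 1, 1),
                 law, noise = noise_spec(axis_sd = 3.9e-8, seed = k)))
profiles <- lapply(1:20, function(k)
  make_step_profile(c(0.5, 1, 2)[1 + k %% 3], 1, 1))
fit <- recover_material(tracks, profiles, law)
summary(fit)
```

## Known limitations

- The EDM force model overestimates forces for cells at the electrode
  edge; the package's stress law comes from a Maxwell-stress calibration
  and should be preferred for quantitative work, with the EDM path used
  for sensitivity studies.
- The constant-$t_c$ assumption is a population average; per-voltage
  recovery fits on real cells scatter around it.
- Hysteresis energies from the first cycle differ from the periodic
  steady state when the load does not return the membrane fully to rest;
  the cycle convention is configurable in `dissipated_energy()` via the
  cycle boundaries.
- The 2-D field model ignores end effects of finite electrode fingers and
  any electrothermal flow.
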