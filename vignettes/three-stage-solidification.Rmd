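---
title: "The three-stage droplet solidification model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-stage droplet solidification model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropsolid)
```

## The physical problem

In spray crystallization a liquid fat — cocoa butter in the packaged
default — is atomized into a cold chamber and each droplet freezes in
flight. Cocoa butter contains enough nucleating impurities that it does
not supercool: crystallization begins the moment the droplet reaches the
phase-change onset temperature and proceeds over a temperature range
rather than at a point. Its temperature history therefore has exactly
three regimes, and the model integrates one ordinary differential
equation per regime:

1. **Pre-cooling**: sensible cooling of the liquid from its initial
   temperature to the onset $T_f$;
2. **Solidification**: latent-heat release between $T_f$ and the solidus
   $T_s$, during which a solid shell grows inward from the surface;
3. **Tempering**: sensible cooling of the solid particle toward ambient.

The droplet is treated as spatially isothermal (lumped capacitance).
That is justified when the Biot number $\mathrm{Bi} = h\,(d/6)/k$ is
below about 0.1, which holds for the micron-sized droplets of production
interest ($\mathrm{Bi}\sim 10^{-2}$). The 2 mm validation droplet has
$\mathrm{Bi}\approx 0.18$ — above the limit — and the package warns
accordingly but still runs, since the available single-droplet
experimental data is at that size and lumped models at comparable Bi
have matched such data well. Droplet diameter, mass and density are
constant throughout: no evaporation, no shrinkage.

## Convective closure

The surface flux uses the Ranz–Marshall correlation
$\mathrm{Nu} = 2 + 0.6\,\mathrm{Pr}^{1/3}\mathrm{Re}^{1/2}$, the
standard closure for a sphere in a gas stream, with
$h = \mathrm{Nu}\,k_a/d$ and $\mathrm{Re} = d\rho_a V_{dg}/\mu_a$.
Air properties are needed as functions of temperature; the package uses
the ideal-gas density ($R = 287\ \mathrm{J\,kg^{-1}K^{-1}}$),
Sutherland's law for viscosity ($\mu_0 = 1.716\times10^{-5}$ Pa s at
273.15 K, $S = 110.4$ K), a Sutherland-form conductivity correlation
($k_0 = 0.0241\ \mathrm{W\,m^{-1}K^{-1}}$, $S_k = 194$ K) and a constant
$c_{p,a} = 1006\ \mathrm{J\,kg^{-1}K^{-1}}$ (it varies by under 1% over
the range of interest). These are the standard dry-air correlations; the
resulting Prandtl number is $\approx 0.71$–0.72 across 250–320 K.

**Where the properties are evaluated.** A droplet cooling in a stream
sees gas whose temperature varies from its own surface value to the
far-field value across the boundary layer. The package evaluates
$\mu_a$, $k_a$ and $\mathrm{Pr}$ at the film temperature
$(T_d + T_a)/2$, updated every step, and the density entering Re at the
far-field ambient state $(T_a, p)$ — the density of the chamber gas the
droplet actually moves through. This combination reproduces the
reference single-droplet figures that the validation scenarios are
compared against (initial cooling rate, trajectory-averaged Nu and h)
noticeably better than evaluating everything at either the film or the
far-field temperature alone, and is a common engineering convention for
external convection with imposed mass flux.

## The solidification-stage closure

The stage-2 energy balance contains two unknowns: temperature and solid
volume fraction $f$. The package closes it by taking $f$ **linear in
temperature**,

$$ f(T) = \mathrm{clip}\!\left(\frac{T_f - T}{T_f - T_s},\ 0,\ 1\right), $$

so that $\rho \dot V_f L$ becomes an effective-capacity term and stage 2
integrates

$$ \rho \tfrac{\pi d^3}{6}\left[C_{psd}(f) + \frac{L}{T_f - T_s}\right]
   \frac{dT}{dt} = \pi d^2 h (T_a - T). $$

Two observable consequences support this choice over the main
alternative (liquid-core *radius* linear in temperature): it yields a
solidification-onset cooling rate of $\approx 0.42$ K/s for the 2 mm
baseline, consistent with the reference value of about 0.5 K/s (the
radius-linear closure gives $\approx 0.16$ K/s, far too slow), and it
reproduces the $\approx 38$ s full-solidification time of the 263 K
scenario. It also realizes exactly the defining property of the
decoupled formulation: every increment of solid fraction releases the
matching increment of latent heat, $q_\mathrm{latent} = m L f$,
tracked as a ledger rather than inferred from temperature steps, so
complete solidification releases exactly $mL$ (0.588 J for a 2 mm
cocoa-butter droplet).

The semisolid heat capacity follows the shrinking liquid core: with
$a = r_l/r = (1-f)^{1/3}$,
$C_{psd} = (1-a)C_{ps} + a\,C_{pd}$. Note that $C_{psd}$ is linear in
the radius ratio, not in the volume fraction: at $f = 0.5$ it is
2004 J/(kg K), not the 1725 J/(kg K) midpoint (which occurs at
$a = 0.5$, i.e. $f = 0.875$).

## The apparent-specific-heat comparator

The classical alternative folds $L$ into a single temperature-dependent
capacity with a spike of height $L/(T_f - T_s)$ over the phase-change
band. `simulate_apparent()` integrates that formulation with fixed-step
explicit Euler, sampling the capacity at the step-start temperature —
deliberately the naive discretization. In the fine-step limit the two
formulations agree (they are algebraically identical under the linear
closure), and the tests verify agreement to better than 0.05 K. With a
step coarse enough to jump from above $T_f$ to below $T_s$ in one go,
the spike is never sampled: the implicitly released latent heat is zero
while the staged model releases all of $mL$ — the classical latent-heat
under-release, made quantitative as the `latent_deficit_J` field.

## The well-mixed gas cell

The real droplet heats the air around it. As a minimal surrogate for
that coupling, `simulate_coupled()` co-integrates a single well-mixed
control volume of size $V_\mathrm{cell}$, flushed by inflow air at
$T_\mathrm{in}$ through a hole of diameter 3.2 mm (the validation-rig
inlet), whose temperature is the ambient the droplet sees. The cell's
thermal mass is evaluated at the inflow state and held constant, which
makes the droplet + cell + outflow energy budget close to machine
precision. The surrogate demonstrates the mechanism — coupling warms the
local gas, reduces the driving force, and lengthens every stage — and
converges to the uncoupled model as $V_\mathrm{cell}\to\infty$ or as the
flush rate grows. It is **off by default**: no packaged scenario or
sweep uses it, because its magnitude is geometry- and mesh-dependent in
a way a single cell cannot represent. There is no default
$V_\mathrm{cell}$ for the same reason.

## Numerical choices

- **Integrator**: `deSolve::lsodar` (adaptive, stiff-capable) with root
  functions at $T = T_f$ and $T = T_s$, so stage transitions are located
  by the solver and land exactly on the thresholds — no
  overshoot-and-clip. Default tolerances `rtol = atol = 1e-8`; the tests
  check that halving them moves the stage durations by less than 0.1%
  and that the global energy audit closes to well under 0.1% of the heat
  exchanged.
- **Termination**: the ambient temperature is an asymptote, so runs end
  when $|T - T_a| < \varepsilon$ with $\varepsilon = 0.5$ K
  (configurable `epsilon_end_K`). Trajectory-averaged Nu and h depend
  mildly on this window; 0.5 K keeps the long near-ambient tail from
  dominating while still covering all stages. Hitting `t_max_s`
  (default 600 s) sets a `truncated` flag instead of erroring.
- **Sampling**: output every 0.05 s by default (0.002 s in the sweep,
  whose droplets are 10× smaller and ~100× faster); time averages use
  the trapezoidal rule on the sampled series.
- **Degenerate inputs**: `T_init = T_a` returns a single-sample
  constant trajectory; `T_init < T_a` is rejected (this is a cooling
  model); a material with $L = 0$ makes the staged and apparent
  formulations coincide for any step size.
- **Frozen-h oracle**: with `h_fixed` in `solidify_control()` stage 1
  has the closed form $T_a + (T_0 - T_a)e^{-6ht/(\rho C_{pd} d)}$; the
  integrator matches it to $10^{-6}$ relative, and the same runs let the
  lumped-capacitance estimator `gwie_h()` be verified as an exact
  inverse (recovery to <0.5%).

## Validation scenarios and the parametric study

Both packaged scenarios use the experimental single-droplet
configuration: $d = 2$ mm, initial 318 K, 1 bar, relative drop-gas speed
83 cm/s. At $T_a = 277$ K the ambient lies inside the 273–291 K
phase-change band, so the droplet can never fully solidify — the
experiment saw no tempering transition and neither does the model. The
$T_a = 263$ K variant exercises all three stages; full solidification at
$\approx 38$ s is the reference checkpoint.

The parametric sweep runs the 16-point grid
$d \in \{200, 300, 400, 500\}$ µm $\times$ $T_a \in \{220, 270\}$ K
$\times$ $V_{dg} \in \{20, 100\}$ cm/s, uncoupled, at 1 bar, with the
initial temperature kept at the validation value 318 K (the study
conditions never restate it). Stage durations are fitted per
$(T_a, V_{dg})$ combination with nonlinear least squares to
$t = C e^{kd}$ ($d$ in µm), initialized from the log-space linear fit;
$r^2$ on the package's own sweep exceeds 0.98. The qualitative claims
hold throughout: both durations increase with $d$, decrease as $T_a$
drops (driving-force $\propto T_d - T_a$) and decrease as $V_{dg}$ rises
($h \propto \sqrt{V_{dg}}$ at most), with ambient temperature dominating
relative speed for every size.

**A structural limitation worth stating plainly.** In an uncoupled
fixed-ambient lumped model both stage durations factor as
$t = \mathrm{const}\cdot d^2 / \langle\mathrm{Nu}(d)\rangle$ with the
temperature integrals independent of $d$ — the latent-heat retardation
multiplies the stage-2 time by a *constant* factor. The fitted
exponential rates of the two stages are therefore equal to within about
0.1%, and the residual difference is slightly *negative* (stage 2 runs
at colder film temperatures, so its Nu grows marginally faster with
$d$). A steeper stage-2 size exponent — as reported from coupled 3-D CFD
runs, where larger droplets heat their surroundings more and for longer
— cannot emerge without gas coupling. The reference fit constants
shipped in `reference_fit_constants()` come from such coupled runs and
are distributed for side-by-side reporting only; the package's own sweep
is expected to produce shorter times, steeper common scaling, and no
stage-2/stage-1 exponent gap, and one acceptance expectation documents
exactly this gap by failing.

## What the scenarios emulate, and what they do not

The packaged scenarios and sweep reproduce the *thermal* history of a
single, stationary, non-evaporating droplet under constant far-field
conditions. They do not emulate: droplet motion and the attendant
variation of $V_{dg}$; evaporation or any mass transfer; supercooling,
nucleation kinetics and recalescence (absent in cocoa butter but present
in aqueous droplets); polymorph selection in the crystallizing fat;
internal temperature gradients (Bi is diagnosed, not resolved); or the
3-D gas flow, turbulence and multi-droplet interactions of a real spray
chamber. Passing tests therefore certify the staged energy balance, its
latent-heat bookkeeping and its convective closure — not a prediction of
industrial spray-dryer performance.

## Parameter reference

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `rho` | 894 | kg/m³ | droplet density (both phases) |
| `cp_liquid` | 2200 | J/(kg K) | liquid specific heat |
| `cp_solid` | 1250 | J/(kg K) | solid specific heat |
| `latent_heat` | 157000 | J/kg | latent heat of crystallization |
| `T_freeze` | 291 | K | phase-change onset |
| `T_solidus` | 273 | K | phase-change end |
| `k_thermal` | 0.18 | W/(m K) | material conductivity (Bi only) |
| `epsilon_end_K` | 0.5 | K | termination band around ambient |
| `rtol`, `atol` | 1e-8 | — | integrator tolerances |
| `sample_dt_s` | 0.05 | s | output sampling interval |
| `t_max_s` | 600 | s | truncation limit |

The cocoa-butter thermal conductivity deserves a flag: it is not part of
the published property set. The default 0.18 W/(m K) is back-derived
from the reported Biot number of ≈0.18 for the 2 mm validation droplet
and is used only in the Biot diagnostic — it never enters the lumped
energy balance, so no simulated temperature depends on it.
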