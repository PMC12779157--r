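---
title: "A neuromechanical model of distension-induced esophageal peristalsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuromechanical model of distension-induced esophageal peristalsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(esoflip)
```

## The model

`esoflip` simulates the smooth-muscle (distal) esophagus under sustained
volumetric distension, the situation probed clinically by FLIP (functional
lumen imaging probe) panometry: a fluid-filled bag distends the lumen and
the organ responds — in health — with repetitive antegrade contractions
(RACs). The model couples three layers on one uniform grid of `N` nodes
over the non-dimensional position $\chi \in [0,1]$:

1. **A chain of Wilson–Cowan relaxation oscillators.** Each node carries an
   excitatory ($E_i$) and an inhibitory ($I_i$) population activity in
   $[0,1]$:
   $$\dot E_i = -E_i + (1-E_i)\,\sigma_E[aE_i + bE_{i-1} - eI_i
     - dI_{i-1} + S_{E,i}],$$
   $$\hat\tau_I \dot I_i = -I_i + (1-I_i)\,\sigma_I[cE_i - fI_i + S_{I,i}],$$
   with the logistic difference sigmoid
   $\sigma[x] = 1/(1+e^{-\lambda(x-\phi)}) - 1/(1+e^{\lambda\phi})$
   (zero at $x = 0$, so rest is a fixed point). Coupling is strictly
   unidirectional: node $i$ reads only its rostral neighbour $i-1$
   (excitatory weight $b$, inhibitory weight $d$); at the rostral-most
   node both terms are absent. Under sustained input
   $(S_E, S_I) = (1.6, 1.35)$ a single unit has a stable limit cycle of
   period $\approx 16$ time units; with no input it is excitable but
   silent.

2. **Distension-sensitive mechanoreceptors.** The local strain excess
   $h_i = \max(\alpha_i/\theta_i - \hat\alpha,\, 0)$ measures lumen
   distension relative to the *active* reference area. Receptors excite
   the excitatory populations rostral of themselves within roughly `x_s`
   (10%) of the organ length (a smoothed-step kernel), and the inhibitory
   populations of *all* segments caudal to themselves (descending
   inhibition — the esophagus relaxes ahead of a bolus):
   $$S_{E,i} = w_E \tanh\Big(g_S \sum_{k \ge i} h_k\,
     \beta_E(\chi_i - \chi_k)\,\Delta\chi\Big), \qquad
   S_{I,i} = w_I \tanh\Big(g_S \sum_{k \le i} h_k\,\Delta\chi\Big).$$

3. **Muscle activation and a 1D closed tube.** Excitation above the
   threshold $\hat E$ contracts the circular muscle by rescaling the rest
   area through $\theta_i \in [\theta_o, 1]$:
   $$\hat\tau_\theta\dot\theta_i = 1 - \theta_i -
     \sigma_\theta[E_i - \hat E],$$
   and the fluid obeys mass and momentum balance in a closed flexible
   tube with the linear tube law $p = \alpha/\theta - 1$:
   $$\partial_\tau \alpha + \partial_\chi(\alpha U) = 0, \qquad
   \partial_\tau U + U\,\partial_\chi U + \psi\,\partial_\chi p +
     \beta U/\alpha = 0 .$$

All quantities are non-dimensional: time in units of the excitatory time
constant, length in organ lengths, area in units of the rest reference
area, pressure in units of the wall stiffness. Only the two dimensionless
groups $\psi$ (stiffness/inertia) and $\beta$ (friction) carry the fluid
physics.

The closed feedback loop — distension activates receptors, receptors
drive the oscillators, excitation contracts the muscle, contraction moves
fluid, fluid moves the strain field — produces RACs autonomously, with no
central pattern generator and no descending command.

## Parameters

`eso_parameters()` returns the baseline set. The values most worth
knowing:

| parameter | default | meaning |
|---|---|---|
| `psi`, `beta` | 3000, 100 | tube stiffness and friction groups |
| `S_IC` | 2 | initial distension ratio (bag volume / rest volume) |
| `alpha_hat` | 1.5 | mechanoreceptor strain threshold |
| `a, b, c, d, e, f` | 16, 20, 12, 40, 15, 3 | synaptic weights (`b`, `d` intersegmental) |
| `w_E`, `w_I` | 1.6, 1.35 | sensory feedback strengths |
| `x_s` | 0.1 | reach of rostral excitation (fraction of length) |
| `tau_theta`, `tau_I` | 0.2, 4 | muscle / inhibitory time-constant ratios |
| `theta_o` | 0.05 | maximal contraction (5% of rest area) |
| `E_hat` | 0.3 | excitation threshold for muscle activation |
| `N` | 70 | grid nodes = oscillators |

Ten parameters (`a`–`f`, `w_E`, `w_I`, `phi_E`, `alpha_hat`) may be
per-segment vectors; `perturb_parameters()` draws seeded Gaussian
heterogeneity, clamped at zero because a negative synaptic weight would
invert the sign semantics of the circuit.

## Numerics

The 5N-variable system is integrated by an adaptive embedded
Runge–Kutta 4(5) pair (Cash–Karp, via deSolve) with a compiled
right-hand side; spatial derivatives are second-order central differences
on the co-located grid, exactly as the model is written — no upwinding
and no flux limiter. Defaults: `rel_tol = 1e-6`, `abs_tol = 1e-8`,
`tau_end = 100`, snapshots every `0.1`. These tolerances resolve the
steep ($g = 1000$) sensory sigmoids; tightening them tenfold changes
$E(\chi = 0.5, \tau = 50)$ of the baseline run by less than $10^{-12}$.

Design notes, in the order they matter:

* **Boundary closure.** The tube is closed: $U = 0$ is pinned at both
  ends, and continuity at the end nodes uses mirror ghost nodes
  consistent with the wall condition $\partial_\chi(\alpha/\theta) = 0$.
  With trapezoidal quadrature this closure conserves the discrete total
  volume *exactly* (to machine precision, observed drift
  $\sim 10^{-15}$), not merely to truncation order. One-sided
  differences at the ends are an admissible alternative; conservation
  then holds only approximately.
* **Timed events** (stimulus offset, bag deflation) split the
  integration, so every leg sees a time-continuous right-hand side.
* **Prescribed-distension mode.** Short-bag experiments replace the
  strain excess with a prescribed field
  $h = h_{\text{bag}}\mathbf{1}[\chi_1 < \chi < \chi_2]
  \mathbf{1}[\tau < \tau_{\text{deflate}}]$ (default level
  $S_{IC} - \hat\alpha = 0.5$, the baseline strain) and freeze the fluid:
  the experiments these scenarios reproduce report only muscle activity,
  and the fluid mechanics of a partially inflated bag is outside the
  model. A coupled variant with a spatially varying initial area profile
  can be built through `initial_state(distension_profile = ...)` for
  comparison.
* **Known artifact.** Central differences on sharp occluding
  contractions produce short-wavelength area wiggles near the
  contraction front. This is a property of the discretization the model
  prescribes; it is documented, not suppressed. It does not affect
  volume conservation or the diagnostics (which read $\theta$).
* **Integrator choice.** deSolve's dense-output Dormand–Prince variant
  exhibited severe step-size stagnation on long quiescent stretches of
  this system; the Cash–Karp pair reproduces the dynamics (matching to
  seven digits) without it. A fixed-step RK4 oracle cross-checks the
  single-oscillator trajectory to $10^{-4}$ in the tests.
* **Sigmoids** are evaluated overflow-safe (arguments clamped far in the
  saturated regime).

## The scenario library

`list_scenarios()` names twelve presets (see `?eso_scenario`): the
baseline FLIP response and the perturbations that reproduce
disorder-like patterns — absent response (`w_E = 0` or
`alpha_hat = 10`), a single swallow-like wave from a rostral pulse,
synchronous oscillation without coupling (`b = d = 0`), overlapping
contractions (`d` reduced or `phi_E` lowered), retrograde propagation
(`w_I = 0`), sustained panesophageal contraction (`c` reduced),
disordered patterns (Gaussian heterogeneity in `e`), and the short-bag
protocols.

Preset magnitudes that the underlying experiments leave open are chosen
to realize the described phenotype and are plainly overridable; two
deserve their reasoning spelled out:

* **Overlap needs `d = 10`, not `d = 20`.** Halving `d` lengthens the
  excitatory phase but the wave transit (~4 time units) still completes
  before the rostral end re-fires (period ~16); only near `d = 10` does
  rostral re-activation precede caudal completion, which is the overlap
  definition used by the diagnostics.
* **Sustained contraction goes through `c`, not `e`.** A uniformly
  sustained state needs inhibitory activity to stay *low* everywhere.
  Reducing `e` (inhibition *of* the excitatory population) leaves the
  intersegmental term $d\,I_{i-1} = 40\,I_{i-1}$ intact, and the chain
  keeps oscillating even when an isolated unit would lock high
  (verified by direct single-unit integration: the limit cycle survives
  down to `e = 7`). Reducing the excitation *of* the inhibitory
  population (`c = 5`) starves $I$ everywhere and the whole chain locks
  into contraction, holding bag pressure near 11 with a coefficient of
  variation below $10^{-5}$.

One sensory variant needs an interpretation note: "local inhibition"
(`betaI_windowed = TRUE`) replaces the all-caudal descending-inhibition
kernel by the mirror image of the excitatory window, confining
distension-induced inhibition to within `x_s` caudal of the receptor. A
literal reuse of the excitatory kernel for the inhibitory sum would be
inert (its argument is non-negative there, so the kernel is identically
~1); the mirrored form is the one that makes the variant mean what it
says.

## Diagnostics and classification

`detect_contractions()` reads threshold crossings of $\theta$
(default 0.7) with linearly interpolated onset/offset times — $\theta$
rather than $\alpha$, so the diagnostics work identically in coupled and
prescribed modes; $\alpha$-based detection is available for FLIP-style
CSA maps. Events are matched across segments into cycles by wavefront
tracking (rank order seeded at the segment with most events, neighbours
matched within half a median period). Per cycle,
`propagation_profile()` fits onset time against position: positive slope
= antegrade. The fit excludes $\chi < 0.1$: the rostral-most oscillator
has no upstream coupling by the boundary rule (its excitation barely
crosses the muscle threshold) and sits outside the phase-locked wave.

`classify_pattern()` applies a deterministic cascade: *absent* (no depth
anywhere), *sustained* (most segments stay contracted most of the run
without re-relaxing), then — for repetitive events — *synchronous* if no
cycle's slope magnitude exceeds one output step per unit $\chi$,
*RAC*/*overlapping*/*retrograde* by the sign vote of the directional
cycles, and *disordered* as the residual class. Two choices matter:

* Cycles with near-zero slope carry no direction information and are
  excluded from the sign vote. Under uniform initial distension every
  mechanoreceptor saturates at $\tau = 0$, so the first one or two
  contractions are necessarily near-synchronous; the chain then
  phase-locks over about four cycles (interior delay RSD decaying
  1.7 → 0.9 → 0.3 → 0.02 in the baseline run). Direction is a property
  of the established wave.
* "Disordered" has no quantitative definition in the clinical
  vocabulary; here it is the residual class, and single-wave responses
  (not repetitive) also land there.

Two behaviours of the baseline physics are worth knowing when reading
reports:

* **Rest tone.** With $E = 0$ the activation relaxes to
  $\theta^\ast = 1 - \sigma_\theta(-\hat E) \approx 0.955$, so a
  quiescent tube sits at pressure $S_{IC}/\theta^\ast - 1 \approx 1.09$,
  not exactly 1 (which holds only at $\tau = 0$, before tone develops).
  The absent-response check is therefore constancy at the
  tone-corrected level.
* **Start-up leak of the short bag.** Descending inhibition is carried
  by the inhibitory populations, which start at rest ($I = 0$); the
  first contraction wave therefore escapes the bag caudally
  (attenuating, dying by $\chi \approx 0.8$) before the inhibitory field
  is established. From the third cycle on, confinement is exact: caudal
  depth stays below the 0.05 quiescence bound. Clinically, bag inflation
  is gradual rather than instantaneous, so the transient is an artifact
  of the idealized initial condition.

## What the simulations do and do not show

All tests run the model itself at its published parameter values; none
use recorded patient data. Passing them shows that the implemented
equations reproduce the qualitative regime map — rest, excitable,
limit-cycle; antegrade phase-locked waves and their parameter-induced
breakdowns — and the conservation and convergence properties of the
discretization (doubling `N` moves the cycle period by well under 5%).
They do not validate the model against clinical FLIP recordings, do not
calibrate dimensional parameters, and say nothing about the lower
esophageal sphincter, extrinsic afferents, inhibitory motor neurons, or
myogenic mechanisms, all of which are outside the model by construction.

## Problem sizes

Full-length runs used throughout (tests, acceptance script) are
`N = 70`, `tau_end = 100`, snapshots every 0.1 — the study conditions.
The grid-refinement check uses `N = 140` at `tau_end = 60`; unit tests
of the operators use small grids (`N` = 3–50) where the expected values
are hand-computable.
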