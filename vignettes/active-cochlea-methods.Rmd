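---
title: "Methods: an actively amplified cochlea and its self-tuning"
author: "activecochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an actively amplified cochlea and its self-tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `activecochlea`, the
numerical choices behind it, and the boundaries of what its tests
demonstrate. It is the package's methodological record: every default
discussed here is the one the code ships with.

## 1. The physical model

The cochlea is idealized as two incompressible fluid compartments of
cross-section $A_{cs}$ separated by the basilar membrane (BM) of length
$L$ and width $W_{bm}$. Eliminating the fluid flux from force balance
and continuity leaves a modified wave equation linking BM height
$h(x,t)$ and the inter-compartment pressure difference $p(x,t)$:

$$\frac{2\rho W_{bm}}{A_{cs}}\,\partial_t^2 h = \partial_x^2 p .$$

At the base, the oval window is a damped harmonic oscillator
(damping $\xi_{ow}$, resonance $\omega_{ow}$, areal density
$\sigma_{ow}$) driven by the ear-canal pressure through a middle-ear
gain $G_{me}$; its motion imposes the pressure *gradient* at $x = 0$.
At the apex the helicotrema connects the compartments, so the pressure
difference vanishes. Locally, pressure and height are related through
an acoustic impedance,
$p = \sigma_{bm} Z(x,\omega)\,\tilde h$, with

$$Z(x,\omega) = \underbrace{\omega_0^2 e^{-2kx} - \omega^2 + i\xi\omega}_{\text{passive}}
              \; + \; \underbrace{C(x)\,\tilde g(x,\omega)}_{\text{hair cells}} .$$

The exponential stiffness makes $\omega_{res}^{pas}(x) = \omega_0
e^{-kx}$ a tonotopic map; with the default constants it runs from
20.8 kHz to 166.1 Hz. (The often-quoted 165 Hz apex value needs one
more digit of the stiffness decay constant than the standard constants
table carries; `activecochlea` reports what the printed constants
give.) Damping $\xi$ is constant in $x$ — position-dependent friction
variants are deliberately out of scope.

*Resonance* always means $\mathrm{Re}\,Z = 0$ of the **total**
impedance (`resonant_frequency_active()`). This matters: for the
single-exponential kernel at $\alpha = 2$ and 99% cancellation the
active term shifts the apex resonance by the factor
$\sqrt{1 + 2f\xi/\omega_{res}^{pas}}$, about +9% (166 → 181 Hz), because
$\xi/\omega_{res}$ is no longer small at the apex. Everything downstream
that needs "the resonance" — the fraction-$f$ activity construction,
the friction criterion band, and the localized/extended classification
threshold — uses the active resonance.

## 2. Hair-cell response kernels

The active pressure is a causal linear functional of past displacement,
$p_{hc} = \sigma_{bm} C(x) \int_0^\infty g(x,\Delta t)\,
h(x, t-\Delta t)\, d\Delta t$, with rates tied to the local passive
resonance, $r_j(x) = \alpha_j\,\omega_{res}^{pas}(x)$. Four families:

| family | $g(x,\Delta t)/\xi\omega_0^2$ (for $\Delta t>0$) | defining property |
|---|---|---|
| `single_exp` | $e^{-r\Delta t}$ | leaky integration of height |
| `approx_derivative` | $e^{-r_1\Delta t} - \frac{r_2}{r_1}e^{-r_2\Delta t}$ | zero mean: static shifts ignored |
| `zero_derivative` | $e^{-r_1\Delta t} - \frac{r_2^2}{r_1^2}e^{-r_2\Delta t}$ | zero *first moment*: $\partial_\omega \tilde g(0)=0$ |
| `instant_derivative` | $\propto -\delta'(\Delta t)$, $\tilde g = -i\xi\omega$ | $C=1$ cancels friction at all $\omega$ |

The $\xi\omega_0^2$ prefactor is kept verbatim so that $C$ is
dimensionless and comparable across families. Two numerical choices:

* **Confluent rates.** At $\alpha_1 = \alpha_2$ the two-exponential
  difference vanishes identically; the family is continued by its
  analytic limit, $g \propto e^{-r\Delta t}(r\Delta t - c)$ with $c=1$
  (zero mean) or $c=2$ (zero first moment), rescaled by one factor of
  $r$ to keep units. Rates are never perturbed to dodge the
  degeneracy, so parameter scans may include the diagonal exactly.
* **Sign of $C$.** Swapping $(\alpha_1,\alpha_2)$ multiplies the
  two-exponential $\tilde g$ by a negative scalar, so the physical
  active impedance $C_f\,\tilde g$ is swap-invariant while $C_f$
  itself changes sign; $C_f < 0$ whenever $\mathrm{Im}\,\tilde g > 0$
  at resonance (e.g. `zero_derivative` with $\alpha_1 < \alpha_2$).
  The package therefore treats the *kernel-plus-strength pair* as the
  physical object and does not force $C \ge 0$; self-tuning (Sec. 6)
  evolves the activity *magnitude* along the kernel's amplifying
  orientation, which is clipped at zero.

The fraction-$f$ profile
$C_f(x) = -f\xi\omega_{res}(x)/\mathrm{Im}\,\tilde g(x,\omega_{res}(x))$
is circular ($\omega_{res}$ depends on $C_f$); it is resolved by
fixed-point iteration seeded at the passive resonance, with relative
tolerance $10^{-12}$ on both $\omega_{res}$ and $C$ and at most 50
iterations (two to four suffice in practice — the real part of the
kernel is a small perturbation to the stiffness). The root of
$\mathrm{Re}\,Z = 0$ is bracketed around the passive resonance and the
bracket grown geometrically until a sign change is found; any bracket
containing exactly one sign change gives the same root, so the growth
factors are not delicate. After convergence the strength is
re-evaluated once at the converged resonance, which pins
$\Xi_{net} = 1-f$ on the resonance line to machine precision (the test
suite checks $10^{-10}$; the acceptance script reports the value at
$N = 1000$).

## 3. Discretization and state space

The BM is discretized into $N$ segments at $x_n = Ln/N$ (`N = 1000` by
default, matching the scale at which the model's mode structure was
characterized; coarser grids are used where stated). The Laplacian is
the standard second difference with $dx = L/N$ and two closures:

* **Base.** A ghost node enforces
  $\partial_x p(0) = 2\rho (A_{ow}/A_{cs})\,\ddot d_{ow}$ at first
  order, $p_0 = p_1 - dx\,(2\rho A_{ow}/A_{cs})\,\ddot d_{ow}$, and the
  oval-window oscillator is driven by the same ghost pressure $p_0$.
* **Apex.** $p = 0$ is imposed at the node *beyond* $x_N$, keeping all
  $N$ heights dynamical.

Because the pressure contains $\ddot h$, assembling
$\partial_t X = \hat J X$ requires one linear solve coupling the
accelerations: a mass matrix over $(\ddot h_1,\dots,\ddot h_N, \ddot
d_{ow})$ — tridiagonal plus the oval-window row/column — is formed and
factorized once per build (`build_jacobian()`), and its condition
number is checked. The state is ordered (heights, velocities,
auxiliary kernel states, oval window); all downstream code reads the
`index_map`, never positions. The single-exponential kernel adds one
auxiliary state per segment ($3N+2$ states), the two-exponential
families two ($4N+2$), the instantaneous derivative none ($2N+2$ — it
simply rescales the friction coefficient).

**Convention sensitivity.** The choice of where exactly $p = 0$ sits
(at $x_N$, half a cell beyond, or one cell beyond) and the order of the
base closure shift the extended-mode frequencies by $O(dx)$. All
large-scale conclusions — the plateau count of 12 extended modes, their
instability pattern, the stability phase diagrams — are insensitive to
this. One integer is not: the smallest $N$ at which the extended count
first reaches its plateau. The topmost extended mode lies within ~1% of
the classification threshold, so that onset ranges from $N = 84$ (the
convention above) through 90 (half-cell apex) to beyond 1000 (apex node
eliminated, giving the $3N-1$-state variant) across equally defensible
closures. The package reports the onset its own convention produces
rather than tuning the convention to a preferred integer.

The frequency-domain counterpart (`frequency_operator()`) assembles the
same discretization for a pure tone directly from $Z(x,\omega)$ and
solves for the complex height profile; it agrees with the resolvent of
the time-domain Jacobian to ~$10^{-13}$ (two independent code paths)
and with long-time `deSolve` integration to the integration tolerance.

## 4. Mode analysis

`eigenmodes()` keeps one member of each conjugate pair, classifies
oscillatory modes against the active apex resonance — ties count as
extended — and normalizes height eigenvectors to unit peak with the
peak entry real-positive. Zero crossings of extended modes are counted
on $\mathrm{Re}(e^{i\varphi} v)$ at the phase $\varphi$ maximizing the
real energy $\sum \mathrm{Re}^2$, which removes the arbitrary complex
phase; entries below $10^{-9}$ of the maximum are treated as zeros.
Localized-mode peak positions are compared against the tonotopic
prediction $\ln(\omega_0/\mathrm{Im}\,\lambda)/k$; at $N = 1000$ they
agree to a few grid cells for mid-cochlea modes.

The uncoupled reference spectrum solves $Z(x_n, -i\lambda) = 0$ per
segment after clearing kernel denominators (quadratic to quartic in
$\lambda$, via `polyroot`), selecting the oscillatory root pair closest
in modulus to the local resonance. Localized modes of the full system
approach these roots as the grid refines and as $f \to 1$; the
convergence is measured on decay rates after matching modes by
frequency, because mode frequencies carry an $f$-independent $O(1/N)$
discretization offset that would mask it.

At coarse grids ($N \lesssim 600$) the single-exponential kernel at
$f = 0.99$ destabilizes some under-resolved localized modes near the
apex and the base; at $N = 1000$ every localized mode is stable and the
instability is confined to the extended set, of which the topmost —
sitting essentially on the resonance line, where the net friction is
$+0.01$ — can remain marginally stable (11 of 12 unstable in this
build).

## 5. Stability criterion and phase diagrams

The analytic criterion asks whether $\Xi_{net}(x_0,\omega) =
\mathrm{Im}\,Z/\xi\omega$ dips below zero anywhere in
$(0, \omega_{res}(x_0))$, scanned on 400 log-spaced points from
$10^{-3}\omega_{res}$ (the resonance endpoint itself is excluded — it
equals $1-f \ge 0$ by construction). The probe position is $x_0 =
2.5$ cm; the criterion's verdict is position-independent for these
kernel families because the rates scale with the local resonance, so
$x_0$ only matters through which frequency band is displayed.
`phase_diagram()` records this verdict *and* the eigenvalue verdict
($\max \mathrm{Re}\,\lambda \le 10^{-6}\xi$, a tolerance chosen because
$f = 1$ parks eigenvalues numerically on the axis) side by side,
without reconciling disagreements — the criterion ignores oval-window
dissipation, so occasional disagreement is informative, not a bug.

For the single-exponential family the criterion has a closed form,
$\Xi_{net}(x_0, 0) = 1 - f(1 + 1/\alpha^2)$, so the stable region is
$\alpha \ge \sqrt{f/(1-f)}$ — about 3 at $f = 0.90$ and 10 at
$f = 0.99$ — and the eigenvalue boundary tracks that square-root law.
Since no $\alpha$ can stay stable as $f \to 1$, this kernel cannot
tune the cochlea to criticality. The approximate-derivative family is
stable at $f = 1$ only in the slow-rate corner
$\alpha_1\alpha_2 \lesssim 1$; the zero-derivative family in the broad
region $\alpha_1\alpha_2 \gtrsim 1$, because its flat transfer at
$\omega = 0$ keeps low-frequency friction positive regardless of $C$
and pushes the negative-friction band *above* resonance, where no
extended mode lives. Eigenvalue verdicts in phase diagrams default to
$N = 300$ per point (the extended-mode structure is already converged
there); boundary bisections in the tests use $N = 120$ for speed.

## 6. Stochastic drive and self-tuning

Incoming sound is modelled as white Gaussian ear-canal pressure noise.
For a stable build, the stationary covariance solves
$J\Sigma + \Sigma J^\top + \sigma^2 B B^\top = 0$; the package solves
it through the eigendecomposition of $J$ (transform the noise into the
eigenbasis, divide by $\lambda_i + \lambda_j$, transform back), which
costs one diagonalization and two matrix products. The full-matrix
residual of this route is checked to $10^{-8}$ in the tests, and the
height variances agree with an explicit Euler–Maruyama ensemble within
its Monte-Carlo error (the oracle runs on a rate-scaled, light-fluid
variant of the model so that the explicit scheme is stable and
stationary within a short window; its known $O(dt)$ variance bias,
about 5% at the step used, is accounted for in the comparison band).

Self-tuning implements
$\tau_a\,dC/dt = 1 - \langle h^2\rangle/h_0^2$ quasi-statically:
because $\tau_a$ is far slower than every mechanical timescale, the
stationary variance is recomputed after each explicit slow Euler step
(step $\tau_a/50$), and $\tau_a$ drops out of the fixed point. The
target $h_0(x)$ is a multiple of the passive rms profile (10× by
default; 5× in the perturbation experiments), and the converged state
is independent of the noise intensity, which scales out of the linear
dynamics. Numerical choices:

* **Per-segment step scale.** The raw feedback has a fixed point
  $C^*(x)$ near $C_{100}(x)$, which spans four orders of magnitude
  along the membrane; uniform additive steps would overshoot the apex
  segments catastrophically. Each segment's step is therefore scaled
  by its own $|C_{100}(x)|$ — equivalent to a position-dependent
  $\tau_a(x)$, which the quasi-static fixed point does not feel.
* **Unstable intermediates.** If a step leaves
  $\max \mathrm{Re}\,\lambda \ge 0$ there is no stationary state; the
  rms ratio term is replaced by the constant 10, driving activity
  down — a stand-in for the physically diverging oscillation
  amplitude that the linear model cannot represent.
* **Convergence.** Declared when the system is stable and
  $|1 - \mathrm{rms}/h_0| <$ 2% at all active segments with
  $x \le 0.9L$. The apex-most segments equilibrate *below* target:
  pushing them harder destabilizes the collective extended modes, so
  their shortfall is a property of the steady state (visible as less
  amplification near the apex), not a convergence failure. The full
  error field is reported either way.

Converged runs show the signature of criticality: localized decay
rates shrink by more than an order of magnitude relative to passive,
the spectrum hugs the imaginary axis from the stable side at every
recorded step, and near full cancellation the logarithmic
susceptibility $d\log(\mathrm{rms})/d\log C$ far exceeds 1 (and grows
with $N$ as the residual discretization damping $\sim 1/N$ shrinks) —
which is exactly why feedback on the rms *order parameter* needs no
fine-tuning while direct control of $C$ would.

Colored-noise drives are out of scope: the stationary-covariance
machinery covers white noise, and the model's qualitative conclusions
do not depend on the spectrum provided it covers the resonant band.

## 7. Perturbation experiments and fixtures

`experiment_dead_zone()` pins activity to zero on an interval (default:
the middle 10% of the membrane) during self-tuning; distant segments
still reach target, and dead segments near the zone edges are partially
amplified by their neighbours — activity is local in effect.
`experiment_stiffness_noise()` multiplies the nodal stiffness by
$1 + 0.01\gamma_n$ with iid standard-normal $\gamma_n$ under a
mandatory seed (draws that render stiffness non-positive are rejected);
self-tuning still achieves comparable average enhancement, with rms
spikes co-located with segments where the perturbed stiffness is
locally non-monotonic (flagged in the returned diagnostics).

`make_fixtures()` freezes the experiment definitions used by the test
suite: the plateau-scale grid ($N = 101$), the dead-zone interval, the
1% stiffness-noise draw, and the probe tones (300 and 2000 Hz). These
fixtures emulate the *study conditions* — clean constants, white drive,
small iid stiffness perturbations. They do not emulate real cochleae:
no measurement noise, no nonlinearity, no micromechanical (tectorial)
degrees of freedom, one-dimensional fluid coupling only. Passing tests
therefore demonstrate internal correctness of the model and its
numerics, not fidelity to physiological data.

## 8. Driven responses

`driven_response()` normalizes every amplitude profile to the passive
peak at the same frequency, so passive runs peak at exactly 1 and
amplification is read directly. `localized_activity()` windows the
fraction-$f$ profile with a Gaussian (default width $0.02L$, roughly
one localized-mode peak): cancelling friction only at the 2000 Hz place
amplifies a 2000 Hz probe severalfold while leaving a 300 Hz probe
essentially passive, and an off-resonance window leaves both passive.
The magnitude of the peak amplification depends on the window's shape
and width and on grid resolution, so the package treats "severalfold"
as the reproducible statement and the window default as a
documentation-level choice, not a fitted quantity.

## 9. Problem sizes and known limitations

Test-suite sizes: full-scale spectra at $N = 1000$ where a claim is
about the full model; plateau and classification structure at
$N = 101{-}300$; self-tuning at $N = 64$; stochastic oracles on a
6-segment rate-scaled variant. The acceptance script's quantities are
all deterministic.

Limitations worth restating: the model is linear, so everything at or
beyond the bifurcation (limit cycles, compressive nonlinearity,
otoacoustic emissions) is outside its reach; the fluid is
one-dimensional; friction is constant in $x$; the feedback is strictly
local, so phenomena requiring efferent (nonlocal) control are not
representable; and integer-valued observables that depend on a mode
sitting within 1% of a classification threshold (the plateau-onset
$N$) inherit $O(dx)$ boundary-convention sensitivity.
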