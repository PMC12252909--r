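# activecochlea

Dynamical-systems modelling of the active cochlea in R: a discretized
transmission-line model of the basilar membrane with explicit hair-cell
forces, eigenmode analysis, stability phase diagrams, driven responses,
and a slow feedback loop that self-tunes hair-cell activity to the edge
of instability.

## The scientific problem

Hearing relies on active amplification. Sound entering the cochlea
becomes a surface wave on the basilar membrane (BM), whose stiffness per
unit mass decays exponentially along its length,
`S(x) = ω₀² e^(−2kx)`, so each place `x` resonates at
`ω_res(x) = ω₀ e^(−kx)` — a tonotopic map from ~20.8 kHz at the base to
~166 Hz at the apex. Friction would blunt the resonances; outer hair
cells inject energy to cancel it. But near-perfect cancellation is a
fine-tuning problem: a couple of percent too much activity makes the
membrane spontaneously unstable.

This package implements a linear model in which that question can be
posed sharply. The two fluid compartments obey a wave equation
`(2ρW_bm/A_cs) ∂²ₜh = ∂²ₓp`, closed by a damped-oscillator oval window
at the base and zero pressure difference at the helicotrema. The local
pressure–height relation is an acoustic impedance

```
Z(x, ω) = ω₀² e^(−2kx) − ω² + i ξ ω  +  C(x) g̃(x, ω)
```

whose last term is the hair-cell contribution: a causal linear-response
kernel `g` (single-exponential, two-exponential approximate-derivative
or zero-derivative, or idealized instantaneous-derivative) with a
dimensionless local strength `C(x)`. Setting
`C_f(x) = −f ξ ω_res(x) / Im g̃(x, ω_res(x))` cancels a fraction `f` of
the friction exactly on the resonance line.

Diagonalizing the resulting state-space Jacobian reveals two mode
families: a near-continuum of *localized* modes, each sharply peaked at
its resonant place, and a handful of collective *extended*
standing-wave modes below the apex resonance. Localized modes can be
brought to their Hopf bifurcations almost independently; the extended
modes are what amplification can accidentally destabilize. The package
evaluates both an analytic net-friction criterion
(`Ξ_net = Im Z / ξω` negative anywhere below resonance ⇒ danger) and
full eigenvalue stability, maps them over kernel parameters, and closes
the loop with order-parameter feedback
`τ_a dC/dt = 1 − ⟨h²⟩/h₀²` that parks every segment at its critical
point without fine-tuning — self-organized criticality in the inner ear.

Intended users: biophysicists and auditory modellers who want a small,
fully scripted laboratory for cochlear criticality rather than a
psychoacoustic simulator.

## Worked example

```r
library(activecochlea)

p   <- cochlea_params(N = 150)            # standard human constants
ker <- hair_cell_kernel("single_exp", alpha = 2)
C99 <- activity_for_fraction(ker, p, f = 0.99)
C99
#> <activity_profile> 150 segments, fraction f = 0.99
#>   range of C: [0.0003277, 4.643]

md <- eigenmodes(build_jacobian(p, ker, C99))
md
#> <cochlea_modes> 301 modes: 139 localized, 12 extended, 150 non-oscillatory
#>   max Re lambda = 1.994 1/s

round(subset(md$table, class == "extended")$freq_hz, 1)
#>  [1]  18.1  41.4  64.1  85.5 105.2 122.9 138.3 151.0 160.9 168.0 173.4 178.7
```

The activity profile cancels 99% of friction at every place (`Ξ_net =
0.01` on the resonance line, to machine precision), yet the spectrum
has a positive `max Re λ`: the twelve extended modes — the standing
waves listed above, from 18 Hz upward — have been destabilized by this
kernel, exactly the trade-off the stability phase diagrams
(`phase_diagram()`, `friction_criterion()`) quantify. A
`zero_derivative` kernel with `alpha1 * alpha2 > 1` amplifies without
that instability, and can be self-tuned:

```r
ts <- self_tune(cochlea_params(N = 64),
                hair_cell_kernel("zero_derivative", alpha1 = 1, alpha2 = 2),
                h0_multiple = 10)
ts
#> <tuning_state> converged after 172 slow steps
#>   max Re lambda = -0.1082 1/s, median rms/h0 = 1.000
```

Every segment reaches ten times its passive rms height while the
spectrum stays (barely) stable — the edge of instability, found by
purely local feedback.

A thin command-line front end wraps the same functions:

```sh
exec/cochlea modes --n 1000 --out out/          # eigenvalue table (CSV)
exec/cochlea selftune --kernel zero_derivative --alpha1 1 --alpha2 2 --out out/
```

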