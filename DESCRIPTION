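Package: activecochlea
Title: Active Cochlear Mechanics: Mode Structure, Stability, and Self-Tuned Criticality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discretized transmission-line model of the cochlea with explicit
    active hair-cell forces. The basilar membrane is modelled as a chain of
    damped harmonic oscillators coupled by incompressible fluid, driven through
    a damped oval-window oscillator and open at the helicotrema. Hair-cell
    activity enters through causal linear-response kernels (single-exponential,
    approximate-derivative, zero-derivative and instantaneous-derivative
    families) whose strength can be set to cancel a fraction of the passive
    friction on the resonance line. The package assembles the first-order
    state-space Jacobian, classifies eigenmodes into localized and extended
    sets, evaluates an analytic net-friction stability criterion against full
    eigenvalue stability, computes pure-tone driven responses and stationary
    root-mean-square displacement under stochastic drive, and implements a slow
    order-parameter feedback that self-tunes activity strength to the edge of
    instability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
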