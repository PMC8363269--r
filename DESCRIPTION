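Package: photonforce
Title: Photonic-Force Stimulation of Hair Bundles: Optics, Mechanics, and
    Trace Analysis
Version: 0.1.0
Authors@R:
    person("Photonforce", "Developers", email = "photonforce@example.org",
           role = c("aut", "cre"))
Description: Models and analysis tools for mechanical stimulation of
    inner-ear hair bundles by photonic (radiation-pressure) force delivered
    through a tapered, lensed optical fiber.  Provides closed-form
    radiation-pressure and Fresnel/Snell computations at dielectric
    interfaces, a geometric-optics ray tracer for the circular cross-section
    of a stereocilium that accumulates per-event momentum transfer, a
    diverging-cone model of the fiber tip's light spot, Hookean
    bundle/probe mechanics including equipartition stiffness estimation,
    displacement-trace analyses (repetition averaging, exponential onset
    fits, adaptation summaries, averaged-periodogram power spectra and
    double-Lorentzian oscillation fits), and seeded generators of synthetic
    bundle traces (Ornstein-Uhlenbeck Brownian motion, low-pass step
    responses with adaptation and twitch, spontaneous oscillations, and
    frequency-sweep responses) for validating every analysis without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
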