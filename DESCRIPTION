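Package: afsim
Title: Lumped-Parameter Hemodynamics of Rate-Controlled Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop lumped-parameter (0D) model of the four-chamber heart
    with systemic and pulmonary circulations, driven beat-by-beat by stochastic
    atrial-fibrillation RR intervals drawn from an exponentially modified
    Gaussian distribution. Computes per-beat hemodynamic and mechano-energetic
    indices (stroke volume, ejection fraction, stroke work, potential energy,
    pressure-volume area, rate pressure product, tension time index, ventricular
    efficiency) from the simulated pressure-volume traces, and sweeps mean heart
    rate to quantify how ventricular rate alone reshapes left-heart load and
    oxygen-consumption surrogates during atrial fibrillation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
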