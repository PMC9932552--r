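Package: headingCD
Title: Competitive-Dynamics Simulation of Heading Perception from Optic Flow
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Synthesizes optic-flow vector-field sequences for simulated
    self-motion through a 3D dot cloud, including mid-trial heading switches
    and brief sensory blackouts, and runs them through a simplified
    competitive-dynamics model of primate areas MT and MSTd: Gaussian motion
    pooling, radial heading templates with inverse-distance weighting,
    recurrent on-center/off-surround shunting dynamics with an exponential
    input trace, and population-vector heading decoding. Provides the
    heading-error, heading-bias and precision statistics used in
    heading-switch psychophysics, full experiment protocols for
    switch-duration and blackout designs, and a random parameter search
    over neurophysiologically motivated ranges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'headingCD-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'flow.R'
    'templates.R'
    'mt.R'
    'dynamics.R'
    'model.R'
    'bias.R'
    'grid.R'
    'experiment.R'
    'search.R'
    'io.R'
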