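Package: avrescue
Title: Monte Carlo Optimization of Avalanche Rescue Strategies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation tools for optimizing avalanche companion
    and organized rescue under the "greatest good for the greatest number"
    criterion. Computes the survival-optimal probing depth for a probe-line
    search as a function of avalanche debris area and rescuer count, and the
    survival-optimal duration of cardiopulmonary resuscitation on an
    extricated pulseless patient while a second subject remains buried.
    Burial-depth and deposit-area inputs are resampled from an empirical
    avalanche table or from a calibrated synthetic generator; survival versus
    burial time is a configurable piecewise-linear curve and resuscitation
    success follows a saturating-exponential model of CPR duration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
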