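Package: ddphen
Title: Degree-Day Phenology Analysis for Multivoltine Orchard Pests
Version: 0.1.0
Authors@R: person("ddphen", "maintainers", email = "maintainers@ddphen.org",
    role = c("aut", "cre"))
Description: Tools to analyse the seasonal phenology of multivoltine orchard
    moths from pheromone-trap catches and daily weather records. Computes
    degree days from daily minimum and maximum temperatures with the single
    sine method (dual thresholds, horizontal cutoff), projects a fixed
    degree-day offset forecast of generation windows, re-expresses weekly
    trap captures on the accumulated degree-day axis, segments flight
    periods at the minima between peaks to estimate operational generation
    times, and summarises durations with stepwise ANOVA, Tukey comparisons
    and jackknife standard errors. A synthetic-data generator with known
    ground truth supports end-to-end validation without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
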