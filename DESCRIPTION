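Package: groupskew
Title: Optimal Group Size and the Stability of Eusocial Groups under
    Resource Variance and Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consumer-resource model of animal group formation under
    stochastic foraging. Individual foraging success follows a Gamma law whose
    scale (mean resource item size) acts as a proxy for environmental
    variance; groups pool harvests and allocate them to survival and
    reproduction either equally (egalitarian groups) or with maximal
    reproductive skew (eusocial groups, a single reproductive dominant).
    The package computes per-capita mortality and natality by quadrature,
    solves the demographic equilibrium for the minimal per-capita resource
    requirement of each strategy, derives optimal group sizes and relative
    carrying capacities (supersaturation), and evaluates the inclusive-fitness
    stability of eusocial groups, including the minimum intra-group
    relatedness that keeps subordinates from defecting. An individual-based
    Monte-Carlo simulator of foraging seasons provides independent estimates
    of all demographic rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
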