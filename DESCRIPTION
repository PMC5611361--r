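Package: twigscale
Title: Leaf-Stem Allometry and Xylem Efficiency-Strength Trade-Off Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of twig-level leaf-stem scaling and the
    stem hydraulic-efficiency versus mechanical-strength trade-off across tree
    species. Derives hydraulic architecture (equivalent vessel diameter,
    hydraulically weighted diameter, vessel density and fraction, theoretical
    Hagen-Poiseuille conductivity), wood density, saturated water content and
    flexural properties from raw measurement tables; fits standardized major axis
    (SMA) allometries with isometry and common-slope tests; computes
    phylogenetically independent contrasts and contrast correlations; runs
    multiple factor analysis over leaf and stem trait groups and nested
    variance-component partitioning; and simulates complete multi-species,
    multi-individual, multi-twig datasets with known allometric and trade-off
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
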