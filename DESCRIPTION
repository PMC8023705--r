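Package: shieldens
Title: Nuclear Magnetic Shielding Densities from Induced Current Densities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes, decomposes, and maps nuclear magnetic shielding
    densities. The current-density susceptibility tensor is evaluated from
    gauge-including atomic orbital (GIAO) density and magnetically perturbed
    density matrices supplied by a quantum-chemistry engine through a
    documented adapter contract, or from analytic ring-current and atomic
    vortex models. Shielding densities follow from the Biot-Savart relation
    and are integrated on multicenter molecular grids (Lindh-style radial
    nodes, Lebedev-type angular nodes, Becke fuzzy-cell partitioning) to give
    per-atom shielding contributions, plane maps, and volumetric fields of
    shielding and deshielding regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
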