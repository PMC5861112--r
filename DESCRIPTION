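Package: cryopa
Title: Simulation of Photoacoustic SNR Enhancement by Cooling the Intermediate Medium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo light transport in voxelized tissue slabs,
    temperature scaling of the Grueneisen parameter and reduced scattering
    coefficient, acoustic forward modelling (velocity-potential shell model
    and spherical-wave superposition), delay-and-sum and
    delay-multiply-and-sum beamforming, and signal-to-noise analysis for
    studying how cooling the intermediate medium improves photoacoustic
    imaging depth. Includes a synthetic-data generator for slab-with-rod
    phantoms and linear-array radio-frequency frames, and an experiment
    runner that sweeps temperature, depth and scenario into reproducible
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
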