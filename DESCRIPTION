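Package: cepaq
Title: Context-Encoding Quantitative Photoacoustic Imaging
Version: 0.1.0
Authors@R:
    person("cepaq", "maintainers", email = "cepaq@example.org", role = c("aut", "cre"))
Description: Machine-learning based quantification of photoacoustic (PA)
    images. Estimates the local light fluence in each voxel of a PA signal
    volume by encoding the voxel's measured-signal context against a
    precomputed fluence-contribution map and regressing a fluence correction
    with a random-forest ensemble; optical absorption and blood oxygen
    saturation follow from the fluence estimate. Ships the complete in-silico
    validation world: random-walk vessel phantoms with hemoglobin-based
    optical properties, a voxel-grid Monte Carlo photon transport simulator
    (fluence maps and per-voxel fluence contribution maps), a three-level
    noise model, non-negative least-squares spectral unmixing, and an
    evaluation bench with reduced-scale benchmark presets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    digest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
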