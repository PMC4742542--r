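Package: dwiphantom
Title: Multi-Compartment Diffusion MRI Phantom Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes realistic whole-brain-style diffusion MRI phantom
    datasets from a voxel-wise microstructural model. Each voxel mixes
    restricted (fiber, axially symmetric Gaussian kernel), hindered
    (isotropic tissue) and free (CSF) diffusion compartments; signals are
    sampled on uniform-coverage single- or multi-shell gradient schemes,
    degraded with Rician noise at a configurable signal-to-noise ratio and
    optionally warped by a synthetic susceptibility-distortion field.
    Includes synthetic microstructure generators (single voxel, crossing
    slab, mini-brain), gradient-table I/O (FSL and MRtrix dialects),
    a fiber orientation distribution pathway via real even spherical
    harmonics, log-linear tensor fitting for self-validation, and a BIDS
    dataset writer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
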