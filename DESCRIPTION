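Package: zershape
Title: Rotation-Invariant 3D Zernike Shape Descriptors for Macromolecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained Gaussian density volumes from atomic structures,
    3D Zernike moment decomposition on the unit ball, Canterakis-norm
    normalization yielding complete rotation-invariant moment descriptors,
    fast geometric (GEO) features, a learned non-negative weighted distance
    for real-time shape retrieval of protein assemblies, and moment-space
    structure superposition obtained as a byproduct of the normalization.
    Includes deterministic synthetic shape benchmarks so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    glmnet,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
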