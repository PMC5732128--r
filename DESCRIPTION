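Package: pinholeMC
Title: Monte Carlo Simulation and Dual-Matrix ML-EM Reconstruction for
    Multi-Pinhole SPECT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative, calibration-free reconstruction for static
    multi-pinhole SPECT cameras. Provides a Monte Carlo forward-projector
    (voxelized photon transport with attenuation and Compton scatter,
    forced-direction variance reduction, knife-edge aperture model), an
    analytical ray-tracing back-projector with a distance-dependent
    detector sampling grid, and the dual-matrix ML-EM iteration that
    couples them while maintaining an absolute counts-to-activity
    relationship. Includes voxelized phantom generators (spheres,
    NEMA-style sphere sets in an elliptical torso, point-source grids, a
    cardiac shell), activity-recovery and spatial-integrity analyses,
    post-filters, and Interfile-style projection input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
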