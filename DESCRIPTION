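Package: mpssfp
Title: Transient-State Balanced SSFP Multi-Parameter Mapping with
    Subspace-Constrained Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantitative MRI parameter mapping with a repeated
    four-pulse transient-state balanced SSFP train. Provides Bloch-simulated
    signal dictionaries (single-spin and slab-resolved multi-spin with
    z-encode separation), stack-of-spirals undersampled acquisition
    simulation with off-resonance phase accrual during extended readouts,
    conjugate-gradient SENSE and subspace-constrained reconstruction with
    and without B0 compensation, a two-pass B0 estimation pipeline with
    phase unwrapping, and dictionary-matching estimation of T1, T2, B0, B1
    and complex proton density, written out as NIfTI parameter maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
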