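Package: hybridose
Title: Hybrid Planar/SPECT Internal Dosimetry with Voxel S-Value Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-specific internal dosimetry for Tc-99m labelled
    radiopharmaceuticals using the hybrid planar/SPECT technique. Provides a
    synthetic digital-phantom simulator (time-resolved activity maps,
    whole-body planar scans, SPECT projections, attenuation maps and camera
    calibration acquisitions), OSEM reconstruction with broad-beam attenuation
    correction and absolute quantification, planar time-activity-curve
    extraction with mono-exponential kinetic fitting, dual iterative adaptive
    threshold segmentation of quantitative SPECT volumes, time-integrated
    activity coefficient (TIAC) estimation including a voiding-bladder model,
    voxel S-value dose-kernel convolution with self-/cross-organ dose
    decomposition and dose-volume histograms, and an organ-level MIRD engine
    with mass-adapted S-factors and a spherical tumour model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
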