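Package: voxdose
Title: Voxel-S-Value Dosimetry and Treatment Planning for Y-90 Radioembolization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level absorbed-dose computation for yttrium-90 microsphere
    radioembolization planned from Tc-99m-MAA SPECT/CT. Generates voxel-S-value
    (VSV) dose kernels for uniform liver and lung media from an embedded Y-90
    beta dose-point kernel, implements seven dose-conversion methods (local
    energy deposition, liver-kernel convolution, tissue-specific kernels, and
    density-corrected and centre-voxel-scaled variants including LiCKLuKD),
    computes dose-volume histograms and DVH dosimetrics, and calculates the
    maximum injected activity by both the three-compartment partition model and
    3D voxel dosimetry. Includes a configurable digital liver/lung/tumor
    phantom generator with SPECT-like degradation so every stage can be
    exercised on synthetic data, and NIfTI input/output for clinical maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
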