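Package: roaddose
Title: Robust Organ-Mapped Dose Accumulation Under Registration Uncertainty
Version: 0.1.0
Authors@R:
    person("Alex", "Carver", email = "alex.carver@example.org",
           role = c("aut", "cre"))
Description: Maps a radiotherapy dose distribution from an original planning
    scan onto a reirradiation scan while accounting for deformable image
    registration (DIR) uncertainty. The discordance among two or more
    displacement vector fields is converted, voxel by voxel within each
    organ at risk, into an ellipsoidal dose-resampling kernel (inverse
    distance weighted centre and weighted-SD dimensions), which is then
    conditionally expanded so that every mapped voxel samples dose from
    inside the organ and so that essentially all original organ dose voxels
    are sampled at least once. Returning the per-kernel maximum yields a
    worst-case ("robust") mapped dose suitable for reirradiation planning.
    Includes a fixed-radius kernel comparator, kernel-magnitude and surface
    distance (MDA, Hausdorff) diagnostics, Jacobian determinant maps, DVH
    statistics and deficit reports, a seeded synthetic-case generator, a
    minimal NIfTI-1 reader/writer, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
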