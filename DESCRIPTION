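Package: csfclearance
Title: Imaging Markers of Cerebrospinal-Fluid Clearance from Multimodal MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for MRI markers of cerebrospinal-fluid (CSF)
    based brain clearance: enhanced perivascular contrast (T1w/T2w ratio)
    images, multiscale Frangi vesselness segmentation of white-matter
    perivascular spaces with per-region morphometry (count, volume, mean
    diameter and their white-matter-normalized fractions), the DTI-ALPS
    perivascular diffusivity index from template-space tensor-element maps,
    eTIV-normalized lateral-ventricle and choroid-plexus volumetrics, and
    cohort-level inference by Freedman-Lane permutation regression of group,
    age and group-by-age effects with lobe-wise Bonferroni thresholds.
    Includes phantom and cohort simulators with known ground truth so that
    every stage is testable without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
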