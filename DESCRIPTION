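Package: octscreen
Title: Automated OCT-Based Ex Vivo Tissue Screening Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for high-throughput optical coherence
    tomography (OCT) screening of ex vivo tissue cultures in multi-well
    plates: plate-view tissue detection with IoU/mAP evaluation, optimal
    imaging-depth selection from axial sweeps, B-scan tissue segmentation
    robust to specular reflections and supporting-membrane interference,
    volumetric morphometry (en-face thickness maps, area, volume), and
    screening assay-quality statistics (pooled-SD repeatability and
    reproducibility, Z'-factor, SSMD). Includes a seeded synthetic phantom
    generator emulating retinal explant cultures so the full pipeline can be
    exercised end-to-end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
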