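Package: meniscus3d
Title: 3D Morphometry and Classification of the Discoid Lateral Meniscus
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes discoid lateral meniscus (DLM) screening indices from 3D
    label volumes of the knee: the ratio of the meniscus to the tibia (RMT),
    the percent coverage of the meniscus (PCM), and the lateral-to-medial
    anteroposterior diameter ratio (L/M). Includes a minimal NIfTI-1 reader and
    writer, a parametric voxel phantom generator with analytic ground truth for
    validation, threshold-based DLM classification, and the cohort statistics
    used in DLM morphometry studies (Mann-Whitney U, Yates-corrected
    chi-square, two-way random-effects intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
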