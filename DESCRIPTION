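Package: cbiqus
Title: Quantitative Ultrasound Analysis of the Cartilage-Bone Interface
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: High-frequency pulse-echo ultrasound analysis of osteochondral
    explants. Generates seeded synthetic raster-scan RF volumes with known
    ground truth (including surface-directed decalcification and PBS-swelling
    operators), extracts signal envelopes via the analytic signal, detects the
    articular-surface and cartilage-bone-interface (CBI) echoes per scan line
    with quality control, computes the quantitative ultrasound parameters
    Delta (cartilage thickness, mm), Alpha (backscatter upswing, dB/mm) and
    CBI backscatter intensity (dB), reconstructs transverse, en face and
    maximum-intensity-projection images, and provides the matched-pair
    statistical layer (paired t-test, one-way ANOVA, Monte-Carlo Dunnett
    post-hoc, Pearson correlation) for repeated-scan experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    withr,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
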