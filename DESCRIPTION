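Package: discmorph
Title: Computer-Assisted Morphometry of Lumbar Intervertebral Discs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Objective measurement of the internal composition of lumbar
    intervertebral discs (IVD) from transverse T2-weighted images. Segments
    the nucleus pulposus (NP) with two computer-assisted algorithms, fuzzy
    C-means clustering and seeded region growing, constrains the extracted
    NP profile with a low-order elliptic-Fourier parametric curve, and
    computes NP-to-CSA area ratios. Includes a synthetic disc-phantom
    generator with known ground truth for validation, and the reliability
    and method-comparison statistics used in disc morphometry studies
    (Pearson correlation with interpretation bands, paired t tests,
    intraclass correlation, split-plot factorial ANOVA, Tukey HSD).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml,
    optparse,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'util.R'
    'morphology.R'
    'io.R'
    'preprocess.R'
    'phantom.R'
    'fcm.R'
    'region_growing.R'
    'contour.R'
    'morphometry.R'
    'stats.R'
    'pipeline.R'
    'cli.R'
    'discmorph-package.R'
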