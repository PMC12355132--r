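Package: HistoStack
Title: Morphology-Preserving Co-Alignment of Serial Histology Sections
    into 2.5D Cores
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs 2.5D biopsy cores from z-ordered stacks of serial
    tissue-section images. Provides a synthetic serial-section phantom
    generator with known ground truth, hue-based tissue masking and ribbon
    labeling, keypoint-based serial similarity (rigid) registration,
    boundary-driven B-spline non-rigid registration that never reads
    interior texture, 2.5D patch extraction with a tissue-fraction filter,
    and the match-weighted median registration-error statistic. Also ships
    a desk-scale reference implementation of a divided depth/space
    attention encoder with momentum self-distillation, combined
    space-time attention rollout, and attention-based multiple-instance
    aggregation with the associated agreement statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    png,
    tiff,
    pROC,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, CellBasedAssays, Alignment
RoxygenNote: 7.3.3
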