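Package: lesionmatch
Title: Report-Guided False-Positive Ruling-Out for Head-and-Neck Tumor
    Auto-Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality assurance of deep-learning auto-segmented head-and-neck
    gross tumor volumes (primary, GTVp; nodal, GTVn) guided by radiology
    reports. Lesion descriptions extracted from PET/CT diagnosis reports
    (via a pluggable large-language-model adapter or a deterministic
    structured dialect) are matched geometrically to connected components
    of auto-segmentation masks, either by reported slice location mapped
    through the PET-CT rigid registration, or by lymph-node level and
    anatomic-region bounding boxes built from organ-at-risk extents.
    Unmatched components are ruled out as false positives; unmatched report
    lesions are flagged as false negatives.  Includes instance-level
    precision accounting, Dice and 95th-percentile Hausdorff metrics with
    paired significance testing, a synthetic phantom-case generator for
    end-to-end validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
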