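Package: sactexture
Title: Grey-Level Texture Analysis of the Post-EVAR Aneurysm Sac
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Masked grey-level texture feature extraction (co-occurrence,
    run-length and grey-level difference statistics) from CT cross-sections
    of the post-EVAR abdominal aortic aneurysm sac, a volume-change
    reference standard for aneurysm expansion, and a three-layer
    backpropagation neural-network classifier evaluated under repeated
    stratified 70:15:15 splits with ROC analysis. Includes a synthetic
    aneurysm-sac phantom generator so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    png,
    tiff,
    jsonlite,
    nortest,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
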