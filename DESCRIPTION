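Package: thyrofacemetrics
Title: Quantitative Eye and Neck Morphology for Thyroid-Related Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis engines for quantifying two facial hallmarks of
    hyperthyroidism from ordinary photographs: scleral exposure around the
    iris (a correlate of exophthalmos) and anterior neck swelling (goiter).
    Provides landmark-driven periocular cropping, polar (rubber-sheet)
    unwrapping of the ocular surface with eyelid-to-iris distance profiling
    at twelve reference positions, neck alignment and skin-mask width
    profiling with four morphology indices (TLR, BPI, BAR, ASR), mean plus
    k-standard-deviation ensemble thresholding calibrated on a normal
    cohort, detection and classification evaluation metrics, and synthetic
    eye and neck phantoms with analytic ground truth for end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
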