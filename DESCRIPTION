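Package: tagrsom
Title: Quantitative Image Analysis for Transrectal Absorber Guide
    Optoacoustic Mesoscopy of Murine Colitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying colon-wall biomarkers from raster-scanning
    optoacoustic mesoscopy (RSOM) volumes acquired with a transrectal absorber
    guide (TAG): fiducial tracing of the ink-filled TAG lumen, rotation and
    bend correction, rigid co-registration of ink/water volume pairs, angular
    sector segmentation of the colon-wall vasculature, and computation of
    colon-wall thickness, total optoacoustic signal intensity and blood
    volume. Includes a synthetic vascular phantom generator with known ground
    truth so every stage of the pipeline can be validated without real
    acquisitions, plus the normality-gated statistical comparisons used in
    longitudinal colitis studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
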