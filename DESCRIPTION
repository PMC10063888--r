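Package: rvgc
Title: Retinal Vessel Geometric Characteristics from Labeled Fundus Vessel Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Measures the twelve retinal vessel geometric characteristics
        (central retinal artery and vein equivalents, arteriovenous ratio,
        box-counting fractal dimension and simple tortuosity, each in the
        optic-disc-referenced measurement zones B and C) from labeled
        fundus vessel maps, using either a cohort-constant or an
        individual optic-disc-based pixel-to-micron image conversion
        factor. Includes a ground-truthed synthetic fundus vasculature
        generator with controllable image centering and resolution, and a
        Bland-Altman agreement layer for comparing measurement protocols
        (constant versus individual conversion factor, optic-disc-centered
        versus macula-centered framing, right versus left eye).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Rcpp, EBImage, png, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
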