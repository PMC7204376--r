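Package: earasym
Title: Objective Facial Paralysis Assessment from Bilateral Eye Aspect Ratio Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies facial-paralysis severity in the eye region from
    68-point facial landmark sequences. Computes an amplified eye aspect
    ratio (EAR) per eye per frame, measures bilateral movement asymmetry
    as the discrete Frechet distance between the two EAR curves, and maps
    that asymmetry to a Facial Nerve Grading Scale 2.0 (FNGS 2.0) eye
    score via nearest-class-median classification with k-fold cross
    validation. Includes a desk-scale cascaded ensemble-of-regression-trees
    (ERT) landmark detector trainable on procedurally rendered faces, and
    a seeded synthetic-patient generator with grade-dependent eyelid
    asymmetry so the full pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
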