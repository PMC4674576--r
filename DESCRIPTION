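Package: phacovision
Title: Video Analysis for Phacoemulsification Cataract Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing microscope video of phacoemulsification
    cataract surgery: iris localisation with a distance-constrained
    randomized Hough transform and a circle-then-ellipse detection cascade,
    surgical probe tracking with an adaptive Tracking-Learning-Detection
    tracker (Median Flow, random-fern ensemble, P-N learning), and lens
    nucleus hardness grading on the Emery-Little scale with a cascaded
    support-vector-machine classifier. Ships seeded synthetic generators
    for edge images, probe videos and tissue patches so every stage can be
    exercised end to end without patient video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
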