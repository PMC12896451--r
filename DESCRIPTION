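Package: pigbouts
Title: Bout-Level Quantification of Pig Agonistic Behavior from Frame-Level Detections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts per-second object-detection streams of pig agonistic
    behavior (aggression, ear biting, tail biting) into behavioral bouts with
    class-specific onset thresholds and a shared termination gap, and
    aggregates bouts into daily and weekly pen-level metrics. Includes
    detection-model evaluation (IoU matching, precision/recall/F1, average
    precision and mAP50, confusion matrices), AI-versus-manual agreement
    statistics (Pearson r, absolute-agreement intraclass correlation,
    Cohen's kappa after explicit bout alignment), growth-performance and
    welfare-score arithmetic, and a seeded synthetic generator of ground-truth
    bout schedules, noisy detection streams and observer-coded annotations so
    the whole pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
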