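Package: emgait
Title: Locomotor EMG Burst Detection, Gait Metrics and Circular Coordination Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for treadmill locomotor electromyography (EMG) in
    the spinal rat: rectified-integrated envelope extraction, hysteresis burst
    detection with rhythmic-episode selection, step-cycle metrics (cycle
    duration, burst duration, peak amplitude and their coefficients of
    variation), circular statistics on burst-onset phases (mean resultant
    vector, Rayleigh criterion, two-sample Watson U-squared, Moore's paired
    test), and the group-comparison battery used to contrast experimental
    cohorts and pre/post-drug conditions. Includes a central-pattern-generator
    style synthetic EMG simulator (von Mises phase coupling, band-limited noise
    carriers) so the whole pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
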