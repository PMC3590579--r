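Package: meipulse
Title: Multiscale Entropy Index Analysis of Cuff-Occlusion Arterial Pulse Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for wrist arterial pulse recordings acquired under a
    cuff-occlusion reactive-hyperemia protocol. Detects per-beat footpoints and
    systolic peaks, builds the concatenated baseline plus hyperemia beat-amplitude
    series, detrends it by empirical mode decomposition, computes multiscale sample
    entropy and the small-scale/large-scale multiscale entropy indices (MEI_SS,
    MEI_LS), and the dilatation index (DI) from phase-windowed mean amplitudes.
    Includes a deterministic synthetic-cohort generator emulating four subject
    archetypes (healthy young, healthy middle-aged or elderly, well-controlled and
    poorly controlled diabetic) and group-comparison/correlation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    withr,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
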