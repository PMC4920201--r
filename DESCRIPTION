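Package: bruwave
Title: Transcription Dynamics from Pulse-Labeled Nascent RNA Coverage
Version: 0.1.0
Authors@R: person("bruwave", "maintainers", email = "bruwave@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-course nascent RNA sequencing
    (Bru-seq style pulse labeling) of a transcriptional response. Quantifies
    productive initiation in TSS-proximal windows (RPKM over the first 30 kb),
    classifies genes into temporal response patterns (sustained, transient,
    delayed, reversal) relative to a starved baseline, and estimates RNA
    polymerase II elongation rates from the displacement of transcription
    wave fronts across long genes between consecutive 30-minute labeling
    windows. Ships a kinetic simulator of pulse-labeled nascent transcription
    (piecewise-constant initiation and position-dependent elongation with
    Poisson read sampling) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
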