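Package: tetherscreen
Title: Analysis of Tethered-Function Dual-Luciferase Splicing Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tethered-function splicing reporter screens
    and their genomic follow-up. Converts dual-luciferase (Firefly/Renilla)
    plate readouts into relative percent-spliced-in (psi) estimates against
    plate-matched negative controls, runs the multi-round hit-calling cascade
    (replicate one-tailed t-tests, Bonferroni-gated gel validation and a
    cross-reporter retest) that partitions hits by tethering position, filters
    rMATS-style skipped-exon tables, and integrates CLIP enriched windows with
    knockdown differential-splicing results into bound-gene enrichment
    statistics and position-dependent splicing maps. A seeded synthetic-data
    generator emulates every input format with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
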