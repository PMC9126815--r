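Package: socphys
Title: Sociability, Fiber Photometry, Slice Electrophysiology and
    Count-Based Differential Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for behavioral-neurophysiology studies of
    social preference. Scores three-chamber sociability sessions from
    center-point tracking (zone occupancy, proximity-entry events,
    preference index with exclusion rules), transforms two-channel fiber
    photometry recordings into delta-F/F, peri-event time histograms and
    session z-scores, computes slice electrophysiology metrics (F-I curves,
    cell quality control, drug-subtracted ramp I-V curves, AMPA/NMDA ratio,
    rectification index, paired-pulse ratio), and selects differentially
    expressed genes from read-count tables by a worst-case pairwise
    fold-change rule with RPM normalization, PCA and Fisher enrichment.
    Includes synthetic-data generators with known ground truth for every
    input modality so the whole pipeline is testable at desk scale, and a
    statistics battery (Shapiro-gated paired and one-sample tests,
    repeated-measures two-way ANOVA, MAD outlier screen) with a
    reproducible run report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
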