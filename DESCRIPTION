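Package: xenoresp
Title: Preclinical Xenograft Tumor Response and Event-Free Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for evaluating antitumor efficacy in mouse xenograft
    studies from serial caliper tumor-volume measurements. Implements
    time-to-event analysis under a volume-quadrupling event with
    log-linear (exponential-growth) interpolation, the five-level
    PD/SD/PR/CR/MCR response classification with objective-response
    calling, Kaplan-Meier event-free-survival estimation and two-group
    log-rank testing written from first principles, four-parameter
    logistic dose-response fitting with IC50 potentiation ratios,
    biomarker-versus-response correlation, and xenograft RNA-seq
    utilities (graft/host read disambiguation, FPKM, Benjamini-Hochberg
    adjustment, and differential-expression filtering). A synthetic-data
    generator reproduces the statistical structure of such studies so
    every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
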