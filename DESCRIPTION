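Package: prosocontrast
Title: Prosodic Phrasing of Contrastive Discourse Status in Dialogue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for studying whether speakers use
    Accentual-Phrase (AP) prosodic phrasing to mark the contrastive vs.
    given status of discourse referents in French map-task dialogue.
    Classifies noun tokens as one- or two-AP phrasings from acoustic
    annotations (pre-boundary lengthening and pitch-accent criteria,
    both at a 10 percent threshold), computes a per-participant 0-20
    prosodic phrasing score, fits crossed random-intercept mixed-effects
    models (logistic on the phrasing outcome, linear on log durations
    and log f0), and correlates phrasing ability with a theory-of-mind
    (hinting task) score. Includes readers for Praat TextGrid/PitchTier
    annotations, a canonical CSV interchange format, and a seeded
    hierarchical synthetic-data generator so every stage is testable
    without recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
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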