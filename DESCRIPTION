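Package: langalign
Title: Turn-by-Turn Language Alignment in Bilingual Conversations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing language choice alignment in bilingual
    caregiver-child interactions. Reads timed, speaker- and language-tagged
    utterance annotations (ELAN EAF or a canonical delimited table), computes
    per-speaker language-use profiles on identifiable speech time, extracts
    dyadic conversational turns coded as language matches or switches, and
    tests whether turn-by-turn matching exceeds chance with a
    frequency-preserving Monte Carlo null, arcsine (Cohen's h) effect sizes,
    and balance/turn-count inclusion filters. Also provides correlation
    comparison tests for session-level correspondence (Fisher r-to-z for
    independent samples, Steiger's Z for overlapping dependent correlations)
    and a seeded synthetic conversation generator with a moment-based
    coupling estimator for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
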