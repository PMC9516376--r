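Package: notephen
Title: Keyword-Guided Phenotyping of Long Clinical Documents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining rare clinical phenotypes, such as severe drug
    hypersensitivity reactions, from archives of free-text clinical notes.
    Long documents (all notes of one inpatient visit, often thousands of
    Chinese characters) are reduced to the few sentences that contain
    task-specific keywords before being embedded and classified, which makes
    fixed-length document encoders usable and fast. The package provides
    corpus input/output with stratified splitting, rule-based sentence
    segmentation for Chinese and English clinical text, built-in guideline
    and smoking keyword lists plus a discriminative TF-IDF keyword deriver,
    an oracle test that upper-bounds what keyword selection can achieve,
    pluggable document embedding backends (encoder truncation, hierarchical
    mean pooling, and a deterministic hashed character n-gram backend),
    grid-searched linear and support-vector classifiers evaluated by
    micro-averaged F1, archive mining that emits alert records with evidence
    sentences, and a seeded synthetic corpus generator so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
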