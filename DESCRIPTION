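Package: qrf2l
Title: q-Rung Orthopair Fuzzy 2-Tuple Linguistic Decision Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multi-criteria group decision making with q-rung
    orthopair fuzzy 2-tuple linguistic (q-RF2L) information. Implements the
    2-tuple linguistic representation model, the q-RF2L number algebra
    (operational laws, score, accuracy, comparison, Hamming distance),
    prioritized Maclaurin symmetric mean aggregation (q-RF2L PMSM and its
    dual PDMSM, with their k = 1, 2, 3, n special cases), an extended WASPAS
    ranking pipeline with priority orders over both experts and criteria,
    theta/q sensitivity scans, and three comparison methods (q-RF2L
    PROMETHEE II outranking flows, the q-RF2L Muirhead mean, and the
    linguistic-free q-rung orthopair fuzzy MSM). Includes panel readers and
    writers in CSV/JSON dialects and a seeded generator of random valid
    decision panels for property testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
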