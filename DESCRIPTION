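Package: binlot
Title: Language-of-Thought Compression Models for Binary Sequence Memory
Version: 0.1.0
Authors@R:
    person("binlot", "developers", email = "binlot@example.org", role = c("aut", "cre"))
Description: Tools for modelling human memory for binary (two-item) sequences as
    compression in a recursive language of thought. Implements the stay/flip
    instruction grammar with nested repetition, exact minimal-description-length
    search (plain and chunk-preserving), a brute-force enumeration oracle, six
    rival sequence-complexity metrics (run/chunk complexity, pair entropy, LZ78,
    subsymmetries, change complexity, and an external algorithmic-complexity
    lookup), a fixed transition-probability surprise model for deviant detection,
    LISAS speed-accuracy scoring of trial tables, random-intercept mixed-model
    comparison via AIC/BIC/Akaike weights, and a synthetic trial generator for
    parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
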