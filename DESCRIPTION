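Package: taxscrub
Title: Taxonomic Name Resolution Against Vascular-Plant Reference Backbones
Version: 0.1.0
Authors@R:
    person("Backbone", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Parses and standardizes botanical scientific names (genus,
    epithet, infraspecific rank and epithet, authority, hybrid markers),
    resolves them against a tab-delimited reference backbone with staged
    fuzzy matching (genus first, then epithet, then infraspecific name and
    authority, Levenshtein distances with per-component thresholds), and
    validates, flattens, summarizes and diffs backbone tables: dangling
    synonym detection, synonym-chain transitive closure, status summaries
    and categorical comparison of two backbones. A deterministic synthetic
    backbone and corrupted-query generator makes every operation testable
    without the full reference download. Includes a command-line interface
    with resolve, validate, summarize, diff and generate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
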