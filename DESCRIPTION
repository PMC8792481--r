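Package: liontrax
Title: Genetic Suitability Scoring for Lion Translocations and CITES Trade Audits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-support pipeline for planning lion (Panthera leo)
    conservation translocations and auditing historical live-lion trade.
    Provides a clade-annotated registry of lion conservation units (mtDNA
    haplogroups, nuclear clades, subspecies, certainty grades, suture-zone
    and hybrid-origin flags), a hierarchical source/target suitability
    classifier (first choice, second choice, third choice, no option, with
    suture-zone directionality and faded hybrid-source modifiers), a reader
    and rule-based re-classifier for CITES Trade Database comparative
    tabulations (inclusion filters, four consolidated trade categories,
    W1/W2/C/U source-class adjustment), quantity-weighted suitability
    summaries and flow tables, and seed-controlled synthetic registry and
    trade-record generators with ground-truth sidecars for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
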