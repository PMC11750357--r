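Package: waspEVE
Title: Detection and Event Inference for Filamentovirus Endogenization in Cynipoid Wasps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers endogenous viral elements (EVEs) of filamentovirus origin in
    cynipoid wasp genome assemblies and groups them into ancestral endogenization
    events. Provides chromosomal-integration evidence scoring (GC/coverage
    envelopes against BUSCO scaffolds, majority-vote contig taxonomy, merged
    transposable-element intervals), an EVE catalog with ORF-integrity calls,
    support-thresholded gene-tree topology classification (type I/II/III),
    transitive scaffold-colocation grouping of loci into events via union-find,
    Nei-Gojobori dN/dS estimation with selection-regime calls, Fisher exact
    core-gene enrichment, and chronogram-based event dating. Ships a synthetic
    scenario generator with a machine-readable truth table, including a fixed
    scenario reproducing the study design it models, so every stage can be
    scored against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
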