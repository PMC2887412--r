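Package: optorf
Title: Growth-Coupled Strain Design with Integrated Metabolic and Regulatory Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based design of microbial production strains at the
    gene level. Compiles gene-protein-reaction (GPR) associations and Boolean
    transcriptional regulatory rules into mixed-integer linear constraints,
    solves regulated flux balance analysis, and searches for gene deletions,
    transcription-factor deletions, and gene overexpressions that couple
    biochemical production to growth via a strong-duality bilevel MILP
    (the OptORF approach), alongside an OptKnock-style reaction-deletion
    baseline. Includes production envelopes, minimal gene covers for reaction
    sets, regulated re-evaluation of designs, minimal overexpression rescue,
    and intervention statistics. Linear and mixed-integer programs are solved
    with the HiGHS solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: python (>= 3.8) with scipy (>= 1.9) on the PATH for the
    HiGHS solver bridge
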