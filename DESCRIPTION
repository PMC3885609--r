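Package: rpe
Title: Reverse Pathway Engineering for Metabolic Gap Filling
Version: 0.1.0
Authors@R:
    person("RPE", "Maintainers", email = "rpe@example.org", role = c("aut", "cre"))
Description: Predicts missing reactions in metabolic networks by reverse
    pathway engineering: biotransformation rules are extracted from an
    atom-mapped reference reaction database, applied in the retro direction
    to a target metabolite, and the resulting candidate reactions are ranked
    and chained back to known metabolic precursors. Candidate enzymes for
    predicted steps are assessed by neighbor-joining phylogenetics with
    bootstrap supports and species-overlap ortholog inference. Ships a
    deterministic fixture generator for a flavor-forming (branched-chain and
    sulfur amino acid catabolism) reaction network so the full pipeline runs
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
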