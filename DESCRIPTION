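Package: chemevolve
Title: Comparative Molecular Evolution of Chemoreceptor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative molecular-evolution
    analysis of insect chemoreceptor (odorant and gustatory receptor)
    gene families: repertoire bookkeeping and pseudogene classification,
    Nei-Gojobori (1986) dN/dS divergence with exact Wilcoxon rank tests,
    parsimony gene-tree/species-tree reconciliation with weighted
    duplication and loss costs, branch-site codon-model likelihood-ratio
    tests for episodic positive selection with family-wise and
    false-discovery-rate control, and a gene-family birth-death simulator
    producing codon alignments with known ground truth so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
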