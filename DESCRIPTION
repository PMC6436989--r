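Package: swphylo
Title: Alignment-Free Phylogenetic Distances from Filtered Spaced-Word
    Matches Between Proteomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates pairwise evolutionary distances between whole or
    partial proteomes without computing full alignments. Spaced words are
    extracted with respect to sets of binary match/don't-care patterns
    optimized by hill-climbing minimization of overlap complexity; spaced-word
    matches are scored with BLOSUM62 over their don't-care columns, filtered
    at a score threshold to discard random background matches, and reduced to
    a one-to-one mapping of occurrences. Mismatch fractions pooled over the
    selected matches are corrected with the Kimura protein distance and
    assembled into distance matrices, from which neighbor-joining trees are
    built. Includes a continuous-time Markov protein sequence simulator (JTT
    and Poisson models) with an alignment-based Kimura oracle for accuracy
    evaluation, and Robinson-Foulds tree comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Alignment, SequenceMatching, Software
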