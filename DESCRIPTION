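Package: starmiR
Title: Design of Vector-Based Overexpression Constructs for Star-Strand microRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs shRNA-style stem-loop inserts that exclusively overexpress
    miRNA* (star-strand) species from Pol III shRNA vectors: the mature star
    sequence is placed in the 3' arm of an artificial hairpin and a seed-mutated
    full complement in the 5' arm. The toolkit detects seed collisions between
    the engineered passenger strand and the natural counterpart miRNA, proposes
    wobble-preserving disruptive substitutions, scores duplex end stabilities
    with an RNA nearest-neighbor model to predict RISC strand selection, screens
    the passenger strand for off-target seed matches in user-supplied 3'UTRs,
    emits annealing-ready cloning oligonucleotides for plvx-shRNA2-style
    backbones, and designs matching luciferase sensor inserts (perfect, bulged,
    and seed-mutant) for psiCHECK and pMIR-Report backbones.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
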