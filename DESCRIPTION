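Package: promdpp
Title: Core Promoter Element Classification and DNA Physical-Property Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies RNA polymerase II promoters (mRNA, lncRNA, miRNA) by
    their core promoter elements (TATA box, Inr, BREu, BREd, DPE) with a
    configurable positional tolerance around each element's canonical
    TSS-relative location, and computes TSS-anchored average profiles of five
    DNA physical properties (duplex free energy, base stacking energy,
    protein-induced deformability, rigidity, Z-DNA(AS) stabilizing energy)
    from di- and tetranucleotide step-parameter tables.  The same profiling
    machinery applies to the three tRNA-gene regions anchored at the TSS, the
    mature 5' end and the discriminator base (A-box/B-box internal
    promoters).  Includes position-frequency-matrix/information-content
    computation for sequence logos and a synthetic promoter and tRNA-gene
    generator with recorded ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
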