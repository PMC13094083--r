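Package: dualcut
Title: Quantification of CRISPR/Cas9-Induced Inversions and Large Deletions
    from Dual-gRNA Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification toolkit for dual guide-RNA CRISPR/Cas9
    experiments that induce chromosomal inversions and large deletions between two
    cut sites. Provides a generative simulator of editing outcomes and of three
    measurement processes (crystal digital PCR droplet panels, short amplicon
    reads, long amplicon reads); estimators for per-genome inversion frequency
    from droplet counts with volume-fraction accounting, windowed indel
    quantification from amplicon reads with negative-control subtraction, and
    breakpoint-junction classification of long reads by flanking-sequence
    matching with bounded insertion tolerance; and internal-reference
    normalisation of editing frequencies using a fixed gRNA, with experiment-level
    concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
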