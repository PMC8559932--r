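Package: lariatuss
Title: Splice-Site Usage, Alternative-Splicing Screens, and Branch-Point
    Calling from Lariat Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies alternative splicing and splice-site selection from
    junction counts and coverage windows, and identifies intron branch points
    from lariat RT-PCR derived reads. Implements five-type PSI (percent
    spliced in) event extraction and differential screening, a per-splice-site
    usage statistic (USS) computed from paired 40-nt exonic/intronic coverage
    windows with differential screening and event-type enrichment, a trainable
    position-weight-matrix splice-site strength scorer on 9-nt donor and 23-nt
    acceptor windows, and a branch-point caller that locates the junction
    between the branch site and the intron 5' terminus while tolerating the
    branch-adenosine-to-T misincorporation signature of reverse transcription
    across the 2',5'-phosphodiester bond. A synthetic-data generator produces
    toy genomes, count tables, and lariat read sets with known ground truth so
    every stage is testable without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
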