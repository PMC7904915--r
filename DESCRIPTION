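Package: hepseq
Title: Exolytic Heparinase Digestion Modelling and Ladder Sequencing of
    Heparin Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Symbolic modelling of heparin/heparan-sulfate chains and their
    digestion by polysaccharide lyases (heparinases), including the exolytic
    reducing-end disaccharide release characteristic of PL15_2 family
    exo-heparinases.  Provides a text notation with parser and writer,
    disaccharide-unit decomposition and the eight-code composition table,
    elemental-formula and mass arithmetic with glycosidic B/C/Y/Z fragment
    ions, in-silico exhaustive endolytic digestion under heparinase I/II/III
    linkage specificities with 3-O-sulfation blocking, ozonolysis
    end-trimming and 2-aminobenzamide reducing-end labelling, stochastic
    (Gillespie) and deterministic time-course simulation of digestion pools
    with an exolytic/endolytic discrimination index, a nested-ladder
    composition-differencing sequencer that deduces ordered disaccharide
    sequences from partial-exolysis ladders, and seeded synthetic-data
    generators emulating HPLC molar-ratio measurements with multiplicative
    noise and labelling-efficiency bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    optparse,
    seqinr,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
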