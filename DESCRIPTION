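Package: ribologic
Title: Design and Simulation of Toehold-Switch Ribocomputing Logic Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for designing RNA-only logic circuits built from
    toehold switches, trigger RNAs and antisense RNAs.  Compiles Boolean
    and arithmetic logic (OR, AND, NIMPLY, XOR, NAND, half adder, half
    subtractor, Feynman gate) into circuit netlists, derives trigger and
    antisense sequences with extended-overhang and single-nucleotide-bulge
    design rules, screens candidate designs in silico with an internal
    secondary-structure and duplex-hybridization engine (ensemble-defect
    proxy, overhang accessibility, crosstalk), and predicts gate truth
    tables and inducer dose-response surfaces with a competitive
    hybridization equilibrium model.  Includes a generator of synthetic
    orthogonal switch libraries so every stage is testable without
    external part collections.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
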