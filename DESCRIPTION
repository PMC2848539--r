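Package: ifacecov
Title: Coverage and Accuracy of Protein-Protein Binding Sites in Local Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well local target-template sequence
    alignments cover protein-protein binding sites, and how accurately
    partial homology models built from such alignments reproduce those
    binding sites. Extracts interface residues from two-chain complexes by
    a van der Waals plus water-diameter distance criterion, computes
    per-alignment coverage, identity and similarity statistics under
    BLOSUM62, classifies full-interface-coverage (FIC) alignments,
    estimates the probability of full interface coverage as a function of
    alignment identity or similarity with a polynomial fit, and assesses
    partial models by Kabsch superposition and interface C-alpha RMSD.
    Includes a synthetic-data generator producing two-chain complexes,
    perturbed models and alignment pools with known ground truth, so the
    whole pipeline is testable without any external database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
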