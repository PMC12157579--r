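Package: barbedwire
Title: Prediction-Mode Triage of AlphaFold2 Models from pLDDT, Packing and Backbone Validation
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies every residue of an AlphaFold2 structure prediction
    into one of six prediction modes (predictive, unpacked high-pLDDT,
    near-predictive, pseudostructure, barbed wire, unphysical) by combining
    the per-residue pLDDT confidence stored in the B-factor field with a
    tertiary-contact packing score and backbone validation evidence
    (Ramachandran status, cis/twisted peptide bonds, CA virtual geometry,
    covalent bond-length and bond-angle z-scores).  Reads PDB and mmCIF
    models, writes per-residue text/JSON annotations, kinemage markup with
    mode-colored CA balls, and mode-filtered PDB subsets.  Includes a
    synthetic backbone decoy generator that builds torsion-scripted models
    with controlled geometric distortions and pLDDT profiles, and an
    overlap stage that scores mode residue sets against locally supplied
    disorder-annotation range files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
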