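Package: pepdesign
Title: Fixed-Backbone Sequence Design of Peptide Ligands at Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for amino-acid sequence design of short (6-residue) peptide
    fragments docked at a protein binding site. Extracts peptide-pocket
    complexes from multichain PDB structures, perturbs all-glycine peptide
    backbones within a bounded RMSD, featurizes complexes into five
    fixed-shape tensors (backbone N/O distance maps, binding-site sequence
    and secondary structure, oligomeric label), and trains an attention-based
    encoder-decoder network that proposes one or six candidate sequences per
    complex. Includes recovery-based evaluation statistics (overall and
    hot-spot sequence recovery, best-of-n, design diversity), a pluggable
    per-residue binding-energy interface with a deterministic surrogate,
    PSSM export for downstream redesign, and a synthetic complex generator
    with a planted geometry-to-sequence mapping for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
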