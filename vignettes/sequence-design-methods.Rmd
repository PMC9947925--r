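---
title: "Methods: fixed-backbone sequence design of peptide ligands at protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-backbone sequence design of peptide ligands at protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Many protein–protein interactions are mediated by short contiguous
stretches of backbone at the interface. `pepdesign` treats the inverse
folding problem at that scale: given the backbone pose of a 6-residue
peptide fragment docked against a binding pocket of 24–48 residues, predict
amino-acid sequences for the peptide that are compatible with the pocket.
The design unit is deliberately small — larger binders can be designed as
overlapping six-residue windows — and the backbone is fixed: the network
sees geometry and pocket chemistry, never the peptide's native residue
identities.

The package implements the full desk-scale pipeline around that model:

1. **Extraction** — enumerate 6-residue fragments of a ligand chain from a
   multichain PDB structure, select the 24–48-residue pocket patch on the
   partner chain(s), and apply dataset selection filters.
2. **Perturbation** — strip the peptide to all-glycine and perturb its
   backbone within a bounded RMSD of the native pose, emulating the
   uncertainty of docked or generated backbones.
3. **Featurization** — five fixed-shape tensors per complex.
4. **Sequence design** — a single-output encoder–decoder and a six-output
   variant built on its frozen encoder.
5. **Evaluation** — sequence recovery overall and at energetic hot-spot
   positions, best-of-n recovery, design diversity, composition tables, and
   PSSM export for downstream constrained redesign.

## Model inputs

Each complex is encoded as five tensors (zero is the pad value throughout;
amino acids use the 20 canonical one-letter codes in alphabetical order,
coded 1–20; secondary structure H/E/L is coded 1–3):

| input | shape | content |
|---|---|---|
| 1 | 48 × 6 × 2 | site–peptide backbone distance maps: N–N distances in channel 1, O–O in channel 2, Å |
| 2 | 48 | pocket amino-acid codes, chain order |
| 3 | 48 | pocket secondary-structure codes |
| 4 | 6 × 6 × 2 | peptide-internal N–N and O–O distance maps, Å |
| 5 | 1 | interface class: 1 homo-oligomeric, 0 hetero-oligomeric |

Rows beyond the true pocket size are zero, and the three site inputs agree
about which rows are padding. Distances are stored in raw Å. Because all
geometry channels are backbone-only, featurization is invariant to the
peptide's residue identities: an all-glycine copy of a complex featurizes
to identical maps.

## Network architecture

The network is implemented in this package on a small reverse-mode
automatic-differentiation engine over dense matrices (BLAS); there is no
external deep-learning dependency. Architecture, in the package's default
configuration (`designer_config()`):

* **Encoder block A** — eight 3 × 3 convolution layers over the 48 × 6
  intermolecular maps (channel widths 16→32), ReLU activations. After every
  layer, activations at padded site rows are re-zeroed; the block ends with
  a masked mean over the site axis, giving one feature vector per peptide
  position. Stride-1 convolutions with per-layer masking were chosen over
  stride pooling deliberately: masking makes a padded row behave exactly
  like the implicit zero boundary of the convolution, so predictions are
  invariant to how many all-zero rows follow the true pocket — a contract
  the test suite checks directly.
* **Encoder block B** — four 3 × 3 convolution layers over the 6 × 6
  peptide-internal maps, mean-pooled to per-position vectors.
* **Context** — learned embeddings of the pocket's amino-acid codes
  (dimension 16) and secondary-structure codes (dimension 8), averaged over
  true pocket residues only (masked mean), concatenated with the
  oligomeric label and broadcast to all six positions.
* **F** — per-position concatenation of block A, block B and context,
  projected through a tanh layer to depth 256. F's second dimension is
  always exactly the six positions to predict.
* **Decoder** — a bidirectional LSTM pass over F (48 units per direction)
  produces annotations from the concatenated forward/backward hidden
  states; a 96-unit LSTM with additive (Bahdanau-style) attention over the
  annotations then emits six 20-way softmax distributions. Training uses
  teacher forcing (the true previous residue conditions each step);
  prediction decodes greedily by argmax. No beam search.

The six-output model copies the trained encoder verbatim and freezes it
(the optimizer never updates those weights, and the test suite checks they
are bit-identical after training). Its own decoder runs five sequential
passes over the same annotations; pass *k* starts from the final LSTM
state of pass *k − 1*, which is how each prediction is conditioned on the
previous one. Initial-state injection was chosen over concatenating the
state into the inputs because it adds no parameters and keeps the five
passes architecturally identical. The single-output model's prediction is
appended as design number six, which makes best-of-six recovery ≥
single-output recovery a structural identity rather than an empirical
claim.

Two numerical choices matter in practice. Distance maps are multiplied by
0.1 on entry to the first convolution: raw-Å inputs (values up to ~15)
push Glorot-initialized layers far from their linear regime and slow
optimization by an order of magnitude. And gradients are clipped to a
global L2 norm of 5 before each Adam update. Neither changes what is
stored in the tensors.

## Training

The single-output model trains with minibatch Adam on categorical
cross-entropy over full target sequences, following a staged learning-rate
schedule; the default mirrors the reference protocol of 5 epochs at 1e-3,
5 at 1e-4 and 2 at 2e-5 (`train_config()`), with the six-output variant at
4/4/2 (`train_config_multi()`). Training can be repeated with restarts,
selecting the candidate with the highest summed recovery on
hetero-oligomeric validation subsets (`select_best_model()`, ties to the
first listed).

The six-output objective is, per sample, the **minimum** over the five
decoder passes of the sequence cross-entropy, plus a diversity penalty —
λ times the mean pairwise probability overlap between passes (λ = 0.1 by
default). The min lets different passes specialize on different plausible
sequences instead of forcing all five onto the single target; the penalty
discourages the degenerate solution where all passes collapse onto one
output. A squared-error alternative (`loss = "mse"`) between output
distributions and the one-hot target is available behind a flag.

All randomness (initialization, shuffling, perturbation, synthetic data)
is seeded, and repeated runs with one seed are bit-identical on one
machine with one BLAS.

## Synthetic complexes and the planted mapping

Everything is testable without downloads through the synthetic generator
(`toy_spec()`, `generate_toy_complex()`): an ideal-geometry peptide built
from canonical φ/ψ dihedrals (helix −60/−45, strand −120/+130, extended
−80/+150) with standard bond geometry (N–CA 1.46 Å, CA–C 1.52 Å, C–N
1.33 Å, C=O 1.23 Å), posed against a pocket of rigid single-residue
backbone templates placed 4–8 Å from peptide anchor atoms in scattered
orientations. Pocket identities and secondary-structure labels are drawn
uniformly; Gaussian coordinate jitter is available (default 0).

The generator plants a deterministic geometry→sequence mapping
(`planted_rule_read()`): the target at peptide position *i* is a fixed
function of the nearest pocket residue's identity and a 6-Å distance bin.
With zero noise the mapping has no label conflicts and a non-learned rule
reader recovers 100% of targets, which upper-bounds what a trained model
can reach. The central wiring test trains the default-size single-output
model on 50 planted complexes under an extended schedule (90/30/20 epochs
at 2e-3/1e-3/5e-4, minibatch 10) and requires ≥95% training-set recovery —
a test of whether gradients, masking, attention and decoding are all
connected correctly, not of generalization.

What the toys do **not** emulate: real side-chain packing, rotamers,
crystal contacts, B-factors, sequence statistics of real interfaces, or
any physical energy. Passing tests therefore demonstrate correctness of
the machinery at desk scale, and nothing about recovery rates on real
PDB-derived interfaces, which would require the full training corpus.

## Extraction, energies and filters

The pocket is the set of partner residues whose minimum backbone-atom
distance to any peptide backbone atom is ≤ 10 Å (configurable), truncated
to the nearest 48 when over-subscribed and rejected below 24. Residues may
span several partner chains; they are re-sorted to chain order after
selection. Homo- vs hetero-oligomeric labels come from pairwise sequence
identity of the two chains at a 90% threshold over the shorter chain.

Physics-based interface scoring is out of scope, so energy-dependent rules
go through a pluggable `energy_model` interface. The packaged surrogate is
a deterministic weighted contact count (5 Å shell, linear taper,
hydrophobicity-weighted, labeled "surrogate REU"); an external per-residue
table can be substituted (`table_energy()`, or `--ddg` on the command
line). Alanine scanning defines per-residue increments as
ΔΔG~i~ = ΔG~B~(i→Ala) − ΔG~B~(native), so a residue that contributes to
binding has a **positive** increment — the convention under which the
hot-spot threshold (ΔΔG~i~ ≥ 3 REU, boundary inclusive) is stated.

Candidate complexes pass five filters, and a rejected record reports the
first criterion it failed: (1) ≥2 peptide residues with ΔΔG~i~ > 0.5 REU;
(2) ≥3 non-terminal peptide residues within 6 Å of the pocket, measured
between closest side-chain heavy atoms — on backbone-only input an
idealized Cβ (Cα for glycine) is the side-chain proxy; (3) resolution
thresholds (2.0/2.5/3.5 Å for homo-/hetero-oligomeric/antibody complexes)
when the header supplies a resolution, skipped with a warning otherwise;
(4) negative binding energy; (5) at least one non-polar residue among the
peptide's hot-spots. For criterion 5, when no residue reaches the 3 REU
hot-spot threshold, the >0.5 REU contributors from criterion 1 stand in:
the composition requirement is about the residues that carry the binding,
and an empty hot-spot set would otherwise veto complexes the other
criteria accept.

## Perturbation protocol

`perturb_peptide()` draws a target RMSD uniformly in (0, 1.07] Å, applies
a rigid-body move (rotation ≤ 10° about the centroid, translation ≤ 1 Å)
plus per-atom Gaussian noise, and scales the net displacement to hit the
target exactly — coordinate RMSD is linear in the displacement, so no
iterative search is needed. RMSD is computed without superposition over
N, CA, C, O: the peptide's pose relative to the pocket is exactly what the
model must be robust to, so rigid drift counts as deviation. Draws that
break consecutive CA–CA geometry (outside 3.2–4.2 Å) are redrawn. The
bound is enforced per draw; the realized mean over many draws sits near
the middle of the band and is reported rather than targeted.

## Secondary structure

Three states from backbone dihedrals: H for φ ∈ (−100°, −30°) and
ψ ∈ (−80°, −5°); E for φ ∈ (−170°, −50°) with ψ ∈ (90°, 180°) or
(−180°, −170°); L otherwise. H/E runs shorter than 3 are smoothed to L and
chain-terminal residues are L. The assignment is a pure function of
coordinates (storage order of chains cannot change any label) and needs no
external binary.

## Problem sizes and limitations

The shipped tests run at desk scale: 100 synthetic complexes for shape
conformance, 1,000 draws for the perturbation bound, 50 complexes for the
memorization oracle (a few minutes on one CPU), and 6–12 complexes for
training-behavior checks. Known limitations:

* Absolute recovery rates on real interfaces are out of scope; they
  require the full PDB-derived corpus and physics-based refinement.
* The surrogate energy is not a physical potential; all energy-conditioned
  outputs carry the name of the energy model that produced them.
* The dihedral secondary-structure assignment is a stand-in for a full
  hydrogen-bond-based method.
* No side-chain reconstruction, mmCIF support, or assembly expansion;
  PDB `ATOM` records only.
* Greedy decoding only; per-position probabilities are exported (PSSM) for
  downstream samplers that want more than the argmax sequence.
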