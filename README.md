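# pepdesign

Fixed-backbone amino-acid sequence design of short peptide ligands docked
at protein–protein interfaces, in R.

## The problem

Protein–protein interfaces are often dominated by a short stretch of
backbone on one side of the contact. `pepdesign` treats inverse folding at
that scale: given the backbone pose of a **6-residue peptide fragment**
against a **24–48-residue binding pocket**, propose peptide sequences
compatible with the pocket. The backbone is fixed and the peptide's native
identities are hidden from the model; only geometry and pocket chemistry
are visible.

Each complex is encoded as five tensors: site–peptide backbone distance
maps (48 × 6 × 2, N–N and O–O channels, Å), pocket amino-acid codes (48),
pocket secondary-structure codes (48), peptide-internal distance maps
(6 × 6 × 2), and a homo/hetero-oligomeric label — zero-padded beyond the
true pocket size. A convolutional encoder turns these into a feature
tensor *F* with one column per peptide position; a bidirectional LSTM
plus an additive-attention LSTM decoder emits a 20-way distribution per
position. A single-output designer decodes one sequence greedily; a
six-output variant reuses the frozen encoder and runs its decoder five
times, each pass conditioned on the previous pass's final hidden state,
with the single-output prediction appended as design six.

Evaluation is recovery-based: overall sequence recovery
*R*<sub>all</sub> = (identical positions)/(all positions), hot-spot
recovery *R*<sub>hot-spot</sub> restricted to residues whose alanine-scan
increment ΔΔG<sub>i</sub> ≥ 3 REU, best-of-n recovery for multi-output
design, and mean pairwise design diversity. Physics-based scoring is out
of scope; energy-dependent steps go through a pluggable `energy_model`
with a deterministic contact-count surrogate (labeled "surrogate REU")
and an external-table adapter.

The neural network, including its reverse-mode automatic differentiation,
is implemented inside the package on plain BLAS matrix algebra — there is
no deep-learning framework dependency.

## Worked example

Synthetic complexes carry a planted geometry→sequence mapping, so the
whole pipeline is testable without downloading structures:

```r
library(pepdesign)

# 20 synthetic peptide-pocket complexes with a planted mapping
ds  <- planted_mapping_dataset(toy_spec(n_complexes = 20, seed = 42))
fts <- lapply(ds$records, featurize_complex)
ds$records[[1]]
#> <complex_record> toy000042: peptide LAAIIL (chain P, start 1), site 40 residues, homo-oligomeric
fts[[1]]
#> <feature_tensors> inter 48x6x2, site 40/48 residues, oligo=1

# train the single-output designer to memorize the planted mapping
model <- build_seq_designer(designer_config(seed = 1))
fit   <- train_seq_designer(model, fts, ds$targets,
                            train_config_overfit(seed = 1))
tail(fit$history, 1)            # final training loss: 0.029
model_recovery(model, fts, ds$targets)
#> [1] 1

# design for the first complex
pred <- predict_single(model, fts[[1]])
pred
#> <seq_prediction> LAAIIL
sequence_recovery(ds$targets[1], pred$sequence)
#> [1] 1

# hot-spots under the surrogate energy, and the full report
labs <- alanine_scan(ds$records[[1]], surrogate_energy())
recovery_report(ds$targets[1], pred$sequence, labels = labs,
                ss = ds$records[[1]]$peptide$ss,
                energy_model_name = "surrogate")
#> <recovery_report> R_all = 1.000 (6 residues), R_hotspot = 1.000 (3 hot-spots), energy model: surrogate

# per-position probabilities as a PSSM, with top-k allowed-residue sets
pssm <- export_pssm(pred)
sapply(pssm$allowed$k3, paste, collapse = "")
#> [1] "LSD" "AIL" "AIL" "IAW" "ILW" "LIQ"
```

A recovery of 1.0 here says the machinery is wired correctly (the planted
mapping is deterministic and the model memorizes 20 training complexes);
it says nothing about recovery on real interfaces, which requires
full-scale training data — see the methods vignette
(`vignettes/sequence-design-methods.Rmd`) for what the synthetic data do
and do not emulate.

The same pipeline is scriptable from a shell via `exec/pepdesign`:

```sh
pepdesign simulate --n 20 --seed 42 --out-dir work
pepdesign train    --tensors work/tensors.json --targets work/targets.tsv \
                   --schedule overfit --out work/model.rds
pepdesign design   --model work/model.rds --in work/tensors.json \
                   --out work/designs.fasta --n 1
pepdesign evaluate --native work/native.fasta --designs work/designs.fasta \
                   --out work/report
```

Other stages: `extract` (PDB → complex records + manifest), `perturb`
(all-glycine backbones within a bounded RMSD), `featurize`, `export-pssm`.

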