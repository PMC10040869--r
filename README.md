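# ligandvs

Target-driven, machine-learning-enabled ligand-based virtual screening for
early-stage hit identification.

## The problem

Ligand-based virtual screening needs known active and inactive compounds —
exactly what a novel protein target lacks. `ligandvs` works around this by
*target expansion*: starting from a single protein accession, it collects
sequence-similar proteins (identity ≥ 40% by default), pools their
experimentally annotated ligands into a training set, and uses that borrowed
chemistry to rank a screening library for the original target. The package is
aimed at computational and medicinal chemists who want a reproducible,
scriptable screening pipeline that also runs fully offline against synthetic
fixtures.

## The method

The pipeline chains seven stages, each usable on its own:

1. **Target expansion** — homology hits at ≥ 40% identity (pluggable backend:
   CSV fixture or local `blastp`).
2. **Compound retrieval & labeling** — bioactivity records are pooled over the
   expanded targets; the dominant assay value type is selected; measurements
   are normalized to nM and a compound is **active** when its median value
   ≤ 1000 nM (Ki/IC50/EC50) or ≥ 50% inhibition, boundaries inclusive.
3. **Vectorization** — Morgan (radius 2, 1024 bits, default), atom-pair,
   topological-torsion, or 166-key MACCS fingerprints.
4. **Model training** — random undersampling to class balance, then
   grid-searched random forest (trees ∈ {50,100,200}, depth ∈ {4,6,10,12}) and
   multilayer perceptron (hidden ∈ {(50,50,50),(50,50),(50)}, activation ∈
   {tanh, relu}, α ∈ {0.01, 1e-4}), scored by mean 10-fold cross-validated
   AUC. Metrics: AUC, precision, recall, specificity, F1, G-mean
   √(recall·specificity), and IBA (1 + 0.1·(recall − specificity))·recall·specificity.
5. **Virtual screening** — each model assigns a probability-of-active score to
   every library compound.
6. **Post-VS analysis** — QED and physicochemical profiles, score
   distributions, k-means clustering of chemical space (k = 100), t-SNE
   visualization, and a Tanimoto-coefficient (Tc = |a∧b|/|a∨b|) baseline
   search.
7. **Data processing** — per-model ranks are averaged into an ensemble rank;
   the top 1% of each model's list and of the ensemble list are merged and
   deduplicated into the virtual-hit report.

A **retrospective validation** protocol withholds the query target's own
actives from training, then checks that the trained models score them above a
general screening library (Welch's t-test on the score means).

## Worked example

Generate a synthetic structure–activity fixture (a homology family whose
actives share an aryl-sulfonamide chemotype, plus a decoy library) and run the
retrospective validation from the command line:

```sh
Rscript inst/cli/lvs.R make-fixtures --dir fixtures --seed 5 --library-size 300
Rscript inst/cli/lvs.R retro --uniprot P10001 --fixtures fixtures \
        --out retro.csv --seed 5
```

which prints:

```
  model mean_score_actives mean_score_library       p_value significance
1    rf          0.9504247         0.09721251 9.891509e-200          ***
2   mlp          0.9989014         0.05038337 1.010951e-197          ***
```

Both models assign the withheld actives (never seen in training) a far higher
mean score than the 300-compound decoy library — mean 0.95 vs 0.10 for the
random forest — and the difference is significant at the *** (p < 0.001)
level. The same protocol is available in R via `run_retrospective()`, and the
full seven-stage pipeline via `run_config()` + `run_pipeline()`, which writes
one folder per stage plus a deterministic `summary.json`.

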