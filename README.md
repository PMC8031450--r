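# pocketgcn

Graph-convolutional regression of protein–ligand binding affinity from 3D
binding-pocket structure, in pure R.

Structure-based drug discovery needs fast scoring functions: given the 3D
structure of a protein–ligand complex, estimate how tightly the ligand
binds, expressed as pKd/pKi = −log₁₀(Kd or Ki). `pocketgcn` is for
computational chemists and method developers who want a complete,
inspectable implementation of a distance-binned graph-convolutional
scoring model together with its whole data pipeline — structure reading,
pocket extraction, featurization, dataset splitting, docking-pose
augmentation, training, and evaluation — with every step testable offline
against a synthetic benchmark with a planted, known signal.

## The model

The binding pocket — all ligand heavy atoms plus protein heavy atoms
within 4.0 Å of any ligand atom — becomes a graph. Each node carries 13
descriptors: a 9-class element one-hot (B, C, N, O, P, S, Se, Halogen,
Metal), hybridization, heavy valence, hetero valence, and the Gasteiger
partial charge (computed by Open Babel). Pairwise proximities are encoded
in *n* ∈ {1, 2, 4, 8} binary adjacency matrices, bin *k* holding pairs
with

&nbsp;&nbsp;&nbsp;&nbsp;4(k−1)/n < d<sub>ij</sub> ≤ 4k/n,

restricted to inter-molecular pairs up to 4 Å and intra-molecular pairs
up to 2 Å. Graphs are zero-padded to 200 nodes; larger pockets are
filtered out.

Each bin's matrix A is normalized with self-loops,
Â = D<sup>−1/2</sup>(A + I)D<sup>−1/2</sup>, and one graph-convolution
layer computes F′ = ReLU(Â F W). The network runs one convolution block
per bin (GC widths 128/128/32 interleaved with node-wise dense layers and
dropout 0.5), sums each block's node features (graph gather),
concatenates the blocks, and regresses the affinity through a final dense
layer. Training is Adam (learning rate 0.001) on mean squared error with
early stopping on validation loss. Performance is reported as RMSE, MAE,
Pearson R, and the regression-line SD
√(Σ(yᵢ − (a + bxᵢ))² / (N−1)).

Because real affinity databases (PDBbind, CSAR) are gated downloads, the
package ships a synthetic pocket generator that plants a linear
contact-count affinity — exactly the information the binned adjacency
matrices expose — so the full pipeline is verifiable end to end from
nothing but code. See `vignette("pocketgcn-methods")` for the complete
model description and design rationale.

## Worked example

Generate a small synthetic dataset on disk, featurize it through the real
file pipeline (PDB/mol2 parsing + Open Babel), fit the 2-bin model, and
evaluate on held-out complexes:

```r
library(pocketgcn)

params <- synth_params(seed = 7)          # planted affinity, labels ~2-12
man    <- generate_dataset(300, params, dir = tempfile())
fd     <- featurize_dataset(man, n_bins = 2)
graphs <- fd$graphs
graphs[[1]]
#> Pocket graph 'syn00001': 21/200 nodes, 2 distance bin(s), label 5.263

fit <- pocket_gcn(graphs[1:240], graphs[241:270], seed = 1)
fit
#> Graph-convolutional binding-affinity model
#> Call: pocket_gcn(train = graphs[1:240], validation = graphs[241:270], seed = 1)
#> Trained on 240 graphs, validated on 30 (45 epochs, best 30, early stop)
#> Best validation MSE: 0.5398

evaluate_fit(fit, graphs[271:300])
#> Affinity prediction evaluation (n = 30)
#>   RMSE 0.8971 | MAE 0.6661 | Pearson R 0.9258 | SD 0.7512
```

The held-out RMSE is in pKd units: predictions are off by about 0.9 log
units of affinity on average, and R ≈ 0.93 says the ranking of binders is
largely recovered — here that reflects the network re-discovering the
planted contact-count weights from structure alone. `predict(fit,
new_graphs)` returns named affinity predictions; `plot(fit)` shows the
training curves; `summary(fit)` adds the architecture and validation
metrics.

The same pipeline drives real data: `read_protein()` / `read_ligand()`
parse PDB and mol2/SDF files, `parse_index()` reads PDBbind-style index
files, `make_splits()` builds core-set-excluded train/validation splits,
and `augment_with_poses()` applies the docking-pose filters (RMSD ≤ 3 Å,
best 3 poses per complex). A command-line driver covering the whole
pipeline lives in `inst/cli/pocketgcn.R`.

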