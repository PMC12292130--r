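# atacGAT

Cell-type annotation for scATAC-seq by integrating chromatin
accessibility with genome sequence. Given an annotated reference and an
unannotated query dataset quantified over the same peaks, `atacGAT`
transfers labels to the query cells with a dual-branch model:

* a **sequence branch** — a 1-D CNN trained to predict each peak's binary
  accessibility across all cells from the peak's DNA window; the
  transposed weights of its per-cell output layer are 64-dimensional cell
  embeddings, and an exact k-nearest-neighbour graph over them connects
  cells with similar regulatory sequence preferences
  (`A_ij = 1` iff cell *j* is among the *k* nearest neighbours of cell *i*);
* an **accessibility branch** — TF-IDF weighting and truncated-SVD
  spectral embedding of the peak-by-cell matrix to 32 dimensions,
  followed by mutual-nearest-neighbour batch correction, giving the node
  features;
* a **graph attention network** — two GAT layers (4 heads + 1 head,
  `h_i' = σ(Σ_{j∈N(i)} α_ij W h_j)` with softmax-normalized attention
  `α_ij`) trained transductively with reference-node cross-entropy plus a
  gradient-reversal domain-adaptation loss, producing per-query-cell
  log-probabilities over the reference classes.

Evaluation (accuracy, macro-F1 = unweighted mean of per-class
`F1_c = 2·P_c·R_c/(P_c+R_c)`, best-method-relative scores), a synthetic
scATAC-seq generator with motif-planted peaks and batch-confounded
accessibility programs, and genome-free / peak-free ablation modes are
included. Who it is for: anyone annotating scATAC-seq queries against an
scATAC-seq reference without recourse to scRNA-seq, and anyone who needs
a controlled, fully synthetic testbed for such intra-omics annotators.

## Worked example

Simulate a small annotated reference plus query, run the full pipeline,
and evaluate against the withheld truth:

```r
library(atacGAT)

sim <- generate_dataset(synthetic_config(
  n_cell_types = 3, n_cells_ref = 150, n_cells_query = 75,
  n_peaks = 400, peak_width = 300, seed = 42))

run <- run_pipeline(
  sim$reference, sim$query, sim$genome, outdir = "example_out",
  mode = "full", k = 10, d_spec = 8,
  seq_config = seq_model_config(window_length = 320, stem_channels = 24,
                                n_towers = 0, pool_width = 160,
                                post_conv_channels = 32, batch_size = 64,
                                learning_rate = 3e-3, max_epochs = 30,
                                n_validation_peaks = 60),
  gat_cfg = gat_config(learning_rate = 1e-3, max_epochs = 150),
  seed = 42, truth = sim$query_labels, verbose = FALSE)

run
#> <pipeline_run> mode 'full', 75 query cells annotated
#>   accuracy 1.0000  macro-F1 1.0000

glance(run$metrics)
#> # A tibble: 1 x 4
#>   accuracy macro_f1 n_classes n_cells
#>      <dbl>    <dbl>     <int>   <int>
#> 1        1        1         3      75

head(tidy(run$result), 3)
#> # A tibble: 3 x 3
#>   cell_id  predicted_label confidence
#>   <chr>    <chr>                <dbl>
#> 1 qry_0001 type1                0.965
#> 2 qry_0002 type2                0.969
#> 3 qry_0003 type3                0.966
```

`accuracy` is the fraction of query cells whose predicted label matches
the withheld truth; `macro_f1` averages per-class F1 scores, so rare
types weigh as much as common ones; `confidence` is the probability of
the winning class from the GAT's log-softmax. `example_out/` receives the
predictions TSV (one row per query cell with per-class log-probabilities),
node features, edge index, model checkpoints, per-class metrics and a
`manifest.yaml` recording every parameter and seed.

A command-line interface with `simulate`, `train-seq`, `embed`,
`build-graph`, `annotate`, `evaluate` and `run` subcommands lives at
`inst/cli/atacgat.R` (after installation:
`Rscript -e 'cat(system.file("cli/atacgat.R", package = "atacGAT"))'`).

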