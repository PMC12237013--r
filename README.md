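# cbcgnn

Graph neural networks for sepsis classification from complete blood count
(CBC) time series, in pure R (with small C++ kernels for the sparse
message-passing operations).

Routine CBC panels — hemoglobin, red blood cells, white blood cells (WBC),
mean corpuscular volume and platelets, plus age and sex — are measured
repeatedly for most inpatients. Standard tabular classifiers score each
measurement independently, ignoring that measurements of one patient are
correlated and temporally ordered. `cbcgnn` represents measurements as graph
nodes and classifies them with minimal message-passing networks:

* **Similarity graphs** — a homogeneous k-nearest-neighbor graph on the
  standardized features, and a heterogeneous graph in which measurements
  connect to percentile-bin nodes of each blood parameter (ten bins per
  parameter by default).
* **Patient-centric graphs** — within a patient, arcs run past→present
  (*directed*), future→present (*reversed directed*), or both
  (*undirected*). With sepsis concentrated at the final position of a
  sequence, the reversed graph keeps the rare sepsis nodes free of control
  dilution while still denoising control sequences: a *structure-induced
  bias* that lifts AUROC well above tabular baselines.
* **Layers** — GraphSAGE (mean), GCN, GAT, GATv2 and GIN, each written from
  its defining update rule `h'_v = act(aggregate_{u->v} transform(h_u))`
  with hand-derived reverse-mode gradients, trained full-graph with Adam,
  validation-loss early stopping and best-epoch restore. `predict_proba()`
  returns per-node class probabilities for every model in the package.
* **Baselines & metrics** — logistic regression, decision tree, random
  forest (grid-tuned with 10-fold CV) and a dense 2-layer MLP; AUROC
  (rank/Mann–Whitney form), macro-F1 and Matthews correlation; uniform
  noise-feature injection for robustness experiments.
* **Interpretability** — graph-compatible partial dependence (100-point
  grids between the 5% and 95% feature percentiles), normalized-variance
  feature importance, average-linkage clustering of models, and attention
  summaries split by the label concordance of each arc.
* **Synthetic cohorts** — a seeded generator reproducing the structural
  descriptors of routine hospital CBC data: ~4% measurement-level sepsis
  prevalence, variable-length sequences, two thirds of sepsis cases as
  singleton measurements, 92.14% of in-sequence sepsis at the final
  position, class-conditional feature shifts (WBC↑, platelets↓,
  hemoglobin↓, MCV↑, age↑), a per-patient random effect, and an external
  split with a mild site shift.

See `vignettes/cbcgnn-methods.Rmd` for the models, their assumptions, and
all design decisions.

## Worked example

```r
library(cbcgnn)

co  <- generate_cohort(cohort_config(n_patients = 5000, seed = 1))
unlist(cohort_stats(co)[c("sepsis_prevalence", "singleton_sepsis_fraction",
                          "last_position_sepsis_fraction")])
#>             sepsis_prevalence     singleton_sepsis_fraction
#>                    0.04395229                    0.64519906
#> last_position_sepsis_fraction
#>                    0.94174757

std <- fit_standardizer(co)                      # train-split moments only
g   <- build_patient_graph(co, "reversed", std)  # future -> present arcs
m   <- train_node_classifier(
  g, model_spec("gat", hidden_dim = 64),
  train_spec(learning_rate = 3e-3, max_epochs = 600, patience = 5, seed = 1))
p   <- predict_proba(m, g)[, "sepsis"]
internal <- co$split == "internal_test"
auroc(co$label[internal], p[internal])
#> [1] 0.9412061
```

The cohort reproduces the generator's calibration targets (64.5% singleton
sepsis, 94.2% last-position sepsis on this seed), and the GAT on the
reversed-directed patient graph reaches internal-test AUROC 0.941, compared
with 0.894 (undirected), 0.883 (directed) and 0.923 for the tabular MLP on
the same cohort: the reversed graph's structure-induced advantage. (The
relative order of the directed and undirected modes varies across seeds on
synthetic cohorts; the reversed graph's lead does not. See the methods
vignette.)
Training stops when the validation loss has risen for `patience` consecutive
epochs and restores the best-validation parameters.

Experiment-scale runs go through the runner:

```r
cfg <- experiment_config(cohort = cohort_config(n_patients = 5000),
                         seeds = 1:3, patient_models = c("gat", "sage", "gcn"),
                         learning_rate = 3e-3, max_epochs = 1000)
rep <- run_patient_centric_benchmark(cfg)   # seed-mean AUROC per grid cell
```

or the CLI (`inst/cli/cbcgnn.R`):

```sh
Rscript inst/cli/cbcgnn.R generate --n-patients 5000 --seed 1 --out out/
Rscript inst/cli/cbcgnn.R benchmark-patient --seed 1 --out out/
```

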