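# dicersite

Multi-class prediction of human Dicer cleavage-site positions in pre-miRNA
hairpins.

Dicer cleaves a precursor miRNA hairpin at two inter-nucleotide intervals,
releasing the mature miRNA duplex. `dicersite` reformulates cleavage-site
prediction as multi-class sequence labeling over sliding windows
("cleavage patterns"): an `s`-nt window has `s − 1` intervals, and a window
is assigned class `k` when the site sits at its k-th interval, class 0 when
it holds none — so one interior site yields `s − 1` positive patterns
instead of a single centred one. Patterns and their parent hairpins (RNA
sequence plus dot-bracket structure) are encoded as overlapping 3-mer
tokens with placeholder completion (84 sequence / 39 structure tokens),
embedded, and processed by two Transformer-based encoder units whose
pooled features are combined by attentional feature fusion

    Z = M(X ⊕ Y) ⊗ X + (1 − M(X ⊕ Y)) ⊗ Y,   M = sigmoid(global + local bottleneck)

(or plain concatenation) before a softmax head over the `s` classes. The
neural engine — forward passes, hand-derived backpropagation, AdamW,
plateau scheduling, early stopping — is implemented inside the package on
base BLAS operations and validated by finite-difference gradient tests.

The package is aimed at researchers studying miRNA biogenesis or designing
siRNA precursors who want positional cleavage calls, and at method
developers who need a fully self-contained, synthetic-data-testable
reference implementation of this model family.

## What's inside

| Area | Functions |
| --- | --- |
| I/O | `read_fasta()`, `read_structures()`, `read_mature_annotation()`, `write_pattern_dataset()` / `read_pattern_dataset()` |
| Dataset construction | `infer_cleavage_sites()`, `generate_patterns()`, `generate_corpus_patterns()`, `build_dataset1()`, `build_dataset2()`, `split_folds()`, `cluster_redundancy()` |
| Encoding | `build_vocab()`, `tokenize_3mer()`, `sinusoidal_pe()`, `assemble_stream()` |
| Model | `dicer_model()`, `dicer_model_config()`, `predict()`, `predict_topk()`, `aff_fuse()`, `concat_fuse()`, `mscam()`, `aff_weight_diagnostics()` |
| Training | `dicer_train_config()`, `small_preset()`, `train_fold()`, `cross_validate()` |
| Evaluation | `evaluate_predictions()`, `top_k_accuracy()`, `macro_f1()`, `weighted_f1()`, `pmf_pse()`, `binarize()`, `binary_metrics()`, plus `tidy()` / `glance()` / `autoplot()` methods |
| Synthetic data | `sim_params()`, `simulate_hairpin()`, `simulate_corpus()` |
| Pipeline | `run_simulate()`, `run_build_dataset()`, `run_train()`, `run_evaluate()`, `run_predict()`; shell dispatcher in `inst/cli/dicersite.R` |

## Worked example

Simulate a small annotated corpus, build a class-balanced dataset,
train one fold at desk scale, and evaluate:

```r
library(dicersite)

corpus <- simulate_corpus(sim_params(n_hairpins = 72, noise = 0, seed = 11))
patterns <- generate_corpus_patterns(
  corpus$hairpins[, c("id", "sequence")], corpus$structures,
  corpus$annotations, pattern_config(s = 14)
)
dataset <- build_dataset2(patterns, neg_per_premirna = 2, seed = 11) |>
  split_folds(k = 5, seed = 11)
dataset
#> <dicer_dataset> 2016 patterns | pattern size 14 (14 classes) | variant: dataset2
#> class counts:  0:144 1:144 2:144 3:144 4:144 5:144 6:144 7:144 8:144 9:144 10:144 11:144 12:144 13:144

pre <- small_preset(s = 14, fusion = "aff", seed = 11)
fold <- train_fold(dataset, fold_id = 0, pre$model, pre$train)
fold$report
#> <dicer_evaluation> 404 patterns, 14 classes
#>   top-1 0.7748 | top-3 0.9579 | macro F1 0.7634 | weighted F1 0.7533
#>   PMF 0.8297 | PSE 0.2857 (N_TP = 364)
#>   binary: acc 0.9282 | spe 0.3793 | sen 0.9707 | mcc 0.3981
```

Reading the report: 77% of held-out windows get the exact interval
(chance ≈ 1/14 ≈ 0.071) and 96% have it in the top three candidates; among
windows where both truth and prediction are positive, 83% match exactly
(PMF) with a mean shift of 0.29 intervals (PSE) — errors are mostly
positive/negative confusions, not mislocalisation, which the low binary
specificity against near-boundary negatives also reflects. Each simulated
hairpin plants a `GYUC` motif immediately 5′ of both cleavage sites, which
is the determinant the model recovers.

An 80-nt hairpin with sites at intervals 27 and 49 reproduces the standard
counting identities:

```r
hp <- tibble::tibble(id = "h", sequence = strrep("ACGU", 20))
ann <- tibble::tibble(premirna_id = "h", arm = c("5p", "3p"),
                      start = c(6L, 50L), end = c(27L, 71L))
sites <- infer_cleavage_sites(hp, ann)    # intervals 27 and 49
pats <- generate_patterns(hp, sites, pattern_config(14))
nrow(pats); sum(pats$label > 0); sum(pats$label == 7)
#> [1] 67
#> [1] 26
#> [1] 2
```

## Documentation

The methods vignette (`vignettes/cleavage-site-model.Rmd`) describes the
model, its assumptions, every tunable parameter, what the synthetic
corpus does and does not emulate, and the package's numerical conventions.
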