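# hybriclass

DNA instance-based image classification by non-specific hybridization.

Instance-based (nearest-neighbour) classifiers need to compare a query
against every stored example — an operation that molecular chemistry does
for free, in parallel. hybriclass implements this idea end to end in
silico: grayscale digit images are encoded as 59-nt DNA strands by a
trained neural encoder so that visually similar images map to strongly
hybridizing sequences. The strands of each class form a "tube"; a query is
classified by adding the reverse complement of its strand to every tube
and picking the class with the highest summed equilibrium hybridization
yield:

```
label(q) = argmax_c  Σ_{t ∈ tube_c}  yield( revcomp(seq(q)), t )
```

The package is aimed at researchers in DNA computing / DNA data storage
who want a fully reproducible dry-lab testbed for similarity-encoded
molecular classification, without external thermodynamics software or
dataset downloads.

## What is inside

* **A two-state nearest-neighbor thermodynamics engine** — duplex minimum
  free energy by dynamic programming over SantaLucia (1998) unified
  dinucleotide stacks (with flat internal-mismatch and affine interior-loop
  penalties), then the closed-form two-state mass-action yield at 25 °C
  and 1 nM per strand. A backend contract
  (`hybridization_conditions(backend = "external_adapter", ...)`) lets a
  full secondary-structure engine stand in with the same call signature.
* **Three trainable models**, built on a small self-contained neural
  network engine (im2col convolutions, hand-derived gradients, Adam):
  a LeNet-5-style feature extractor with a 50-D FC2 feature head, a
  two-layer convolutional yield predictor (the differentiable surrogate of
  the thermodynamic oracle), and the feature-to-sequence encoder
  (50 → 128 → 4×59 with column-wise softmax).
* **The instance-based classifier**: tube libraries (FASTA-persistable),
  yield-sum classification, evaluation (accuracy, confusion matrix,
  intra/inter-class yields) and top-k neighbor retrieval.
* **A synthetic 10-class digit-glyph generator** plus an MNIST-dialect IDX
  reader, so the pipeline runs with no downloads but accepts the real
  dataset.
* A stage-wise command line (`inst/cli/hybriclass`) driven by one YAML
  config, writing manifests beside every artifact.

See `vignettes/hybriclass-methods.Rmd` for the model, the encoder loss
(confidence term + similarity-supervision term with thresholds T1/T2), and
the design decisions (surrogate refitting, hinge margins, threshold
calibration).

## Worked example

```r
library(hybriclass)

glyphs <- generate_glyph_dataset(200, seed = 11, n_test_per_class = 10)
fit <- hybriclass(glyphs$train$images, glyphs$train$labels, seed = 1)
#> stage 1/3: training feature extractor (2000 images)
#>   validation accuracy 1.000
#> stage 2/3: corpus of 20000 pairs
#>   corpus: 20000 pairs; training predictor
#>   holdout MSE 0.0204
#>   calibrated T1 = 13.92
#> stage 3/3: training encoder (5 refit rounds)
#>   refit 1: surrogate holdout MSE 0.0189
#>   ...
#> library: 2000 instances in 10 tubes

ev <- evaluate_classifier(glyphs$test$images, glyphs$test$labels,
                          fit$library, fit$feature_model,
                          fit$encoder_model, fit$conditions)
ev
#> Overall accuracy: 1.000 (0 misclassified)
#> Per-class accuracy:
#> 0 1 2 3 4 5 6 7 8 9
#> 1 1 1 1 1 1 1 1 1 1
#> Mean intra-class yield 1.000 vs inter-class 0.591
```

Reading the numbers: the backbone separates the glyph classes perfectly
(validation accuracy 1.000); the surrogate predicts oracle yields with
holdout MSE ≈ 0.02; and after encoding, a query strand's reverse
complement hybridizes at yield ≈ 1 with instances of its own class but
only 0.59 on average with other tubes — enough separation for the
yield-sum vote to classify all 100 held-out queries correctly (the fit
takes a few minutes on one CPU). Individual pieces are exposed too:

```r
s <- random_sequence(59, seed = 7)
predict_yield(s, reverse_complement(s))       # ~1.0: specific binding
duplex_free_energy("ATCGGATCCGAT", reverse_complement("ATCGGATCCGAT"))
#> [1] -16.89232  (kcal/mol at 25 C)
top_k_neighbors(glyphs$test$images[1, , ], fit$library, k = 50,
                fit$feature_model, fit$encoder_model)
```

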