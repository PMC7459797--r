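# mrimodal

Classification of 2D brain-MRI slices into the four standard tumor
imaging modalities — **T1, T1CE, T2, FLAIR** — for radiology pipelines
that must route or verify multimodal acquisitions automatically. The
hard cases are the pairs that look alike: T2 vs FLAIR tumors are both
hyper-intense (they differ mainly in fluid signal), and T1 vs T1CE
tumors both have shallow contrast.

The package implements the full pipeline as a reusable R library plus a
thin command-line tool:

1. **Hybrid contrast enhancement** — K-means intensity split (K = 2),
   edge-gated texture histogram equalization per cluster, DCT-domain
   alpha-rooting refinement.
2. **Feature extraction** — a pluggable backbone contract
   (224×224×3 in, 1000 features out) with a deterministic seeded toy
   backbone; adapters for pretrained VGG-style networks are defined but
   require externally supplied weights.
3. **Correntropy-based group-sparse feature selection (CML-ELM)** —
   accelerated proximal minimization of the Welsch loss
   `Σ [1 − exp(−r²/2σ²)]` with a group-L2 penalty `p₀ Σⱼ ‖Wⱼ‖₂` over
   feature rows, backtracking step-size search, momentum restarts, and
   an ELM-driven MSER stopping rule.
4. **PLS fusion** — direction pairs `(uᵢ, vᵢ)` maximizing
   `Cov(Au, Bv)` from one SVD of the cross-covariance; fused features
   are the concatenated score matrices.
5. **Extreme learning machine** — random sigmoid hidden layer, output
   weights solved in closed form from `β = (H'H + I/c)⁻¹H'T`.
6. **Metrics** — accuracy, FNR (= 100 − accuracy), confusion matrices,
   multiclass MCC, repeated-run summaries (population variance, SEM),
   and normal-theory confidence margins.
7. **Simulators** — modality-mimicking 256×256 brain phantoms (with
   deliberate T2/FLAIR overlap) and feature tables with known
   informative columns, so everything is testable without gated
   clinical data.

## Worked example

Simulate 40 phantoms (10 per class), run the whole pipeline with a
60:40 stratified split, and evaluate the held-out slices:

```r
library(mrimodal)
res <- run_pipeline(pipeline_config(seed = 7L))
```

This prints nothing by itself; the result object carries everything:

```r
cat(sprintf("train accuracy: %.2f%%\ntest accuracy:  %.2f%%\ntest MCC:       %.4f\n",
    res$metrics_train$accuracy, res$metrics_test$accuracy, res$mcc_test))
#> train accuracy: 100.00%
#> test accuracy:  87.50%
#> test MCC:       0.8377
res$metrics_test$confusion
#>        predicted
#> truth   FLAIR T1 T1CE T2
#>   FLAIR     3  1    0  0
#>   T1        0  4    0  0
#>   T1CE      1  0    3  0
#>   T2        0  0    0  4
```

Training fits perfectly; 14 of 16 held-out slices are classified
correctly, and the two errors are the expected confusions (FLAIR→T1,
T1CE→FLAIR neighborhoods). Selection reduced each 1000-column feature
block to a few dozen columns (31 and 38 here) before fusion.

The statistics utilities reproduce published-style run summaries: for
three repeated accuracies 97.37, 97.76, 98.16,

```r
s <- summarize_runs(c(97.37, 97.76, 98.16))
s
#> <run_summary> n=3  min 97.370  avg 97.763  max 98.160  var 0.1040  sd 0.3225  sem 0.1862
round_half_up(ci_margin(s$sem, 95), 3)
#> [1] 0.365
```

i.e. 97.763 ± 0.365 at the 95% level.

## Command line

```sh
exec/mrimodal simulate --what phantoms --n 40 --out phantoms/ --seed 7
exec/mrimodal extract --backbone toy --in phantoms/ --out features.csv --seed 7
exec/mrimodal select --features features.csv --out selected.csv --seed 7
exec/mrimodal pipeline --seed 7 --out run7/
```

Subcommands: `simulate`, `enhance`, `extract`, `select`, `fuse`,
`train`, `predict`, `evaluate`, `stats`, `pipeline`.

## Method vignette

See `vignettes/multimodal-classification.Rmd` for the models, the
default parameters and their rationale, numerical choices, what the
simulators do and do not emulate, and known limitations.
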