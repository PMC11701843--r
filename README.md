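# mutbench

Benchmarks of **cross-context generalization for transcriptomic
mutation-status classifiers**: do smaller, more regularized gene-expression
models transfer better to a new dataset or a held-out cancer type than the
models that simply perform best on held-out data?

The package is aimed at computational cancer biologists who train
classifiers of driver-gene mutation status from bulk RNA-seq and want a
tested, reproducible harness for the whole experiment: label construction
from point mutations plus copy-number events, hypermutation filtering,
cancer-type validity rules, regularization sweeps for linear and neural
models, two competing model-selection strategies, and baseline-corrected
evaluation — runnable end to end on synthetic multi-context cohorts with
known ground truth, or on your own expression/mutation/CNV files.

## The model and the statistics

For a target gene, each sample gets a binary label: positive if it carries
a non-silent somatic variant, or a role-concordant copy-number event (gain
for oncogenes, loss for tumor suppressors; continuous CNV thresholds
log2(3/2) and log2(5/2) on a diploid-centered log scale, or GISTIC-style
integer calls). Hypermutated samples (burden ≥ mean + 2 SD) are removed
first. The linear classifier solves

  ŵ = argmin_w  C · l(X, y; w) + ‖w‖₁

with l the logistic negative log-likelihood, features standardized per
split, and log10(mutation count + 1) as a burden covariate; C runs over 43
log-even values on [10⁻³, 10³] plus 21 on [10³, 10⁷]. The neural
alternative is a 3-layer ReLU network (second hidden layer = half the
first, rounded up; 2-unit softmax output) trained 100 epochs with
mini-batch Adam, swept over hidden size, dropout, or weight decay.

Per regularization value the holdout AUPR is averaged over 4 folds × 2
seeds. Two selectors are compared: **best** (top mean holdout AUPR) and
**smallest good** (most regularized value within one standard error of the
best — the `lambda.1se` heuristic). Generalization is scored with
**corrected AUPR** (raw AUPR minus the evaluation set's prevalence, the
random-classifier baseline); the **generalization difference** corrected
holdout − corrected test is positive when a model travels badly. Per-gene
best-minus-smallest-good differences are tested with a two-sided Wilcoxon
signed-rank test (zeros dropped).

## Worked example

Simulate a 2-context cohort (5 driver genes, moderate covariate shift on
the held-out context) and run the full linear benchmark:

```r
library(mutbench)

cfg <- run_config(
  mode = "cross_dataset", model = "linear",
  train_context = "context_1", test_context = "context_2",
  synthetic = cohort_config(n_target_genes = 5, n_genes = 40,
                            context_shift = 1, seed = 42))
res <- run_experiment(cfg)
res
#> run_result: 5 gene(s) analysed, 0 skipped
#>   median best-minus-smallest-good difference: 0.0000 (Wilcoxon p = 1.000)
#>   median generalization difference (best model): 0.0975

res$selection[, c("gene", "best_param", "smallest_good_param", "difference")]
#>   gene best_param smallest_good_param   difference
#> 1 TG01 0.13894955          0.10000000  0.008370336
#> 2 TG02 0.07196857          0.05179475 -0.001824340
#> 3 TG03 0.13894955          0.05179475  0.005248732
#> 4 TG04 0.05179475          0.05179475  0.000000000
#> 5 TG05 0.13894955          0.05179475 -0.009073839
```

Reading this: for each gene the two selection strategies picked a LASSO
`C` from the holdout data only; `difference` is the best model's mean test
AUPR minus the smallest good model's (positive = best model generalized
better; exactly 0 when one C wins both criteria, as for TG04). The signs
scatter around zero — neither strategy dominates — while the positive
median generalization difference (0.0975) reflects the injected covariate
shift: models lose about 0.1 corrected AUPR when leaving their training
context. `res$by_gene` ranks genes by that loss, and with
`output_dir` set every table (sweep, selection, generalization,
aggregates, manifest) is written as TSV/JSON. File-based inputs
(expression TSV, MAF-like mutations, CNV in either dialect, annotations)
go through `run_config(paths = ...)`; `inst/scripts/mutbench` is a thin
command-line wrapper over the same functions.

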