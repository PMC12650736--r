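# mtgsel — multi-task ensemble gene selection for tumor classification

Gene expression studies of cancer routinely face the *high-dimension,
low-sample* regime: thousands of genes measured on a few dozen tumors.
Sparse classifiers can pick informative genes, but on such data the
selected panel is notoriously unstable — refit on a slightly different
subsample and a different gene list comes out. `mtgsel` is for analysts
who want a binary tumor classifier *and* a gene panel that is stable
under resampling.

## The model

The training set `(X ∈ R^{n×d}, y ∈ {−1,+1}^n)` is subsampled into `m`
overlapping tasks, each a random draw (without replacement, per class) of
`round(η·n)` samples.  The tasks are fitted jointly by multi-task
logistic regression with an ℓ2,1 row-group penalty on the `d × m` weight
matrix `W`:

    min over W, c   Σ_k (1/n_k) Σ_i log(1 + exp(−y_ik (x_ik·W_k + c_k)))
                    + λ Σ_j ‖W_j·‖₂

The penalty sums the Euclidean norms of gene rows across tasks, so a gene
is either in or out of *every* task's model simultaneously — selection
consensus across subsamples is built into the optimization rather than
obtained by post-hoc voting.  The convex objective is minimized by
proximal gradient descent: a gradient step on the smooth loss followed by
row-wise block soft-thresholding `W_j ← (1 − λ/(γ‖A_j‖₂))₊ A_j`, with a
backtracking line search on the step parameter γ that guarantees a
monotonically non-increasing objective.  Prediction averages the `m` task
logits and applies the logistic link; λ is chosen by stratified 5-fold
cross-validation over a log grid anchored at the analytically computed
`λ_max`.

The package also ships the standard comparison methods (L1 and
elastic-net logistic regression on the same solver engine, ReliefF and
mRMR filters with a downstream logistic classifier), a synthetic-data
generator with planted relevant genes, and a repeated-split experiment
harness.

## Worked example

```r
library(mtgsel)

# a synthetic benchmark: 100 tumors, 500 genes, 20 truly relevant
sim <- simulate_dataset(n = 100, d = 500, seed = 1)
parts <- split_train_test(sim$dataset, train_fraction = 0.5, seed = 1)

fit <- mtle(parts$train, m = 8, eta = 0.7, seed = 1)
fit
#> Multi-task ensemble logistic regression (l2,1 gene selection)
#>   n=50 samples, d=500 genes, m=8 tasks (eta=0.70)
#>   lambda=0.638968 (by CV), 1 genes selected, 13 iterations

mean(predict(fit, parts$test, type = "class") == parts$test$y)
#> [1] 0.54
selection_metrics(fit$selection, sim$truth)
#>           n_selected n_relevant_recovered
#>                    1                    0
```

The printed fit says: cross-validation chose a heavy penalty
(λ ≈ 0.64), the solver converged in 13 accepted proximal steps, and only
one gene survived thresholding.  At these default generator settings the
planted per-gene effects are weak relative to `n = 50` training samples,
so near-null models win cross-validation and test accuracy sits close to
chance — see the methods vignette for the signal-strength analysis.  With
twice the samples the same call recovers a majority of the planted panel:

```r
sim2 <- simulate_dataset(n = 200, d = 500, seed = 1)
fit2 <- mtle(sim2$dataset, m = 8, seed = 1)
selection_metrics(fit2$selection, sim2$truth)
#>           n_selected n_relevant_recovered
#>                   22                   13
```

Real datasets enter through delimited text:

```r
ds <- read_expression_table("expr.tsv", "samples_by_genes", "labels.tsv")
fit <- mtle(ds, m = 8, seed = 1)
```

A thin command-line interface wrapping these functions (subcommands
`simulate`, `fit`, `predict`, `cv`, `compare`, `sweep-k`) is installed at
`system.file("cli", "mtgsel.R", package = "mtgsel")`.

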