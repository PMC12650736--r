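# Penalty-weight selection by stratified 5-fold cross-validation.

# Stratified fold assignment: per-class shuffle, then deal round-robin with
# a pointer that continues across classes, so overall fold sizes differ by
# at most one and each class is spread as evenly as possible.
make_folds <- function(y01, nfolds) {
  fold <- integer(length(y01))
  ptr <- 0L
  for (cl in sort(unique(y01))) {
    idx <- which(y01 == cl)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    for (i in seq_along(idx)) {
      fold[idx[i]] <- (ptr %% nfolds) + 1L
      ptr <- ptr + 1L
    }
  }
  fold
}

#' Default logarithmic penalty grid
#'
#' `nlambda` log-spaced values from `min_ratio * lambda_max` up to
#' `lambda_max`, returned ascending.  Anchoring the top at `lambda_max`
#' guarantees the null (all-zero) model is on the grid.
#'
#' @param lambda_max see [mtl_lambda_max()].
#' @param nlambda number of grid points.
#' @param min_ratio ratio of the smallest to the largest grid value.
#' @export
default_lambda_grid <- function(lambda_max, nlambda = 20L,
                                min_ratio = 1e-3) {
  stopifnot(lambda_max > 0, nlambda >= 1, min_ratio > 0, min_ratio <= 1)
  exp(seq(log(lambda_max * min_ratio), log(lambda_max),
          length.out = nlambda))
}

# Warm-started fits along a descending grid; returns list of mtl_fit results.
fit_lambda_path <- function(tc, grid_desc, control) {
  W <- NULL; cvec <- NULL
  fits <- vector("list", length(grid_desc))
  for (i in seq_along(grid_desc)) {
    fit <- mtl_fit(tc, grid_desc[i], control, W0 = W, c0 = cvec)
    W <- fit$W; cvec <- fit$c
    fits[[i]] <- fit
  }
  fits
}

# Ensemble prediction on the link scale: average the m task logits.
ensemble_logits <- function(x, W, cvec) {
  drop(x %*% rowMeans(W)) + mean(cvec)
}

# Mean validation log-loss for labels in -1/+1 given averaged logits.
val_logloss <- function(ypm, z) mean(log1pexp_neg(ypm * z))

# Matrix-level CV engine.  Consumes RNG state sequentially; callers wrap it
# (together with any downstream draws) in with_seed_().
cv_mtl_engine <- function(x, y01, grid, m, eta, nfolds, standardize,
                          control, tau = 0.5) {
  n <- nrow(x)
  ypm <- 2 * y01 - 1
  folds <- make_folds(y01, nfolds)
  for (f in seq_len(nfolds)) {
    if (length(unique(y01[folds != f])) < 2L)
      stop(sprintf("fold %d leaves a single-class training set", f),
           call. = FALSE)
  }
  if (is.null(grid)) {
    xs <- if (standardize) standardize_columns(x)$x else x
    tc_full <- task_collection(xs, ypm, m = m, eta = eta)
    grid <- default_lambda_grid(mtl_lambda_max(tc_full))
  } else {
    grid <- sort(as.numeric(grid))
    if (any(grid <= 0)) stop("grid values must be positive", call. = FALSE)
  }
  grid_desc <- rev(grid)

  ll <- acc <- matrix(NA_real_, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (standardize) {
      std <- standardize_columns(x[tr, , drop = FALSE])
      xtr <- std$x
      xva <- standardize_columns(x[va, , drop = FALSE],
                                 center = std$center, scale = std$scale)$x
    } else {
      xtr <- x[tr, , drop = FALSE]
      xva <- x[va, , drop = FALSE]
    }
    tc <- task_collection(xtr, ypm[tr], m = m, eta = eta)
    fits <- fit_lambda_path(tc, grid_desc, control)
    for (i in seq_along(grid_desc)) {
      z <- ensemble_logits(xva, fits[[i]]$W, fits[[i]]$c)
      j <- length(grid) - i + 1L           # position in ascending grid
      ll[f, j] <- val_logloss(ypm[va], z)
      acc[f, j] <- mean(as.integer(stats::plogis(z) > tau) == y01[va])
    }
  }
  mean_ll <- colMeans(ll)
  mean_acc <- colMeans(acc)
  # ties broken toward the larger (sparser) lambda
  chosen <- max(grid[mean_ll <= min(mean_ll) + 1e-12])
  structure(
    list(grid = grid, mean_val_logloss = mean_ll,
         mean_val_accuracy = mean_acc, chosen_lambda = chosen,
         fold_assignments = folds, nfolds = nfolds, m = m, eta = eta),
    class = "mtl_cv"
  )
}

#' Select the penalty weight by cross-validation
#'
#' Stratified k-fold cross-validation over a logarithmic grid of penalty
#' weights.  Within each fold, tasks are redrawn from the fold's training
#' portion, the model is fitted for every grid value (warm-started along
#' the descending grid), and held-out samples are scored with logit-averaged
#' probabilities.  The chosen lambda minimizes mean validation log-loss,
#' with ties broken toward the larger (sparser) value.  The same lambda is
#' shared by all tasks.
#'
#' @param ds an [expr_dataset] (the training data).
#' @param grid ascending positive penalty values, or `NULL` for the default
#'   20-point grid spanning `[1e-3, 1] * lambda_max` (see
#'   [default_lambda_grid()]).
#' @param m,eta task count and sampling rate, as in [draw_task_subsets()].
#' @param nfolds number of folds (default 5).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @param standardize z-score genes on each fold's training portion.
#' @param control an [mtl_control()].
#' @return An object of class `mtl_cv` with elements `grid`,
#'   `mean_val_logloss`, `mean_val_accuracy`, `chosen_lambda`,
#'   `fold_assignments`.
#' @export
cv_select_lambda <- function(ds, grid = NULL, m = 8L, eta = 0.7,
                             nfolds = 5L, seed = NULL, standardize = TRUE,
                             control = mtl_control()) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (ds$n < 10L) stop("cross-validation needs at least 10 samples",
                       call. = FALSE)
  with_seed_(seed,
             cv_mtl_engine(ds$x, ds$y, grid, m = m, eta = eta,
                           nfolds = nfolds, standardize = standardize,
                           control = control))
}

#' @export
print.mtl_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d lambda values\n", x$nfolds, length(x$grid)))
  cat(sprintf("  chosen lambda = %.6g (mean val log-loss %.4f, accuracy %.3f)\n",
              x$chosen_lambda,
              x$mean_val_logloss[which(x$grid == x$chosen_lambda)],
              x$mean_val_accuracy[which(x$grid == x$chosen_lambda)]))
  invisible(x)
}

#' Export a CV record as CSV
#'
#' @param cv an `mtl_cv` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cv_table <- function(cv, path) {
  stopifnot(inherits(cv, "mtl_cv"))
  utils::write.csv(data.frame(lambda = cv$grid,
                              mean_val_logloss = cv$mean_val_logloss,
                              mean_val_accuracy = cv$mean_val_accuracy),
                   path, row.names = FALSE)
  invisible(path)
}
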