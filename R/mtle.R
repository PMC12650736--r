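#' Multi-task ensemble logistic regression with l2,1 gene selection
#'
#' Fits the package's core model: `m` tasks, each a random subsample of the
#' training data at rate `eta`, are fitted jointly by logistic regression
#' under the row-group penalty `lambda * sum_j ||W_j.||_2`, which zeroes
#' whole gene rows and so selects the same compact gene set for every task.
#' The convex objective is minimized by proximal gradient descent with
#' backtracking line search; prediction averages the `m` task logits before
#' the logistic link.  When `lambda` is `NULL` (the default) it is chosen
#' by stratified `nfolds`-fold cross-validation minimizing validation
#' log-loss over a logarithmic grid anchored at `lambda_max`.
#'
#' @param x numeric matrix (samples by genes) or an [expr_dataset].
#' @param y binary labels (ignored when `x` is an [expr_dataset]).
#' @param m number of subsampled tasks (default 8).
#' @param eta per-task sampling rate in (0, 1] (default 0.7).
#' @param lambda penalty weight; `NULL` selects it by cross-validation.
#' @param grid optional ascending lambda grid for the cross-validation.
#' @param nfolds folds for the cross-validation (default 5).
#' @param standardize z-score each gene on the training data (scale floor
#'   1e-12); the stored transform is applied to any prediction input.
#'   Regularized linear models are scale-sensitive, so this is on by
#'   default.
#' @param stratify_tasks draw task subsets per class (default), guaranteeing
#'   both classes in every task.
#' @param tau decision threshold on the predicted probability, in (0, 1);
#'   `p > tau` predicts class 1, ties go to class 0.
#' @param tol row-norm tolerance for calling a gene selected; the prox
#'   produces exact zeros, so this only guards float noise.
#' @param seed integer seed; folds, task draws and hence the fit are fully
#'   deterministic given it.
#' @param control an [mtl_control()] with solver settings.
#' @return An object of class `mtle` with components `W` (d x m weight
#'   matrix, rows named by gene), `c` (m biases), `lambda`, `tau`,
#'   `selection` (a `gene_selection`), `cv` (an `mtl_cv` or `NULL`),
#'   `tasks` (per-task sample indices), `trace`, `center`/`scale`,
#'   `fitted` (training probabilities), and bookkeeping fields.
#' @examples
#' sim <- simulate_dataset(n = 60, d = 40, n_relevant = 5, seed = 1)
#' fit <- mtle(sim$dataset, m = 4, seed = 1)
#' fit
#' head(predict(fit, sim$dataset$x))
#' @seealso [predict.mtle()], [select_genes()], [cv_select_lambda()]
#' @export
mtle <- function(x, y = NULL, m = 8L, eta = 0.7, lambda = NULL,
                 grid = NULL, nfolds = 5L, standardize = TRUE,
                 stratify_tasks = TRUE, tau = 0.5, tol = 1e-8,
                 seed = NULL, control = mtl_control()) {
  cl <- match.call()
  ds <- if (inherits(x, "expr_dataset")) x else expr_dataset(x, labels = y)
  if (length(unique(ds$y)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  stop_if_not_scalar_prob(tau, "tau")

  fit <- with_seed_(seed, {
    cv <- NULL
    if (is.null(lambda)) {
      cv <- cv_mtl_engine(ds$x, ds$y, grid, m = m, eta = eta,
                          nfolds = nfolds, standardize = standardize,
                          control = control)
      lambda <- cv$chosen_lambda
      grid <- cv$grid
    }
    if (standardize) {
      std <- standardize_columns(ds$x)
      xs <- std$x; center <- std$center; scale <- std$scale
    } else {
      xs <- ds$x
      center <- rep(0, ds$d); scale <- rep(1, ds$d)
    }
    tc <- task_collection(xs, ds$ypm, m = m, eta = eta,
                          stratified = stratify_tasks)
    # warm-start down the grid to the chosen lambda; with no grid, cold fit
    if (!is.null(grid) && lambda %in% grid) {
      path <- rev(grid[grid >= lambda])
      fits <- fit_lambda_path(tc, path, control)
      res <- fits[[length(fits)]]
    } else {
      res <- mtl_fit(tc, lambda, control)
    }
    list(cv = cv, lambda = lambda, tc = tc, res = res,
         center = center, scale = scale, xs = xs)
  })

  W <- fit$res$W
  rownames(W) <- ds$gene_ids
  z <- ensemble_logits(fit$xs, W, fit$res$c)
  obj <- structure(
    list(W = W, c = fit$res$c, lambda = fit$lambda, tau = tau,
         m = as.integer(m), eta = eta,
         gene_ids = ds$gene_ids, classes = ds$classes,
         center = fit$center, scale = fit$scale, standardize = standardize,
         cv = fit$cv, tasks = fit$tc$subsets,
         trace = fit$res$trace, iterations = fit$res$iterations,
         converged = fit$res$converged,
         fitted = stats::plogis(z), y = ds$y,
         n = ds$n, d = ds$d, tol = tol, seed = seed, call = cl),
    class = "mtle"
  )
  obj$selection <- select_genes(obj, tol = tol)
  obj
}

#' Fit the full pipeline: CV, task redraw, refit, selection
#'
#' Convenience wrapper around [mtle()] returning the fitted model, its gene
#' selection and the cross-validation record as separate components.
#'
#' @param train an [expr_dataset].
#' @inheritParams mtle
#' @param ... further arguments passed to [mtle()].
#' @return `list(model, selection, cv)`.
#' @export
fit_pipeline <- function(train, m = 8L, eta = 0.7, grid = NULL,
                         seed = NULL, ...) {
  fit <- mtle(train, m = m, eta = eta, grid = grid, seed = seed, ...)
  list(model = fit, selection = fit$selection, cv = fit$cv)
}

#' Genes selected by a fitted model
#'
#' A gene is selected when the Euclidean norm of its weight row across the
#' `m` tasks exceeds `tol`.  Block soft-thresholding produces exact zeros,
#' so `tol` (default 1e-8) only absorbs floating-point noise.
#'
#' @param object an `mtle` fit, or a numeric weight matrix with gene row
#'   names.
#' @param tol nonnegative selection tolerance on the row norm.
#' @return An object of class `gene_selection`: `row_norms` (named, in gene
#'   order), `selected` (indices sorted by descending norm), `gene_ids`,
#'   `tol`.
#' @export
select_genes <- function(object, tol = 1e-8) {
  stopifnot(tol >= 0)
  if (inherits(object, "mtle")) {
    W <- object$W; gene_ids <- object$gene_ids
  } else {
    W <- as.matrix(object)
    gene_ids <- rownames(W) %||% paste0("gene", seq_len(nrow(W)))
  }
  rn <- row_norms2(W)
  names(rn) <- gene_ids
  sel <- which(rn > tol)
  sel <- sel[order(rn[sel], decreasing = TRUE)]
  structure(list(row_norms = rn, selected = sel, gene_ids = gene_ids,
                 tol = tol),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("Gene selection: %d of %d genes (tol=%.1e)\n",
              length(x$selected), length(x$row_norms), x$tol))
  if (length(x$selected)) {
    top <- utils::head(x$selected, 10L)
    cat("  top genes:", paste(x$gene_ids[top], collapse = ", "), "\n")
  }
  invisible(x)
}

resolve_newdata <- function(object, newdata) {
  x <- if (inherits(newdata, "expr_dataset")) newdata$x else as.matrix(newdata)
  if (ncol(x) != object$d)
    stop(sprintf("newdata has %d genes; the model was fitted on %d",
                 ncol(x), object$d), call. = FALSE)
  if (!is.null(colnames(x)) && !identical(colnames(x), object$gene_ids)) {
    if (!all(object$gene_ids %in% colnames(x)))
      stop("newdata gene names do not match the fitted model", call. = FALSE)
    x <- x[, object$gene_ids, drop = FALSE]
  }
  if (object$standardize)
    x <- standardize_columns(x, center = object$center,
                             scale = object$scale)$x
  x
}

#' Predict from a fitted multi-task ensemble
#'
#' Task logits `z_k = x'W_k + c_k` are averaged over the `m` tasks and
#' passed through the logistic link: `p = sigma(mean_k z_k)`.  Class labels
#' are `1` when `p > tau` strictly, else `0`.
#'
#' @param object an `mtle` fit.
#' @param newdata matrix (samples by genes) or [expr_dataset]; genes must
#'   match the training data (reordered by name when names are available).
#'   The training standardization is applied automatically.
#' @param type `"response"` (probabilities, default), `"class"` (0/1
#'   labels) or `"link"` (averaged logits).
#' @param tau decision threshold; defaults to the fitted model's.
#' @param ... unused.
#' @return Numeric (or integer, for `"class"`) vector, one value per sample.
#' @export
predict.mtle <- function(object, newdata, type = c("response", "class",
                                                   "link"),
                         tau = object$tau, ...) {
  type <- match.arg(type)
  stop_if_not_scalar_prob(tau, "tau")
  x <- resolve_newdata(object, newdata)
  z <- ensemble_logits(x, object$W, object$c)
  switch(type,
         link = z,
         response = stats::plogis(z),
         class = as.integer(stats::plogis(z) > tau))
}

#' Model coefficients
#'
#' @param object an `mtle` fit.
#' @param scale `"standardized"` (the scale on which the model was fitted
#'   and on which selection norms are defined) or `"original"` (weights
#'   mapped back to raw expression units, biases adjusted accordingly).
#' @param ... unused.
#' @return List with `W` (d x m) and `c` (length m).
#' @export
coef.mtle <- function(object, scale = c("standardized", "original"), ...) {
  scale <- match.arg(scale)
  if (scale == "standardized" || !object$standardize)
    return(list(W = object$W, c = object$c))
  W <- object$W / object$scale
  cvec <- object$c - colSums(object$W * (object$center / object$scale))
  list(W = W, c = cvec)
}

#' @export
print.mtle <- function(x, ...) {
  cat("Multi-task ensemble logistic regression (l2,1 gene selection)\n")
  cat(sprintf("  n=%d samples, d=%d genes, m=%d tasks (eta=%.2f)\n",
              x$n, x$d, x$m, x$eta))
  cat(sprintf("  lambda=%.6g%s, %d genes selected, %d iterations%s\n",
              x$lambda, if (is.null(x$cv)) "" else " (by CV)",
              length(x$selection$selected), x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
summary.mtle <- function(object, n_top = 10L, ...) {
  sel <- object$selection
  top <- utils::head(sel$selected, n_top)
  structure(
    list(n = object$n, d = object$d, m = object$m, eta = object$eta,
         lambda = object$lambda, cv = !is.null(object$cv),
         iterations = object$iterations, converged = object$converged,
         objective = object$trace[length(object$trace)],
         n_selected = length(sel$selected),
         train_accuracy = mean(as.integer(object$fitted > object$tau)
                               == object$y),
         top_genes = data.frame(gene_id = sel$gene_ids[top],
                                row_norm = unname(sel$row_norms[top]))),
    class = "summary.mtle"
  )
}

#' @export
print.summary.mtle <- function(x, ...) {
  cat("Multi-task ensemble logistic regression\n")
  cat(sprintf("  n=%d, d=%d, m=%d tasks (eta=%.2f)\n", x$n, x$d, x$m, x$eta))
  cat(sprintf("  lambda=%.6g%s; final objective %.6f after %d iterations%s\n",
              x$lambda, if (x$cv) " (chosen by 5-fold CV)" else "",
              x$objective, x$iterations,
              if (x$converged) "" else " (iteration cap reached)"))
  cat(sprintf("  genes selected: %d; training accuracy %.3f\n",
              x$n_selected, x$train_accuracy))
  if (nrow(x$top_genes)) {
    cat("  top genes by cross-task row norm:\n")
    print(x$top_genes, row.names = FALSE)
  }
  invisible(x)
}

#' Diagnostic plots for a fitted model
#'
#' Left panel: the objective trace over accepted solver iterations
#' (non-increasing by construction).  Right panel: per-gene cross-task row
#' norms, with selected genes highlighted.
#'
#' @param x an `mtle` fit.
#' @param ... passed to the underlying plot calls.
#' @export
plot.mtle <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l",
                 xlab = "iteration", ylab = "objective",
                 main = "Proximal gradient descent", ...)
  rn <- x$selection$row_norms
  cols <- ifelse(seq_along(rn) %in% x$selection$selected, "firebrick",
                 "grey60")
  graphics::plot(seq_along(rn), rn, type = "h", col = cols,
                 xlab = "gene index", ylab = "cross-task row norm",
                 main = sprintf("%d genes selected",
                                length(x$selection$selected)), ...)
  invisible(x)
}

#' Residuals of the fitted training probabilities
#'
#' @param object an `mtle` fit.
#' @param type `"response"` (`y - p`) or `"deviance"`.
#' @param ... unused.
#' @export
residuals.mtle <- function(object, type = c("response", "deviance"), ...) {
  type <- match.arg(type)
  p <- object$fitted
  y <- object$y
  if (type == "response") return(y - p)
  dev <- -2 * (y * log(pmax(p, 1e-15)) + (1 - y) * log(pmax(1 - p, 1e-15)))
  sign(y - p) * sqrt(dev)
}

#' Simulate class labels from the fitted probabilities
#'
#' Draws Bernoulli labels at the model's predicted probabilities, for the
#' training samples or for `newdata`.
#'
#' @param object an `mtle` fit.
#' @param nsim number of simulated label vectors.
#' @param seed optional integer seed.
#' @param newdata optional matrix or [expr_dataset] to simulate for.
#' @param ... unused.
#' @return A data.frame with `nsim` columns of 0/1 labels.
#' @export
simulate.mtle <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                          ...) {
  p <- if (is.null(newdata)) object$fitted
       else predict(object, newdata, type = "response")
  sims <- with_seed_(seed, replicate(nsim, stats::rbinom(length(p), 1L, p)))
  out <- as.data.frame(matrix(sims, ncol = nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Serialize a fitted model to JSON
#'
#' Stores everything needed to reload and predict: weights, biases, lambda,
#' tau, gene identifiers and the standardization transform.
#'
#' @param object an `mtle` fit.
#' @param path output path.
#' @return Invisibly, `path`.
#' @seealso [mtle_from_json()]
#' @export
mtle_to_json <- function(object, path) {
  stopifnot(inherits(object, "mtle"))
  payload <- list(W = unname(object$W), c = object$c,
                  lambda = object$lambda, tau = object$tau,
                  m = object$m, eta = object$eta,
                  gene_ids = object$gene_ids, classes = object$classes,
                  center = unname(object$center),
                  scale = unname(object$scale),
                  standardize = object$standardize)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' Reload a serialized model
#'
#' @param path path written by [mtle_to_json()].
#' @return A prediction-capable `mtle` object.
#' @export
mtle_from_json <- function(path) {
  p <- jsonlite::fromJSON(path)
  W <- as.matrix(p$W)
  rownames(W) <- p$gene_ids
  structure(
    list(W = W, c = as.numeric(p$c), lambda = p$lambda, tau = p$tau,
         m = as.integer(p$m), eta = p$eta, gene_ids = p$gene_ids,
         classes = p$classes, center = as.numeric(p$center),
         scale = as.numeric(p$scale), standardize = isTRUE(p$standardize),
         d = nrow(W), tol = 1e-8),
    class = "mtle"
  )
}
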