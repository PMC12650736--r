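# Repeated-split experiment harness: method comparison and the
# ensemble-size sweep.

#' Experiment configuration
#'
#' Bundles everything a comparison run needs so results are fully
#' replayable: the data source, the split protocol (train fractions 0.5
#' and/or 0.6, repeated `n_repeats` times), the methods to compare, and the
#' ensemble settings.
#'
#' @param dataset an [expr_dataset] or `sim_dataset` (when a `sim_dataset`
#'   is given, recovery metrics against the planted truth are reported).
#' @param train_fractions subset of `c(0.5, 0.6)` (or any fractions).
#' @param n_repeats repeated random splits per fraction (default 10).
#' @param methods subset of `"ours"`, `"l1"`, `"elastic_net"`, `"mrmr"`,
#'   `"relieff"`.
#' @param m,eta ensemble settings for `"ours"` (defaults 8 and 0.7).
#' @param n_filter gene count used by the filter methods (default 50).
#' @param base_seed integer; repeat `r` splits with seed `base_seed + r`,
#'   shared across methods so comparisons are paired.
#' @param control an [mtl_control()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(dataset, train_fractions = c(0.5, 0.6),
                              n_repeats = 10L,
                              methods = c("ours", "l1", "elastic_net",
                                          "mrmr", "relieff"),
                              m = 8L, eta = 0.7, n_filter = 50L,
                              base_seed = 1L, control = mtl_control()) {
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(n_repeats >= 1L, length(methods) >= 1L)
  structure(list(dataset = dataset, train_fractions = train_fractions,
                 n_repeats = as.integer(n_repeats), methods = methods,
                 m = as.integer(m), eta = eta,
                 n_filter = as.integer(n_filter),
                 base_seed = as.integer(base_seed), control = control),
            class = "experiment_config")
}

run_one_method <- function(method, train, test, truth, cfg, seed) {
  if (method == "ours") {
    fit <- mtle(train, m = cfg$m, eta = cfg$eta, seed = seed,
                control = cfg$control)
    acc <- mean(predict(fit, test, type = "class") == test$y)
    sel <- fit$selection$selected
  } else if (method %in% c("l1", "elastic_net")) {
    fit <- fit_penalized_single_task(train, penalty = method, seed = seed,
                                     control = cfg$control)
    acc <- mean(predict(fit, test, type = "class") == test$y)
    sel <- fit$selected
  } else {
    res <- filter_then_classify(train, test, method = method,
                                n_select = cfg$n_filter, seed = seed)
    acc <- res$accuracy[1L]
    sel <- match(res$selected_genes[[1L]], train$gene_ids)
  }
  met <- if (is.null(truth)) c(n_selected = length(sel),
                               n_relevant_recovered = NA_real_)
         else selection_metrics(sel, truth)
  c(accuracy = acc, met)
}

#' Repeated-split method comparison
#'
#' For each training fraction and repeat `r`, the dataset is split with
#' seed `base_seed + r` (the same split for every method, so comparisons
#' are paired), each method is fitted on the training part and scored on
#' the held-out part, and per-method means and standard deviations over
#' repeats are reported.  On simulated data the number of selected genes
#' and of planted genes recovered are reported as well.
#'
#' @param cfg an [experiment_config()].
#' @return A data.frame with one row per method x fraction: mean/sd test
#'   accuracy, mean selected genes, mean relevant genes recovered.
#' @export
run_comparison <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  ds <- if (inherits(cfg$dataset, "sim_dataset")) cfg$dataset$dataset
        else cfg$dataset
  truth <- if (inherits(cfg$dataset, "sim_dataset")) cfg$dataset$truth
           else NULL
  rows <- list()
  for (frac in cfg$train_fractions) {
    per_method <- lapply(cfg$methods, function(m) {
      matrix(NA_real_, cfg$n_repeats, 3L,
             dimnames = list(NULL, c("accuracy", "n_selected",
                                     "n_relevant_recovered")))
    })
    names(per_method) <- cfg$methods
    for (r in seq_len(cfg$n_repeats)) {
      seed_r <- cfg$base_seed + r
      parts <- split_train_test(ds, frac, stratified = TRUE, seed = seed_r)
      for (method in cfg$methods) {
        per_method[[method]][r, ] <-
          run_one_method(method, parts$train, parts$test, truth, cfg,
                         seed = seed_r)
      }
    }
    for (method in cfg$methods) {
      res <- per_method[[method]]
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, train_fraction = frac,
        n_repeats = cfg$n_repeats,
        mean_accuracy = mean(res[, "accuracy"]),
        sd_accuracy = stats::sd(res[, "accuracy"]),
        mean_selected = mean(res[, "n_selected"]),
        mean_recovered = mean(res[, "n_relevant_recovered"])
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accuracy as a function of the number of tasks
#'
#' Runs the full pipeline (CV, refit, predict) at each ensemble size in
#' `k_values`, with splits shared across sizes within a repeat, and
#' reports the mean test accuracy per size.  Reproduces the qualitative
#' finding that accuracy improves and then plateaus as the number of
#' subsampled tasks grows.
#'
#' @param cfg an [experiment_config()] (its `m` is ignored; `methods` is
#'   not used).
#' @param k_values ensemble sizes to sweep, conventionally
#'   `c(2, 4, 6, 8, 10)`.
#' @param train_fraction split fraction used for the sweep (default 0.5).
#' @return data.frame with columns `k`, `mean_accuracy`, `sd_accuracy`.
#' @export
sweep_num_tasks <- function(cfg, k_values = c(2L, 4L, 6L, 8L, 10L),
                            train_fraction = 0.5) {
  stopifnot(inherits(cfg, "experiment_config"), all(k_values >= 1L))
  ds <- if (inherits(cfg$dataset, "sim_dataset")) cfg$dataset$dataset
        else cfg$dataset
  acc <- matrix(NA_real_, cfg$n_repeats, length(k_values))
  for (r in seq_len(cfg$n_repeats)) {
    seed_r <- cfg$base_seed + r
    parts <- split_train_test(ds, train_fraction, stratified = TRUE,
                              seed = seed_r)
    for (i in seq_along(k_values)) {
      fit <- mtle(parts$train, m = k_values[i], eta = cfg$eta,
                  seed = seed_r, control = cfg$control)
      acc[r, i] <- mean(predict(fit, parts$test, type = "class")
                        == parts$test$y)
    }
  }
  data.frame(k = as.integer(k_values),
             mean_accuracy = colMeans(acc),
             sd_accuracy = apply(acc, 2L, stats::sd))
}
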