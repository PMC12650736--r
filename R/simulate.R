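# Synthetic high-dimension low-sample datasets with planted relevant genes,
# and the selection/recovery metrics evaluated on them.

#' Benchmark simulation configurations
#'
#' The six standard size settings S1-S6 used throughout the package's
#' simulation study (samples x genes): S1 100x500, S2 200x500, S3 100x1000,
#' S4 200x1000, S5 100x2000, S6 200x2000, each with 20 planted relevant
#' genes.
#'
#' @param name one of `"S1"` .. `"S6"`.
#' @return `list(n, d, n_relevant)`.
#' @export
sim_config <- function(name = c("S1", "S2", "S3", "S4", "S5", "S6")) {
  name <- match.arg(name)
  sizes <- list(S1 = c(100L, 500L), S2 = c(200L, 500L),
                S3 = c(100L, 1000L), S4 = c(200L, 1000L),
                S5 = c(100L, 2000L), S6 = c(200L, 2000L))[[name]]
  list(n = sizes[1L], d = sizes[2L], n_relevant = 20L)
}

#' Simulate an expression dataset with planted relevant genes
#'
#' Rows are drawn i.i.d. from a `d`-dimensional normal with AR(1)
#' correlation `Sigma_ab = rho^|a-b|` and unit variances (mimicking local
#' correlation among neighboring genes).  `n_relevant` gene indices are
#' planted uniformly at random; their coefficients alternate
#' `+effect_size, -effect_size, ...` and all other coefficients are zero.
#' Labels follow the logistic model `y_i ~ Bernoulli(sigma(x_i . beta))`.
#' A label vector that comes out single-class is redrawn (up to
#' `max_retries` times).
#'
#' @param n,d samples and genes.
#' @param n_relevant number of planted informative genes (default 20).
#' @param rho AR(1) correlation in `[0, 1)` (default 0.5).
#' @param effect_size magnitude of the planted coefficients (default 0.75).
#' @param seed integer seed; the dataset is deterministic given it.
#' @param max_retries redraw budget for a degenerate single-class label
#'   vector.
#' @return Object of class `sim_dataset`: `dataset` (an [expr_dataset]
#'   with labels coded 0/1), `truth` (sorted planted gene indices), `beta`
#'   (the generating coefficient vector), `config`.
#' @examples
#' sim <- simulate_dataset(n = 100, d = 500, seed = 1)  # the S1 setting
#' length(sim$truth)  # 20
#' @export
simulate_dataset <- function(n, d, n_relevant = 20L, rho = 0.5,
                             effect_size = 0.75, seed = NULL,
                             max_retries = 100L) {
  stopifnot(n_relevant <= d, rho >= 0, rho < 1, effect_size > 0)
  out <- with_seed_(seed, {
    x <- matrix(stats::rnorm(n * d), n, d)
    if (rho > 0 && d > 1L) {
      fac <- sqrt(1 - rho^2)
      for (j in 2:d) x[, j] <- rho * x[, j - 1L] + fac * x[, j]
    }
    truth <- sort(sample.int(d, n_relevant))
    beta <- numeric(d)
    beta[truth] <- effect_size * (-1)^(seq_len(n_relevant) - 1L)
    p <- stats::plogis(drop(x %*% beta))
    y <- stats::rbinom(n, 1L, p)
    for (try in seq_len(max_retries)) {
      if (length(unique(y)) == 2L) break
      y <- stats::rbinom(n, 1L, p)
    }
    if (length(unique(y)) < 2L)
      stop("simulated labels single-class after retries; increase n or
           effect_size", call. = FALSE)
    list(x = x, y = y, truth = truth, beta = beta)
  })
  width <- max(4L, nchar(d))
  ds <- expr_dataset(out$x, labels = out$y,
                     sample_ids = sprintf("s%03d", seq_len(n)),
                     gene_ids = sprintf(paste0("g%0", width, "d"),
                                        seq_len(d)))
  structure(list(dataset = ds, truth = out$truth, beta = out$beta,
                 config = list(n = n, d = d, n_relevant = n_relevant,
                               rho = rho, effect_size = effect_size,
                               seed = seed)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated dataset: n=%d, d=%d, %d planted genes (rho=%.2f, effect=%.2f)\n",
    cfg$n, cfg$d, cfg$n_relevant, cfg$rho, cfg$effect_size))
  invisible(x)
}

#' Selection/recovery metrics against the planted truth
#'
#' @param selected integer gene indices the method selected (or a
#'   `gene_selection`).
#' @param truth integer indices of the planted relevant genes.
#' @return Named numeric vector `c(n_selected, n_relevant_recovered)`.
#' @examples
#' selection_metrics(c(1, 2, 30), truth = 1:20)  # 3 selected, 2 recovered
#' @export
selection_metrics <- function(selected, truth) {
  if (inherits(selected, "gene_selection")) selected <- selected$selected
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  c(n_selected = length(selected),
    n_relevant_recovered = length(intersect(selected, truth)))
}

#' Write a simulated dataset to disk
#'
#' Emits the expression TSV and label TSV (via [write_expression_table()])
#' plus a JSON file with the planted truth (1-based gene indices, gene ids
#' and generating coefficients) so downstream stages can be tested offline.
#'
#' @param sim a `sim_dataset`.
#' @param prefix path prefix; writes `<prefix>_expr.tsv`,
#'   `<prefix>_labels.tsv`, `<prefix>_truth.json`.
#' @return Invisibly, the three paths.
#' @export
write_sim_dataset <- function(sim, prefix) {
  stopifnot(inherits(sim, "sim_dataset"))
  expr_path <- paste0(prefix, "_expr.tsv")
  label_path <- paste0(prefix, "_labels.tsv")
  truth_path <- paste0(prefix, "_truth.json")
  write_expression_table(sim$dataset, expr_path, label_path)
  writeLines(jsonlite::toJSON(
    list(truth = sim$truth,
         truth_gene_ids = sim$dataset$gene_ids[sim$truth],
         beta = sim$beta, config = sim$config),
    auto_unbox = TRUE, digits = NA, pretty = TRUE), truth_path)
  invisible(c(expr_path, label_path, truth_path))
}
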