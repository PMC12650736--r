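# Filter baselines: ReliefF and mRMR gene scoring, plus the
# filter-then-classify comparison pipeline.

#' ReliefF gene scores
#'
#' Classic binary-class ReliefF: for each evaluated instance, find its
#' `k_neighbors` nearest hits (same class) and nearest misses (other
#' class) by Euclidean distance on all genes, and move each gene's score up
#' by the mean miss difference and down by the mean hit difference.  Gene
#' differences are range-normalized, `diff_j = |x_j - x'_j| / (max_j -
#' min_j)`; zero-range genes contribute 0 and score exactly 0.  By default
#' every training instance is evaluated once in order, so the score is
#' deterministic without a seed; set `n_iters < n` for the classic sampled
#' variant.
#'
#' @param train an [expr_dataset] (features typically standardized first;
#'   the range normalization makes per-gene scores scale-invariant either
#'   way).
#' @param k_neighbors neighbors per class, capped at (class size - 1).
#' @param n_iters number of evaluated instances; `NULL` (default) uses all.
#' @param seed seed for the sampled variant.
#' @return Object of class `filter_scores` with `method = "relieff"` and a
#'   named per-gene `scores` vector (higher = more class-informative).
#' @export
relieff_scores <- function(train, k_neighbors = 10L, n_iters = NULL,
                           seed = NULL) {
  stopifnot(inherits(train, "expr_dataset"))
  if (length(unique(train$y)) < 2L)
    stop("ReliefF needs both classes present", call. = FALSE)
  x <- train$x
  n <- train$n
  rng <- apply(x, 2L, function(v) diff(range(v)))
  ok <- rng > 0
  xn <- x
  xn[, ok] <- sweep(x[, ok, drop = FALSE], 2L, rng[ok], "/")
  xn[, !ok] <- 0   # zero-range genes: all diffs defined as 0

  iters <- with_seed_(seed, {
    if (is.null(n_iters) || n_iters >= n) seq_len(n)
    else sort(sample(n, n_iters))
  })
  scores <- numeric(train$d)
  for (i in iters) {
    di <- sqrt(colSums((t(xn) - xn[i, ])^2))
    hits <- which(train$y == train$y[i]); hits <- hits[hits != i]
    miss <- which(train$y != train$y[i])
    kh <- min(k_neighbors, length(hits))
    km <- min(k_neighbors, length(miss))
    if (kh < 1L || km < 1L)
      stop("a class has too few samples for ReliefF neighbors",
           call. = FALSE)
    nh <- hits[order(di[hits])][seq_len(kh)]
    nm <- miss[order(di[miss])][seq_len(km)]
    dh <- abs(xn[nh, , drop = FALSE] -
                matrix(xn[i, ], kh, train$d, byrow = TRUE))
    dm <- abs(xn[nm, , drop = FALSE] -
                matrix(xn[i, ], km, train$d, byrow = TRUE))
    scores <- scores + colMeans(dm) - colMeans(dh)
  }
  scores <- scores / length(iters)
  names(scores) <- train$gene_ids
  structure(list(method = "relieff", scores = scores,
                 params = list(k_neighbors = k_neighbors,
                               n_iters = length(iters))),
            class = "filter_scores")
}

# Equal-frequency discretization into at most n_bins levels; constant genes
# collapse to a single level.
discretize_ef <- function(v, n_bins) {
  br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = br, include.lowest = TRUE))
}

# Mutual information (nats) between two integer-coded vectors.
mi_disc <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pr <- rowSums(p); pc <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pr, pc)[nz]))
}

#' mRMR greedy gene selection
#'
#' Minimum-redundancy maximum-relevance: genes are discretized into
#' `n_bins` equal-frequency bins and selected greedily by the MID
#' (difference) criterion — the first gene maximizes `I(gene; label)`, each
#' subsequent gene maximizes `I(g; y) - (1/|S|) sum_{s in S} I(g; s)`.
#' Equal-frequency binning makes the relevance term invariant to monotone
#' transforms of the features.  Fully deterministic; ties go to the
#' lower gene index.
#'
#' @param train an [expr_dataset].
#' @param n_select number of genes to select, at most `d`.
#' @param n_bins bins for discretization (default 3, the common microarray
#'   choice).
#' @return Object of class `filter_scores` with `method = "mrmr"`, `order`
#'   (the greedy selection order, gene indices), `relevance` (named
#'   `I(g; y)` vector).
#' @export
mrmr_select <- function(train, n_select, n_bins = 3L) {
  stopifnot(inherits(train, "expr_dataset"))
  if (n_select > train$d)
    stop("cannot select more genes than the dataset has", call. = FALSE)
  if (n_bins < 2L) stop("'n_bins' must be at least 2", call. = FALSE)
  disc <- apply(train$x, 2L, discretize_ef, n_bins = n_bins)
  rel <- apply(disc, 2L, mi_disc, b = train$y)
  names(rel) <- train$gene_ids

  order_sel <- integer(n_select)
  red_sum <- numeric(train$d)        # running sum of I(g; s) over selected s
  remaining <- rep(TRUE, train$d)
  for (step in seq_len(n_select)) {
    crit <- if (step == 1L) rel
            else rel - red_sum / (step - 1L)
    crit[!remaining] <- -Inf
    pick <- which.max(crit)
    order_sel[step] <- pick
    remaining[pick] <- FALSE
    if (step < n_select) {
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] +
        vapply(idx, function(g) mi_disc(disc[, g], disc[, pick]),
               numeric(1))
    }
  }
  structure(list(method = "mrmr", order = order_sel, relevance = rel,
                 params = list(n_bins = n_bins)),
            class = "filter_scores")
}

#' @export
print.filter_scores <- function(x, ...) {
  cat(sprintf("%s filter scores (%s)\n", toupper(x$method),
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# Top-n gene indices for either filter.
filter_top_genes <- function(fs, n_select) {
  if (fs$method == "mrmr") fs$order[seq_len(n_select)]
  else order(fs$scores, decreasing = TRUE)[seq_len(n_select)]
}

#' Filter-then-classify baseline
#'
#' Scores genes on the training data only (no test leakage), keeps the top
#' `n_select`, and fits a ridge-stabilized logistic regression
#' (`lambda = 1e-6`, pure l2) on them.  When `n_select` is a vector, the
#' filter is computed once and one accuracy is reported per count.
#'
#' @param train,test [expr_dataset]s with matching genes.
#' @param method `"relieff"` or `"mrmr"`.
#' @param n_select gene count(s) to keep (the conventional grid is
#'   `c(10, 20, 30, 40, 50)`).
#' @param seed seed (only the sampled ReliefF variant uses randomness).
#' @param k_neighbors,n_bins filter parameters.
#' @return `list(method, n_select, accuracy, selected_genes)` where
#'   `accuracy` is one test accuracy per requested count and
#'   `selected_genes` the corresponding character vectors of gene ids.
#' @export
filter_then_classify <- function(train, test,
                                 method = c("relieff", "mrmr"),
                                 n_select = c(10L, 20L, 30L, 40L, 50L),
                                 seed = NULL, k_neighbors = 10L,
                                 n_bins = 3L) {
  method <- match.arg(method)
  stopifnot(inherits(train, "expr_dataset"), inherits(test, "expr_dataset"))
  n_select <- as.integer(n_select)
  if (any(n_select < 1L) || any(n_select > train$d))
    stop("'n_select' values must lie in [1, d]", call. = FALSE)

  std <- standardize_columns(train$x)
  train_std <- expr_dataset(std$x, labels = train$y,
                            sample_ids = train$sample_ids,
                            gene_ids = train$gene_ids)
  fs <- if (method == "relieff")
    relieff_scores(train_std, k_neighbors = k_neighbors, seed = seed)
  else
    mrmr_select(train_std, n_select = max(n_select), n_bins = n_bins)

  xte <- standardize_columns(test$x, center = std$center,
                             scale = std$scale)$x
  acc <- numeric(length(n_select))
  genes <- vector("list", length(n_select))
  for (i in seq_along(n_select)) {
    keep <- filter_top_genes(fs, n_select[i])
    fit <- st_fit(std$x[, keep, drop = FALSE], train$ypm,
                  lambda = 1e-6, en_mix = 0)
    z <- drop(xte[, keep, drop = FALSE] %*% fit$w) + fit$b
    acc[i] <- mean(as.integer(stats::plogis(z) > 0.5) == test$y)
    genes[[i]] <- train$gene_ids[keep]
  }
  list(method = method, n_select = n_select, accuracy = acc,
       selected_genes = genes)
}
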