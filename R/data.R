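#' Expression dataset container
#'
#' Bundles an `n x d` expression matrix (samples in rows, genes in columns)
#' with sample identifiers, gene identifiers and a binary class label per
#' sample.  Labels are stored both as `{0, 1}` codes (the lexicographically
#' smaller class name maps to 0) and as `{-1, +1}` values used by the
#' logistic loss.
#'
#' @param x numeric matrix, samples in rows and genes in columns.  `NA`/`NaN`
#'   values are rejected.
#' @param labels vector of length `nrow(x)` with at most two distinct values
#'   (factor, character or numeric).
#' @param sample_ids,gene_ids identifier vectors; default to the matrix
#'   dimnames, or generated names when absent.
#' @return An object of class `expr_dataset`: a list with elements `x`,
#'   `y` (0/1 integer), `ypm` (-1/+1 numeric), `sample_ids`, `gene_ids`,
#'   `classes` (the two original class names, sorted), `n`, `d`.
#' @examples
#' x <- matrix(rnorm(20), 4, 5)
#' ds <- expr_dataset(x, labels = c("tumor", "normal", "tumor", "normal"))
#' ds$classes  # "normal" -> 0, "tumor" -> 1
#' @export
expr_dataset <- function(x, labels, sample_ids = NULL, gene_ids = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric", call. = FALSE)
  if (anyNA(x)) stop("expression matrix contains NA/NaN values", call. = FALSE)
  n <- nrow(x); d <- ncol(x)
  if (length(labels) != n)
    stop(sprintf("found %d labels for %d samples", length(labels), n),
         call. = FALSE)
  sample_ids <- as.character(sample_ids %||% rownames(x) %||%
                               paste0("sample", seq_len(n)))
  gene_ids <- as.character(gene_ids %||% colnames(x) %||%
                             paste0("gene", seq_len(d)))
  if (length(sample_ids) != n || length(gene_ids) != d)
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("gene identifiers must be unique", call. = FALSE)

  lab_chr <- as.character(labels)
  if (anyNA(lab_chr)) stop("labels contain missing values", call. = FALSE)
  classes <- sort(unique(lab_chr))
  if (length(classes) > 2L)
    stop(sprintf("labels must have at most two classes, found %d",
                 length(classes)), call. = FALSE)
  y <- as.integer(match(lab_chr, classes) - 1L)

  dimnames(x) <- list(sample_ids, gene_ids)
  structure(
    list(x = x, y = y, ypm = 2 * y - 1, sample_ids = sample_ids,
         gene_ids = gene_ids, classes = classes, n = n, d = d),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d samples x %d genes\n", x$n, x$d))
  tab <- table(factor(x$y, levels = 0:1))
  cls <- if (length(x$classes) == 2L) x$classes else c(x$classes, "-")
  cat(sprintf("  classes: %s (n=%d, code 0), %s (n=%d, code 1)\n",
              cls[1L], tab[1L], cls[2L], tab[2L]))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) c(x$n, x$d)

# Row-subset of a dataset, keeping ids and the class coding of the parent
# (so a single-class subset keeps its 0/1 codes).
ds_subset <- function(ds, idx) {
  out <- ds
  out$x <- ds$x[idx, , drop = FALSE]
  out$y <- ds$y[idx]
  out$ypm <- ds$ypm[idx]
  out$sample_ids <- ds$sample_ids[idx]
  out$n <- length(idx)
  out
}

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression table with labels
#'
#' Reads a TSV/CSV expression matrix (delimiter chosen by file extension:
#' `.csv` is comma-separated, anything else tab-separated) with one header
#' row and one leading identifier column, plus a two-column label file
#' (header `sample_id`, `class`) mapping each sample to its class.
#'
#' @param path path to the expression table.
#' @param orientation `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the matrix is transposed on read).
#' @param label_path path to the label table.
#' @return An [expr_dataset] in samples-by-genes orientation.
#' @seealso [write_expression_table()] for the inverse operation.
#' @export
read_expression_table <- function(path,
                                  orientation = c("samples_by_genes",
                                                  "genes_by_samples"),
                                  label_path) {
  orientation <- match.arg(orientation)
  tab <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           row.names = 1L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  x <- as.matrix(tab)
  if (!is.numeric(x))
    stop("expression table contains non-numeric cells", call. = FALSE)
  if (orientation == "genes_by_samples") x <- t(x)

  lab <- utils::read.table(label_path, header = TRUE,
                           sep = infer_sep(label_path),
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(lab) < 2L)
    stop("label file must have two columns: sample_id, class", call. = FALSE)
  pos <- match(rownames(x), lab[[1L]])
  if (anyNA(pos)) {
    missing <- rownames(x)[is.na(pos)]
    stop(sprintf("label file is missing sample id(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  expr_dataset(x, labels = lab[[2L]][pos], sample_ids = rownames(x),
               gene_ids = colnames(x))
}

#' Write an expression dataset as delimited text
#'
#' Writes the matrix (samples by genes, header row plus identifier column)
#' and a two-column label file, the formats read back by
#' [read_expression_table()].  Values are printed at full double precision
#' so a write/read round trip reproduces the matrix exactly as printed.
#'
#' @param ds an [expr_dataset].
#' @param path,label_path output paths (extension selects TSV vs CSV).
#' @return Invisibly, `c(path, label_path)`.
#' @export
write_expression_table <- function(ds, path, label_path) {
  stopifnot(inherits(ds, "expr_dataset"))
  sep <- infer_sep(path)
  xfmt <- format(ds$x, digits = 17, trim = TRUE, scientific = FALSE)
  tab <- cbind(sample_id = ds$sample_ids, as.data.frame(xfmt))
  colnames(tab) <- c("sample_id", ds$gene_ids)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  cls <- if (length(ds$classes) == 2L) ds$classes[ds$y + 1L]
         else rep(ds$classes, ds$n)
  lab <- data.frame(sample_id = ds$sample_ids, class = cls)
  utils::write.table(lab, label_path, sep = infer_sep(label_path),
                     quote = FALSE, row.names = FALSE)
  invisible(c(path, label_path))
}

#' Deterministic train/test split
#'
#' Partitions a dataset into disjoint train and test parts.  With
#' `stratified = TRUE` (the default) the per-class training counts are
#' `round(train_fraction * n_class)`, so class proportions are preserved to
#' within rounding.
#'
#' @param ds an [expr_dataset].
#' @param train_fraction fraction of samples assigned to training, in (0, 1).
#' @param stratified draw per class rather than from the pooled samples.
#' @param seed integer seed making the split reproducible; `NULL` uses the
#'   current RNG state.
#' @return `list(train = , test = )`, both [expr_dataset]s.
#' @export
split_train_test <- function(ds, train_fraction, stratified = TRUE,
                             seed = NULL) {
  stopifnot(inherits(ds, "expr_dataset"))
  stop_if_not_scalar_prob(train_fraction, "train_fraction")
  idx_train <- with_seed_(seed, {
    if (stratified) {
      cls_sizes <- table(ds$y)
      if (any(cls_sizes < 2L))
        stop("stratified split needs at least 2 samples per class",
             call. = FALSE)
      unlist(lapply(sort(unique(ds$y)), function(cl) {
        pool <- which(ds$y == cl)
        k <- round(train_fraction * length(pool))
        k <- min(max(k, 1L), length(pool) - 1L)
        sample(pool, k)
      }), use.names = FALSE)
    } else {
      k <- round(train_fraction * ds$n)
      k <- min(max(k, 1L), ds$n - 1L)
      sample(ds$n, k)
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(ds$n), idx_train)
  list(train = ds_subset(ds, idx_train), test = ds_subset(ds, idx_test))
}

#' Write a gene ranking and metrics to disk
#'
#' Emits two files derived from a gene selection: `<prefix>_genes.tsv`
#' with one row per gene of nonzero weight-row norm (columns `gene_id`,
#' `row_norm`, `selected`), sorted by norm descending, and
#' `<prefix>_metrics.json` with the supplied metrics list.  Output is
#' byte-stable for fixed inputs.
#'
#' @param selection a `gene_selection` object (see [select_genes()]).
#' @param metrics named list of scalar metrics, serialized as JSON.
#' @param prefix path prefix for the two output files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(selection, metrics, prefix) {
  stopifnot(inherits(selection, "gene_selection"))
  gene_path <- paste0(prefix, "_genes.tsv")
  metric_path <- paste0(prefix, "_metrics.json")
  keep <- which(selection$row_norms > 0)
  ord <- keep[order(selection$row_norms[keep], selection$gene_ids[keep],
                    decreasing = c(TRUE, FALSE), method = "radix")]
  tab <- data.frame(
    gene_id = selection$gene_ids[ord],
    row_norm = format(selection$row_norms[ord], digits = 12, trim = TRUE),
    selected = as.integer(ord %in% selection$selected)
  )
  utils::write.table(tab, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = 12,
                              pretty = TRUE),
             metric_path)
  invisible(c(gene_path, metric_path))
}
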