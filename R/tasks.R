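#' Draw the subsampled tasks of the multi-task ensemble
#'
#' Each of the `m` tasks is an independent draw, without replacement, of
#' `round(eta * n)` training samples.  Tasks may overlap with each other
#' (the "without replacement" applies within a task, not across tasks).
#' With `stratified = TRUE` (default) the draw is per class at rate `eta`,
#' which guarantees both classes are present in every task; unstratified
#' draws are redrawn up to `max_redraws` times if single-class.
#'
#' @param ds an [expr_dataset] (the training data).
#' @param m number of tasks, at least 1.
#' @param eta sampling rate in (0, 1]; each task has `round(eta * n)` samples.
#' @param seed integer seed; draws are deterministic given it.
#' @param stratified draw per class (default) or from the pooled samples.
#' @param max_redraws redraw budget for single-class unstratified draws.
#' @return An object of class `task_collection`: list with the per-task
#'   index sets `subsets`, views `Xk` and `yk` (labels in -1/+1), sizes
#'   `nk`, and `m`, `eta`, `n`, `d`.
#' @examples
#' ds <- expr_dataset(matrix(rnorm(200), 20, 10), labels = rep(0:1, 10))
#' tc <- draw_task_subsets(ds, m = 4, eta = 0.7, seed = 1)
#' lengths(tc$subsets)  # all equal round(0.7 * 20) = 14
#' @export
draw_task_subsets <- function(ds, m, eta, seed = NULL, stratified = TRUE,
                              max_redraws = 100L) {
  stopifnot(inherits(ds, "expr_dataset"))
  task_collection(ds$x, ds$ypm, m = m, eta = eta, seed = seed,
                  stratified = stratified, max_redraws = max_redraws)
}

# Matrix-level constructor used internally (x may already be standardized).
task_collection <- function(x, ypm, m, eta, seed = NULL, stratified = TRUE,
                            max_redraws = 100L) {
  n <- nrow(x); d <- ncol(x)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta > 1)
    stop("'eta' must lie in (0, 1]", call. = FALSE)
  nk <- round(eta * n)
  if (nk < 2L) stop("round(eta * n) must be at least 2", call. = FALSE)

  pos <- which(ypm > 0); neg <- which(ypm < 0)
  if (stratified && (length(pos) == 0L || length(neg) == 0L))
    stop("stratified task draws need both classes present", call. = FALSE)

  subsets <- with_seed_(seed, lapply(seq_len(m), function(k) {
    if (stratified) {
      npos <- round(eta * length(pos))
      npos <- min(max(npos, 1L), length(pos), nk - 1L)
      nneg <- nk - npos
      if (nneg < 1L || nneg > length(neg))
        stop("cannot form a stratified subset of size round(eta * n)",
             call. = FALSE)
      sort(c(sample(pos, npos), sample(neg, nneg)))
    } else {
      for (try in seq_len(max_redraws + 1L)) {
        idx <- sort(sample(n, nk))
        if (length(unique(sign(ypm[idx]))) == 2L) return(idx)
      }
      stop(sprintf("subset %d single-class after %d redraws", k, max_redraws),
           call. = FALSE)
    }
  }))

  structure(
    list(subsets = subsets,
         Xk = lapply(subsets, function(i) x[i, , drop = FALSE]),
         yk = lapply(subsets, function(i) ypm[i]),
         nk = lengths(subsets),
         m = as.integer(m), eta = eta, n = n, d = d,
         seed = seed, stratified = stratified),
    class = "task_collection"
  )
}

#' @export
print.task_collection <- function(x, ...) {
  cat(sprintf("Task collection: m=%d tasks of %d samples (eta=%.2f, n=%d, d=%d)\n",
              x$m, x$nk[1L], x$eta, x$n, x$d))
  invisible(x)
}

#' Export task index sets as JSON
#'
#' Writes the 1-based per-task sample indices so an experiment can be
#' replayed exactly.
#' @param tc a `task_collection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
export_task_subsets <- function(tc, path) {
  stopifnot(inherits(tc, "task_collection"))
  writeLines(jsonlite::toJSON(list(m = tc$m, eta = tc$eta, n = tc$n,
                                   subsets = tc$subsets),
                              auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
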