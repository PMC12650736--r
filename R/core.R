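# Mathematical core: multi-task logistic loss, gradient, l2,1 proximal
# operator, and the penalty threshold lambda_max.

#' Multi-task logistic loss
#'
#' The smooth part of the objective:
#' `sum_k (1/n_k) sum_i log(1 + exp(-y_ik (x_ik . W_k + c_k)))`,
#' with labels in \{-1, +1\} and per-task averaging.  Evaluation is
#' overflow-safe for arbitrarily large margins.
#'
#' @param tc a `task_collection`.
#' @param W `d x m` weight matrix (column k = task k).
#' @param cvec length-`m` bias vector.
#' @return A single nonnegative number.
#' @export
mtl_smooth_loss <- function(tc, W, cvec) {
  check_dims(tc, W, cvec)
  total <- 0
  for (k in seq_len(tc$m)) {
    margin <- tc$yk[[k]] * (tc$Xk[[k]] %*% W[, k] + cvec[k])
    total <- total + sum(log1pexp_neg(margin)) / tc$nk[k]
  }
  total
}

#' Penalized objective
#'
#' Smooth loss plus the row-group penalty
#' `lambda * sum_j ||W_j.||_2` over the `d` genes: the l2,1 norm of the
#' `d x m` weight matrix, which zeroes entire gene rows and so gives every
#' gene a shared in/out status across tasks.
#'
#' @inheritParams mtl_smooth_loss
#' @param lambda penalty weight, nonnegative.
#' @export
mtl_objective <- function(tc, W, cvec, lambda) {
  if (lambda < 0) stop("'lambda' must be nonnegative", call. = FALSE)
  mtl_smooth_loss(tc, W, cvec) + lambda * sum(row_norms2(W))
}

#' Gradient of the smooth loss
#'
#' Column k of the weight gradient is
#' `(1/n_k) X_k' (-y_k * sigma(-y_k * (X_k W_k + c_k)))`; the bias gradient
#' is the analogous mean.  Each column depends only on task k's data.
#'
#' @inheritParams mtl_smooth_loss
#' @return `list(W = d x m matrix, c = length-m vector)`.
#' @export
mtl_gradient <- function(tc, W, cvec) {
  check_dims(tc, W, cvec)
  Gw <- matrix(0, tc$d, tc$m)
  gc <- numeric(tc$m)
  for (k in seq_len(tc$m)) {
    yk <- tc$yk[[k]]
    margin <- yk * (tc$Xk[[k]] %*% W[, k] + cvec[k])
    s <- yk * (-1 / (1 + exp(margin)))         # -y * sigma(-margin)
    Gw[, k] <- crossprod(tc$Xk[[k]], s) / tc$nk[k]
    gc[k] <- sum(s) / tc$nk[k]
  }
  list(W = Gw, c = gc)
}

check_dims <- function(tc, W, cvec) {
  if (!is.matrix(W) || nrow(W) != tc$d || ncol(W) != tc$m)
    stop(sprintf("W must be %d x %d", tc$d, tc$m), call. = FALSE)
  if (length(cvec) != tc$m)
    stop(sprintf("bias vector must have length %d", tc$m), call. = FALSE)
  invisible(TRUE)
}

#' Proximal operator of the l2,1 norm (block soft-thresholding)
#'
#' Row-wise shrinkage `W_j = max(0, 1 - theta / ||A_j||_2) * A_j`, the exact
#' minimizer of `(1/2)||W - A||_F^2 + theta * sum_j ||W_j||_2`.  Rows with
#' norm at most `theta` are set exactly to zero, which is what makes the
#' penalty perform gene selection.
#'
#' @param A numeric matrix (`d x m`).
#' @param theta nonnegative threshold (`lambda / gamma` in the solver).
#' @return Matrix of the same shape as `A`.
#' @examples
#' prox_l21(rbind(c(3, 4), c(0.3, 0.4)), theta = 1)
#' @export
prox_l21 <- function(A, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0)
    stop("'theta' must be a single nonnegative number", call. = FALSE)
  A <- as.matrix(A)
  if (theta == 0) return(A)
  rn <- row_norms2(A)
  shrink <- pmax(0, 1 - theta / pmax(rn, .Machine$double.xmin))
  A * shrink
}

#' Smallest penalty weight with an all-zero solution
#'
#' Computes `lambda_max = max_j ||grad_j L(0, c*)||_2`, the KKT threshold at
#' which the zero weight matrix (with per-task intercepts at their
#' null-model optimum `c*_k = log(n_k+ / n_k-)`) becomes globally optimal.
#' Any `lambda >= lambda_max` yields `W = 0` at convergence; the default
#' cross-validation grid is anchored at this value.
#'
#' @param tc a `task_collection`.
#' @return A positive number.
#' @export
mtl_lambda_max <- function(tc) {
  cstar <- vapply(tc$yk, function(y) {
    p <- mean(y > 0)
    p <- min(max(p, 1e-12), 1 - 1e-12)
    log(p / (1 - p))
  }, numeric(1))
  g <- mtl_gradient(tc, matrix(0, tc$d, tc$m), cstar)
  max(row_norms2(g$W))
}
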