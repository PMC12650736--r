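# Proximal gradient descent (ISTA) with backtracking line search.

#' Solver control parameters
#'
#' @param gamma0 initial inverse step length (step = 1/gamma).  Each outer
#'   iteration starts from `max(gamma0, gamma_prev / alpha)` — one step of
#'   re-growth — so the step length can recover after a conservative phase
#'   without re-paying the full backtracking cost every iteration.
#' @param alpha backtracking growth factor for gamma, greater than 1.
#' @param tol_rel stop when the relative objective decrease falls below this.
#' @param max_iters outer iteration cap.
#' @param bt_max backtracking retries allowed within one iteration.
#' @return A list of class `mtl_control`.
#' @export
mtl_control <- function(gamma0 = 1, alpha = 2, tol_rel = 1e-6,
                        max_iters = 1000L, bt_max = 50L) {
  stopifnot(gamma0 > 0, alpha > 1, tol_rel >= 0, max_iters >= 1, bt_max >= 1)
  structure(list(gamma0 = gamma0, alpha = alpha, tol_rel = tol_rel,
                 max_iters = as.integer(max_iters),
                 bt_max = as.integer(bt_max)),
            class = "mtl_control")
}

#' One proximal gradient step
#'
#' Forms `A = W - (1/gamma) * grad_W L` and applies block soft-thresholding
#' at `lambda / gamma`; the unpenalized biases take a plain gradient step.
#'
#' @param tc a `task_collection`.
#' @param W,cvec current iterate.
#' @param gamma inverse step length, positive.
#' @param lambda penalty weight.
#' @return `list(W = , c = )`, the updated iterate.
#' @export
proximal_step <- function(tc, W, cvec, gamma, lambda) {
  stopifnot(gamma > 0)
  g <- mtl_gradient(tc, W, cvec)
  list(W = prox_l21(W - g$W / gamma, lambda / gamma),
       c = cvec - g$c / gamma)
}

#' Fit the multi-task model at a fixed penalty
#'
#' Proximal gradient descent from `W = 0, c = 0` (the problem is convex, so
#' initialization does not affect the solution).  Each iteration takes a
#' gradient step on the smooth loss followed by the l2,1 prox; the step is
#' backtracked (gamma grown by `alpha`) until the quadratic-majorizer
#' sufficient-decrease condition
#' `L(W') <= L(W) + <grad, W'-W> + (gamma/2)||W'-W||^2`
#' holds, which guarantees a monotonically non-increasing objective.
#' Iteration stops when the relative objective decrease drops below
#' `control$tol_rel` or `control$max_iters` is reached.
#'
#' @param tc a `task_collection`.
#' @param lambda penalty weight, nonnegative.
#' @param control an [mtl_control()] list.
#' @param W0,c0 optional warm start (defaults to zero).
#' @return `list(W, c, trace, iterations, converged)`, where `trace` holds
#'   the objective after each accepted step (element 1 = initial value).
#' @export
mtl_fit <- function(tc, lambda, control = mtl_control(),
                    W0 = NULL, c0 = NULL) {
  if (lambda < 0) stop("'lambda' must be nonnegative", call. = FALSE)
  W <- W0 %||% matrix(0, tc$d, tc$m)
  cvec <- c0 %||% numeric(tc$m)
  m <- tc$m

  # per-task margins y_ik * (x_ik . W_k + c_k); loss and gradient both
  # derive from them, so they are computed once per visited point
  margins_at <- function(W, cvec)
    lapply(seq_len(m), function(k)
      tc$yk[[k]] * (tc$Xk[[k]] %*% W[, k] + cvec[k]))
  loss_from <- function(marg) {
    total <- 0
    for (k in seq_len(m))
      total <- total + sum(log1pexp_neg(marg[[k]])) / tc$nk[k]
    total
  }
  grad_from <- function(marg) {
    Gw <- matrix(0, tc$d, m)
    gc <- numeric(m)
    for (k in seq_len(m)) {
      s <- tc$yk[[k]] * (-1 / (1 + exp(marg[[k]])))
      Gw[, k] <- crossprod(tc$Xk[[k]], s) / tc$nk[k]
      gc[k] <- sum(s) / tc$nk[k]
    }
    list(W = Gw, c = gc)
  }

  penalty <- function(W) lambda * sum(row_norms2(W))
  marg <- margins_at(W, cvec)
  f <- loss_from(marg)
  obj <- f + penalty(W)
  trace <- numeric(control$max_iters + 1L)
  trace[1L] <- obj
  converged <- FALSE
  t <- 0L
  gamma_prev <- control$gamma0
  while (t < control$max_iters) {
    t <- t + 1L
    g <- grad_from(marg)
    gamma <- max(control$gamma0, gamma_prev / control$alpha)
    accepted <- FALSE
    for (bt in seq_len(control$bt_max)) {
      Wn <- prox_l21(W - g$W / gamma, lambda / gamma)
      cn <- cvec - g$c / gamma
      dW <- Wn - W; dc <- cn - cvec
      margn <- margins_at(Wn, cn)
      fn <- loss_from(margn)
      quad <- f + sum(g$W * dW) + sum(g$c * dc) +
        (gamma / 2) * (sum(dW^2) + sum(dc^2))
      if (fn <= quad + 1e-12) { accepted <- TRUE; break }
      gamma <- gamma * control$alpha
    }
    if (!accepted)
      stop("backtracking line search exceeded its retry cap", call. = FALSE)
    gamma_prev <- gamma
    W <- Wn; cvec <- cn; f <- fn; marg <- margn
    obj_new <- f + penalty(W)
    if (!is.finite(obj_new))
      stop("objective became non-finite; check the input data", call. = FALSE)
    trace[t + 1L] <- obj_new
    rel <- (obj - obj_new) / max(abs(obj), 1)
    obj <- obj_new
    if (rel < control$tol_rel) { converged <- TRUE; break }
  }
  list(W = W, c = cvec, trace = trace[seq_len(t + 1L)],
       iterations = t, converged = converged)
}

#' First-order optimality residual
#'
#' Distance of `(W, c)` from stationarity of the convex objective, measured
#' through the subgradient conditions of the l2,1 penalty: for a gene row
#' with `||W_j.|| > 0` the residual is
#' `||grad_j L + lambda * W_j / ||W_j.|| ||_2`; for a zero row it is
#' `max(0, ||grad_j L||_2 - lambda)`.  The bias gradient norm is included.
#' The maximum over genes (and biases) is returned; it tends to zero at the
#' global minimum.
#'
#' @param tc a `task_collection`.
#' @param W,cvec a (fitted) iterate.
#' @param lambda the penalty weight the fit used.
#' @return A single nonnegative number.
#' @export
optimality_residual <- function(tc, W, cvec, lambda) {
  g <- mtl_gradient(tc, W, cvec)
  rn <- row_norms2(W)
  res <- numeric(tc$d)
  nz <- rn > 0
  if (any(nz))
    res[nz] <- row_norms2(g$W[nz, , drop = FALSE] +
                            lambda * W[nz, , drop = FALSE] / rn[nz])
  if (any(!nz))
    res[!nz] <- pmax(0, row_norms2(g$W[!nz, , drop = FALSE]) - lambda)
  max(res, sqrt(sum(g$c^2)))
}
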