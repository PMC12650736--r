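# Fixture builders and independent numerical oracles used across tests.
# Oracles are deliberately written with different algorithms than the
# package (finite differences, damped Newton, smoothed-penalty BFGS) so
# agreement is evidence, not tautology.

rand_ds <- function(n, d, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * d), n, d)
  y <- sample(rep(0:1, length.out = n))
  expr_dataset(x, labels = y)
}

rand_tc <- function(n = 16, d = 6, m = 2, eta = 0.8, seed = 1) {
  draw_task_subsets(rand_ds(n, d, seed), m = m, eta = eta, seed = seed + 100)
}

# Central finite differences of the smooth loss.
fd_gradient <- function(tc, W, cvec, h = 1e-5) {
  Gw <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(nrow(W))) {
    for (k in seq_len(ncol(W))) {
      Wp <- W; Wp[j, k] <- W[j, k] + h
      Wm <- W; Wm[j, k] <- W[j, k] - h
      Gw[j, k] <- (mtl_smooth_loss(tc, Wp, cvec) -
                     mtl_smooth_loss(tc, Wm, cvec)) / (2 * h)
    }
  }
  gc <- numeric(length(cvec))
  for (k in seq_along(cvec)) {
    cp <- cvec; cp[k] <- cvec[k] + h
    cm <- cvec; cm[k] <- cvec[k] - h
    gc[k] <- (mtl_smooth_loss(tc, W, cp) -
                mtl_smooth_loss(tc, W, cm)) / (2 * h)
  }
  list(W = Gw, c = gc)
}

# Unpenalized logistic regression by damped Newton (IRLS with step
# halving), intercept included.  Returns c(intercept, weights).
newton_logistic <- function(x, y01, max_iter = 200L, tol = 1e-13) {
  X <- cbind(1, x)
  ypm <- 2 * y01 - 1
  nll <- function(b) {
    t <- ypm * drop(X %*% b)
    sum(pmax(-t, 0) + log1p(exp(-abs(t))))
  }
  beta <- numeric(ncol(X))
  f <- nll(beta)
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    g <- crossprod(X, p - y01)
    H <- crossprod(X * (p * (1 - p)), X) + 1e-12 * diag(ncol(X))
    dir <- solve(H, g)
    step <- 1
    repeat {
      bn <- beta - step * dir
      fn <- nll(bn)
      if (fn <= f + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    conv <- abs(f - fn) < tol * max(1, abs(f))
    beta <- bn; f <- fn
    if (conv) break
  }
  beta
}

# Independent minimizer of the penalized multi-task objective: the l2,1
# norm is smoothed as sum_j sqrt(||W_j||^2 + eps), and the now-smooth
# objective is minimized by BFGS with analytic gradients from several
# starting points.  The smoothing bias is bounded by lambda * d * sqrt(eps).
smoothed_bfgs_objective <- function(tc, lambda, eps = 1e-12,
                                    n_starts = 3L) {
  d <- tc$d; m <- tc$m
  unpack <- function(par) list(W = matrix(par[seq_len(d * m)], d, m),
                               c = par[d * m + seq_len(m)])
  fn <- function(par) {
    p <- unpack(par)
    mtl_smooth_loss(tc, p$W, p$c) +
      lambda * sum(sqrt(rowSums(p$W^2) + eps))
  }
  gr <- function(par) {
    p <- unpack(par)
    g <- mtl_gradient(tc, p$W, p$c)
    r <- sqrt(rowSums(p$W^2) + eps)
    c(as.numeric(g$W + lambda * p$W / r), g$c)
  }
  best <- Inf
  set.seed(42)
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1L) numeric(d * m + m)
            else stats::rnorm(d * m + m, sd = 0.3)
    res <- stats::optim(par0, fn, gr, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    # evaluate the true (unsmoothed) objective at the BFGS solution
    p <- unpack(res$par)
    best <- min(best, mtl_objective(tc, p$W, p$c, lambda))
  }
  best
}

# Euclidean norm of the difference of two matrices.
frob <- function(a, b) sqrt(sum((a - b)^2))
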