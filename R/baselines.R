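# Single-task penalized logistic regression baselines (L1, elastic net),
# run on the same proximal-gradient engine as the multi-task model but with
# an elementwise soft-threshold prox.  The ridge part of the elastic net is
# differentiable and lives in the smooth term.

st_smooth_loss <- function(x, ypm, w, b, ridge) {
  margin <- ypm * (drop(x %*% w) + b)
  mean(log1pexp_neg(margin)) + (ridge / 2) * sum(w^2)
}

st_gradient <- function(x, ypm, w, b, ridge) {
  margin <- ypm * (drop(x %*% w) + b)
  s <- -ypm * stats::plogis(-margin)
  list(w = drop(crossprod(x, s)) / nrow(x) + ridge * w,
       b = sum(s) / nrow(x))
}

soft_threshold <- function(a, theta) sign(a) * pmax(abs(a) - theta, 0)

# ISTA with backtracking for
#   (1/n) sum log(1+exp(-y(xw+b))) + lambda*(en_mix*|w|_1 + (1-en_mix)/2*|w|_2^2)
st_fit <- function(x, ypm, lambda, en_mix = 1, control = mtl_control(),
                   w0 = NULL, b0 = NULL) {
  stopifnot(lambda >= 0, en_mix >= 0, en_mix <= 1)
  ridge <- lambda * (1 - en_mix)
  l1 <- lambda * en_mix
  w <- w0 %||% numeric(ncol(x))
  b <- b0 %||% 0
  f <- st_smooth_loss(x, ypm, w, b, ridge)
  obj <- f + l1 * sum(abs(w))
  trace <- numeric(control$max_iters + 1L)
  trace[1L] <- obj
  converged <- FALSE
  t <- 0L
  gamma_prev <- control$gamma0
  while (t < control$max_iters) {
    t <- t + 1L
    g <- st_gradient(x, ypm, w, b, ridge)
    gamma <- max(control$gamma0, gamma_prev / control$alpha)
    accepted <- FALSE
    for (bt in seq_len(control$bt_max)) {
      wn <- soft_threshold(w - g$w / gamma, l1 / gamma)
      bn <- b - g$b / gamma
      dw <- wn - w; db <- bn - b
      fn <- st_smooth_loss(x, ypm, wn, bn, ridge)
      quad <- f + sum(g$w * dw) + g$b * db +
        (gamma / 2) * (sum(dw^2) + db^2)
      if (fn <= quad + 1e-12) { accepted <- TRUE; break }
      gamma <- gamma * control$alpha
    }
    if (!accepted)
      stop("backtracking line search exceeded its retry cap", call. = FALSE)
    gamma_prev <- gamma
    w <- wn; b <- bn; f <- fn
    obj_new <- f + l1 * sum(abs(w))
    trace[t + 1L] <- obj_new
    rel <- (obj - obj_new) / max(abs(obj), 1)
    obj <- obj_new
    if (rel < control$tol_rel) { converged <- TRUE; break }
  }
  list(w = w, b = b, trace = trace[seq_len(t + 1L)], iterations = t,
       converged = converged, objective = obj)
}

# Smallest lambda at which the l1 part zeroes all weights (KKT at the
# intercept-only optimum); en_mix scales it because only the l1 fraction
# thresholds.
st_lambda_max <- function(x, ypm, en_mix = 1) {
  p <- mean(ypm > 0)
  p <- min(max(p, 1e-12), 1 - 1e-12)
  b <- log(p / (1 - p))
  g <- st_gradient(x, ypm, numeric(ncol(x)), b, ridge = 0)
  max(abs(g$w)) / max(en_mix, 1e-3)
}

cv_st_engine <- function(x, y01, grid, en_mix, nfolds, standardize,
                         control) {
  ypm <- 2 * y01 - 1
  folds <- make_folds(y01, nfolds)
  if (is.null(grid)) {
    xs <- if (standardize) standardize_columns(x)$x else x
    grid <- default_lambda_grid(st_lambda_max(xs, ypm, en_mix))
  } else {
    grid <- sort(as.numeric(grid))
  }
  grid_desc <- rev(grid)
  ll <- matrix(NA_real_, nfolds, length(grid))
  for (f in seq_len(nfolds)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (standardize) {
      std <- standardize_columns(x[tr, , drop = FALSE])
      xtr <- std$x
      xva <- standardize_columns(x[va, , drop = FALSE],
                                 center = std$center, scale = std$scale)$x
    } else {
      xtr <- x[tr, , drop = FALSE]; xva <- x[va, , drop = FALSE]
    }
    w <- NULL; b <- NULL
    for (i in seq_along(grid_desc)) {
      fit <- st_fit(xtr, ypm[tr], grid_desc[i], en_mix, control,
                    w0 = w, b0 = b)
      w <- fit$w; b <- fit$b
      z <- drop(xva %*% w) + b
      ll[f, length(grid) - i + 1L] <- val_logloss(ypm[va], z)
    }
  }
  mean_ll <- colMeans(ll)
  list(grid = grid, mean_val_logloss = mean_ll,
       chosen_lambda = max(grid[mean_ll <= min(mean_ll) + 1e-12]),
       fold_assignments = folds)
}

#' Single-task penalized logistic regression (L1 / elastic net)
#'
#' The comparison baselines: logistic regression with penalty
#' `lambda * (en_mix * ||w||_1 + (1 - en_mix)/2 * ||w||_2^2)` — pure lasso
#' at `en_mix = 1`, elastic net below.  Solved by the package's
#' proximal-gradient engine with an elementwise soft-threshold prox; when
#' `lambda` is `NULL` it is chosen by the same stratified 5-fold
#' cross-validation (minimum validation log-loss, ties to the larger value).
#'
#' @param train an [expr_dataset] or numeric matrix.
#' @param y labels when `train` is a matrix.
#' @param penalty `"l1"` (sets `en_mix = 1`) or `"elastic_net"`.
#' @param lambda penalty weight; `NULL` selects by cross-validation.
#' @param en_mix l1 fraction of the elastic-net penalty, in `[0, 1]`
#'   (default 0.5 for `"elastic_net"`).
#' @param grid optional CV grid.
#' @param nfolds,seed,standardize,control as in [mtle()].
#' @return Object of class `penalized_logistic` with `w` (named weights on
#'   the standardized scale), `b`, `lambda`, `selected` (gene indices with
#'   nonzero weight, by decreasing magnitude), `cv`.
#' @export
fit_penalized_single_task <- function(train, y = NULL,
                                      penalty = c("l1", "elastic_net"),
                                      lambda = NULL, en_mix = NULL,
                                      grid = NULL, nfolds = 5L,
                                      seed = NULL, standardize = TRUE,
                                      control = mtl_control()) {
  penalty <- match.arg(penalty)
  en_mix <- en_mix %||% if (penalty == "l1") 1 else 0.5
  if (penalty == "l1") en_mix <- 1
  ds <- if (inherits(train, "expr_dataset")) train
        else expr_dataset(train, labels = y)

  out <- with_seed_(seed, {
    cv <- NULL
    if (is.null(lambda)) {
      cv <- cv_st_engine(ds$x, ds$y, grid, en_mix = en_mix,
                         nfolds = nfolds, standardize = standardize,
                         control = control)
      lambda <- cv$chosen_lambda
      grid <- cv$grid
    }
    if (standardize) {
      std <- standardize_columns(ds$x)
      xs <- std$x; center <- std$center; scale <- std$scale
    } else {
      xs <- ds$x; center <- rep(0, ds$d); scale <- rep(1, ds$d)
    }
    if (!is.null(grid) && lambda %in% grid) {
      w <- NULL; b <- NULL
      for (l in rev(grid[grid >= lambda])) {
        fit <- st_fit(xs, ds$ypm, l, en_mix, control, w0 = w, b0 = b)
        w <- fit$w; b <- fit$b
      }
    } else {
      fit <- st_fit(xs, ds$ypm, lambda, en_mix, control)
    }
    list(fit = fit, cv = cv, lambda = lambda, center = center,
         scale = scale)
  })

  w <- out$fit$w
  names(w) <- ds$gene_ids
  sel <- which(abs(w) > 1e-8)
  sel <- sel[order(abs(w[sel]), decreasing = TRUE)]
  structure(
    list(w = w, b = out$fit$b, lambda = out$lambda, en_mix = en_mix,
         penalty = penalty, selected = sel, gene_ids = ds$gene_ids,
         center = out$center, scale = out$scale, standardize = standardize,
         cv = out$cv, iterations = out$fit$iterations,
         converged = out$fit$converged, objective = out$fit$objective,
         d = ds$d),
    class = "penalized_logistic"
  )
}

#' @export
print.penalized_logistic <- function(x, ...) {
  cat(sprintf("%s logistic regression: lambda=%.6g, %d of %d genes selected\n",
              if (x$penalty == "l1") "L1-penalized" else "Elastic-net",
              x$lambda, length(x$selected), x$d))
  invisible(x)
}

#' @export
predict.penalized_logistic <- function(object, newdata,
                                       type = c("response", "class",
                                                "link"),
                                       tau = 0.5, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "expr_dataset")) newdata$x
       else as.matrix(newdata)
  if (ncol(x) != object$d)
    stop("newdata gene count does not match the fitted model", call. = FALSE)
  if (object$standardize)
    x <- standardize_columns(x, center = object$center,
                             scale = object$scale)$x
  z <- drop(x %*% object$w) + object$b
  switch(type,
         link = z,
         response = stats::plogis(z),
         class = as.integer(stats::plogis(z) > tau))
}
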