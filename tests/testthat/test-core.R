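test_that("smooth loss matches hand values and is overflow-safe", {
  tc <- rand_tc(n = 14, d = 4, m = 3, seed = 1)
  # W = 0, c = 0: every averaged sample contributes log 2, summed over tasks
  expect_equal(mtl_smooth_loss(tc, matrix(0, 4, 3), numeric(3)), 3 * log(2))

  # one task, one sample, x = 1, y = +1, w = 1, c = 0 -> log(1 + e^-1).
  # Build the single-sample task directly from a two-sample dataset.
  ds1 <- expr_dataset(matrix(c(1, -1), 2, 1), labels = c(1, 0))
  tc1 <- draw_task_subsets(ds1, m = 1, eta = 1, seed = 1)
  tc1$subsets[[1]] <- 1L
  tc1$Xk[[1]] <- matrix(1, 1, 1)
  tc1$yk[[1]] <- 1
  tc1$nk <- 1L
  expect_equal(mtl_smooth_loss(tc1, matrix(1, 1, 1), 0), log(1 + exp(-1)))

  # margins of +-1000 everywhere: finite, no overflow, value ~ 0 on the
  # correct side and ~ |margin| on the wrong side
  xsep <- matrix(c(1, 1, -1, -1), 4, 1)
  dsep <- expr_dataset(xsep, labels = c(1, 1, 0, 0))
  tcsep <- draw_task_subsets(dsep, m = 1, eta = 1, seed = 1)
  expect_lt(mtl_smooth_loss(tcsep, matrix(1000, 1, 1), 0), 1e-300)
  wrong <- mtl_smooth_loss(tcsep, matrix(-1000, 1, 1), 0)
  expect_true(is.finite(wrong))
  expect_equal(wrong, 1000, tolerance = 1e-10)
})

test_that("objective adds the row-group penalty", {
  tc <- rand_tc(n = 12, d = 3, m = 2, seed = 2)
  W <- matrix(0, 3, 2)
  expect_equal(mtl_objective(tc, W, numeric(2), 0),
               mtl_smooth_loss(tc, W, numeric(2)))
  # lambda = 0 case and a single nonzero row (3, 4): penalty adds 5
  W2 <- W; W2[2, ] <- c(3, 4)
  expect_equal(mtl_objective(tc, W2, numeric(2), 1),
               mtl_smooth_loss(tc, W2, numeric(2)) + 5)
  # W = 0: objective independent of lambda
  expect_equal(mtl_objective(tc, W, numeric(2), 99),
               mtl_objective(tc, W, numeric(2), 0))
  expect_error(mtl_objective(tc, W, numeric(2), -1), "nonnegative")
})

test_that("gradient matches central finite differences on random instances", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(8:20, 1); d <- sample(2:10, 1); m <- sample(1:3, 1)
    tc <- rand_tc(n = n, d = d, m = m, seed = s)
    W <- matrix(rnorm(d * m, sd = 0.5), d, m)
    cvec <- rnorm(m, sd = 0.5)
    g <- mtl_gradient(tc, W, cvec)
    fd <- fd_gradient(tc, W, cvec)
    expect_lt(max(abs(g$W - fd$W)), 1e-5)
    expect_lt(max(abs(g$c - fd$c)), 1e-5)
  }
})

test_that("gradient has block structure and saturates on separated data", {
  tc <- rand_tc(n = 20, d = 5, m = 3, seed = 3)
  W <- matrix(rnorm(15), 5, 3)
  cvec <- rnorm(3)
  g1 <- mtl_gradient(tc, W, cvec)
  tc2 <- tc
  tc2$Xk[[2]] <- tc2$Xk[[2]] + 10     # perturb only task 2's data
  g2 <- mtl_gradient(tc2, W, cvec)
  expect_equal(g1$W[, 1], g2$W[, 1])
  expect_equal(g1$W[, 3], g2$W[, 3])
  expect_false(isTRUE(all.equal(g1$W[, 2], g2$W[, 2])))

  # perfectly separated with huge margins: gradient ~ 0
  xsep <- matrix(rep(c(-1, 1), each = 4), 8, 1) * 1e4
  dsep <- expr_dataset(xsep, labels = rep(c(0, 1), each = 4))
  tcsep <- draw_task_subsets(dsep, m = 1, eta = 1, seed = 1)
  gs <- mtl_gradient(tcsep, matrix(1, 1, 1), 0)
  expect_lt(max(abs(gs$W)), 1e-12)
})

test_that("prox_l21 matches hand values and an independent minimizer", {
  A <- rbind(c(3, 4), c(1, 1))
  expect_equal(prox_l21(A, 0), A)                       # identity at 0
  expect_equal(prox_l21(rbind(c(3, 4)), 5), rbind(c(0, 0)))  # boundary kill
  expect_equal(prox_l21(rbind(c(3, 4)), 1), rbind(c(2.4, 3.2)))
  expect_error(prox_l21(A, -1), "nonnegative")

  # rows of zeros stay zero
  expect_equal(prox_l21(matrix(0, 3, 2), 2), matrix(0, 3, 2))

  # independent oracle: numeric minimization of 0.5||w - a||^2 + theta||w||
  # per row, from several starts
  set.seed(10)
  for (r in 1:20) {
    mcols <- sample(2:3, 1)
    a <- rnorm(mcols, sd = 2)
    theta <- runif(1, 0, 3)
    ours <- drop(prox_l21(matrix(a, 1), theta))
    obj <- function(w) 0.5 * sum((w - a)^2) + theta * sqrt(sum(w^2))
    best <- Inf; bestw <- NULL
    for (start in list(a, a / 2, numeric(mcols))) {
      o <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 5000))
      if (o$value < best) { best <- o$value; bestw <- o$par }
    }
    expect_lt(abs(obj(ours) - best), 1e-4)
    expect_lt(sqrt(sum((ours - bestw)^2)), 1e-2)
  }
})

test_that("prox_l21 is non-expansive and thresholds exactly at theta", {
  set.seed(11)
  for (r in 1:100) {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(12), 4, 3)
    theta <- runif(1, 0, 2)
    expect_lte(frob(prox_l21(A, theta), prox_l21(B, theta)),
               frob(A, B) + 1e-12)
  }
  A <- matrix(rnorm(30), 10, 3)
  theta <- 1.2
  P <- prox_l21(A, theta)
  expect_identical(which(rowSums(P^2) > 0),
                   which(sqrt(rowSums(A^2)) > theta))
})

test_that("the penalized objective is convex along random segments", {
  tc <- rand_tc(n = 15, d = 4, m = 2, seed = 12)
  set.seed(13)
  for (r in 1:25) {
    U <- matrix(rnorm(8), 4, 2); V <- matrix(rnorm(8), 4, 2)
    cu <- rnorm(2); cv <- rnorm(2)
    a <- runif(1)
    lhs <- mtl_objective(tc, a * U + (1 - a) * V, a * cu + (1 - a) * cv,
                         0.7)
    rhs <- a * mtl_objective(tc, U, cu, 0.7) +
      (1 - a) * mtl_objective(tc, V, cv, 0.7)
    expect_lte(lhs, rhs + 1e-10)
  }
})

test_that("ensemble prediction averages logits before the link", {
  ds <- rand_ds(30, 4, seed = 14)
  fit <- mtle(ds, m = 3, lambda = 0.05, seed = 1)

  # W = 0, c = 0 model predicts exactly 0.5
  fit0 <- fit
  fit0$W <- matrix(0, 4, 3); fit0$c <- numeric(3)
  expect_equal(unname(predict(fit0, ds$x)), rep(0.5, 30))
  # and p = 0.5 at tau = 0.5 maps to class 0 (strict inequality)
  expect_equal(unname(predict(fit0, ds$x, type = "class")), rep(0L, 30))

  # identical columns reduce to single-task logistic prediction
  w <- rnorm(4); b <- 0.3
  fit1 <- fit
  fit1$W <- matrix(w, 4, 3); fit1$c <- rep(b, 3)
  xs <- scale(ds$x, center = fit$center, scale = fit$scale)
  expect_equal(unname(predict(fit1, ds$x, type = "link")),
               unname(drop(xs %*% w) + b))

  # m = 2 with per-sample logits (2, -2) averages to probability 0.5
  fit2 <- fit
  fit2$standardize <- FALSE
  fit2$W <- matrix(0, 4, 3)
  fit2$c <- c(2, -2, 0)
  expect_equal(unname(predict(fit2, ds$x)), rep(0.5, 30))

  # threshold extremes
  expect_true(all(predict(fit, ds$x, type = "class", tau = 1 - 1e-9) == 0L))
  expect_error(predict(fit, ds$x, tau = 1.5), "between 0 and 1")
  expect_error(predict(fit, ds$x[, 1:3]), "genes")
})

test_that("gene selection thresholds row norms and nests across tolerances", {
  W <- rbind(c(0, 0), c(1e-12, 0), c(0.3, 0))
  rownames(W) <- paste0("g", 1:3)
  sel <- select_genes(W, tol = 1e-8)
  expect_equal(unname(sel$selected), 3L)
  expect_equal(unname(sel$row_norms), c(0, 1e-12, 0.3))

  expect_length(select_genes(matrix(0, 4, 2))$selected, 0L)

  set.seed(15)
  for (r in 1:10) {
    W <- matrix(rnorm(20) * rbinom(20, 1, 0.5), 10, 2)
    tols <- sort(runif(2, 0, 1))
    s_small <- select_genes(W, tol = tols[1])$selected
    s_big <- select_genes(W, tol = tols[2])$selected
    expect_true(all(s_big %in% s_small))
  }
  # selected are sorted by descending row norm
  W <- matrix(rnorm(30), 15, 2)
  sel <- select_genes(W)
  expect_true(all(diff(sel$row_norms[sel$selected]) <= 0))
})
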