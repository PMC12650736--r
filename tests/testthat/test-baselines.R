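test_that("elastic net at full l1 mix reduces exactly to the lasso", {
  ds <- rand_ds(30, 10, seed = 1)
  f1 <- fit_penalized_single_task(ds, penalty = "l1", lambda = 0.05)
  f2 <- fit_penalized_single_task(ds, penalty = "elastic_net",
                                  lambda = 0.05, en_mix = 1)
  expect_equal(f1$w, f2$w)
  expect_equal(f1$b, f2$b)
})

test_that("lambda above the single-task lambda_max zeroes all weights", {
  ds <- rand_ds(40, 12, seed = 2)
  xs <- scale(ds$x)
  lmax <- mtgsel:::st_lambda_max(xs, ds$ypm, en_mix = 1)
  fit <- fit_penalized_single_task(ds, penalty = "l1", lambda = lmax * 1.01,
                                   control = mtl_control(tol_rel = 1e-10,
                                                         max_iters = 5000))
  expect_true(all(fit$w == 0))
  expect_length(fit$selected, 0L)
})

test_that("penalized fits match the coordinate-descent reference (glmnet)", {
  set.seed(3)
  n <- 30; d <- 8
  x <- matrix(rnorm(n * d), n, d)
  y <- as.integer(runif(n) < plogis(x %*% c(1.2, -1, 0.5, rep(0, 5))))
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  ds <- expr_dataset(x, labels = y)
  obj <- function(w, b, lambda, mix) {
    mean(log1p(exp(-ds$ypm * (drop(x %*% w) + b)))) +
      lambda * (mix * sum(abs(w)) + (1 - mix) / 2 * sum(w^2))
  }
  for (mix in c(1, 0.5)) {
    lambda <- 0.04
    ours <- mtgsel:::st_fit(x, ds$ypm, lambda, en_mix = mix,
                            control = mtl_control(tol_rel = 1e-12,
                                                  max_iters = 50000))
    g <- glmnet::glmnet(x, y, family = "binomial", alpha = mix,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e6)
    w_g <- as.numeric(g$beta); b_g <- as.numeric(g$a0)
    expect_lt(abs(obj(ours$w, ours$b, lambda, mix) -
                    obj(w_g, b_g, lambda, mix)), 1e-5)
  }
})

test_that("elastic-net solutions approach the lasso as the mix tends to 1", {
  ds <- rand_ds(30, 10, seed = 4)
  l1 <- fit_penalized_single_task(ds, penalty = "l1", lambda = 0.05,
                                  control = mtl_control(tol_rel = 1e-10,
                                                        max_iters = 10000))
  gaps <- vapply(c(0.9, 0.99, 0.999), function(mix) {
    en <- fit_penalized_single_task(ds, penalty = "elastic_net",
                                    lambda = 0.05, en_mix = mix,
                                    control = mtl_control(tol_rel = 1e-10,
                                                          max_iters = 10000))
    sqrt(sum((en$w - l1$w)^2))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-2)
})

test_that("ReliefF reproduces a hand-unrolled 4-point computation", {
  # class 1: (0,0), (0,1); class 0: (1,1), (1,0); k = 1.
  # Gene 1 separates the classes, gene 2 is uninformative.  Unrolling the
  # hit/miss neighbors by hand gives score +1 for gene 1 and -1 for gene 2.
  x <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  ds <- expr_dataset(x, labels = c(1, 1, 0, 0))
  fs <- relieff_scores(ds, k_neighbors = 1)
  expect_equal(unname(fs$scores), c(1, -1))
})

test_that("ReliefF scores respect symmetry, constancy and informativeness", {
  sim <- simulate_dataset(60, 20, n_relevant = 5, rho = 0,
                          effect_size = 2, seed = 5)
  ds <- sim$dataset
  # duplicated column gets an identical score
  x2 <- cbind(ds$x, dup = ds$x[, 3])
  ds2 <- expr_dataset(x2, labels = ds$y)
  fs2 <- relieff_scores(ds2, k_neighbors = 5)
  expect_equal(unname(fs2$scores[3]), unname(fs2$scores[21]))

  # constant gene scores exactly zero
  x3 <- cbind(ds$x, const = rep(1, 60))
  fs3 <- relieff_scores(expr_dataset(x3, labels = ds$y), k_neighbors = 5)
  expect_identical(unname(fs3$scores[21]), 0)

  # planted informative genes outrank pure noise in most random worlds
  wins <- 0L
  for (s in 1:20) {
    sm <- simulate_dataset(80, 30, n_relevant = 3, rho = 0,
                           effect_size = 2, seed = 100 + s)
    fs <- relieff_scores(sm$dataset, k_neighbors = 10)
    top3 <- order(fs$scores, decreasing = TRUE)[1:3]
    if (length(intersect(top3, sm$truth)) >= 2) wins <- wins + 1L
  }
  expect_gte(wins, 19L)   # > 0.95 of seeds
})

test_that("mRMR greedy selection is exact against brute force on a toy", {
  set.seed(6)
  n <- 60
  g1 <- rnorm(n)
  y <- as.integer(g1 + rnorm(n, sd = 0.4) > 0)
  x <- cbind(g1 = g1,
             g2 = g1 + rnorm(n, sd = 0.05),   # near-duplicate of g1
             g3 = rnorm(n), g4 = rnorm(n), g5 = rnorm(n))
  ds <- expr_dataset(x, labels = y)
  fs <- mrmr_select(ds, n_select = 4, n_bins = 3)

  disc <- apply(ds$x, 2, mtgsel:::discretize_ef, n_bins = 3)
  rel <- apply(disc, 2, mtgsel:::mi_disc, b = ds$y)
  # step 1: maximal relevance
  expect_equal(fs$order[1], unname(which.max(rel)))
  # the redundant near-duplicate must not be chosen second
  expect_false(fs$order[2] == 2L)
  # every later step maximizes the greedy MID criterion (brute force)
  for (step in 2:4) {
    S <- fs$order[seq_len(step - 1)]
    cand <- setdiff(1:5, S)
    crit <- vapply(cand, function(g) {
      rel[g] - mean(vapply(S, function(s)
        mtgsel:::mi_disc(disc[, g], disc[, s]), numeric(1)))
    }, numeric(1))
    expect_equal(fs$order[step], cand[which.max(crit)])
  }
  # no repeats
  expect_equal(anyDuplicated(fs$order), 0L)
})

test_that("mRMR relevance is invariant to monotone feature transforms", {
  ds <- rand_ds(50, 6, seed = 7)
  f1 <- mrmr_select(ds, n_select = 3)
  xt <- ds$x
  xt[, 2] <- exp(xt[, 2]); xt[, 4] <- xt[, 4]^3
  f2 <- mrmr_select(expr_dataset(xt, labels = ds$y), n_select = 3)
  expect_equal(unname(f1$relevance), unname(f2$relevance))
  expect_equal(f1$order, f2$order)
})

test_that("mRMR handles label-independent data and bad inputs", {
  ds <- rand_ds(40, 5, seed = 8)
  fs <- mrmr_select(ds, n_select = 5)
  expect_equal(sort(fs$order), 1:5)
  expect_true(all(fs$relevance < 0.2))   # ~0 relevance up to MI bias
  expect_error(mrmr_select(ds, n_select = 6), "more genes")
})

test_that("filter-then-classify reports one accuracy per count, no leakage", {
  sim <- simulate_dataset(80, 40, n_relevant = 5, effect_size = 2,
                          seed = 9)
  sp <- split_train_test(sim$dataset, 0.5, seed = 1)
  res <- filter_then_classify(sp$train, sp$test, method = "mrmr",
                              n_select = c(10, 20, 30))
  expect_length(res$accuracy, 3L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
  expect_length(res$selected_genes[[2]], 20L)

  # leakage guard: permuting test labels cannot change the selected genes
  test_perm <- sp$test
  set.seed(123)
  perm <- expr_dataset(test_perm$x, labels = sample(test_perm$y))
  res2 <- filter_then_classify(sp$train, perm, method = "mrmr",
                               n_select = c(10, 20, 30))
  expect_identical(res$selected_genes, res2$selected_genes)

  # n_select = d is equivalent to no filtering for relieff too
  res3 <- filter_then_classify(sp$train, sp$test, method = "relieff",
                               n_select = 40)
  expect_setequal(res3$selected_genes[[1]], sp$train$gene_ids)
})
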