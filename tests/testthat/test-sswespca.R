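test_that("edge weights are the summed squared loadings", {
  edges <- cbind(i = c(1L, 2L), j = c(2L, 3L))
  expect_equal(edge_weights(c(3, 4, 0), edges), c(25, 16))
  expect_equal(edge_weights(numeric(3), edges), c(0, 0))
  set.seed(11)
  u <- rnorm(20)
  eidx <- cbind(sample(20, 30, TRUE), sample(20, 30, TRUE))
  eidx <- eidx[eidx[, 1] != eidx[, 2], , drop = FALSE]
  expect_equal(edge_weights(u, eidx),
               apply(eidx, 1, function(e) u[e[1]]^2 + u[e[2]]^2))
  expect_equal(edge_weights(u, eidx, sqrt = TRUE),
               sqrt(edge_weights(u, eidx)))
})

test_that("sparse projection is deterministic when the pool equals k", {
  z <- c(1, -2, 3, 4, -5)
  eidx <- cbind(i = c(1L, 2L, 4L), j = c(2L, 3L, 5L))
  w <- c(5, 2, 1)
  p <- sparse_project(z, eidx, w, k = 1, omega = 0)
  expect_identical(p$support, c(1L, 2L))
  expect_equal(p$z, c(1, -2, 0, 0, 0))
  # omega = 0: independent of the RNG state
  set.seed(1); p1 <- sparse_project(z, eidx, w, k = 2, omega = 0)
  set.seed(999); p2 <- sparse_project(z, eidx, w, k = 2, omega = 0)
  expect_identical(p1, p2)
  expect_error(sparse_project(z, eidx, w, k = 5), "exceeds")
})

test_that("oversampled projection draws k edges from the top-(1+omega)k pool", {
  set.seed(21)
  z <- rnorm(12)
  eidx <- cbind(i = 1:6 * 2L - 1L, j = 1:6 * 2L)   # 6 disjoint edges
  w <- c(6, 5, 4, 3, 2, 1)
  pool_vertices <- sort(unique(as.vector(eidx[1:4, ])))  # top ceil(2*2)=4 edges
  seen <- character(0)
  for (i in 1:60) {
    p <- sparse_project(z, eidx, w, k = 2, omega = 1)
    expect_length(p$edges, 2)
    expect_true(all(p$edges %in% 1:4))
    expect_true(all(p$support %in% pool_vertices))
    seen <- union(seen, paste(p$edges, collapse = "-"))
  }
  # all C(4,2)=6 outcomes occur under repeated sampling
  expect_setequal(seen, apply(utils::combn(4, 2), 2, paste, collapse = "-"))
})

test_that("the evaluator rewards a separating probe and degrades gracefully", {
  scores_top <- 0
  for (s in 1:10) {
    set.seed(s)
    y <- factor(rep(c("a", "b"), each = 20))
    X <- matrix(rnorm(6 * 40), 6, 40)
    X[1, ] <- ifelse(y == "a", -3, 3) + rnorm(40, 0, 0.3)
    imp <- evaluator_importance(X, y, evaluator = "rf", seed = s)
    scores_top <- scores_top + (which.max(imp) == 1)
    expect_equal(max(imp), 2)
    expect_equal(min(imp), 0)
  }
  expect_gte(scores_top, 9)

  expect_warning(imp <- evaluator_importance(matrix(rnorm(20), 2), factor(rep("a", 10))),
                 "single-class")
  expect_equal(imp, c(1, 1))
  # constant matrix -> constant importances -> all-ones fallback
  expect_warning(imp2 <- evaluator_importance(matrix(1, 3, 20),
                                              factor(rep(c("a", "b"), 10)),
                                              evaluator = "linear"),
                 "constant importances")
  expect_equal(imp2, rep(1, 3))
})

test_that("reweighting keeps unit norm and shrinking support", {
  u <- c(0.6, 0.8, 0, 0)
  expect_equal(reweight_and_normalize(u, c(1, 1, 0, 0)), u)
  u2 <- reweight_and_normalize(u, c(2, 0, 0, 0))
  expect_equal(u2, c(1, 0, 0, 0))
  expect_error(reweight_and_normalize(u, c(0, 0, 0, 0)), "vanished")
  set.seed(3)
  for (i in 1:10) {
    uu <- rnorm(10); tt <- runif(10, 0, 2)
    expect_equal(sum(reweight_and_normalize(uu, tt)^2), 1)
  }
})

test_that("the sample-score update is a normalized projection", {
  expect_equal(update_v(diag(3), c(1, 0, 0)), c(1, 0, 0))
  set.seed(4)
  u0 <- rnorm(8); u0 <- u0 / sqrt(sum(u0^2))
  v0 <- rnorm(5); v0 <- v0 / sqrt(sum(v0^2))
  X <- u0 %*% t(v0)
  v <- update_v(X, u0)
  expect_equal(abs(sum(v * v0)), 1)
  expect_equal(sum(v^2), 1)
  expect_error(update_v(matrix(0, 3, 3), c(1, 0, 0)), "zero")
})

test_that("fit_pc converges under the stated tolerance with legal support", {
  coh <- small_cohort()
  lab <- waterfall_labels(coh$ic50, min_samples = 20)
  y <- stats::setNames(lab$label, lab$sample_id)
  blk <- coh$blocks$expression
  eidx <- suppressWarnings(align_edges(coh$edges, blk$probe_ids))
  X <- blk$values - rowMeans(blk$values)
  p <- selection_params(k = 6, seed = 5, n_restarts = 3)
  fit <- fit_pc(X, y[colnames(X)], eidx, p)
  expect_true(fit$converged)
  expect_lt(fit$audit[[fit$iterations]]$loss, p$tol)
  expect_equal(sum(fit$u^2), 1, tolerance = 1e-9)
  expect_equal(sum(fit$v^2), 1, tolerance = 1e-9)
  # support legality: support equals the vertex union of the last sampled edges
  last_edges <- fit$audit[[fit$iterations]]$edges
  expect_length(last_edges, p$k)
  legal <- sort(unique(as.vector(eidx[last_edges, ])))
  expect_true(all(fit$support %in% legal))

  # determinism: same seed, same everything
  fit2 <- fit_pc(X, y[colnames(X)], eidx, p)
  expect_identical(fit$support, fit2$support)
  expect_identical(fit$iterations, fit2$iterations)
  expect_identical(fit$u, fit2$u)
})

test_that("deflated components are orthogonal and the key matrix uses the union", {
  coh <- small_cohort()
  lab <- waterfall_labels(coh$ic50, min_samples = 20)
  y <- stats::setNames(lab$label, lab$sample_id)
  blk <- coh$blocks$expression
  eidx <- suppressWarnings(align_edges(coh$edges, blk$probe_ids))
  X <- blk$values - rowMeans(blk$values)
  p <- selection_params(k = 6, seed = 9, n_pcs = 2, n_restarts = 2)
  fit <- fit_multi_pc(X, y[colnames(X)], eidx, p)
  expect_length(fit$loadings, 2)
  u1 <- fit$loadings[[1]]$u; u2 <- fit$loadings[[2]]$u
  # Hotelling deflation removes the first component exactly: the matrix the
  # second fit saw has no u1 direction left
  X2 <- X - u1 %*% crossprod(u1, X)
  expect_lt(max(abs(crossprod(u1, X2))), 1e-8)
  # loadings themselves are exactly orthogonal whenever the sparse supports
  # are disjoint (sparse masking can reintroduce a small overlap otherwise)
  if (length(intersect(fit$loadings[[1]]$support, fit$loadings[[2]]$support)) == 0) {
    expect_identical(sum(u1 * u2), 0)
  } else {
    expect_lt(abs(sum(u1 * u2)), 0.25)
  }
  # unsupervised two-component fit: variance ordering puts the decoy and the
  # planted component on disjoint gene sets, so orthogonality is exact
  pu <- p; pu$evaluator <- "none"; pu$seed <- 17L
  fitu <- fit_multi_pc(X, NULL, eidx, pu)
  if (length(intersect(fitu$loadings[[1]]$support, fitu$loadings[[2]]$support)) == 0) {
    expect_identical(sum(fitu$loadings[[1]]$u * fitu$loadings[[2]]$u), 0)
  }
  expect_identical(fit$support,
                   sort(union(fit$loadings[[1]]$support, fit$loadings[[2]]$support)))
  expect_identical(rownames(fit$key_matrix), blk$probe_ids[fit$support])

  p1 <- p; p1$n_pcs <- 1L
  f1 <- fit_multi_pc(X, y[colnames(X)], eidx, p1)
  expect_identical(f1$support, f1$loadings[[1]]$support)
})
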