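test_that("the dip statistic matches the exhaustive small-n oracle", {
  set.seed(51)
  for (i in 1:150) {
    n <- sample(4:12, 1)
    x <- switch(sample(4, 1),
                runif(n), rnorm(n),
                c(rnorm(ceiling(n / 2), -4, 0.2), rnorm(floor(n / 2), 4, 0.2)),
                round(runif(n, 0, 4)) / 2)
    if (length(unique(x)) < 2) next
    expect_equal(dip_statistic(x, max_points = 0),
                 drpfuse:::cpp_dip_oracle(x), tolerance = 1e-7)
  }
})

test_that("dip bounds hold and bimodality is detected", {
  set.seed(52)
  for (i in 1:50) {
    n <- sample(10:300, 1)
    d <- dip_statistic(rnorm(n), max_points = 0)
    expect_gte(d, 1 / (2 * n) - 1e-9)
    expect_lte(d, 0.25 + 1e-9)
  }
  dt <- dip_test(c(rnorm(100, -5, 0.1), rnorm(100, 5, 0.1)),
                 n_boot = 500, seed = 53)
  expect_lt(dt$pvalue, 0.05)
  expect_gt(dt$dip, 0.2)
  # a dip of 0 can never beat any bootstrap dip
  expect_equal(dip_pvalue(0, 50, n_boot = 200, seed = 53)$pvalue, 1)
  expect_error(dip_statistic(rep(1, 10)), "constant")
})

test_that("weight normalization maps the endpoints and midpoint linearly", {
  expect_equal(normalize_range(c(0.1, 0.5, 0.9), 0.5, 1.5), c(0.5, 1.0, 1.5))
  expect_equal(normalize_range(c(0, 2, 4), 0.5, 1.5), c(0.5, 1.0, 1.5))
  expect_warning(w <- normalize_range(c(1, 1, 1), 0.5, 1.5), "identical")
  expect_equal(w, rep(1, 3))
  expect_error(normalize_range(1:3, 2, 1), "a must be < b")
})

test_that("beta weights average per-column variances with denominator n-1", {
  const <- matrix(5, 4, 3)
  cols123 <- matrix(rep(c(1, 2, 3), 4), 3, 4)
  expect_equal(attr(beta_weights(list(const, cols123, cols123 * 2)), "raw")[1], 0)
  expect_equal(attr(beta_weights(list(const, cols123, cols123 * 2)), "raw")[2], 1)
  expect_error(beta_weights(list(matrix(1, 1, 3))), "single-row")
})

test_that("fuse is the entrywise weighted sum and detects misalignment", {
  set.seed(54)
  blocks <- replicate(3, matrix(rnorm(25), 5, 5), simplify = FALSE)
  f <- fuse(blocks, c(1, 1, 1), c(1, 1, 1))
  expect_equal(f$values, blocks[[1]] + blocks[[2]] + blocks[[3]], tolerance = 1e-12)

  alpha <- runif(3, 0.5, 1.5); beta <- runif(3, 0.5, 1.5)
  f2 <- fuse(blocks, alpha, beta)
  ref <- matrix(0, 5, 5)
  for (i in 1:3) ref <- ref + alpha[i] * beta[i] * blocks[[i]]
  expect_equal(f2$values, ref, tolerance = 1e-9)

  # zero weight makes the output independent of that block
  b2 <- blocks; b2[[2]] <- matrix(rnorm(25), 5, 5)
  expect_equal(fuse(blocks, c(1, 0, 1), c(1, 5, 1))$values,
               fuse(b2, c(1, 0, 1), c(1, 5, 1))$values)

  expect_error(fuse(list(blocks[[1]], matrix(0, 4, 5)), c(1, 1), c(1, 1)),
               "alignment")
})

test_that("fusion is linear in each block", {
  set.seed(55)
  a <- matrix(rnorm(16), 4); b <- matrix(rnorm(16), 4); c0 <- matrix(rnorm(16), 4)
  al <- c(0.7, 1.2); be <- c(1.1, 0.6)
  f_ab <- fuse(list(a + b, c0), al, be)$values
  f_a <- fuse(list(a, c0), al, be)$values
  f_b <- fuse(list(b, matrix(0, 4, 4)), al, be)$values
  expect_equal(f_ab, f_a + f_b, tolerance = 1e-12)
  expect_equal(fuse(list(3 * a, c0), al, be)$values,
               3 * f_a - 2 * fuse(list(matrix(0, 4, 4), c0), al, be)$values,
               tolerance = 1e-12)
})

test_that("alpha weights rank the bimodal block highest", {
  coh <- simulate_cohort(sim_spec(n_samples = 80, seed = 56))
  sims <- lapply(names(coh$blocks), function(b) {
    blk <- coh$blocks[[b]]
    kp <- coh$truth$signal_probes[[b]]
    v <- blk$values[kp, , drop = FALSE]
    omics_similarity(omics_block(v - rowMeans(v), blk$name))
  })
  names(sims) <- names(coh$blocks)
  al <- alpha_weights(sims, n_boot = 300, seed = 57)
  expect_identical(names(sims)[which.max(al)], "methylation")
  expect_equal(max(al), 1.5)   # the maximum maps to b
  expect_equal(min(al), 0.5)   # the minimum maps to a
})
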