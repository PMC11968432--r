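test_that("omics labels map to their kernels", {
  expect_identical(kernel_for_omics("expression"), "spearman")
  expect_identical(kernel_for_omics("methylation"), "spearman")
  expect_identical(kernel_for_omics("copynumber"), "kendall")
  expect_error(kernel_for_omics("other"), "config error")
  expect_identical(kernel_for_omics("other", override = "kendall"), "kendall")
})

test_that("similarity matrices are symmetric with unit diagonal and bounded", {
  set.seed(31)
  m <- matrix(rnorm(15 * 20), 15, 20,
              dimnames = list(paste0("p", 1:15), paste0("s", 1:20)))
  for (s in list(spearman_similarity(m), kendall_similarity(m))) {
    expect_equal(diag(s$values), stats::setNames(rep(1, 20), paste0("s", 1:20)))
    expect_equal(s$values, t(s$values))
    expect_true(all(s$values >= -1 & s$values <= 1))
  }
  rev3 <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(spearman_similarity(rev3)$values["a", "b"], -1)
  expect_equal(kendall_similarity(rev3)$values["a", "b"], -1)
})

test_that("spearman matches the rank-then-pearson oracle", {
  set.seed(32)
  for (i in 1:50) {
    k <- sample(5:50, 1)
    m <- matrix(rnorm(2 * k), k, 2, dimnames = list(NULL, c("x", "y")))
    got <- spearman_similarity(m)$values["x", "y"]
    expect_equal(got, cor(rank(m[, 1]), rank(m[, 2])), tolerance = 1e-12)
  }
})

test_that("kendall matches the pair-enumeration oracle", {
  expect_equal(kendall_similarity(matrix(c(1, 2, 3, 1, 3, 2), 3, 2,
                                         dimnames = list(NULL, c("x", "y"))))$values["x", "y"],
               1 / 3)   # C = 2, D = 1 over 3 pairs
  tau_a_oracle <- function(x, y) {
    s <- 0
    for (i in seq_along(x)[-length(x)]) for (j in (i + 1):length(x))
      s <- s + sign(x[j] - x[i]) * sign(y[j] - y[i])
    s / (length(x) * (length(x) - 1) / 2)
  }
  set.seed(33)
  for (i in 1:50) {
    k <- sample(4:50, 1)
    m <- matrix(rnorm(2 * k), k, 2, dimnames = list(NULL, c("x", "y")))
    expect_equal(kendall_similarity(m)$values["x", "y"],
                 tau_a_oracle(m[, 1], m[, 2]), tolerance = 1e-12)
    # with ties, tau-a still uses the fixed n(n-1)/2 denominator
    mt <- matrix(sample(1:4, 2 * k, TRUE), k, 2, dimnames = list(NULL, c("x", "y")))
    expect_equal(kendall_similarity(mt)$values["x", "y"],
                 tau_a_oracle(mt[, 1], mt[, 2]), tolerance = 1e-12)
  }
})

test_that("spearman is invariant under monotone transforms of the values", {
  set.seed(34)
  m <- matrix(rnorm(10 * 8), 10, 8, dimnames = list(NULL, paste0("s", 1:8)))
  s1 <- spearman_similarity(m)$values
  s2 <- spearman_similarity(exp(m))$values
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("constant sample vectors give similarity 0 with a warning", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, 2] <- 7
  expect_warning(s <- spearman_similarity(m), "constant sample")
  expect_equal(unname(s$values["a", "b"]), 0)
})

test_that("anchors x queries matrices restrict to the requested samples", {
  set.seed(35)
  m <- matrix(rnorm(12 * 10), 12, 10, dimnames = list(NULL, paste0("s", 1:10)))
  s <- spearman_similarity(m, anchors = paste0("s", 1:6), queries = paste0("s", 7:10))
  expect_equal(dim(s$values), c(6, 4))
  full <- spearman_similarity(m)$values
  expect_equal(s$values, full[1:6, 7:10])
})
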