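test_that("kan_phi branches behave as written", {
  x <- seq(-1, 1, length.out = 21)
  nb <- 8 + 3
  # spline branch disabled, identity residual -> w2 * x
  expect_equal(kan_phi(x, 0, 1.5, rnorm(nb), residual_act = "identity"), 1.5 * x)
  # both branches off -> 0
  expect_equal(kan_phi(x, 1, 0, rep(0, nb)), rep(0, 21))
})

test_that("the B-spline basis matches an independent de Boor recursion", {
  grid_size <- 8; order <- 3
  h <- 2 / grid_size
  knots <- seq(-1 - order * h, 1 + order * h, by = h)
  x <- c(seq(-1, 1, length.out = 17), 0.123, -0.777)
  B <- bspline_basis(x, grid_size, order)$B
  for (i in seq_len(grid_size + order)) {
    expect_equal(B[, i], deboor_basis(x, i, order, knots), tolerance = 1e-12)
  }
  # partition of unity inside the grid
  expect_equal(rowSums(B), rep(1, length(x)), tolerance = 1e-12)
})

test_that("the vectorized KAN layer equals the double-loop reference", {
  set.seed(61)
  lay <- drpfuse:::kan_layer_init(4, 3, 8, 3)
  lay$bias <- rnorm(3)
  X <- matrix(runif(5 * 4, -1.6, 1.6), 5, 4)  # includes extrapolation range
  out <- kan_layer_forward(X, lay)
  ref <- matrix(rep(lay$bias, each = 5), 5, 3)
  for (q in 1:3) for (p in 1:4) {
    ref[, q] <- ref[, q] + kan_phi(X[, p], lay$w1[q, p], lay$w2[q, p],
                                   lay$coef[q, p, ], 8, 3)
  }
  expect_equal(out, ref, tolerance = 1e-9)
  # single edge reduces to kan_phi
  l1 <- drpfuse:::kan_layer_init(1, 1, 8, 3)
  expect_equal(drop(kan_layer_forward(matrix(X[, 1]), l1)),
               kan_phi(X[, 1], l1$w1[1, 1], l1$w2[1, 1], l1$coef[1, 1, ]),
               tolerance = 1e-12)
  # all-zero parameters give the zero map
  l0 <- drpfuse:::kan_layer_init(4, 3, 8, 3)
  l0$w1[] <- 0; l0$w2[] <- 0; l0$coef[] <- 0
  expect_equal(kan_layer_forward(X, l0), matrix(0, 5, 3))
})

test_that("1-D convolution matches the naive sliding-window oracle", {
  x <- matrix(rnorm(3 * 11), 3, 11)
  expect_equal(conv1d_forward(x, c(0, 1, 0))[[1]], x)          # identity kernel
  expect_equal(conv1d_forward(matrix(2, 1, 9), c(1, 1, 1) / 3)[[1]][, 2:8, drop = FALSE],
               matrix(2, 1, 7))                                # interior constant
  naive <- function(row, ker) {
    ks <- length(ker); P <- (ks - 1) / 2; L <- length(row)
    rp <- c(rep(0, P), row, rep(0, P))
    vapply(seq_len(L), function(l) sum(ker * rp[l:(l + ks - 1)]), 0)
  }
  set.seed(62)
  for (ks in c(3, 5, 7)) {
    ker <- rnorm(ks)
    got <- conv1d_forward(x, ker)[[1]]
    expect_equal(got, t(apply(x, 1, naive, ker)), tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with finite differences", {
  spec <- predictor_spec(conv_channels = 2, kernel_size = 3, kan_hidden = 4,
                        epochs = 1, seed = 63)
  set.seed(63)
  net <- drpfuse:::nn_init(spec, 10)
  X <- matrix(rnorm(5 * 10), 5, 10)
  y <- c(1, 0, 1, 0, 1)
  fw <- drpfuse:::nn_forward(net, X, cache = TRUE)
  z <- drop(fw$logit)
  gr <- drpfuse:::nn_backward(net, fw, matrix((1 / (1 + exp(-z)) - y) / 5, ncol = 1))
  lossf <- function(n) drpfuse:::bce_loss(drop(drpfuse:::nn_forward(n, X)), y)
  eps <- 1e-6
  probe <- function(get, set, g) {
    v <- get(net)
    for (i in sample(length(v), min(4, length(v)))) {
      n2 <- net; vv <- get(n2); vv[i] <- vv[i] + eps
      n2 <- set(n2, vv)
      expect_equal((lossf(n2) - lossf(net)) / eps, g[i], tolerance = 1e-3)
    }
  }
  probe(function(n) n$conv$w, function(n, v) { n$conv$w[] <- v; n }, gr$conv$w)
  probe(function(n) n$layers[[1]]$coef,
        function(n, v) { n$layers[[1]]$coef[] <- v; n }, gr$layers[[1]]$coef)
  probe(function(n) n$layers[[2]]$w2,
        function(n, v) { n$layers[[2]]$w2[] <- v; n }, gr$layers[[2]]$w2)
})

test_that("training separates a separable cohort and is seed-deterministic", {
  set.seed(64)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(rnorm(n * 20), n, 20)
  X[, 1:4] <- X[, 1:4] + outer(y, rep(2.5, 4))
  spec <- predictor_spec(epochs = 150, seed = 65, patience = 0)
  m <- train_predictor(X, y, spec)
  pred <- predict(m, X)
  expect_gte(mean((pred$probability > 0.5) == y), 0.95)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))

  m2 <- train_predictor(X, y, spec)
  expect_equal(tail(m$history, 1), tail(m2$history, 1), tolerance = 1e-6)

  # permutation equivariance of prediction
  perm <- sample(n)
  expect_equal(predict(m, X[perm, ])$probability, pred$probability[perm])
})

test_that("the default predictor stays under the parameter budget", {
  spec <- predictor_spec(seed = 1)
  net <- drpfuse:::nn_init(spec, 96)   # typical fused-row length
  expect_lt(n_params(net), 50000)
  mlp <- drpfuse:::nn_init(predictor_spec(head = "mlp", seed = 1), 96)
  expect_lt(abs(log(n_params(mlp) / n_params(net))), log(1.6))
})

test_that("a 2-layer KAN fits sin(3x) to small error", {
  xs <- matrix(seq(-1, 1, length.out = 200), ncol = 1)
  ys <- sin(3 * xs[, 1])
  spec <- predictor_spec(conv_channels = 0, kan_hidden = 8, grid_size = 8,
                        spline_order = 3, epochs = 2000, lr = 0.01,
                        patience = 0, seed = 11)
  m <- train_predictor(xs, ys, spec, loss = "mse")
  xn <- sweep(sweep(xs, 2, m$scale$lo), 2, m$scale$rng, "/") * 2 - 1
  pred <- drop(drpfuse:::nn_forward(m$net, xn))
  expect_lt(mean((pred - ys)^2), 1e-3)
})

test_that("classification metrics follow their definitions", {
  yt <- factor(c(rep("responsive", 10), rep("non_responsive", 10)),
               levels = c("non_responsive", "responsive"))
  yp <- yt
  yp[1] <- "non_responsive"            # 1 FN
  yp[11:12] <- "responsive"            # 2 FP
  met <- evaluate_metrics(yt, yp)
  expect_equal(met$sensitivity, 0.9)
  expect_equal(met$specificity, 0.8)
  expect_equal(met$precision, 9 / 11)
  expect_equal(met$accuracy, 0.85)
  expect_equal(met$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))

  perfect <- evaluate_metrics(yt, yt)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)

  allpos <- evaluate_metrics(yt, factor(rep("responsive", 20),
                                        levels = levels(yt)))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
})
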