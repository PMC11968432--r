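# Conv1D + Kolmogorov-Arnold network classifier.
#
# The network is small by design (well under 50k trainable parameters): the
# cohorts this package targets have at most a few hundred samples, and the
# classifier head replaces dense layers with learnable one-dimensional edge
# functions phi(x) = w1 * spline(x) + w2 * b(x), summed across inputs.
# Everything (B-spline bases, convolution, backprop, Adam) is implemented
# directly on base R matrices; sizes are tiny so vectorized R is fast enough.

#' Predictor architecture and training settings
#'
#' @param conv_channels channels of the 1-D convolution (0 disables the
#'   convolution front end)
#' @param kernel_size convolution kernel width (odd)
#' @param pool max-pooling width/stride after the convolution
#' @param kan_hidden hidden widths of the KAN head (vector; the final 1-unit
#'   logit layer is appended automatically)
#' @param grid_size B-spline grid intervals on \[-1, 1\]
#' @param spline_order B-spline degree
#' @param residual_act residual activation `b(x)`: `"silu"` or `"identity"`
#' @param head `"kan"` or `"mlp"` (parameter-matched dense head, for the
#'   ablation)
#' @param epochs,lr,batch_size,patience,val_fraction,seed training settings;
#'   `batch_size = 0` trains full-batch, `patience = 0` disables early
#'   stopping
#' @return a `predictor_spec` list
#' @export
predictor_spec <- function(conv_channels = 2, kernel_size = 5, pool = 2,
                           kan_hidden = 8, grid_size = 8, spline_order = 3,
                           residual_act = c("silu", "identity"),
                           head = c("kan", "mlp"),
                           epochs = 300, lr = 1e-3, batch_size = 0,
                           patience = 20, val_fraction = 0.15, seed = 1) {
  residual_act <- match.arg(residual_act)
  head <- match.arg(head)
  if (kernel_size %% 2 == 0) stop("kernel_size must be odd")
  if (spline_order < 1) stop("spline_order must be >= 1")
  if (grid_size < spline_order + 1) stop("grid_size must be >= spline_order + 1")
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size), pool = as.integer(pool),
                 kan_hidden = as.integer(kan_hidden),
                 grid_size = as.integer(grid_size),
                 spline_order = as.integer(spline_order),
                 residual_act = residual_act, head = head,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 seed = seed),
            class = "predictor_spec")
}

# ---------------------------------------------------------------------------
# B-spline basis on a fixed uniform grid over [-1, 1]
# ---------------------------------------------------------------------------

#' B-spline basis values (and derivatives) on the KAN grid
#'
#' Uniform knots over \[-1, 1\] extended by `order` intervals on both sides;
#' `grid_size + order` basis functions.  Inputs outside the grid are
#' extrapolated linearly from the boundary (value and first derivative).
#'
#' @param x numeric vector of evaluation points
#' @param grid_size grid intervals
#' @param order spline degree
#' @return list with matrices `B` and `dB` (`length(x)` x basis count)
#' @export
bspline_basis <- function(x, grid_size = 8, order = 3) {
  h <- 2 / grid_size
  knots <- seq(-1 - order * h, 1 + order * h, by = h)
  nk <- length(knots)
  lo <- -1; hi <- 1
  xc <- pmin(pmax(x, lo), hi)
  M <- length(x)
  # degree-0 bases on the clamped points (last interval closed)
  B <- matrix(0, M, nk - 1)
  for (i in seq_len(nk - 1)) {
    B[, i] <- as.numeric(xc >= knots[i] & xc < knots[i + 1])
  }
  B[xc == knots[nk], nk - 1] <- 1
  dB <- NULL
  for (k in seq_len(order)) {
    nb <- nk - 1 - k
    Bk <- matrix(0, M, nb)
    dBk <- matrix(0, M, nb)
    for (i in seq_len(nb)) {
      d1 <- knots[i + k] - knots[i]
      d2 <- knots[i + k + 1] - knots[i + 1]
      Bk[, i] <- (xc - knots[i]) / d1 * B[, i] +
                 (knots[i + k + 1] - xc) / d2 * B[, i + 1]
      dBk[, i] <- k * (B[, i] / d1 - B[, i + 1] / d2)
    }
    B <- Bk
    dB <- dBk
  }
  if (order == 0) dB <- matrix(0, M, ncol(B))
  # linear extrapolation beyond the grid
  out <- x != xc
  if (any(out)) B[out, ] <- B[out, , drop = FALSE] + (x[out] - xc[out]) * dB[out, , drop = FALSE]
  list(B = B, dB = dB)
}

silu <- function(x) x / (1 + exp(-x))
dsilu <- function(x) { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) }

#' One KAN edge function
#'
#' `phi(x) = w1 * spline(x) + w2 * b(x)` with the spline a B-spline curve on
#' the fixed grid (linear extrapolation outside it).
#'
#' @param x numeric vector of inputs
#' @param w1,w2 scalar weights of the spline and residual branches
#' @param spline_coeffs basis coefficients (length `grid_size + order`)
#' @param grid_size,spline_order grid settings, see [bspline_basis()]
#' @param residual_act `"silu"` or `"identity"`
#' @return numeric vector `phi(x)`
#' @export
kan_phi <- function(x, w1, w2, spline_coeffs, grid_size = 8, spline_order = 3,
                    residual_act = "silu") {
  bb <- bspline_basis(x, grid_size, spline_order)
  res <- if (residual_act == "silu") silu(x) else x
  w1 * drop(bb$B %*% spline_coeffs) + w2 * res
}

# one KAN layer: params w1, w2 (q x p), coef (q x p x nb), bias (q)
kan_layer_init <- function(p_in, p_out, grid_size, order) {
  nb <- grid_size + order
  list(w1 = matrix(1, p_out, p_in),
       w2 = matrix(rnorm(p_out * p_in, sd = sqrt(2 / p_in)), p_out, p_in),
       coef = array(rnorm(p_out * p_in * nb, sd = 0.1 / sqrt(p_in)),
                    c(p_out, p_in, nb)),
       bias = numeric(p_out),
       grid_size = grid_size, order = order, nb = nb,
       p_in = p_in, p_out = p_out)
}

kan_layer_fwd <- function(layer, X, cache = FALSE) {
  N <- nrow(X); p <- layer$p_in; q <- layer$p_out; nb <- layer$nb
  bb <- bspline_basis(as.vector(X), layer$grid_size, layer$order)
  # reshape to N x (p*nb), column block pp holds the nb bases of input pp
  Bm <- matrix(aperm(array(bb$B, c(N, p, nb)), c(1, 3, 2)), N, p * nb)
  dBm <- matrix(aperm(array(bb$dB, c(N, p, nb)), c(1, 3, 2)), N, p * nb)
  ceff <- layer$coef
  for (b in seq_len(nb)) ceff[, , b] <- ceff[, , b] * layer$w1
  Ceff <- matrix(aperm(ceff, c(1, 3, 2)), q, nb * p)
  S <- silu(X)
  out <- Bm %*% t(Ceff) + S %*% t(layer$w2) +
         matrix(layer$bias, N, q, byrow = TRUE)
  if (!cache) return(out)
  list(out = out, X = X, Bm = Bm, dBm = dBm, Ceff = Ceff, S = S)
}

kan_layer_bwd <- function(layer, cache, dOut) {
  N <- nrow(dOut); p <- layer$p_in; q <- layer$p_out; nb <- layer$nb
  dCeff <- crossprod(dOut, cache$Bm)                       # q x (p*nb)
  dC <- aperm(array(dCeff, c(q, nb, p)), c(1, 3, 2))       # q x p x nb
  dcoef <- dC
  dw1 <- matrix(0, q, p)
  for (b in seq_len(nb)) {
    dcoef[, , b] <- dC[, , b] * layer$w1
    dw1 <- dw1 + dC[, , b] * layer$coef[, , b]
  }
  dw2 <- crossprod(dOut, cache$S)
  dbias <- colSums(dOut)
  # input gradient
  Tm <- (dOut %*% cache$Ceff) * cache$dBm                  # N x (p*nb)
  agg <- matrix(0, p * nb, p)
  agg[cbind(seq_len(p * nb), rep(seq_len(p), each = nb))] <- 1
  dX <- Tm %*% agg + (dOut %*% layer$w2) * dsilu(cache$X)
  list(grads = list(w1 = dw1, w2 = dw2, coef = dcoef, bias = dbias), dX = dX)
}

#' KAN layer forward pass
#'
#' `out_q = bias_q + sum_p phi_(q,p)(x_p)` for a batch of input rows.
#'
#' @param x numeric matrix (samples x inputs) or vector (one sample)
#' @param layer a KAN layer parameter list with elements `w1`, `w2`
#'   (out x in), `coef` (out x in x basis), `bias`, `grid_size`, `order`
#' @param residual_act `"silu"` or `"identity"` (the packaged networks use
#'   silu)
#' @return numeric matrix, samples x outputs
#' @export
kan_layer_forward <- function(x, layer, residual_act = "silu") {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (residual_act != "silu")
    stop("only the silu residual is implemented for the vectorized layer")
  lay <- layer
  if (is.null(lay$nb)) lay$nb <- dim(lay$coef)[3]
  if (is.null(lay$p_in)) lay$p_in <- ncol(lay$w1)
  if (is.null(lay$p_out)) lay$p_out <- nrow(lay$w1)
  if (is.null(lay$bias)) lay$bias <- numeric(lay$p_out)
  kan_layer_fwd(lay, x)
}

# ---------------------------------------------------------------------------
# 1-D convolution front end
# ---------------------------------------------------------------------------

#' 1-D convolution (cross-correlation) with same padding
#'
#' Plain sliding-window cross-correlation of each input row with each kernel;
#' no nonlinearity or pooling (those are applied inside the full predictor).
#'
#' @param x numeric matrix (samples x length) or vector
#' @param kernels numeric matrix (kernel_size x channels) or vector
#' @param bias per-channel bias (default 0)
#' @return list of per-channel matrices (samples x length)
#' @export
conv1d_forward <- function(x, kernels, bias = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  if (is.null(dim(kernels))) kernels <- matrix(kernels)
  ks <- nrow(kernels); C <- ncol(kernels)
  if (ks %% 2 == 0) stop("kernel size must be odd")
  if (is.null(bias)) bias <- numeric(C)
  N <- nrow(x); L <- ncol(x); P <- (ks - 1) / 2
  xpad <- cbind(matrix(0, N, P), x, matrix(0, N, P))
  lapply(seq_len(C), function(c) {
    out <- matrix(bias[c], N, L)
    for (t in seq_len(ks)) out <- out + kernels[t, c] * xpad[, t:(t + L - 1), drop = FALSE]
    out
  })
}

conv_block_fwd <- function(par, X, pool, cache = FALSE) {
  N <- nrow(X); L <- ncol(X); C <- ncol(par$w); ks <- nrow(par$w)
  conv <- conv1d_forward(X, par$w, par$b)
  Lp <- floor(L / pool)
  act <- lapply(conv, function(m) pmax(m, 0))
  pooled <- vector("list", C)
  amax <- vector("list", C)
  for (c in seq_len(C)) {
    pm <- matrix(-Inf, N, Lp); am <- matrix(1L, N, Lp)
    for (o in seq_len(pool)) {
      idx <- (seq_len(Lp) - 1) * pool + o
      better <- act[[c]][, idx, drop = FALSE] > pm
      am[better] <- o
      pm[better] <- act[[c]][, idx, drop = FALSE][better]
    }
    pooled[[c]] <- pm; amax[[c]] <- am
  }
  out <- do.call(cbind, pooled)
  if (!cache) return(out)
  list(out = out, X = X, conv = conv, amax = amax, Lp = Lp, pool = pool)
}

conv_block_bwd <- function(par, cache, dOut) {
  C <- ncol(par$w); ks <- nrow(par$w)
  N <- nrow(cache$X); L <- ncol(cache$X); Lp <- cache$Lp; pool <- cache$pool
  P <- (ks - 1) / 2
  xpad <- cbind(matrix(0, N, P), cache$X, matrix(0, N, P))
  dw <- matrix(0, ks, C); db <- numeric(C)
  for (c in seq_len(C)) {
    dPool <- dOut[, (c - 1) * Lp + seq_len(Lp), drop = FALSE]
    dAct <- matrix(0, N, L)
    for (o in seq_len(pool)) {
      idx <- (seq_len(Lp) - 1) * pool + o
      sel <- cache$amax[[c]] == o
      tmp <- dPool; tmp[!sel] <- 0
      dAct[, idx] <- dAct[, idx] + tmp
    }
    dConv <- dAct * (cache$conv[[c]] > 0)
    for (t in seq_len(ks)) {
      dw[t, c] <- sum(dConv * xpad[, t:(t + L - 1), drop = FALSE])
    }
    db[c] <- sum(dConv)
  }
  list(grads = list(w = dw, b = db))
}

# ---------------------------------------------------------------------------
# dense (MLP) layer for the ablation head
# ---------------------------------------------------------------------------

mlp_layer_init <- function(p_in, p_out) {
  list(W = matrix(rnorm(p_out * p_in, sd = sqrt(2 / p_in)), p_out, p_in),
       bias = numeric(p_out), p_in = p_in, p_out = p_out)
}

mlp_layer_fwd <- function(layer, X, act, cache = FALSE) {
  Z <- X %*% t(layer$W) + matrix(layer$bias, nrow(X), layer$p_out, byrow = TRUE)
  out <- if (act) silu(Z) else Z
  if (!cache) return(out)
  list(out = out, X = X, Z = Z, act = act)
}

mlp_layer_bwd <- function(layer, cache, dOut) {
  dZ <- if (cache$act) dOut * dsilu(cache$Z) else dOut
  list(grads = list(W = crossprod(dZ, cache$X), bias = colSums(dZ)),
       dX = dZ %*% layer$W)
}

# ---------------------------------------------------------------------------
# network assembly / forward / backward
# ---------------------------------------------------------------------------

nn_init <- function(spec, input_len) {
  conv <- NULL
  feat <- input_len
  if (spec$conv_channels > 0) {
    conv <- list(w = matrix(rnorm(spec$kernel_size * spec$conv_channels,
                                  sd = sqrt(2 / spec$kernel_size)),
                            spec$kernel_size, spec$conv_channels),
                 b = numeric(spec$conv_channels))
    feat <- floor(input_len / spec$pool) * spec$conv_channels
  }
  widths <- c(feat, spec$kan_hidden, 1L)
  layers <- list()
  if (spec$head == "kan") {
    for (i in seq_len(length(widths) - 1))
      layers[[i]] <- kan_layer_init(widths[i], widths[i + 1],
                                    spec$grid_size, spec$spline_order)
  } else {
    # parameter-matched dense head: same per-layer budget as the KAN layers
    nb <- spec$grid_size + spec$spline_order
    kan_params <- sum((widths[-length(widths)] * widths[-1]) * (nb + 2))
    hid <- max(4L, round(kan_params / (feat + 2 * max(spec$kan_hidden, 1) + 2)))
    widths <- c(feat, hid, max(spec$kan_hidden, 4L), 1L)
    for (i in seq_len(length(widths) - 1))
      layers[[i]] <- mlp_layer_init(widths[i], widths[i + 1])
  }
  list(spec = spec, conv = conv, layers = layers, widths = widths)
}

nn_forward <- function(net, X, cache = FALSE) {
  caches <- list()
  H <- X
  if (!is.null(net$conv)) {
    cc <- conv_block_fwd(net$conv, H, net$spec$pool, cache)
    if (cache) { caches$conv <- cc; H <- cc$out } else H <- cc
  }
  for (i in seq_along(net$layers)) {
    if (net$spec$head == "kan") {
      lc <- kan_layer_fwd(net$layers[[i]], H, cache)
    } else {
      lc <- mlp_layer_fwd(net$layers[[i]], H, act = i < length(net$layers), cache)
    }
    if (cache) { caches[[paste0("l", i)]] <- lc; H <- lc$out } else H <- lc
  }
  if (cache) list(logit = H, caches = caches) else H
}

nn_backward <- function(net, fw, dLogit) {
  grads <- list(layers = vector("list", length(net$layers)))
  d <- dLogit
  for (i in rev(seq_along(net$layers))) {
    if (net$spec$head == "kan") {
      bw <- kan_layer_bwd(net$layers[[i]], fw$caches[[paste0("l", i)]], d)
    } else {
      bw <- mlp_layer_bwd(net$layers[[i]], fw$caches[[paste0("l", i)]], d)
    }
    grads$layers[[i]] <- bw$grads
    d <- bw$dX
  }
  if (!is.null(net$conv)) {
    grads$conv <- conv_block_bwd(net$conv, fw$caches$conv, d)$grads
  }
  grads
}

#' Number of trainable parameters of a fitted predictor
#' @param model a fitted predictor (or bare network)
#' @return integer parameter count
#' @export
n_params <- function(model) {
  net <- if (!is.null(model$net)) model$net else model
  cnt <- 0L
  if (!is.null(net$conv)) cnt <- cnt + length(net$conv$w) + length(net$conv$b)
  for (l in net$layers)
    cnt <- cnt + sum(vapply(l[names(l) %in% c("w1", "w2", "coef", "bias", "W")],
                            length, integer(1)))
  cnt
}

# Adam over the nested parameter list
adam_init <- function(net) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = list(conv = if (!is.null(net$conv)) zero_like(net$conv),
                layers = lapply(net$layers, function(l)
                  zero_like(l[names(l) %in% c("w1", "w2", "coef", "bias", "W")]))),
       v = list(conv = if (!is.null(net$conv)) zero_like(net$conv),
                layers = lapply(net$layers, function(l)
                  zero_like(l[names(l) %in% c("w1", "w2", "coef", "bias", "W")]))),
       t = 0L)
}

adam_update <- function(par, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m2 <- b1 * m + (1 - b1) * grad
  v2 <- b2 * v + (1 - b2) * grad^2
  mh <- m2 / (1 - b1^t)
  vh <- v2 / (1 - b2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
}

adam_step <- function(net, grads, st, lr) {
  st$t <- st$t + 1L
  if (!is.null(net$conv)) {
    for (nm in names(grads$conv)) {
      up <- adam_update(net$conv[[nm]], grads$conv[[nm]],
                        st$m$conv[[nm]], st$v$conv[[nm]], lr, st$t)
      net$conv[[nm]] <- up$par; st$m$conv[[nm]] <- up$m; st$v$conv[[nm]] <- up$v
    }
  }
  for (i in seq_along(net$layers)) {
    for (nm in names(st$m$layers[[i]])) {
      up <- adam_update(net$layers[[i]][[nm]], grads$layers[[i]][[nm]],
                        st$m$layers[[i]][[nm]], st$v$layers[[i]][[nm]], lr, st$t)
      net$layers[[i]][[nm]] <- up$par
      st$m$layers[[i]][[nm]] <- up$m; st$v$layers[[i]][[nm]] <- up$v
    }
  }
  list(net = net, st = st)
}

bce_loss <- function(z, y) {
  mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

#' Train the drug-response predictor
#'
#' Seeded mini-batch Adam minimizing binary cross-entropy (or squared error
#' for `loss = "mse"`, used e.g. for function-approximation checks).  Input
#' features are min-max scaled to \[-1, 1\] on the training set; the scaling
#' is stored with the model and applied at prediction time.
#'
#' @param X numeric matrix, samples x features (rows of the fused feature
#'   matrix)
#' @param y binary labels (factor with levels non_responsive/responsive, or
#'   0/1 numeric); for `loss = "mse"` a numeric target
#' @param spec a [predictor_spec()]
#' @param loss `"bce"` or `"mse"`
#' @return object of class `drp_predictor` with fields `net`, `history`
#'   (per-epoch training loss), `scale`, `spec`
#' @export
train_predictor <- function(X, y, spec = predictor_spec(), loss = c("bce", "mse")) {
  loss <- match.arg(loss)
  X <- as.matrix(X)
  if (is.factor(y)) y <- as.numeric(y == "responsive")
  y <- as.numeric(y)
  if (loss == "bce" && length(unique(y)) < 2)
    stop("both classes must be present in the training labels")
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rngc <- ifelse(hi > lo, hi - lo, 1)
  Xs <- sweep(sweep(X, 2, lo), 2, rngc, "/") * 2 - 1
  N <- nrow(Xs)

  with_seed(spec$seed, {
    net <- nn_init(spec, ncol(Xs))
    st <- adam_init(net)
    # validation split for early stopping
    use_val <- spec$patience > 0 && spec$val_fraction > 0 &&
      floor(N * spec$val_fraction) >= 4 && loss == "bce"
    if (use_val) {
      nv <- floor(N * spec$val_fraction)
      vidx <- sample(N, nv)
      tidx <- setdiff(seq_len(N), vidx)
      if (length(unique(y[tidx])) < 2) { use_val <- FALSE; tidx <- seq_len(N) }
    } else tidx <- seq_len(N)
    Xtr <- Xs[tidx, , drop = FALSE]; ytr <- y[tidx]
    history <- numeric(spec$epochs)
    best_val <- Inf; best_net <- net; wait <- 0L
    bs <- if (spec$batch_size <= 0) length(tidx) else min(spec$batch_size, length(tidx))
    for (ep in seq_len(spec$epochs)) {
      ord <- if (bs < length(tidx)) sample(length(tidx)) else seq_along(tidx)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, length(ord), by = bs)) {
        bidx <- ord[start:min(start + bs - 1, length(ord))]
        Xb <- Xtr[bidx, , drop = FALSE]; yb <- ytr[bidx]
        fw <- nn_forward(net, Xb, cache = TRUE)
        z <- drop(fw$logit)
        if (any(!is.finite(z))) stop("training diverged: non-finite logits at epoch ", ep)
        if (loss == "bce") {
          l <- bce_loss(z, yb)
          dz <- (1 / (1 + exp(-z)) - yb) / length(yb)
        } else {
          l <- mean((z - yb)^2)
          dz <- 2 * (z - yb) / length(yb)
        }
        grads <- nn_backward(net, fw, matrix(dz, ncol = 1))
        up <- adam_step(net, grads, st, spec$lr)
        net <- up$net; st <- up$st
        ep_loss <- ep_loss + l; nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (use_val) {
        zval <- drop(nn_forward(net, Xs[vidx, , drop = FALSE]))
        vl <- bce_loss(zval, y[vidx])
        if (vl < best_val - 1e-9) { best_val <- vl; best_net <- net; wait <- 0L }
        else {
          wait <- wait + 1L
          if (wait >= spec$patience) { history <- history[seq_len(ep)]; break }
        }
      }
    }
    if (use_val) net <- best_net
    structure(list(net = net, history = history,
                   scale = list(lo = lo, rng = rngc), spec = spec),
              class = "drp_predictor")
  })
}

#' @export
print.drp_predictor <- function(x, ...) {
  cat(sprintf("<drp_predictor: %s head, %d parameters, %d epoch(s)>\n",
              x$spec$head, n_params(x), length(x$history)))
  invisible(x)
}

#' Predict response probabilities and labels
#'
#' @param object a fitted [train_predictor()] model
#' @param newdata numeric matrix, samples x features (same feature space as
#'   training)
#' @param ... unused
#' @return data frame with `probability` (sigmoid of the logit) and `label`
#'   (`responsive` iff probability > 0.5)
#' @export
predict.drp_predictor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$scale$lo), 2, object$scale$rng, "/") * 2 - 1
  z <- drop(nn_forward(object$net, Xs))
  p <- 1 / (1 + exp(-z))
  data.frame(probability = p,
             label = factor(ifelse(p > 0.5, "responsive", "non_responsive"),
                            levels = c("non_responsive", "responsive")),
             row.names = rownames(newdata))
}

#' Classification metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy and F1 = 2PR/(P+R), with `responsive` as the positive class,
#' plus the per-class table and macro averages.  Undefined ratios (empty
#' denominators) are reported as 0.
#'
#' @param y_true,y_pred true and predicted labels (factors or characters
#'   with levels non_responsive/responsive)
#' @return list with `confusion`, `sensitivity`, `specificity`, `precision`,
#'   `accuracy`, `f1`, `per_class` (data frame), `macro_f1`
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  lv <- c("non_responsive", "responsive")
  y_true <- factor(as.character(y_true), levels = lv)
  y_pred <- factor(as.character(y_pred), levels = lv)
  cm <- table(truth = y_true, prediction = y_pred)
  safe <- function(num, den) if (den == 0) 0 else num / den
  per <- lapply(lv, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- safe(tp, tp + fp); rec <- safe(tp, tp + fn)
    data.frame(class = cl, precision = prec, recall = rec,
               f1 = safe(2 * prec * rec, prec + rec))
  })
  per <- do.call(rbind, per)
  tp <- cm["responsive", "responsive"]; tn <- cm["non_responsive", "non_responsive"]
  fp <- cm["non_responsive", "responsive"]; fn <- cm["responsive", "non_responsive"]
  list(confusion = cm,
       sensitivity = safe(tp, tp + fn),
       specificity = safe(tn, tn + fp),
       precision = safe(tp, tp + fp),
       accuracy = (tp + tn) / length(y_true),
       f1 = per$f1[per$class == "responsive"],
       per_class = per,
       macro_f1 = mean(per$f1))
}
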