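#' Parameters for semi-supervised weighted edge sparse PCA
#'
#' @param k number of pathway edges retained per principal component
#' @param omega oversampling fraction for the randomized edge selection
#'   (candidate pool has `ceiling((1 + omega) * k)` edges)
#' @param rho per-iteration decay of `omega`, floored at 0
#' @param n_pcs number of components to extract
#' @param tol convergence tolerance on the L2 norm of the loading update
#' @param max_iter iteration cap per component
#' @param seed RNG seed for the sampling and initialization
#' @param evaluator supervised importance model: `"rf"` (random forest),
#'   `"linear"` (per-probe absolute t statistics) or `"none"` (disables the
#'   supervision, recovering plain edge sparse PCA)
#' @param rf_trees number of trees for the random-forest evaluator
#' @param sqrt_edge_weights use `sqrt(u_i^2 + u_j^2)` instead of
#'   `u_i^2 + u_j^2` as the edge weight (the ranking is identical)
#' @param n_restarts random restarts of the alternating fit; the restart
#'   whose sample scores align best with the labels is kept (the variance
#'   objective decides when the evaluator is disabled).  The iteration is
#'   nonconvex and a single random start can lock onto a high-variance but
#'   label-independent component before any signal edge enters the sampled
#'   pool; restarts with supervised selection are the standard remedy.
#' @return a `selection_params` list
#' @export
selection_params <- function(k = 10, omega = 0.5, rho = 0.05, n_pcs = 1,
                             tol = 1e-4, max_iter = 100, seed = NULL,
                             evaluator = c("rf", "linear", "none"),
                             rf_trees = 200, sqrt_edge_weights = FALSE,
                             n_restarts = 8) {
  evaluator <- match.arg(evaluator)
  stopifnot(k >= 1, omega >= 0, rho >= 0, tol > 0, n_pcs >= 1, max_iter >= 1,
            n_restarts >= 1)
  structure(list(k = as.integer(k), omega = omega, rho = rho,
                 n_pcs = as.integer(n_pcs), tol = tol,
                 max_iter = as.integer(max_iter), seed = seed,
                 evaluator = evaluator, rf_trees = as.integer(rf_trees),
                 sqrt_edge_weights = sqrt_edge_weights,
                 n_restarts = as.integer(n_restarts)),
            class = "selection_params")
}

#' Edge weights from a loading vector
#'
#' The weight of edge (i, j) is `u_i^2 + u_j^2`; with
#' `sqrt = TRUE` the square root is returned (same ranking).
#'
#' @param u numeric loading vector (length = probes)
#' @param edges_idx integer matrix of probe index pairs, see [align_edges()]
#' @param sqrt take the square root of the sum
#' @return numeric vector of per-edge weights
#' @export
edge_weights <- function(u, edges_idx, sqrt = FALSE) {
  if (!all(is.finite(u))) stop("non-finite loading vector")
  w <- u[edges_idx[, 1]]^2 + u[edges_idx[, 2]]^2
  if (sqrt) base::sqrt(w) else w
}

#' Randomized greedy sparse projection onto edge groups
#'
#' Ranks the edges by weight (ties broken by lower edge index), forms the
#' candidate pool of the top `ceiling((1 + omega) * k)` edges, samples `k` of
#' them uniformly without replacement, and keeps the entries of `z` on the
#' union of sampled-edge vertices (zero elsewhere).  With `omega = 0` the
#' pool has exactly `k` edges and the projection is deterministic.
#'
#' @param z numeric vector to sparsify (length = probes)
#' @param edges_idx integer matrix of probe index pairs
#' @param weights per-edge weights, see [edge_weights()]
#' @param k number of edges to keep
#' @param omega oversampling fraction
#' @return list with `z` (sparsified vector), `edges` (sampled edge row
#'   indices) and `support` (probe indices kept)
#' @export
sparse_project <- function(z, edges_idx, weights, k, omega = 0) {
  l <- nrow(edges_idx)
  if (k > l) stop("k exceeds the number of edges")
  pool_size <- min(l, ceiling((1 + omega) * k))
  ord <- order(-weights, seq_len(l))    # ties: lower edge index first
  pool <- ord[seq_len(pool_size)]
  sampled <- if (pool_size == k) pool else sort(sample(pool, k))
  support <- sort(unique(as.vector(edges_idx[sampled, , drop = FALSE])))
  out <- numeric(length(z))
  out[support] <- z[support]
  list(z = out, edges = sort(sampled), support = support)
}

#' Supervised per-probe importance scores
#'
#' Fits the evaluator on the currently selected probes against the binary
#' response labels and returns importance scores min-max rescaled to
#' \[0, 2\].  Degenerate cases (single-class labels, constant importances)
#' fall back to all-ones scores with a warning, which makes the reweighting
#' step an identity.
#'
#' @param X_hat selected-probe submatrix, probes x samples
#' @param y binary labels (factor or 0/1), length = samples
#' @param evaluator `"rf"` or `"linear"`
#' @param rf_trees trees for the random forest
#' @param seed seed passed to the forest
#' @return numeric importance vector, one entry per row of `X_hat`
#' @export
evaluator_importance <- function(X_hat, y, evaluator = c("rf", "linear"),
                                 rf_trees = 200, seed = 1) {
  evaluator <- match.arg(evaluator)
  p <- nrow(X_hat)
  y <- factor(y)
  if (nlevels(y) < 2) {
    warning("single-class labels: importance fallback to all-ones")
    return(rep(1, p))
  }
  if (evaluator == "rf") {
    df <- as.data.frame(t(X_hat))
    colnames(df) <- paste0("p", seq_len(p))
    fit <- ranger::ranger(x = df, y = y, num.trees = rf_trees,
                          importance = "impurity", seed = seed,
                          num.threads = 1, verbose = FALSE)
    imp <- fit$variable.importance
  } else {
    yy <- as.numeric(y) - 1
    imp <- apply(X_hat, 1, function(r) {
      if (sd(r) == 0) return(0)
      abs(cor(r, yy)) * sqrt(length(yy))
    })
  }
  rng <- max(imp) - min(imp)
  if (!is.finite(rng) || rng == 0) {
    warning("constant importances: scaling undefined, fallback to all-ones")
    return(rep(1, p))
  }
  2 * (imp - min(imp)) / rng
}

#' Reweight a sparse loading by importance scores and renormalize
#'
#' @param u_hat sparse loading vector
#' @param t_scores importance per entry of `u_hat` (0 off support)
#' @return unit-norm reweighted loading
#' @export
reweight_and_normalize <- function(u_hat, t_scores) {
  stopifnot(length(u_hat) == length(t_scores))
  u <- u_hat * t_scores
  nrm <- sqrt(sum(u^2))
  if (nrm == 0) stop("loading vanished after importance reweighting")
  u / nrm
}

#' Update the sample-score vector
#'
#' `v = X'u / ||X'u||`.
#'
#' @param X data matrix, probes x samples
#' @param u unit loading vector
#' @return unit-norm sample score vector
#' @export
update_v <- function(X, u) {
  v <- drop(crossprod(X, u))
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("X'u is zero: cannot update sample scores")
  v / nrm
}

#' Fit one pathway-constrained sparse principal component
#'
#' Alternating iteration: `u <- Xv`, edge weighting, randomized greedy edge
#' projection (with `omega` decaying by `rho` per iteration, floored at 0),
#' supervised importance reweighting of the selected probes, renormalization
#' and sample-score update, until the loading change drops below `tol`.
#'
#' @param X data matrix, probes x samples (rows should be roughly centered)
#' @param y binary response labels (ignored when `evaluator = "none"`)
#' @param edges_idx integer matrix of probe index pairs, see [align_edges()]
#' @param params a [selection_params()] list
#' @return an object of class `sparse_loading`: fields `u`, `v`, `support`,
#'   `k_edges`, `iterations`, `converged`, `objective` (u'Xv trace) and
#'   `audit` (per-iteration sampled edges, omega, loss)
#' @export
fit_pc <- function(X, y, edges_idx, params = selection_params()) {
  base_seed <- if (is.null(params$seed)) sample.int(1e6, 1) else params$seed
  ybin <- if (params$evaluator == "none") NULL else as.numeric(factor(y)) - 1
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(params$n_restarts)) {
    p_r <- params
    p_r$seed <- base_seed + 7919L * (r - 1L)
    fit <- fit_pc_once(X, y, edges_idx, p_r)
    score <- if (is.null(ybin) || sd(ybin) == 0 || sd(fit$v) == 0) {
      fit$objective[fit$iterations]
    } else {
      abs(cor(fit$v, ybin))
    }
    if (score > best_score) { best <- fit; best_score <- score }
  }
  best$restart_score <- best_score
  best
}

fit_pc_once <- function(X, y, edges_idx, params) {
  m <- nrow(X); n <- ncol(X)
  k <- params$k
  if (ceiling((1 + params$omega) * k) > nrow(edges_idx) && k > nrow(edges_idx))
    stop("k exceeds the number of usable edges")
  with_seed(params$seed, {
    v <- rnorm(n)
    v <- v / sqrt(sum(v^2))
    u <- numeric(m)
    omega <- params$omega
    audit <- list()
    objective <- numeric(0)
    converged <- FALSE
    iterations <- 0L
    for (it in seq_len(params$max_iter)) {
      u_full <- drop(X %*% v)
      w <- edge_weights(u_full, edges_idx, sqrt = params$sqrt_edge_weights)
      proj <- sparse_project(u_full, edges_idx, w, k, omega)
      u_hat <- proj$z
      if (params$evaluator != "none") {
        t_sup <- evaluator_importance(
          X[proj$support, , drop = FALSE], y,
          evaluator = params$evaluator, rf_trees = params$rf_trees,
          seed = if (is.null(params$seed)) 1L else params$seed)
        t_full <- numeric(m)
        t_full[proj$support] <- t_sup
      } else {
        t_full <- as.numeric(seq_len(m) %in% proj$support)
      }
      u_new <- reweight_and_normalize(u_hat, t_full)
      v <- update_v(X, u_new)
      loss <- sqrt(sum((u - u_new)^2))
      audit[[it]] <- list(edges = proj$edges, omega = omega, loss = loss)
      objective[it] <- drop(crossprod(u_new, X %*% v))
      u <- u_new
      iterations <- it
      if (omega > 0) omega <- max(0, omega - params$rho)
      if (loss < params$tol) { converged <- TRUE; break }
    }
    structure(list(u = u, v = v, support = which(u != 0),
                   k_edges = k, iterations = iterations,
                   converged = converged, objective = objective,
                   audit = audit),
              class = "sparse_loading")
  })
}

#' @export
print.sparse_loading <- function(x, ...) {
  cat(sprintf("<sparse_loading: |support|=%d, %d iteration(s), converged=%s>\n",
              length(x$support), x$iterations, x$converged))
  invisible(x)
}

#' Fit several components with deflation and build the key matrix
#'
#' After each component the data matrix is deflated by Hotelling projection
#' (`X <- X - u (u'X)`) and the next component is fitted on the residual.
#' The key matrix contains the rows of the *original* matrix indexed by the
#' union of all component supports.
#'
#' @inheritParams fit_pc
#' @return list with `loadings` (list of `sparse_loading`), `support`
#'   (union, sorted probe indices) and `key_matrix` (original rows on the
#'   support union)
#' @export
fit_multi_pc <- function(X, y, edges_idx, params = selection_params()) {
  X0 <- X
  loadings <- list()
  for (pc in seq_len(params$n_pcs)) {
    if (sqrt(sum(X^2)) < 1e-12) {
      warning("deflated matrix numerically zero: stopping at ", pc - 1L, " component(s)")
      break
    }
    p_pc <- params
    if (!is.null(p_pc$seed)) p_pc$seed <- p_pc$seed + 1000L * (pc - 1L)
    fit <- fit_pc(X, y, edges_idx, p_pc)
    loadings[[pc]] <- fit
    X <- X - fit$u %*% crossprod(fit$u, X)
  }
  support <- sort(unique(unlist(lapply(loadings, `[[`, "support"))))
  list(loadings = loadings, support = support,
       key_matrix = X0[support, , drop = FALSE])
}
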