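#' Hartigan dip statistic
#'
#' Minimum over all unimodal CDFs of the sup-distance to the empirical CDF,
#' computed exactly by enumerating modal placements with hull-based
#' feasibility thresholds (see the methods vignette for the construction).
#' Samples larger than `max_points` are first reduced to a deterministic
#' random subsample (a subsample of iid draws is itself iid, so the
#' Monte-Carlo calibration in [dip_pvalue()] stays exact for the capped
#' statistic: its null is plain uniform samples of the capped size).
#'
#' @param x numeric sample, at least 4 values, not all equal
#' @param max_points subsampling cap (0 disables capping)
#' @return the dip statistic (between `1/(2n)` and `0.25` for distinct
#'   values, where `n` is the size after capping)
#' @export
dip_statistic <- function(x, max_points = 500) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("dip needs at least 4 finite values")
  if (max(x) == min(x)) stop("degenerate input: constant sample")
  cpp_dip(x, as.integer(max_points))$dip
}

dip_null_table <- function(n, n_boot, max_points, seed) {
  key <- paste(n, n_boot, max_points, if (is.null(seed)) "R" else seed, sep = "_")
  tab <- .drpfuse_cache[[key]]
  if (is.null(tab)) {
    tab <- with_seed(seed, cpp_dip_null(as.integer(n), as.integer(n_boot),
                                        as.integer(max_points)))
    .drpfuse_cache[[key]] <- tab
  }
  tab
}

#' Monte-Carlo p-value for the dip statistic
#'
#' Fraction of `n_boot` uniform(0, 1) samples of size `n` whose dip is at
#' least the observed one.  Null tables are memoised per
#' `(n, n_boot, max_points, seed)` within the session.
#'
#' @param dip observed dip statistic
#' @param n sample size the dip was computed from (before thinning)
#' @param n_boot bootstrap replicates (default 2000; below 100 a warning is
#'   issued)
#' @param seed seed for the null draws (`NULL`: current RNG stream, not
#'   memoised reproducibly)
#' @param max_points thinning cap, must match the one used for the observed
#'   dip
#' @return object of class `dip_result`: fields `dip`, `pvalue`, `n_boot`, `n`
#' @export
dip_pvalue <- function(dip, n, n_boot = 2000, seed = NULL, max_points = 500) {
  if (n_boot < 100) warning("n_boot below 100: p-value resolution is coarse")
  tab <- dip_null_table(n, n_boot, max_points, seed)
  structure(list(dip = dip, pvalue = mean(tab >= dip),
                 n_boot = as.integer(n_boot), n = as.integer(n)),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("<dip_result: dip=%.5f p=%.4f (n=%d, %d bootstraps)>\n",
              x$dip, x$pvalue, x$n, x$n_boot))
  invisible(x)
}

#' Dip test of unimodality
#'
#' @inheritParams dip_statistic
#' @inheritParams dip_pvalue
#' @return a `dip_result`, see [dip_pvalue()]
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL, max_points = 500) {
  d <- dip_statistic(x, max_points)
  dip_pvalue(d, length(x[is.finite(x)]), n_boot, seed, max_points)
}

#' Map raw scores linearly onto a range
#'
#' The normalization used for the fusion weights: the maximum raw score maps
#' to `b`, the minimum to `a`.  A degenerate spread (max = min) maps every
#' score to the midpoint with a warning.
#'
#' @param x raw scores
#' @param a,b target range, `a < b`
#' @return normalized scores in `[a, b]`
#' @export
normalize_range <- function(x, a = 0.5, b = 1.5) {
  if (a >= b) stop("config error: a must be < b")
  rng <- max(x) - min(x)
  if (rng == 0) {
    warning("identical raw scores: weights set to the range midpoint")
    return(rep((a + b) / 2, length(x)))
  }
  a + (b - a) / rng * (x - min(x))
}

sim_block_values <- function(s) {
  if (inherits(s, "similarity_matrix")) s$values else as.matrix(s)
}

#' Bimodality (dip) weights for similarity blocks
#'
#' For each block the dip test is applied to the vector of off-diagonal
#' upper-triangular entries of its similarity matrix.  The raw bimodality
#' score is the standardized dip (the Monte-Carlo z-score of the observed
#' dip against the uniform null): clearly bimodal blocks have empirical
#' p-values that all saturate at 0, so `1 - p` cannot rank them, while the
#' z-score carries the same evidence on a continuous scale.  Raw scores are
#' then normalized onto `[a, b]`; the Monte-Carlo p-values themselves are
#' reported in the attributes.
#'
#' @param sim_blocks list of `similarity_matrix` objects (or plain matrices)
#' @param n_boot dip bootstrap count
#' @param seed seed for the bootstrap null
#' @param a,b normalization range
#' @param max_points dip thinning cap
#' @return numeric weights, one per block, with attributes `dips` and
#'   `pvalues`
#' @export
alpha_weights <- function(sim_blocks, n_boot = 2000, seed = NULL,
                          a = 0.5, b = 1.5, max_points = 500) {
  raw <- dips <- pvs <- numeric(length(sim_blocks))
  for (i in seq_along(sim_blocks)) {
    v <- sim_block_values(sim_blocks[[i]])
    entries <- v[upper.tri(v)]
    if (length(entries) < 4) stop("fewer than 4 off-diagonal entries in block ", i)
    dt <- dip_test(entries, n_boot = n_boot, seed = seed, max_points = max_points)
    tab <- dip_null_table(dt$n, n_boot, max_points, seed)
    dips[i] <- dt$dip
    pvs[i] <- dt$pvalue
    raw[i] <- (dt$dip - mean(tab)) / max(sd(tab), 1e-12)
  }
  structure(normalize_range(raw, a, b), dips = dips, pvalues = pvs)
}

#' Variance weights for similarity blocks
#'
#' Per-block mean of the per-column sample variances (denominator `n - 1`),
#' normalized onto `[a, b]`.
#'
#' @inheritParams alpha_weights
#' @return numeric weights, one per block, with attribute `raw`
#' @export
beta_weights <- function(sim_blocks, a = 0.5, b = 1.5) {
  raw <- vapply(sim_blocks, function(s) {
    v <- sim_block_values(s)
    if (nrow(v) < 2) stop("single-row similarity block: variance undefined")
    mean(apply(v, 2, var))
  }, numeric(1))
  structure(normalize_range(raw, a, b), raw = raw)
}

#' Fuse similarity blocks into one feature matrix
#'
#' Entrywise weighted sum `X' = sum_i alpha_i * beta_i * block_i`.  All
#' blocks must share the anchor and query orderings.
#'
#' @param sim_blocks list of `similarity_matrix` objects (or matrices)
#' @param alpha,beta per-block weights, see [alpha_weights()] and
#'   [beta_weights()]
#' @return object of class `fused_features`: `values` (anchors x queries),
#'   `alpha`, `beta`, `anchors`, `queries`
#' @export
fuse <- function(sim_blocks, alpha, beta) {
  nb <- length(sim_blocks)
  stopifnot(length(alpha) == nb, length(beta) == nb, nb >= 1)
  ref <- sim_block_values(sim_blocks[[1]])
  anchors <- rownames(ref); queries <- colnames(ref)
  out <- matrix(0, nrow(ref), ncol(ref), dimnames = dimnames(ref))
  for (i in seq_len(nb)) {
    v <- sim_block_values(sim_blocks[[i]])
    if (!all(dim(v) == dim(ref)))
      stop("alignment error: block ", i, " has mismatching dimensions")
    if (!is.null(anchors) && !is.null(rownames(v)) && !identical(rownames(v), anchors))
      stop("alignment error: block ", i, " anchors differ")
    out <- out + alpha[i] * beta[i] * v
  }
  structure(list(values = out, alpha = as.numeric(alpha), beta = as.numeric(beta),
                 anchors = anchors, queries = queries),
            class = "fused_features")
}

#' @export
print.fused_features <- function(x, ...) {
  cat(sprintf("<fused_features: %d x %d, alpha=(%s), beta=(%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%.3f", x$alpha), collapse = ", "),
              paste(sprintf("%.3f", x$beta), collapse = ", ")))
  invisible(x)
}
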