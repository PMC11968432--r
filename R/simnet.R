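#' Similarity kernel for an omics label
#'
#' Expression and methylation blocks use Spearman rank correlation; copy
#' number uses Kendall's tau.  Blocks labelled `"other"` need an explicit
#' override.
#'
#' @param name omics label
#' @param override kernel name to force (`"spearman"` or `"kendall"`)
#' @return `"spearman"` or `"kendall"`
#' @export
kernel_for_omics <- function(name, override = NULL) {
  if (!is.null(override)) {
    return(match.arg(override, c("spearman", "kendall")))
  }
  switch(name,
         expression = "spearman",
         methylation = "spearman",
         copynumber = "kendall",
         stop("config error: no similarity kernel defined for omics '", name,
              "'; supply an override"))
}

new_similarity_matrix <- function(values, anchors, queries, kernel) {
  values[values > 1] <- 1
  values[values < -1] <- -1
  dimnames(values) <- list(anchors, queries)
  structure(list(values = values, anchors = anchors, queries = queries,
                 kernel = kernel),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix (%s): %d anchors x %d queries>\n",
              x$kernel, length(x$anchors), length(x$queries)))
  invisible(x)
}

sim_input <- function(block, anchors, queries) {
  vals <- if (inherits(block, "omics_block")) block$values else as.matrix(block)
  if (nrow(vals) < 2) stop("need at least 2 probes for sample similarity")
  if (is.null(anchors)) anchors <- colnames(vals)
  if (is.null(queries)) queries <- colnames(vals)
  if (!all(anchors %in% colnames(vals)) || !all(queries %in% colnames(vals)))
    stop("anchors/queries must be sample identifiers of the block")
  list(vals = vals, anchors = anchors, queries = queries)
}

warn_constant <- function(vals, ids) {
  const <- ids[apply(vals[, ids, drop = FALSE], 2, function(c) max(c) == min(c))]
  if (length(const))
    warning("constant sample vector(s), similarity set to 0: ",
            paste(head(const, 5), collapse = ", "))
}

#' Spearman sample-similarity matrix
#'
#' Entry (a, q) is the Spearman rank correlation between the probe vectors
#' of anchor sample a and query sample q.  Constant sample vectors produce a
#' similarity of 0 with a warning.
#'
#' @param block an [omics_block()] or plain probes x samples matrix
#' @param anchors,queries sample identifiers (default: all samples); keeping
#'   the anchors fixed to the training set prevents test-sample leakage into
#'   training features
#' @return a `similarity_matrix` (anchors x queries)
#' @export
spearman_similarity <- function(block, anchors = NULL, queries = NULL) {
  si <- sim_input(block, anchors, queries)
  warn_constant(si$vals, unique(c(si$anchors, si$queries)))
  v <- suppressWarnings(
    cor(si$vals[, si$anchors, drop = FALSE], si$vals[, si$queries, drop = FALSE],
        method = "spearman"))
  v[is.na(v)] <- 0
  new_similarity_matrix(v, si$anchors, si$queries, "spearman")
}

#' Kendall sample-similarity matrix
#'
#' Entry (a, q) is Kendall's tau between the probe vectors of the two
#' samples.  The default is tau-a, `(C - D) / (k(k-1)/2)` over the probe
#' pairs; `variant = "b"` applies the usual tie correction (identical when
#' there are no ties).
#'
#' @inheritParams spearman_similarity
#' @param variant `"a"` (default) or `"b"`
#' @return a `similarity_matrix` (anchors x queries)
#' @export
kendall_similarity <- function(block, anchors = NULL, queries = NULL,
                               variant = c("a", "b")) {
  variant <- match.arg(variant)
  si <- sim_input(block, anchors, queries)
  warn_constant(si$vals, unique(c(si$anchors, si$queries)))
  A <- si$vals[, si$anchors, drop = FALSE]
  Q <- si$vals[, si$queries, drop = FALSE]
  v <- suppressWarnings(cor(A, Q, method = "kendall"))  # tau-b
  if (variant == "a") {
    k <- nrow(si$vals)
    n0 <- k * (k - 1) / 2
    tie_pairs <- function(col) {
      t <- table(col)
      sum(t * (t - 1) / 2)
    }
    ta <- apply(A, 2, tie_pairs)
    tq <- apply(Q, 2, tie_pairs)
    # tau_b = (C-D)/sqrt((n0-t1)(n0-t2));  tau_a = (C-D)/n0
    scale <- sqrt(outer(n0 - ta, n0 - tq)) / n0
    v <- v * scale
  }
  v[is.na(v)] <- 0
  new_similarity_matrix(v, si$anchors, si$queries, "kendall")
}

#' Build the similarity matrix for an omics block
#'
#' Dispatches on the omics label via [kernel_for_omics()].
#'
#' @inheritParams spearman_similarity
#' @param override kernel override, see [kernel_for_omics()]
#' @param kendall_variant tau variant for copy-number blocks
#' @return a `similarity_matrix`
#' @export
omics_similarity <- function(block, anchors = NULL, queries = NULL,
                             override = NULL, kendall_variant = "a") {
  kern <- kernel_for_omics(if (inherits(block, "omics_block")) block$name else "other",
                           override)
  if (kern == "spearman") spearman_similarity(block, anchors, queries)
  else kendall_similarity(block, anchors, queries, variant = kendall_variant)
}

#' Write a similarity matrix to TSV
#' @param sim a `similarity_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_similarity <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# drpfuse-similarity v1 kernel=", sim$kernel), con)
  writeLines(paste(c("anchor_id", sim$queries), collapse = "\t"), con)
  body <- apply(sim$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE), collapse = "\t"))
  writeLines(paste(sim$anchors, body, sep = "\t"), con)
  invisible(path)
}
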