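#' Construct an omics block
#'
#' An omics block is one feature matrix of a multi-omics cohort, stored
#' probes x samples, together with its probe and sample identifiers and an
#' omics label that later selects the similarity kernel.
#'
#' @param values numeric matrix, probes x samples
#' @param name omics label: `"expression"`, `"copynumber"`, `"methylation"`
#'   or `"other"`
#' @param probe_ids character vector of row identifiers; defaults to
#'   `rownames(values)`
#' @param sample_ids character vector of column identifiers; defaults to
#'   `colnames(values)`
#' @return an object of class `omics_block` with fields `values`, `name`,
#'   `probe_ids`, `sample_ids`
#' @export
omics_block <- function(values, name, probe_ids = rownames(values),
                        sample_ids = colnames(values)) {
  name <- match.arg(name, c("expression", "copynumber", "methylation", "other"))
  values <- as.matrix(values)
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("omics block needs probe and sample identifiers")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || ncol(values) != length(sample_ids))
    stop("identifier lengths do not match the matrix dimensions")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe identifiers: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("omics block contains non-finite values after loading")
  if (nrow(values) < 2 || ncol(values) < 3)
    stop("an omics block needs at least 2 probes and 3 samples")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, name = name, probe_ids = probe_ids,
                 sample_ids = sample_ids),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block '%s': %d probes x %d samples>\n",
              x$name, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an omics block from a tab-separated file
#'
#' Expects a header row of sample identifiers and a first column of probe
#' identifiers; lines starting with `#` are ignored.  Probe rows with more
#' than `max_missing` missing entries are dropped; remaining missing entries
#' are imputed with the probe median.
#'
#' @param path TSV file path
#' @param name omics label, see [omics_block()]
#' @param max_missing maximum tolerated fraction of missing values per probe
#'   row (default 0.1)
#' @return an [omics_block()]
#' @export
read_omics_block <- function(path, name, max_missing = 0.1) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed omics TSV (need probe column + samples): ", path)
  probe_ids <- as.character(df[[1]])
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier in header of ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(probe_ids))
    stop("duplicate probe identifier in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    stop("non-numeric values in column '", sample_ids[bad[1]], "' of ", path)
  }
  miss <- rowMeans(is.na(mat))
  if (any(miss > max_missing)) {
    message(sum(miss > max_missing), " probe row(s) dropped (more than ",
            round(100 * max_missing), "% missing)")
    keep <- miss <= max_missing
    mat <- mat[keep, , drop = FALSE]
    probe_ids <- probe_ids[keep]
  }
  if (anyNA(mat)) {
    for (i in which(rowSums(is.na(mat)) > 0)) {
      mat[i, is.na(mat[i, ])] <- median(mat[i, ], na.rm = TRUE)
    }
  }
  omics_block(mat, name, probe_ids, sample_ids)
}

#' Write an omics block to a tab-separated file
#'
#' Emits a schema-version comment line followed by the matrix body; the
#' numeric body round-trips bit-exactly through [read_omics_block()].
#'
#' @param block an [omics_block()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_omics_block <- function(block, path) {
  stopifnot(inherits(block, "omics_block"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# drpfuse-omics v1", con)
  writeLines(paste(c("probe_id", block$sample_ids), collapse = "\t"), con)
  body <- apply(block$values, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(block$probe_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Construct a pathway edge set
#'
#' Unordered gene-gene pairs used as the structural prior for edge sparse
#' PCA.  Self-loops are discarded, duplicate edges (in either orientation)
#' collapsed.
#'
#' @param from,to character vectors of endpoint identifiers
#' @param weights optional nonnegative per-edge weights
#' @return an object of class `edge_set` with fields `from`, `to`, `weights`
#' @export
edge_set <- function(from, to, weights = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("from/to length mismatch")
  loops <- from == to
  if (any(loops)) {
    message(sum(loops), " self-loop edge(s) discarded")
    from <- from[!loops]; to <- to[!loops]
    if (!is.null(weights)) weights <- weights[!loops]
  }
  if (length(from) == 0) stop("edge set is empty")
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  if (!is.null(weights)) {
    if (length(weights) != length(key)) stop("weights not length-matched to edges")
    if (any(weights < 0)) stop("edge weights must be nonnegative")
    weights <- weights[keep]
  }
  structure(list(from = a[keep], to = b[keep], weights = weights),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set: %d edges over %d vertices>\n", length(x$from),
              length(unique(c(x$from, x$to)))))
  invisible(x)
}

#' @export
length.edge_set <- function(x) length(x$from)

#' Read a pathway edge list
#'
#' Two-column, tab-separated (SIF-like) file, one `geneA<TAB>geneB` pair per
#' line; `#` comment lines are skipped.
#'
#' @param path file path
#' @return an [edge_set()]
#' @export
read_edge_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) stop("empty edge file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed edge line ", which(bad)[1], " in ", path)
  edge_set(vapply(parts, `[[`, "", 1), vapply(parts, `[[`, "", 2))
}

#' Write an edge set
#' @param edges an [edge_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_edge_set <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# drpfuse-edges v1", con)
  writeLines(paste(edges$from, edges$to, sep = "\t"), con)
  invisible(path)
}

#' Resolve an edge set against a probe list
#'
#' Maps gene-level edges onto probe indices by exact identifier match; edges
#' with an endpoint absent from `probe_ids` are dropped with a warning.
#'
#' @param edges an [edge_set()]
#' @param probe_ids probe identifiers of the target omics block
#' @return integer matrix with columns `i`, `j` (probe indices, i < j)
#' @export
align_edges <- function(edges, probe_ids) {
  i <- match(edges$from, probe_ids)
  j <- match(edges$to, probe_ids)
  bad <- is.na(i) | is.na(j)
  if (any(bad))
    warning(sum(bad), " edge(s) dropped: endpoint not among probes")
  if (all(bad)) stop("no edge could be resolved against the probe list")
  cbind(i = i[!bad], j = j[!bad])
}

#' Read a per-sample IC50 table
#'
#' CSV with columns `sample_id` and `ic50`; `#` comment lines are skipped.
#'
#' @param path file path
#' @return named numeric vector of IC50 values
#' @export
read_ic50 <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "ic50") %in% colnames(df)))
    stop("IC50 table needs columns sample_id, ic50: ", path)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  stats::setNames(as.numeric(df$ic50), df$sample_id)
}

# ---------------------------------------------------------------------------
# run configuration
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' All tunable parameters of the pipeline with their defaults.  See the
#' methods vignette for the rationale behind each value.
#'
#' @return named list of parameters
#' @export
default_config <- function() {
  list(
    seed = 1L,
    min_samples = 200L,        # drug filter: minimum finite IC50 count
    strict_balance = FALSE,    # TRUE: skip drug instead of moving the cutoff
    k_edges = 10L,             # edges kept per principal component
    omega = 0.5,               # oversampling fraction for edge sampling
    rho = 0.05,                # per-iteration omega decay
    n_pcs = 1L,                # components per omics block
    tol = 1e-4,                # convergence tolerance on the loading update
    max_iter = 100L,
    evaluator = "rf",          # supervised importance model: rf | linear | none
    rf_trees = 200L,
    sqrt_edge_weights = FALSE, # use sqrt(u_i^2 + u_j^2) as edge weight
    kernel_override = NULL,    # similarity kernel override for 'other' blocks
    kendall_variant = "a",     # tau-a (tau-b behind the flag)
    fusion_a = 0.5,            # lower end of the weight normalization range
    fusion_b = 1.5,            # upper end
    n_boot = 2000L,            # dip bootstrap count
    dip_max_points = 500L,     # order-statistic thinning cap for the dip
    conv_channels = 2L,
    kernel_size = 5L,
    pool = 2L,
    kan_hidden = 8L,
    grid_size = 8L,
    spline_order = 3L,
    residual_act = "silu",     # residual activation b(x): silu | identity
    head = "kan",              # classifier head: kan | mlp (ablation)
    epochs = 300L,
    lr = 1e-3,
    batch_size = 0L,           # 0 = full batch
    patience = 20L,            # early stopping patience (0 disables)
    val_fraction = 0.15,
    cv_folds = 5L,
    cv_repeats = 1L,
    ablation = "none"          # none | no-weighting | no-conv | no-similarity | mlp-head
  )
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take their documented defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults
#' @return validated configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown))
        stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
      cfg <- modifyList(cfg, user)
    }
  }
  validate_config(cfg)
}

#' Validate a configuration list
#' @param cfg configuration list (see [default_config()])
#' @return the validated configuration, with integer-valued fields coerced
#' @export
validate_config <- function(cfg) {
  stop_if <- function(bad, msg) if (bad) stop("config error: ", msg)
  stop_if(cfg$omega < 0, "omega must be >= 0")
  stop_if(cfg$rho < 0, "rho must be >= 0")
  stop_if(cfg$fusion_a >= cfg$fusion_b, "a must be < b")
  stop_if(cfg$k_edges < 1, "k_edges must be >= 1")
  stop_if(cfg$tol <= 0, "tol must be > 0")
  stop_if(cfg$n_pcs < 1, "n_pcs must be >= 1")
  stop_if(cfg$min_samples < 4, "min_samples must be >= 4")
  stop_if(!cfg$evaluator %in% c("rf", "linear", "none"), "unknown evaluator")
  stop_if(cfg$kernel_size %% 2 == 0, "kernel_size must be odd")
  stop_if(cfg$spline_order < 1, "spline_order must be >= 1")
  stop_if(cfg$grid_size < cfg$spline_order + 1, "grid_size must be >= spline_order + 1")
  stop_if(!cfg$head %in% c("kan", "mlp"), "head must be kan or mlp")
  stop_if(!cfg$ablation %in% c("none", "no-weighting", "no-conv",
                               "no-similarity", "mlp-head"),
          "unknown ablation switch")
  stop_if(cfg$cv_folds < 2, "cv_folds must be >= 2")
  for (k in c("seed", "min_samples", "k_edges", "n_pcs", "max_iter", "rf_trees",
              "n_boot", "dip_max_points", "conv_channels", "kernel_size",
              "pool", "kan_hidden", "grid_size", "spline_order", "epochs",
              "batch_size", "patience", "cv_folds", "cv_repeats"))
    cfg[[k]] <- as.integer(cfg[[k]])
  cfg
}
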