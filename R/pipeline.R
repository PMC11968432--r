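#' Run the full drug-response pipeline with cross-validation
#'
#' Orchestrates waterfall labelling, per-omics semi-supervised edge sparse
#' PCA, similarity-network construction, dip/variance weighted fusion and
#' the Conv1D + KAN classifier under stratified k-fold cross-validation.
#' All anchor-dependent computations (probe selection, similarity anchors,
#' fusion weights, feature scaling) use the training fold only, so test
#' samples never influence training features.
#'
#' @param cohort cohort list as returned by [simulate_cohort()], or a list
#'   with elements `blocks` (named list of [omics_block()]), `edges`
#'   ([edge_set()]) and `ic50` (named numeric)
#' @param config configuration list; missing entries take the
#'   [default_config()] values
#' @return a `pipeline_report`: per-fold and mean metrics, fusion weights,
#'   selected probes per omics, the labels used, and the effective config
#' @export
run_pipeline <- function(cohort, config = list()) {
  cfg <- validate_config(modifyList(default_config(), config))
  ab <- cfg$ablation
  if (ab == "no-conv") cfg$conv_channels <- 0L
  if (ab == "mlp-head") cfg$head <- "mlp"

  labels <- waterfall_labels(cohort$ic50, min_samples = cfg$min_samples,
                             strict = cfg$strict_balance)
  ids <- labels$sample_id
  y <- stats::setNames(labels$label, ids)

  folds_all <- list()
  fold_metrics <- list()
  weights_log <- list()
  supports <- stats::setNames(vector("list", length(cohort$blocks)),
                              names(cohort$blocks))
  edges <- cohort$edges

  for (rep in seq_len(cfg$cv_repeats)) {
    folds <- stratified_folds(y, cfg$cv_folds, seed = cfg$seed + 131L * rep)
    folds_all[[rep]] <- folds
    for (f in seq_len(cfg$cv_folds)) {
      test_ids <- ids[folds == f]
      train_ids <- ids[folds != f]
      fit <- fit_fold(cohort, edges, y, train_ids, test_ids, cfg,
                      seed = cfg$seed + 1000L * rep + 10L * f)
      fold_metrics[[length(fold_metrics) + 1L]] <-
        c(list(repeat_ = rep, fold = f), fit$metrics)
      weights_log[[length(weights_log) + 1L]] <- fit$weights
      for (b in names(fit$supports))
        supports[[b]] <- union(supports[[b]], fit$supports[[b]])
    }
  }

  metric_names <- c("sensitivity", "specificity", "precision", "accuracy",
                    "f1", "macro_f1")
  mean_metrics <- vapply(metric_names, function(m)
    mean(vapply(fold_metrics, function(fm) fm[[m]], numeric(1))), numeric(1))

  structure(list(mean_metrics = as.list(mean_metrics),
                 fold_metrics = fold_metrics,
                 weights = weights_log,
                 selected_probes = supports,
                 labels = labels,
                 cutoff = attr(labels, "cutoff"),
                 label_method = attr(labels, "method"),
                 config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n  mean test metrics over",
      length(x$fold_metrics), "fold(s):\n")
  for (m in names(x$mean_metrics))
    cat(sprintf("    %-12s %.4f\n", m, x$mean_metrics[[m]]))
  invisible(x)
}

# stratified fold assignment, seeded; returns integer fold id per sample
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    out <- integer(length(y))
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      idx <- sample(idx)
      out[idx] <- rep_len(seq_len(k), length(idx))
    }
    out
  })
}

# one train/test fit: selection -> similarity -> fusion -> classifier
fit_fold <- function(cohort, edges, y, train_ids, test_ids, cfg, seed) {
  y_train <- y[train_ids]
  sel_params <- selection_params(
    k = cfg$k_edges, omega = cfg$omega, rho = cfg$rho, n_pcs = cfg$n_pcs,
    tol = cfg$tol, max_iter = cfg$max_iter, seed = seed,
    evaluator = cfg$evaluator, rf_trees = cfg$rf_trees,
    sqrt_edge_weights = cfg$sqrt_edge_weights)

  keys <- list()
  supports <- list()
  for (b in names(cohort$blocks)) {
    blk <- cohort$blocks[[b]]
    eidx <- suppressWarnings(align_edges(edges, blk$probe_ids))
    ctr <- rowMeans(blk$values[, train_ids, drop = FALSE])
    Xc <- blk$values - ctr
    fit <- fit_multi_pc(Xc[, train_ids, drop = FALSE], y_train, eidx, sel_params)
    supports[[b]] <- blk$probe_ids[fit$support]
    keys[[b]] <- list(values = Xc[fit$support, , drop = FALSE], name = blk$name)
  }

  if (cfg$ablation == "no-similarity") {
    feat_all <- do.call(cbind, lapply(keys, function(k) t(k$values)))
    feats_train <- feat_all[train_ids, , drop = FALSE]
    feats_test <- feat_all[test_ids, , drop = FALSE]
    weights <- list(alpha = NULL, beta = NULL)
  } else {
    sims_train <- list()
    sims_all <- list()
    for (b in names(keys)) {
      kb <- omics_block_like(keys[[b]])
      s <- omics_similarity(kb, anchors = train_ids,
                            queries = c(train_ids, test_ids),
                            override = cfg$kernel_override,
                            kendall_variant = cfg$kendall_variant)
      sims_all[[b]] <- s
      sims_train[[b]] <- s$values[, train_ids, drop = FALSE]
    }
    if (cfg$ablation == "no-weighting") {
      alpha <- rep(1, length(keys)); beta <- rep(1, length(keys))
    } else {
      alpha <- alpha_weights(sims_train, n_boot = cfg$n_boot, seed = cfg$seed,
                             a = cfg$fusion_a, b = cfg$fusion_b,
                             max_points = cfg$dip_max_points)
      beta <- beta_weights(sims_train, a = cfg$fusion_a, b = cfg$fusion_b)
    }
    fused <- fuse(sims_all, alpha, beta)
    feats_train <- t(fused$values[, train_ids, drop = FALSE])
    feats_test <- t(fused$values[, test_ids, drop = FALSE])
    weights <- list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                    dips = attr(alpha, "dips"), pvalues = attr(alpha, "pvalues"))
  }

  spec <- predictor_spec(
    conv_channels = cfg$conv_channels, kernel_size = cfg$kernel_size,
    pool = cfg$pool, kan_hidden = cfg$kan_hidden, grid_size = cfg$grid_size,
    spline_order = cfg$spline_order, residual_act = cfg$residual_act,
    head = cfg$head, epochs = cfg$epochs, lr = cfg$lr,
    batch_size = cfg$batch_size, patience = cfg$patience,
    val_fraction = cfg$val_fraction, seed = seed)
  model <- train_predictor(feats_train, y_train, spec)
  pred <- predict(model, feats_test)
  metrics <- evaluate_metrics(y[test_ids], pred$label)
  metrics$confusion <- NULL
  metrics$per_class <- NULL
  list(metrics = metrics, weights = weights, supports = supports,
       model = model)
}

omics_block_like <- function(k) {
  structure(list(values = k$values, name = k$name,
                 probe_ids = rownames(k$values),
                 sample_ids = colnames(k$values)),
            class = "omics_block")
}

#' Ablation experiment
#'
#' Runs the full pipeline and one ablated variant on identical folds and
#' seeds and reports both metric sets with their paired differences.
#' Switches are one at a time; combining two raises a configuration error.
#'
#' @param cohort see [run_pipeline()]
#' @param config base configuration (must not itself carry an ablation)
#' @param switch one of `"no-weighting"`, `"no-conv"`, `"no-similarity"`,
#'   `"mlp-head"`
#' @return list with `full`, `ablated` (pipeline reports) and `delta`
#'   (ablated minus full, per mean metric)
#' @export
ablate <- function(cohort, config = list(), switch) {
  switch <- match.arg(switch, c("no-weighting", "no-conv", "no-similarity",
                                "mlp-head"))
  base_ab <- if (is.null(config$ablation)) "none" else config$ablation
  if (base_ab != "none")
    stop("config error: ablation switches are one at a time (config already sets '",
         base_ab, "')")
  full <- run_pipeline(cohort, config)
  config$ablation <- switch
  ablated <- run_pipeline(cohort, config)
  delta <- Map(function(a, b) a - b, ablated$mean_metrics, full$mean_metrics)
  list(full = full, ablated = ablated, delta = delta)
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `pipeline_report`
#' @param path output path (`NULL` returns the JSON string)
#' @return the path, or the JSON string when `path` is `NULL`
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(
    mean_metrics = report$mean_metrics,
    fold_metrics = report$fold_metrics,
    weights = report$weights,
    selected_probes = report$selected_probes,
    cutoff = report$cutoff,
    label_method = report$label_method,
    config = report$config[!vapply(report$config, is.null, logical(1))])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
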