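#' Specification of a synthetic multi-omics cohort
#'
#' The generator emulates the data shape the pipeline targets: three omics
#' blocks of unequal width over a shared gene namespace, a pathway edge list
#' with planted signal edges, a latent drug-sensitivity factor that shifts
#' the signal genes and lowers IC50, a label-independent high-variance decoy
#' component, and one omics block whose values separate the cohort into two
#' clusters (bimodal similarity entries).  See the methods vignette for what
#' the generator does and does not emulate.
#'
#' @param n_samples cohort size
#' @param m_expr,m_cnv,m_meth probe counts of the three blocks
#' @param n_genes genes in the pathway namespace (probes are gene-named)
#' @param n_edges random background pathway edges
#' @param planted_edges number of signal edges (disjoint gene pairs)
#' @param effect signal effect size (latent-factor loading scale)
#' @param decoy_edges decoy edges whose genes carry a label-independent
#'   variance factor
#' @param decoy_effect decoy factor loading scale
#' @param bimodal_sep cluster separation of the designated bimodal block
#' @param noise_sd per-block measurement noise (named: expr, cnv, meth)
#' @param bimodal_block which omics gets the cluster-separated signal
#' @param ic50_base,ic50_coef,ic50_sd,ic50_frac IC50 model: samples with
#'   latent factor above `z0 = qnorm(1 - ic50_frac)` are responders whose
#'   sensitivity `(pnorm(z) - pnorm(z0)) / ic50_frac` is uniform on (0, 1);
#'   `ic50 = base - coef * sensitivity + noise`.  This yields a resistant
#'   plateau (samples unaffected at the maximum tested dose) joined to a
#'   rank-linear responsive tail — a waterfall curve with a sharp elbow at
#'   the plateau junction
#' @param seed RNG seed; identical seeds give bit-identical cohorts
#' @return a `sim_spec` list
#' @export
sim_spec <- function(n_samples = 120, m_expr = 300, m_cnv = 200, m_meth = 250,
                     n_genes = 300, n_edges = 200, planted_edges = 10,
                     effect = 1.5, decoy_edges = 10, decoy_effect = 1.8,
                     bimodal_sep = 1.6,
                     noise_sd = c(expr = 1, cnv = 1, meth = 1),
                     bimodal_block = "methylation",
                     ic50_base = 5, ic50_coef = 6, ic50_sd = 0.2,
                     ic50_frac = 0.5,
                     seed = 1) {
  stopifnot(n_samples >= 10, planted_edges >= 1,
            2 * (planted_edges + decoy_edges) <= min(m_expr, m_cnv, m_meth),
            all(noise_sd > 0))
  if (2 * (planted_edges + decoy_edges) > n_genes)
    stop("spec error: more planted genes than available genes")
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate a multi-omics cohort with planted pathway signal
#'
#' @param spec a [sim_spec()]
#' @return list with `blocks` (named list of [omics_block()]), `edges`
#'   ([edge_set()]), `ic50` (named vector) and `truth` (signal/decoy gene
#'   sets, per-block signal probes, latent factor `z`, cluster `c`,
#'   ground-truth labels)
#' @export
simulate_cohort <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    genes <- sprintf("g%03d", seq_len(spec$n_genes))
    samples <- sprintf("s%03d", seq_len(spec$n_samples))
    n <- spec$n_samples

    # signal and decoy genes drawn from the low indices so that every block
    # (blocks carry prefixes of the gene list) contains them
    n_sig <- 2L * spec$planted_edges
    n_dec <- 2L * spec$decoy_edges
    low <- sample(seq_len(min(spec$m_expr, spec$m_cnv, spec$m_meth)), n_sig + n_dec)
    sig_genes <- genes[low[seq_len(n_sig)]]
    dec_genes <- if (n_dec > 0) genes[low[n_sig + seq_len(n_dec)]] else character(0)
    planted <- cbind(sig_genes[seq(1, n_sig, 2)], sig_genes[seq(2, n_sig, 2)])
    decoy <- if (n_dec > 0) cbind(dec_genes[seq(1, n_dec, 2)], dec_genes[seq(2, n_dec, 2)])
             else NULL

    # background pathway edges
    bg_from <- sample(genes, 4 * spec$n_edges, replace = TRUE)
    bg_to <- sample(genes, 4 * spec$n_edges, replace = TRUE)
    ok <- bg_from != bg_to
    bg <- unique(cbind(pmin(bg_from[ok], bg_to[ok]), pmax(bg_from[ok], bg_to[ok])))
    bg <- bg[seq_len(min(spec$n_edges, nrow(bg))), , drop = FALSE]
    all_edges <- rbind(planted, decoy, bg)
    edges <- edge_set(all_edges[, 1], all_edges[, 2])

    # latent sensitivity factor and responder-cluster indicator
    z <- rnorm(n)
    z0 <- qnorm(1 - spec$ic50_frac)
    cl <- as.integer(z > z0)

    make_block <- function(m, name, noise, signal_scale, decoy_scale, bimodal) {
      gsub <- genes[seq_len(m)]
      X <- matrix(rnorm(m * n, sd = noise), m, n, dimnames = list(gsub, samples))
      sidx <- match(sig_genes, gsub)
      sidx <- sidx[!is.na(sidx)]
      if (length(sidx)) {
        # signed loadings: each signal gene shifts up or down with the factor
        load <- runif(length(sidx), 0.8, 1.2) * signal_scale *
                sample(c(-1, 1), length(sidx), replace = TRUE)
        if (bimodal) {
          X[sidx, ] <- X[sidx, ] + outer(load, (cl - 0.5) * 2 * spec$bimodal_sep)
        } else {
          X[sidx, ] <- X[sidx, ] + outer(load, z)
        }
      }
      didx <- match(dec_genes, gsub)
      didx <- didx[!is.na(didx)]
      if (length(didx) && decoy_scale > 0) {
        w <- rnorm(n)
        dload <- runif(length(didx), 0.8, 1.2) * decoy_scale *
                 sample(c(-1, 1), length(didx), replace = TRUE)
        X[didx, ] <- X[didx, ] + outer(dload, w)
      }
      omics_block(X, name, gsub, samples)
    }

    bim <- spec$bimodal_block
    blocks <- list(
      expression = make_block(spec$m_expr, "expression", spec$noise_sd[["expr"]],
                              spec$effect, spec$decoy_effect, bim == "expression"),
      copynumber = make_block(spec$m_cnv, "copynumber", spec$noise_sd[["cnv"]],
                              0.6 * spec$effect, 0.6 * spec$decoy_effect,
                              bim == "copynumber"),
      methylation = make_block(spec$m_meth, "methylation", spec$noise_sd[["meth"]],
                               spec$effect, 0.6 * spec$decoy_effect,
                               bim == "methylation"))

    sens <- pmax(stats::pnorm(z) - (1 - spec$ic50_frac), 0) / spec$ic50_frac
    ic50 <- spec$ic50_base - spec$ic50_coef * sens +
            rnorm(n, sd = spec$ic50_sd)
    names(ic50) <- samples

    truth <- list(
      signal_genes = sig_genes,
      decoy_genes = dec_genes,
      planted_edges = planted,
      signal_probes = lapply(blocks, function(b) intersect(sig_genes, b$probe_ids)),
      z = stats::setNames(z, samples),
      z0 = z0,
      cluster = stats::setNames(cl, samples),
      label = stats::setNames(
        factor(ifelse(z > z0, "responsive", "non_responsive"),
               levels = c("non_responsive", "responsive")), samples))
    list(blocks = blocks, edges = edges, ic50 = ic50, truth = truth, spec = spec)
  })
}

#' Support-recovery score
#'
#' Set-overlap metrics between the probes selected by the sparse PCA stage
#' and the planted signal probes.
#'
#' @param selected character vector of selected probe identifiers
#' @param truth character vector of planted probe identifiers
#' @return list with `jaccard`, `precision`, `recall`
#' @export
recovery_score <- function(selected, truth) {
  selected <- unique(as.character(selected))
  truth <- unique(as.character(truth))
  inter <- length(intersect(selected, truth))
  uni <- length(union(selected, truth))
  list(jaccard = if (uni == 0) NA_real_ else inter / uni,
       precision = if (length(selected) == 0) 0 else inter / length(selected),
       recall = if (length(truth) == 0) NA_real_ else inter / length(truth))
}

#' Write a simulated cohort to disk
#'
#' Emits the same TSV/SIF/CSV formats the pipeline readers consume.
#'
#' @param cohort a [simulate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$blocks))
    write_omics_block(cohort$blocks[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_edge_set(cohort$edges, file.path(dir, "pathways.sif"))
  con <- file(file.path(dir, "ic50.csv"), "w")
  writeLines("# drpfuse-ic50 v1", con)
  writeLines("sample_id,ic50", con)
  writeLines(paste(names(cohort$ic50), format(cohort$ic50, digits = 17),
                   sep = ","), con)
  close(con)
  invisible(dir)
}
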