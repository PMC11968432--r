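# shared fixtures, built in code at test time

write_tiny_omics <- function(path, body = NULL, samples = c("s1", "s2", "s3", "s4"),
                             probes = c("pA", "pB", "pC")) {
  if (is.null(body)) {
    set.seed(401)
    body <- matrix(round(rnorm(length(probes) * length(samples)), 4),
                   length(probes), length(samples))
  }
  lines <- c(paste(c("probe_id", samples), collapse = "\t"),
             vapply(seq_along(probes), function(i)
               paste(c(probes[i], body[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(body)
}

# small memoised cohort for the slower integration-style unit tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_spec(
        n_samples = 60, m_expr = 120, m_cnv = 100, m_meth = 110,
        n_genes = 120, n_edges = 80, planted_edges = 6, decoy_edges = 6,
        seed = 301))
    }
    cache
  }
})

# independent de Boor evaluation of one B-spline basis function, used as the
# textbook oracle for the packaged basis
deboor_basis <- function(x, i, k, knots) {
  if (k == 0) {
    last <- i + 1 == length(knots)
    return(as.numeric(x >= knots[i] & (x < knots[i + 1] | (last & x == knots[i + 1]))))
  }
  a <- (x - knots[i]) / (knots[i + k] - knots[i])
  b <- (knots[i + k + 1] - x) / (knots[i + k + 1] - knots[i + 1])
  a * deboor_basis(x, i, k - 1, knots) + b * deboor_basis(x, i + 1, k - 1, knots)
}

# exhaustive perpendicular-distance scan for the waterfall elbow
elbow_scan <- function(sorted_ic50, distance = "perpendicular") {
  n <- length(sorted_ic50)
  dx <- n - 1; dy <- sorted_ic50[n] - sorted_ic50[1]
  dev <- abs(dy * (seq_len(n) - 1) - dx * (sorted_ic50 - sorted_ic50[1]))
  dev <- if (distance == "perpendicular") dev / sqrt(dx^2 + dy^2) else dev / dx
  which.max(dev)
}
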