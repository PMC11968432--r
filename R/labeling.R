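#' Filter a drug's IC50 vector
#'
#' Removes missing entries and enforces the minimum sample count below which
#' the drug is skipped.
#'
#' @param ic50 named numeric vector of per-sample IC50 values
#' @param min_samples minimum number of finite values (default 200; lower it
#'   for small synthetic cohorts)
#' @return the finite subvector
#' @export
filter_drug <- function(ic50, min_samples = 200) {
  x <- ic50[is.finite(ic50)]
  if (length(x) < min_samples) {
    cond <- structure(
      class = c("drpfuse_drug_skipped", "error", "condition"),
      list(message = sprintf("drug skipped: %d finite IC50 values < minimum %d",
                             length(x), min_samples),
           call = sys.call(-1)))
    stop(cond)
  }
  x
}

#' Waterfall cutoff for IC50 binarization
#'
#' Sorts the IC50 values and fits a line to the sorted curve against its
#' ranks.  If the Pearson correlation exceeds 0.95 the curve is considered
#' linear and the cutoff is the median; otherwise the cutoff is placed at the
#' sorted point furthest from the chord through the extreme points (the elbow
#' of the waterfall).
#'
#' @param ic50 numeric vector, at least 4 finite values
#' @param r_threshold linearity threshold on the Pearson fit (default 0.95)
#' @param distance `"perpendicular"` (default) or `"vertical"` distance to
#'   the chord for the elbow search
#' @return an object of class `waterfall_fit` with fields `pearson_r`,
#'   `cutoff`, `method` (`"median"` or `"furthest-point"`)
#' @export
waterfall_cutoff <- function(ic50, r_threshold = 0.95,
                             distance = c("perpendicular", "vertical")) {
  distance <- match.arg(distance)
  x <- ic50[is.finite(ic50)]
  if (length(x) < 4) stop("need at least 4 finite IC50 values")
  if (max(x) == min(x)) stop("degenerate input: constant IC50 vector")
  s <- sort(x)
  n <- length(s)
  r <- cor(s, seq_len(n))
  if (r > r_threshold) {
    fit <- list(pearson_r = r, cutoff = median(s), method = "median")
  } else {
    # chord through (1, min) and (n, max)
    dx <- n - 1
    dy <- s[n] - s[1]
    # signed area-based distance of each sorted point from the chord
    dev <- abs(dy * (seq_len(n) - 1) - dx * (s - s[1]))
    if (distance == "perpendicular") dev <- dev / sqrt(dx^2 + dy^2) else dev <- dev / dx
    idx <- which.max(dev)
    fit <- list(pearson_r = r, cutoff = s[idx], method = "furthest-point")
  }
  structure(fit, class = "waterfall_fit")
}

#' @export
print.waterfall_fit <- function(x, ...) {
  cat(sprintf("<waterfall_fit: method=%s cutoff=%.4g pearson_r=%.4f>\n",
              x$method, x$cutoff, x$pearson_r))
  invisible(x)
}

#' Assign responsive / non-responsive labels
#'
#' Samples with IC50 at or below the cutoff are labelled responsive (lower
#' IC50 = more sensitive).  If the responsive fraction falls below
#' `min_fraction`, the cutoff is raised to the corresponding lower quantile
#' so that the balance constraint holds (all samples are kept).
#'
#' @param ic50 named numeric vector of finite IC50 values
#' @param fit a [waterfall_cutoff()] result
#' @param min_fraction minimum responsive fraction (default 0.25)
#' @return an object of class `response_labels`: data frame with columns
#'   `sample_id`, `ic50`, `label`, plus attributes `cutoff` and `method`
#' @export
assign_labels <- function(ic50, fit, min_fraction = 0.25) {
  stopifnot(inherits(fit, "waterfall_fit"))
  x <- ic50[is.finite(ic50)]
  cutoff <- fit$cutoff
  method <- fit$method
  n <- length(x)
  if (mean(x <= cutoff) < min_fraction) {
    s <- sort(x)
    cutoff <- s[ceiling(min_fraction * n)]  # order statistic: fraction >= min_fraction
    method <- paste0(method, "+balance")
  }
  lab <- factor(ifelse(x <= cutoff, "responsive", "non_responsive"),
                levels = c("non_responsive", "responsive"))
  if (all(lab == "responsive"))
    warning("all samples labelled responsive (cutoff above the IC50 range)")
  out <- data.frame(sample_id = if (is.null(names(x))) as.character(seq_along(x)) else names(x),
                    ic50 = unname(x), label = lab, stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff, method = method, class = c("response_labels", "data.frame"))
}

#' One-call waterfall labelling
#'
#' Convenience wrapper: filter, fit the waterfall cutoff and assign labels.
#'
#' @inheritParams filter_drug
#' @inheritParams assign_labels
#' @param strict if `TRUE`, a drug whose responsive fraction is below
#'   `min_fraction` is skipped instead of having its cutoff moved
#' @return a `response_labels` object, see [assign_labels()]
#' @export
waterfall_labels <- function(ic50, min_samples = 200, min_fraction = 0.25,
                             strict = FALSE) {
  x <- filter_drug(ic50, min_samples)
  fit <- waterfall_cutoff(x)
  if (strict && mean(x <= fit$cutoff) < min_fraction) {
    cond <- structure(
      class = c("drpfuse_drug_skipped", "error", "condition"),
      list(message = "drug skipped: responsive fraction below minimum (strict mode)",
           call = sys.call()))
    stop(cond)
  }
  assign_labels(x, fit, min_fraction)
}

#' Write response labels to CSV
#' @param labels a `response_labels` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_response_labels <- function(labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# drpfuse-labels v1", con)
  df <- as.data.frame(labels)
  df$cutoff <- attr(labels, "cutoff")
  df$method <- attr(labels, "method")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
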