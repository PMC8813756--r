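# Non-variable CpG filtering, principal-component extraction, PC1 outlier
# exclusion, and the sample-sample correlation screen.

#' Identify non-variable CpGs across one or more cohorts
#'
#' A CpG is non-variable when the range between its 10th and 90th
#' percentile of beta values (linear-interpolation quantiles) is below
#' `threshold` in every supplied matrix; it is retained as variable as
#' soon as a single cohort shows at least that much spread. Only CpGs
#' present in all matrices are classified.
#'
#' @param betas_list A beta matrix or list of beta matrices (CpG x sample)
#'   with CpG row names.
#' @param threshold Range threshold on the beta scale; default 0.05.
#' @return Object of class `filter_report` with `nonvariable_ids`,
#'   `variable_ids`, `ranges` (CpG x cohort matrix of percentile ranges),
#'   `threshold`.
#' @export
nonvariable_cpgs <- function(betas_list, threshold = 0.05) {
  if (is.matrix(betas_list)) betas_list <- list(betas_list)
  stopifnot(length(betas_list) >= 1)
  ids <- Reduce(intersect, lapply(betas_list, rownames))
  if (length(ids) == 0) stop("no CpG ids shared by all matrices")
  for (i in seq_along(betas_list))
    if (ncol(betas_list[[i]]) < 10)
      warning("matrix ", i, " has fewer than 10 samples; ",
              "percentile ranges may be unstable")
  ranges <- vapply(betas_list, function(B) {
    q <- apply(B[ids, , drop = FALSE], 1, stats::quantile,
               probs = c(0.1, 0.9), names = FALSE, type = 7)
    q[2, ] - q[1, ]
  }, numeric(length(ids)))
  ranges <- matrix(ranges, nrow = length(ids),
                   dimnames = list(ids, names(betas_list)))
  nonvar <- rowSums(ranges < threshold) == ncol(ranges)
  structure(list(nonvariable_ids = ids[nonvar],
                 variable_ids = ids[!nonvar],
                 ranges = ranges, threshold = threshold),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CpG variability filter (10th-90th percentile range < ",
      x$threshold, ")\n  non-variable: ", length(x$nonvariable_ids),
      "  variable: ", length(x$variable_ids), "\n", sep = "")
  invisible(x)
}

#' Remove deconvolution marker CpGs from a beta matrix
#'
#' Marker CpGs used to estimate cell composition are excluded from
#' variance analyses to prevent circular conclusions.
#'
#' @param betas CpG x sample matrix with row names.
#' @param marker_ids CpG ids to drop.
#' @param verbose Log the number of removed rows.
#' @return The beta matrix without marker rows.
#' @export
exclude_reference_cpgs <- function(betas, marker_ids, verbose = FALSE) {
  drop <- rownames(betas) %in% marker_ids
  if (all(drop)) stop("all CpGs are reference markers; nothing remains")
  if (verbose) message("excluded ", sum(drop), " marker CpG(s)")
  betas[!drop, , drop = FALSE]
}

#' Principal components of a beta matrix
#'
#' Row-centres the matrix (per-CpG mean), performs a singular value
#' decomposition, and returns per-sample scores (right singular vectors
#' scaled by the singular values). Each component's sign is fixed so that
#' its scores correlate non-negatively with the per-sample mean beta value
#' (falling back to a positive first loading when that correlation is
#' degenerate), making PC1 reproducible across runs.
#'
#' @param betas CpG x sample matrix, no missing values.
#' @param n_components Number of components to return.
#' @return Object of class `pc_result` with `scores` (sample x component),
#'   `variance_explained`, `center` (per-CpG means), `loadings`.
#' @export
first_pcs <- function(betas, n_components = 2) {
  if (any(!is.finite(betas))) stop("missing or non-finite beta values")
  X <- as.matrix(betas) - rowMeans(betas)
  sv <- svd(X)
  tot <- sum(sv$d^2)
  if (tot < .Machine$double.eps)
    stop("degenerate input: beta matrix has zero variance")
  n_components <- min(n_components, length(sv$d))
  ve <- sv$d^2 / tot
  scores <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2,
                  sv$d[seq_len(n_components)], `*`)
  loadings <- sv$u[, seq_len(n_components), drop = FALSE]
  msamp <- colMeans(betas)
  for (j in seq_len(n_components)) {
    r <- suppressWarnings(stats::cor(scores[, j], msamp))
    flip <- if (is.na(r) || abs(r) < .Machine$double.eps)
      loadings[1, j] < 0 else r < 0
    if (flip) {
      scores[, j] <- -scores[, j]
      loadings[, j] <- -loadings[, j]
    }
  }
  dimnames(scores) <- list(colnames(betas),
                           paste0("PC", seq_len(n_components)))
  structure(list(scores = scores,
                 variance_explained = ve[seq_len(n_components)],
                 center = rowMeans(betas), loadings = loadings),
            class = "pc_result")
}

#' Flag PC1 outliers by quartile fences
#'
#' A sample is an outlier when its score lies strictly below
#' `Q1 - 3 IQR` or strictly above `Q3 + 3 IQR`, with quartiles computed by
#' linear interpolation.
#'
#' @param scores Named numeric vector of PC scores (typically PC1).
#' @param k Fence multiplier; default 3.
#' @return Character vector (or integer indices when unnamed) of flagged
#'   samples.
#' @export
pc1_outliers <- function(scores, k = 3) {
  if (length(scores) < 8)
    warning("fewer than 8 samples; quartile fences are unstable")
  q <- stats::quantile(scores, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  out <- scores < q[1] - k * iqr | scores > q[2] + k * iqr
  if (is.null(names(scores))) which(out) else names(scores)[out]
}

#' Average sample-sample Spearman correlation
#'
#' For each sample, the mean Spearman correlation of its beta vector with
#' every other sample's; unusually dissimilar samples stand out with low
#' values.
#'
#' @param betas CpG x sample matrix.
#' @return Named numeric vector, one mean correlation per sample.
#' @export
sample_correlation_screen <- function(betas) {
  n <- ncol(betas)
  stopifnot(n >= 2)
  cc <- stats::cor(as.matrix(betas), method = "spearman")
  stats::setNames((colSums(cc) - 1) / (n - 1), colnames(betas))
}
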