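# Reference-based cell-type deconvolution of bulk beta values.
#
# Two estimators over the same contract (non-negative proportions summing
# to 1 at marker CpGs):
#   * rpc  — robust partial correlation: iteratively reweighted robust
#            regression (Huber weights, c = 1.345, MAD scale) of the
#            sample's marker betas on the reference columns, no intercept,
#            negative coefficients truncated to 0, remainder rescaled.
#   * nnls — non-negative least squares followed by sum-to-one
#            normalisation, the non-robust limit of rpc.

# Ordinary least squares via QR; shared fallback and noise-free short-cut.
.ols_coef <- function(X, y) {
  qr.coef(qr(X), y)
}

#' Robust partial correlation deconvolution of one sample
#'
#' Fits the sample's marker-CpG beta vector on the reference profiles by
#' iteratively reweighted least squares with Huber weights (tuning constant
#' 1.345 on the MAD scale, up to 50 iterations), without an intercept.
#' Negative coefficients are truncated to zero and the remainder is rescaled
#' to sum to one. Missing marker values are dropped; if fewer than half of
#' the markers remain the sample is rejected.
#'
#' @param beta_at_markers Numeric vector of beta values aligned to the
#'   reference rows (names checked when present).
#' @param reference Marker CpG x cell type matrix of beta values.
#' @param maxit Maximum IRLS iterations.
#' @return Named proportion vector over the reference cell types.
#' @export
rpc_deconvolve_sample <- function(beta_at_markers, reference, maxit = 50) {
  y <- .align_marker_vector(beta_at_markers, reference)
  X <- attr(y, "reference")
  coefs <- tryCatch({
    ols <- .ols_coef(X, y)
    res <- y - X %*% ols
    if (sqrt(mean(res^2)) < 1e-8) {
      # (near-)noise-free: robust and ordinary fits coincide; the MAD scale
      # would collapse to zero, so use the exact least-squares solution
      as.vector(ols)
    } else {
      fit <- MASS::rlm(X, y, psi = MASS::psi.huber, k = 1.345,
                       maxit = maxit)
      as.vector(stats::coef(fit))
    }
  }, error = function(e) {
    warning("robust fit failed (", conditionMessage(e),
            "); falling back to ordinary least squares")
    as.vector(.ols_coef(X, y))
  })
  .truncate_normalize(coefs, colnames(reference))
}

#' Non-negative least-squares deconvolution of one sample
#'
#' Minimises the squared residual of the marker betas on the reference
#' columns subject to non-negative coefficients (Lawson-Hanson NNLS), then
#' rescales the coefficients to sum to one.
#'
#' @inheritParams rpc_deconvolve_sample
#' @return Named proportion vector over the reference cell types.
#' @export
nnls_deconvolve_sample <- function(beta_at_markers, reference) {
  y <- .align_marker_vector(beta_at_markers, reference)
  X <- attr(y, "reference")
  coefs <- pracma::lsqnonneg(X, as.vector(y))$x
  .truncate_normalize(coefs, colnames(reference))
}

# Align a beta vector to the reference rows, dropping missing markers.
.align_marker_vector <- function(beta, reference) {
  if (!is.null(names(beta)) && !is.null(rownames(reference))) {
    shared <- intersect(rownames(reference), names(beta))
    if (length(shared) == 0)
      stop("alignment error: no shared marker CpG ids")
    beta <- beta[shared]
    reference <- reference[shared, , drop = FALSE]
  } else if (length(beta) != nrow(reference)) {
    stop("alignment error: beta vector length ", length(beta),
         " does not match reference rows ", nrow(reference))
  }
  keep <- is.finite(beta)
  if (sum(keep) < 0.5 * nrow(reference))
    stop("insufficient markers: fewer than 50% of marker values present")
  y <- as.vector(beta[keep])
  attr(y, "reference") <- as.matrix(reference[keep, , drop = FALSE])
  y
}

.truncate_normalize <- function(coefs, cell_types) {
  coefs[!is.finite(coefs)] <- 0
  coefs <- pmax(coefs, 0)
  s <- sum(coefs)
  if (s <= 0) {
    warning("all coefficients non-positive; returning uniform proportions")
    coefs <- rep(1 / length(coefs), length(coefs))
  } else {
    coefs <- coefs / s
  }
  names(coefs) <- cell_types
  coefs
}

#' Reference-based deconvolution of a cohort
#'
#' Applies [rpc_deconvolve_sample()] or [nnls_deconvolve_sample()] to every
#' sample over the intersection of the beta matrix's CpGs with the
#' reference markers.
#'
#' @param betas CpG x sample beta matrix.
#' @param reference Marker CpG x cell type matrix.
#' @param method `"rpc"` (robust, default) or `"nnls"`.
#' @param verbose Log the number of markers used.
#' @return Object of class `deconv_result`: `proportions` (sample x cell
#'   type, rows on the simplex), `fit_rmse` (per-sample residual RMSE at
#'   the markers), `method`, `n_markers_used`.
#' @export
deconvolve_cohort <- function(betas, reference, method = c("rpc", "nnls"),
                              verbose = FALSE) {
  method <- match.arg(method)
  shared <- intersect(rownames(reference), rownames(betas))
  if (length(shared) == 0)
    stop("alignment error: no marker CpGs found in the beta matrix")
  if (verbose)
    message("deconvolving ", ncol(betas), " samples on ", length(shared),
            " marker CpGs (", method, ")")
  R <- as.matrix(reference[shared, , drop = FALSE])
  B <- as.matrix(betas[shared, , drop = FALSE])
  fun <- switch(method, rpc = rpc_deconvolve_sample,
                nnls = nnls_deconvolve_sample)
  props <- t(vapply(seq_len(ncol(B)), function(i) fun(B[, i], R),
                    numeric(ncol(R))))
  dimnames(props) <- list(colnames(betas), colnames(reference))
  resid <- B - R %*% t(props)
  structure(list(
    proportions = props,
    fit_rmse = stats::setNames(sqrt(colMeans(resid^2)), colnames(betas)),
    method = method,
    n_markers_used = length(shared)
  ), class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat("Reference-based deconvolution (", x$method, "), ",
      nrow(x$proportions), " samples x ", ncol(x$proportions),
      " cell types, ", x$n_markers_used, " markers\n", sep = "")
  cat("mean composition:\n")
  print(round(colMeans(x$proportions), 4))
  invisible(x)
}
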