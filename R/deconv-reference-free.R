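# Reference-free decomposition of a beta matrix into K latent component
# methylomes (M, CpG x K, in [0,1]) and per-sample component proportions
# (Omega, samples x K, rows on the unit simplex), by alternating
# constrained least squares, with bootstrap-deviance selection of K.

# Exact simplex-constrained least squares for one sample:
#   min ||y - M w||^2  s.t.  w >= 0, sum(w) = 1
# Equality-constrained closed form first; negative coordinates are fixed to
# zero one at a time (active set). A is crossprod(M), c is crossprod(M, y).
.simplex_weights <- function(A, cvec) {
  K <- length(cvec)
  free <- seq_len(K)
  w <- numeric(K)
  repeat {
    kf <- length(free)
    if (kf == 1) {
      w[] <- 0; w[free] <- 1
      return(w)
    }
    KKT <- rbind(cbind(A[free, free, drop = FALSE], 1), c(rep(1, kf), 0))
    rhs <- c(cvec[free], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) {
      solve(KKT + diag(1e-10, kf + 1), rhs)
    })
    wf <- sol[seq_len(kf)]
    if (all(wf >= -1e-12)) {
      w[] <- 0
      w[free] <- pmax(wf, 0)
      return(w / sum(w))
    }
    free <- free[-which.min(wf)]
  }
}

# Row-normalised simplex weights for every column of B given M; vectorised
# equality-constrained solve, per-sample active set only where needed.
.fit_omega <- function(M, B) {
  A <- crossprod(M)
  C <- crossprod(M, B)                      # K x n
  Ai <- tryCatch(solve(A), error = function(e) solve(A + diag(1e-10, ncol(A))))
  Wu <- Ai %*% C
  u <- Ai %*% rep(1, ncol(A))
  W <- Wu + u %*% t((1 - colSums(Wu)) / sum(u))
  neg <- which(apply(W < -1e-12, 2, any))
  for (i in neg) W[, i] <- .simplex_weights(A, C[, i])
  W <- pmax(W, 0)
  t(W / rep(colSums(W), each = nrow(W)))    # n x K
}

.reconstruction_mse <- function(B, M, Omega) {
  mean((B - M %*% t(Omega))^2)
}

#' Reference-free factorization of a beta matrix
#'
#' Decomposes the `n_top_variable_cpgs` most variable CpG rows of `betas`
#' into K latent methylomes and per-sample proportions by alternating
#' constrained least squares: given Omega, each CpG row of M is updated by
#' least squares and clipped to [0,1]; given M, each sample's Omega row is
#' the exact simplex-constrained least-squares solution. Either block
#' update is kept only where it does not increase that row's residual sum
#' of squares, so the reconstruction deviance is non-increasing across
#' iterations. Initialisation is a Ward-linkage hierarchical clustering of
#' samples with cluster mean profiles as starting M.
#'
#' @param betas CpG x sample matrix, finite values.
#' @param K Number of latent components, `1 <= K < n_samples`.
#' @param n_top_variable_cpgs CpG rows retained (by variance); default
#'   10000.
#' @param tol Relative deviance-change stopping tolerance.
#' @param max_iter Maximum alternating iterations.
#' @param seed Integer seed (initialisation is deterministic; the seed
#'   also fixes any downstream use).
#' @return Object of class `reffree_fit`: `M` (CpG x K, in [0,1]), `Omega`
#'   (samples x K, rows on the simplex), `K`, `deviance` (mean squared
#'   reconstruction error on the retained CpGs), `deviance_trace`,
#'   `n_iter`, `converged`, `cpg_ids` (retained CpGs).
#' @export
reffree_factorize <- function(betas, K, n_top_variable_cpgs = 10000,
                              tol = 1e-6, max_iter = 100, seed = 1L) {
  if (any(!is.finite(betas))) stop("data error: non-finite beta values")
  n <- ncol(betas)
  if (K >= n) stop("invalid K: must be smaller than the number of samples")
  if (K < 1) stop("invalid K: must be at least 1")
  set.seed(seed)
  rv <- .row_vars(betas)
  keep <- order(rv, decreasing = TRUE)[seq_len(min(n_top_variable_cpgs,
                                                   nrow(betas)))]
  keep <- sort(keep)
  B <- as.matrix(betas[keep, , drop = FALSE])
  p <- nrow(B)
  if (K == 1) {
    M <- matrix(rowMeans(B), p, 1, dimnames = list(rownames(B), "C1"))
    Omega <- matrix(1, n, 1, dimnames = list(colnames(B), "C1"))
    dev <- .reconstruction_mse(B, M, Omega)
    return(structure(list(M = M, Omega = Omega, K = 1L, deviance = dev,
                          deviance_trace = dev, n_iter = 0L,
                          converged = TRUE, cpg_ids = rownames(B)),
                     class = "reffree_fit"))
  }
  # Ward clustering of samples -> cluster mean methylomes as initial M
  cl <- stats::cutree(stats::hclust(stats::dist(t(B)), method = "ward.D2"),
                      k = K)
  M <- vapply(seq_len(K), function(k) {
    idx <- which(cl == k)
    if (length(idx) == 1) B[, idx] else rowMeans(B[, idx, drop = FALSE])
  }, numeric(p))
  Omega <- .fit_omega(M, B)
  dev_trace <- .reconstruction_mse(B, M, Omega)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # --- M update: per-CpG least squares on Omega, clipped to [0,1] ------
    OtO <- crossprod(Omega)
    Mhat <- t(tryCatch(solve(OtO, crossprod(Omega, t(B))),
                       error = function(e)
                         solve(OtO + diag(1e-10, K), crossprod(Omega, t(B)))))
    Mhat <- pmin(pmax(Mhat, 0), 1)
    R_old <- B - M %*% t(Omega)
    R_new <- B - Mhat %*% t(Omega)
    worse <- rowSums(R_new^2) > rowSums(R_old^2)    # clipping can hurt a row
    if (any(worse)) Mhat[worse, ] <- M[worse, , drop = FALSE]
    M <- Mhat
    # --- Omega update: exact simplex least squares per sample ------------
    Omega_hat <- .fit_omega(M, B)
    R_old <- B - M %*% t(Omega)
    R_new <- B - M %*% t(Omega_hat)
    worse <- colSums(R_new^2) > colSums(R_old^2)
    if (any(worse)) Omega_hat[worse, ] <- Omega[worse, , drop = FALSE]
    Omega <- Omega_hat
    dev <- .reconstruction_mse(B, M, Omega)
    dev_trace <- c(dev_trace, dev)
    prev <- dev_trace[length(dev_trace) - 1]
    if (prev - dev < tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  dimnames(M) <- list(rownames(B), paste0("C", seq_len(K)))
  dimnames(Omega) <- list(colnames(B), paste0("C", seq_len(K)))
  structure(list(M = M, Omega = Omega, K = as.integer(K),
                 deviance = dev_trace[length(dev_trace)],
                 deviance_trace = dev_trace, n_iter = iter,
                 converged = converged, cpg_ids = rownames(B)),
            class = "reffree_fit")
}

.row_vars <- function(x) {
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}

#' @export
print.reffree_fit <- function(x, ...) {
  cat("Reference-free factorization: K = ", x$K, ", ",
      length(x$cpg_ids), " CpGs x ", nrow(x$Omega), " samples, deviance ",
      signif(x$deviance, 4), " (", x$n_iter, " iterations, ",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}

#' Project new samples onto fitted latent methylomes
#'
#' Estimates simplex-constrained component proportions for each column of
#' `betas` given a fixed latent methylome matrix `M` (rows aligned by CpG
#' id when names are present).
#'
#' @param M CpG x K latent methylome matrix.
#' @param betas CpG x sample matrix.
#' @return Samples x K proportion matrix.
#' @export
project_omega <- function(M, betas) {
  if (!is.null(rownames(M)) && !is.null(rownames(betas))) {
    shared <- intersect(rownames(M), rownames(betas))
    if (length(shared) == 0) stop("alignment error: no shared CpG ids")
    M <- M[shared, , drop = FALSE]
    betas <- betas[shared, , drop = FALSE]
  }
  Omega <- .fit_omega(as.matrix(M), as.matrix(betas))
  dimnames(Omega) <- list(colnames(betas), colnames(M))
  Omega
}

#' Bootstrap-deviance selection of the component count
#'
#' For each candidate K, samples are resampled with replacement `n_boot`
#' times; the factorization is fitted on the resample and evaluated on the
#' out-of-bag samples with a cross-fitted Gaussian deviance. CpGs are split
#' into two random halves: an out-of-bag sample's proportions are
#' re-estimated on the fitted methylomes restricted to one half, and its
#' deviance `mean_j (r_j^2 / s_j^2 + log s_j^2)` is evaluated on the other
#' half, with `s_j^2` the training residual variance of CpG j (floored at
#' `var_floor`). The CpG split stops extra components from absorbing the
#' evaluation sample's own noise, and the training variances penalise
#' overfitted K (they fall below the true noise level, inflating the
#' standardised residuals); too small a K leaves structure in the
#' residuals. The K with the smallest mean out-of-bag deviance wins.
#'
#' @param betas CpG x sample matrix.
#' @param k_range Integer vector of candidate K values (each `< n`).
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param n_top_variable_cpgs,tol,max_iter Passed to
#'   [reffree_factorize()].
#' @param var_floor Lower bound on training residual variances.
#' @return List with `K` (selected), `deviance_table` (data frame of K and
#'   mean out-of-bag deviance), `boot_deviances` (K x n_boot matrix).
#' @export
select_k <- function(betas, k_range = 2:6, n_boot = 5, seed = 1L,
                     n_top_variable_cpgs = 10000, tol = 1e-5,
                     max_iter = 50, var_floor = 1e-9) {
  n <- ncol(betas)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= n))
    stop("invalid K range: candidates must lie in [2, n_samples - 1]")
  if (n_boot < 2) stop("n_boot must be at least 2")
  set.seed(seed)
  rv <- .row_vars(betas)
  keep <- sort(order(rv, decreasing = TRUE)[seq_len(min(n_top_variable_cpgs,
                                                        nrow(betas)))])
  B <- as.matrix(betas[keep, , drop = FALSE])
  boot_dev <- matrix(NA_real_, length(k_range), n_boot,
                     dimnames = list(paste0("K", k_range), NULL))
  fit_seeds <- sample.int(.Machine$integer.max - 1L, n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) > 0) break
      message("empty out-of-bag set; resample redrawn")
    }
    Btr <- B[, idx, drop = FALSE]
    Boob <- B[, oob, drop = FALSE]
    half <- sample.int(nrow(B)) <= nrow(B) / 2   # CpG split for cross-fitting
    for (ki in seq_along(k_range)) {
      K <- k_range[ki]
      fit <- reffree_factorize(Btr, K, n_top_variable_cpgs = nrow(B),
                               tol = tol, max_iter = max_iter,
                               seed = fit_seeds[b])
      res_tr <- Btr - fit$M %*% t(fit$Omega)
      df <- max(length(idx) - K, 1)
      s2 <- pmax(rowSums(res_tr^2) / df, var_floor)
      Om_oob <- .fit_omega(fit$M[half, , drop = FALSE],
                           Boob[half, , drop = FALSE])
      res_oob <- Boob[!half, , drop = FALSE] -
        fit$M[!half, , drop = FALSE] %*% t(Om_oob)
      boot_dev[ki, b] <- mean(colMeans(res_oob^2 / s2[!half] +
                                         log(s2[!half])))
    }
  }
  mean_dev <- rowMeans(boot_dev)
  list(K = k_range[which.min(mean_dev)],
       deviance_table = data.frame(K = k_range, deviance = mean_dev,
                                   row.names = NULL),
       boot_deviances = boot_dev)
}

#' Match estimated components to ground-truth components
#'
#' Greedy one-to-one assignment by maximal absolute correlation between
#' estimated and true proportion columns; used to undo label switching
#' when evaluating recovery.
#'
#' @param est,truth Matrices with the same number of rows (samples).
#' @return Data frame with `est_column`, `true_column`, `correlation`
#'   (absolute Spearman-free Pearson correlation of the matched pair).
#' @export
match_components <- function(est, truth) {
  cc <- abs(stats::cor(est, truth))
  out <- data.frame(est_column = integer(0), true_column = integer(0),
                    correlation = numeric(0))
  for (i in seq_len(min(ncol(est), ncol(truth)))) {
    j <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(est_column = j[1], true_column = j[2],
                                 correlation = cc[j[1], j[2]]))
    cc[j[1], ] <- -Inf
    cc[, j[2]] <- -Inf
  }
  out[order(out$true_column), ]
}
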