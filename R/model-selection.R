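# Repeated cross-validation comparison of six linear models predicting the
# dominant methylation axis (PC1) from phenotypes and/or estimated cell
# composition, with win counting, the winner's adjusted R-squared, and a
# per-CpG variance decomposition.

#' The six model specifications
#'
#' In fixed order: intercept-only; phenotypes (gestational age, child sex,
#' ancestry components); reference-based cell types; reference-based cell
#' types + phenotypes; reference-free components; reference-free
#' components + phenotypes.
#'
#' @return Named list of model specs (`name`, logical flags `rb`, `rf`,
#'   `pheno`).
#' @export
model_specs <- function() {
  mk <- function(name, rb, rf, pheno)
    list(name = name, rb = rb, rf = rf, pheno = pheno)
  specs <- list(
    mk("intercept", FALSE, FALSE, FALSE),
    mk("phenotypes", FALSE, FALSE, TRUE),
    mk("ref_based", TRUE, FALSE, FALSE),
    mk("ref_based+phenotypes", TRUE, FALSE, TRUE),
    mk("ref_free", FALSE, TRUE, FALSE),
    mk("ref_free+phenotypes", FALSE, TRUE, TRUE)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

# Drop the largest-mean column of a proportion block: rows sum to one, so
# the full block is collinear with the intercept.
.drop_reference_column <- function(P, prefix) {
  P <- as.matrix(P)
  drop <- which.max(colMeans(P))
  out <- P[, -drop, drop = FALSE]
  colnames(out) <- paste0(prefix, colnames(P)[-drop])
  out
}

#' Build the design matrix for one model specification
#'
#' The intercept column is always present. Cell-type or component blocks
#' drop their largest-mean column (rows on the simplex are collinear with
#' the intercept); sex is coded 0/1; ancestry components are any phenotype
#' columns whose name starts with `ancestry`. Rows with missing values in
#' the required covariates are removed (complete-case analysis) and
#' reported via the `rows_kept` attribute.
#'
#' @param spec One element of [model_specs()].
#' @param proportions_rb Sample x cell-type matrix (reference-based).
#' @param omega_rf Sample x component matrix (reference-free).
#' @param phenotypes Data frame with `gestational_age`, `sex` and ancestry
#'   columns, rows aligned with the proportion matrices.
#' @return Numeric design matrix with attribute `rows_kept` (integer row
#'   indices retained).
#' @export
build_model_matrix <- function(spec, proportions_rb = NULL, omega_rf = NULL,
                               phenotypes = NULL) {
  n <- max(nrow(proportions_rb), nrow(omega_rf), nrow(phenotypes), 0)
  if (n == 0) stop("no inputs supplied to build a design for")
  blocks <- list("(Intercept)" = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  if (isTRUE(spec$rb)) {
    stopifnot(!is.null(proportions_rb), nrow(proportions_rb) == n)
    blocks$rb <- .drop_reference_column(proportions_rb, "rb_")
  }
  if (isTRUE(spec$rf)) {
    stopifnot(!is.null(omega_rf), nrow(omega_rf) == n)
    blocks$rf <- .drop_reference_column(omega_rf, "rf_")
  }
  if (isTRUE(spec$pheno)) {
    stopifnot(!is.null(phenotypes), nrow(phenotypes) == n)
    anc <- grep("^ancestry", colnames(phenotypes), value = TRUE)
    ph <- cbind(gestational_age = phenotypes$gestational_age,
                sex = as.numeric(phenotypes$sex))
    if (length(anc))
      ph <- cbind(ph, as.matrix(phenotypes[, anc, drop = FALSE]))
    blocks$pheno <- ph
  }
  X <- do.call(cbind, blocks)
  keep <- which(stats::complete.cases(X))
  if (length(keep) < n)
    message(n - length(keep), " incomplete row(s) removed for model '",
            spec$name, "'")
  X <- X[keep, , drop = FALSE]
  attr(X, "rows_kept") <- keep
  X
}

# OLS prediction with a tiny-ridge fallback for singular folds.
.fit_predict <- function(Xtr, ytr, Xte) {
  qr_tr <- qr(Xtr)
  if (qr_tr$rank < ncol(Xtr)) {
    beta <- solve(crossprod(Xtr) + diag(1e-8, ncol(Xtr)), crossprod(Xtr, ytr))
    attr(beta, "ridge") <- TRUE
  } else {
    beta <- qr.coef(qr_tr, ytr)
  }
  as.vector(Xte %*% beta)
}

#' Repeated k-fold cross-validation over the six models
#'
#' For every repeat one random fold partition is drawn and shared by all
#' models; each model is fitted by ordinary least squares on the training
#' folds and its out-of-fold predictions are pooled across the k folds
#' into one RMSE per repeat. The repeat's winner is the model with the
#' smallest RMSE (ties going to the earlier model in the fixed ordering).
#' Singular training designs fall back to a ridge penalty of 1e-8.
#'
#' @param y Numeric response (PC1 scores), finite.
#' @param designs Named list of design matrices, all with `length(y)` rows,
#'   in the fixed model order.
#' @param folds Number of folds; default 10.
#' @param repeats Number of repeats; default 500.
#' @param seed Integer seed.
#' @return Object of class `cv_result`: `rmse` (repeats x models), `wins`,
#'   `win_proportions`, `mean_rmse`, `ci` (2.5/97.5 percentiles of the
#'   repeat RMSEs per model), `winner`, `winner_adjusted_r2` (winning model
#'   refitted on all data), `folds`, `repeats`, `seed`.
#' @export
repeated_cv <- function(y, designs, folds = 10, repeats = 500, seed = 1L) {
  stopifnot(is.list(designs), length(designs) >= 1, all(is.finite(y)))
  n <- length(y)
  if (n < 2 * folds) stop("need at least 2 observations per fold")
  for (d in designs) stopifnot(nrow(d) == n)
  m <- length(designs)
  model_names <- names(designs)
  if (is.null(model_names)) model_names <- paste0("model", seq_len(m))
  set.seed(seed)
  rmse <- matrix(NA_real_, repeats, m, dimnames = list(NULL, model_names))
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (j in seq_len(m)) {
      X <- designs[[j]]
      pred <- numeric(n)
      for (f in seq_len(folds)) {
        te <- fold_id == f
        pred[te] <- .fit_predict(X[!te, , drop = FALSE], y[!te],
                                 X[te, , drop = FALSE])
      }
      rmse[r, j] <- sqrt(mean((y - pred)^2))
    }
  }
  winners <- apply(rmse, 1, which.min)          # which.min = earliest on ties
  wins <- tabulate(winners, nbins = m)
  names(wins) <- model_names
  best <- which.max(wins)
  structure(list(
    rmse = rmse, wins = wins, win_proportions = wins / repeats,
    mean_rmse = colMeans(rmse),
    ci = apply(rmse, 2, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE),
    winner = model_names[best],
    winner_adjusted_r2 = adjusted_r2(y, designs[[best]]),
    folds = folds, repeats = repeats, seed = seed
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Repeated cross-validation (", x$folds, " folds x ", x$repeats,
      " repeats)\n", sep = "")
  tab <- data.frame(wins = x$wins,
                    win_pct = round(100 * x$win_proportions, 1),
                    mean_rmse = signif(x$mean_rmse, 4),
                    ci_lo = signif(x$ci[1, ], 4),
                    ci_hi = signif(x$ci[2, ], 4))
  print(tab)
  cat("winner: ", x$winner, " (adjusted R^2 = ",
      round(x$winner_adjusted_r2, 3), ")\n", sep = "")
  invisible(x)
}

#' Adjusted R-squared of a least-squares fit
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `p` the number of
#' non-intercept predictors (the design is expected to carry an intercept
#' column).
#'
#' @param y Numeric response.
#' @param design Design matrix including the intercept column.
#' @return Scalar adjusted R-squared.
#' @export
adjusted_r2 <- function(y, design) {
  design <- as.matrix(design)
  n <- length(y)
  fit <- stats::lm.fit(design, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  p <- fit$rank - 1
  if (n - p - 1 <= 0) return(NA_real_)
  r2 <- if (tss < .Machine$double.eps) 1 else 1 - rss / tss
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Per-CpG adjusted R-squared under two designs
#'
#' Regresses every CpG's beta values on the reference-based and on the
#' reference-free design and extracts the adjusted R-squared of each fit.
#'
#' @param betas CpG x sample matrix.
#' @param design_rb,design_rf Design matrices (samples x predictors,
#'   intercept included) from [build_model_matrix()].
#' @return Data frame with `cpg_id`, `r2_ref_based`, `r2_ref_free`.
#' @export
per_cpg_r2 <- function(betas, design_rb, design_rf) {
  Y <- t(as.matrix(betas))                       # samples x CpGs
  one <- function(design) {
    design <- as.matrix(design)
    stopifnot(nrow(design) == nrow(Y))
    qd <- qr(design)
    p <- qd$rank - 1
    n <- nrow(Y)
    fitted <- qr.fitted(qd, Y)
    rss <- colSums((Y - fitted)^2)
    tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
    r2 <- ifelse(tss < .Machine$double.eps, 1, 1 - rss / tss)
    1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  data.frame(cpg_id = rownames(betas),
             r2_ref_based = one(design_rb),
             r2_ref_free = one(design_rf),
             row.names = NULL)
}

#' CpGs exceeding an adjusted R-squared threshold in every dataset
#'
#' @param r2_tables List of named numeric vectors (adjusted R-squared per
#'   CpG id), one per dataset.
#' @param threshold Strict lower bound; default 0.30.
#' @return Character vector of CpG ids with value strictly above
#'   `threshold` in all datasets; invariant to dataset order.
#' @export
high_r2_intersection <- function(r2_tables, threshold = 0.30) {
  stopifnot(length(r2_tables) >= 1)
  sets <- lapply(r2_tables, function(v) names(v)[!is.na(v) & v > threshold])
  sort(Reduce(intersect, sets))
}
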