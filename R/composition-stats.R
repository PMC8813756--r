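# Nonparametric composition statistics: Spearman association matrices with
# Bonferroni control, paired signed-rank comparisons of cell types,
# nonparametric relative effects, and a permutation global rank-based
# multivariate group test.

# two-sided Spearman p by the t approximation
.spearman_p <- function(rho, n) {
  p <- numeric(length(rho))
  exact1 <- abs(rho) >= 1 - 1e-12
  p[exact1] <- 0
  ok <- !exact1 & !is.na(rho)
  tt <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(tt), n - 2)
  p[is.na(rho)] <- NA_real_
  p
}

#' Spearman association matrix with Bonferroni control
#'
#' Mid-rank Spearman correlations between every column of `A` and every
#' column of `B`, two-sided p values by the t approximation, and Bonferroni
#' adjustment over all `ncol(A) * ncol(B)` tests.
#'
#' @param A,B Numeric matrices or data frames on the same samples (rows).
#' @param alpha Significance threshold after adjustment; default 0.01.
#' @return Object of class `association_result`: `rho`, `p_raw`,
#'   `p_bonferroni`, `significant` (logical at `alpha`), `n_tests`, `n`,
#'   `alpha`.
#' @export
spearman_associations <- function(A, B, alpha = 0.01) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  if (nrow(A) < 5) stop("need at least 5 shared samples")
  rho <- stats::cor(A, B, method = "spearman")
  n_tests <- length(rho)
  p_raw <- matrix(.spearman_p(rho, nrow(A)), nrow(rho),
                  dimnames = dimnames(rho))
  structure(list(rho = rho, p_raw = p_raw,
                 p_bonferroni = pmin(1, p_raw * n_tests),
                 significant = pmin(1, p_raw * n_tests) < alpha,
                 n_tests = n_tests, n = nrow(A), alpha = alpha),
            class = "association_result")
}

# mid-ranked signed-rank statistic with tie-corrected normal Z
.signed_rank_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, Z = 0, p = 1, n_nonzero = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
  list(W = W, Z = Z, p = 2 * stats::pnorm(-abs(Z)), n_nonzero = n)
}

#' Exact signed-rank p value by sign enumeration
#'
#' Enumerates all `2^n` sign assignments of the non-zero differences
#' (mid-ranks of absolute values held fixed, so ties are handled exactly)
#' and returns the exact p value of the observed statistic.
#'
#' @param d Numeric vector of paired differences (zeros dropped, at most
#'   20 non-zero values).
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @return Exact p value.
#' @export
exact_signed_rank_p <- function(d, alternative = c("two.sided", "greater",
                                                   "less")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  if (n > 20) stop("exact enumeration limited to 20 non-zero differences")
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  W_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  switch(alternative,
         two.sided = mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-12),
         greater = mean(W_all >= W_obs - 1e-12),
         less = mean(W_all <= W_obs + 1e-12))
}

#' Exact Spearman p value by permutation enumeration
#'
#' Enumerates all `n!` permutations of one variable's mid-ranks and
#' returns the two-sided exact p value of the observed correlation.
#'
#' @param x,y Numeric vectors, `n <= 8`.
#' @return Exact two-sided p value.
#' @export
exact_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n > 8) stop("exact enumeration limited to n <= 8")
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perm <- .all_permutations(n)
  rho_all <- apply(perm, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    shifted <- sub + (sub >= i)
    cbind(rep.int(i, nrow(sub)), shifted)
  }))
}

#' Paired cell-type comparison by signed-rank tests
#'
#' Per cell type, the paired Wilcoxon signed-rank test of the two time
#' points' proportions on the same individuals. Zero differences are
#' dropped; absolute differences are mid-ranked and the Z statistic uses
#' the tie-corrected normal approximation (positive Z means larger values
#' at time 1). For at most `exact_limit` non-zero differences the p value
#' is the exact enumeration over sign assignments. Medians and their
#' difference are reported in percentage points; Bonferroni adjustment is
#' over the number of cell types.
#'
#' @param props_t1,props_t2 Sample x cell-type proportion matrices on the
#'   identical, aligned samples (time 1, e.g. first trimester, and time 2,
#'   e.g. term).
#' @param alpha Significance threshold after adjustment; default 0.01.
#' @param exact_limit Largest number of non-zero differences for which the
#'   exact enumeration p value is used; default 10.
#' @return Object of class `paired_test_result`: data frame `table` with
#'   `cell_type`, `median_t1`, `median_t2`, `median_difference` (all in
#'   percent, difference = t2 - t1), `Z`, `p_raw`, `p_bonferroni`,
#'   `significant`, `exact`.
#' @export
paired_celltype_tests <- function(props_t1, props_t2, alpha = 0.01,
                                  exact_limit = 10) {
  props_t1 <- as.matrix(props_t1); props_t2 <- as.matrix(props_t2)
  stopifnot(nrow(props_t1) == nrow(props_t2),
            ncol(props_t1) == ncol(props_t2))
  if (!is.null(rownames(props_t1)) && !is.null(rownames(props_t2)) &&
      !identical(rownames(props_t1), rownames(props_t2)))
    stop("paired matrices must be aligned on identical sample ids")
  if (nrow(props_t1) < 6) stop("need at least 6 pairs")
  K <- ncol(props_t1)
  rows <- lapply(seq_len(K), function(k) {
    d <- props_t1[, k] - props_t2[, k]
    st <- .signed_rank_z(d)
    exact <- st$n_nonzero > 0 && st$n_nonzero <= exact_limit
    p <- if (exact) exact_signed_rank_p(d) else st$p
    if (st$n_nonzero == 0)
      message("all paired differences zero for cell type ",
              colnames(props_t1)[k])
    data.frame(cell_type = colnames(props_t1)[k],
               median_t1 = 100 * stats::median(props_t1[, k]),
               median_t2 = 100 * stats::median(props_t2[, k]),
               median_difference = 100 * (stats::median(props_t2[, k]) -
                                          stats::median(props_t1[, k])),
               Z = st$Z, p_raw = p, exact = exact)
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(1, tab$p_raw * K)
  tab$significant <- tab$p_bonferroni < alpha
  structure(list(table = tab, n_pairs = nrow(props_t1), alpha = alpha),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat("Paired signed-rank comparison (", x$n_pairs, " pairs, alpha = ",
      x$alpha, ")\n", sep = "")
  tab <- x$table
  tab[c("median_t1", "median_t2", "median_difference", "Z")] <-
    lapply(tab[c("median_t1", "median_t2", "median_difference", "Z")],
           round, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Nonparametric relative effects per cell type
#'
#' For each cell type, proportions of all N samples are mid-ranked
#' globally; a group's relative effect is
#' `(mean group rank - (N + 1) / 2) / N + 1/2`, the probability that a
#' random observation from that group exceeds a random observation from
#' the pooled data. The sample-size-weighted mean of the effects is 0.5
#' for every cell type.
#'
#' @param props Sample x cell-type proportion matrix.
#' @param groups Group label per sample.
#' @return Groups x cell-type matrix of relative effects in [0,1].
#' @export
relative_effects <- function(props, groups) {
  props <- as.matrix(props)
  groups <- factor(groups)
  stopifnot(nrow(props) == length(groups))
  N <- nrow(props)
  R <- apply(props, 2, rank)
  mean_ranks <- rowsum(R, groups) / as.vector(table(groups))
  eff <- (mean_ranks - (N + 1) / 2) / N + 0.5
  dimnames(eff) <- list(levels(groups), colnames(props))
  eff
}

#' Global rank-based multivariate group comparison
#'
#' Tests whether the multivariate cell-type composition differs between
#' groups. Proportions are mid-ranked per cell type over all samples; the
#' ANOVA-type statistic is the between-group sum of squared deviations of
#' group mean rank vectors (weighted by group size), summed over cell
#' types and normalised by the total rank variance. Its null distribution
#' is obtained by permuting group labels; the p value uses the add-one
#' convention, so it lies in `[1/(n_permutations + 1), 1]`. Nonparametric
#' relative effects per group and cell type accompany the test.
#'
#' @param props Sample x cell-type proportion matrix.
#' @param groups Group label per sample; at least 2 groups of at least 3
#'   samples each.
#' @param n_permutations Number of label permutations; default 2000.
#' @param seed Integer seed.
#' @return Object of class `group_comparison`: `relative_effects`,
#'   `anova_type_statistic`, `p_permutation`, `n_permutations`,
#'   `group_sizes`.
#' @export
global_rank_manova <- function(props, groups, n_permutations = 2000,
                               seed = 1L) {
  props <- as.matrix(props)
  groups <- factor(groups)
  stopifnot(nrow(props) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 3))
    stop("every group must contain at least 3 samples (smallest has ",
         min(sizes), ")")
  N <- nrow(props)
  R <- apply(props, 2, rank)
  center <- (N + 1) / 2
  tot <- sum(sweep(R, 2, colMeans(R))^2)
  stat_fun <- function(g) {
    mr <- rowsum(R, g) / as.vector(table(g))
    sum(as.vector(table(g)) * rowSums((mr - center)^2))
  }
  if (tot < .Machine$double.eps) {
    eff <- relative_effects(props, groups)
    return(structure(list(relative_effects = eff, anova_type_statistic = 0,
                          p_permutation = 1,
                          n_permutations = as.integer(n_permutations),
                          group_sizes = sizes),
                     class = "group_comparison"))
  }
  obs <- stat_fun(groups) / tot
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    gp <- groups[sample.int(N)]
    if (stat_fun(gp) / tot >= obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(relative_effects = relative_effects(props, groups),
                 anova_type_statistic = obs,
                 p_permutation = (1 + exceed) / (n_permutations + 1),
                 n_permutations = as.integer(n_permutations),
                 group_sizes = sizes),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Global rank-based multivariate group comparison\n",
      "  ANOVA-type statistic: ", signif(x$anova_type_statistic, 4),
      "   permutation p: ", signif(x$p_permutation, 4), " (",
      x$n_permutations, " permutations)\n", sep = "")
  cat("relative effects:\n")
  print(round(x$relative_effects, 3))
  invisible(x)
}

#' Associations of cell-type proportions with gestational age and sex
#'
#' Per cell type: Spearman correlation of the proportion with gestational
#' age (two-sided t-approximation p), and a two-sample Wilcoxon rank-sum
#' comparison between the sexes. Each family of tests is Bonferroni
#' adjusted over the number of cell types.
#'
#' @param props Sample x cell-type proportion matrix.
#' @param phenotypes Data frame with `gestational_age` and `sex` (0/1),
#'   rows aligned with `props`.
#' @param alpha Significance threshold after adjustment; default 0.01.
#' @return Object of class `ga_sex_result` with data frames `ga`
#'   (`cell_type`, `rho`, `p_raw`, `p_bonferroni`, `significant`) and
#'   `sex` (`cell_type`, `W`, `p_raw`, `p_bonferroni`, `significant`).
#' @export
ga_sex_associations <- function(props, phenotypes, alpha = 0.01) {
  props <- as.matrix(props)
  stopifnot(nrow(props) == nrow(phenotypes),
            all(c("gestational_age", "sex") %in% colnames(phenotypes)))
  K <- ncol(props)
  rho <- as.vector(stats::cor(props, phenotypes$gestational_age,
                              method = "spearman"))
  p_ga <- .spearman_p(rho, nrow(props))
  ga <- data.frame(cell_type = colnames(props), rho = rho, p_raw = p_ga,
                   p_bonferroni = pmin(1, p_ga * K))
  ga$significant <- ga$p_bonferroni < alpha
  sex <- do.call(rbind, lapply(seq_len(K), function(k) {
    wt <- suppressWarnings(
      stats::wilcox.test(props[phenotypes$sex == 1, k],
                         props[phenotypes$sex == 0, k]))
    data.frame(cell_type = colnames(props)[k],
               W = unname(wt$statistic), p_raw = wt$p.value)
  }))
  sex$p_bonferroni <- pmin(1, sex$p_raw * K)
  sex$significant <- sex$p_bonferroni < alpha
  structure(list(ga = ga, sex = sex, alpha = alpha),
            class = "ga_sex_result")
}

#' @export
print.ga_sex_result <- function(x, ...) {
  cat("Gestational-age associations (Spearman, Bonferroni over cell types)\n")
  print(transform(x$ga, rho = round(rho, 3)), row.names = FALSE)
  cat("Sex comparisons (rank-sum)\n")
  print(x$sex, row.names = FALSE)
  invisible(x)
}
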