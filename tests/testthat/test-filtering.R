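# Variability filter, PCA, outlier fences, correlation screen.

test_that("percentile-range filter matches a brute-force oracle", {
  set.seed(20)
  A <- matrix(runif(50 * 20), 50, 20,
              dimnames = list(paste0("cg", 1:50), NULL))
  B <- matrix(runif(50 * 15), 50, 15,
              dimnames = list(paste0("cg", 1:50), NULL))
  A[1, ] <- 0.7                    # constant CpG: zero range
  B[1, ] <- 0.7
  A[2, ] <- seq(0.2, 0.3, length.out = 20)   # range 0.10 in A
  B[2, ] <- seq(0.2, 0.3, length.out = 15)
  rep_ <- nonvariable_cpgs(list(A, B), threshold = 0.05)
  expect_true("cg1" %in% rep_$nonvariable_ids)
  expect_true("cg2" %in% rep_$variable_ids)   # 0.10 >= 0.05 in both
  # independent oracle: type-7 quantiles by explicit sorting/interpolation
  q7 <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  oracle <- vapply(rownames(A), function(id) {
    all(vapply(list(A, B), function(m)
      (q7(m[id, ], 0.9) - q7(m[id, ], 0.1)) < 0.05, logical(1)))
  }, logical(1))
  expect_setequal(rep_$nonvariable_ids, names(oracle)[oracle])
  # invariant to sample and CpG order
  perm <- nonvariable_cpgs(list(A[sample(50), sample(20)],
                                B[sample(50), ]), threshold = 0.05)
  expect_setequal(perm$nonvariable_ids, rep_$nonvariable_ids)
})

test_that("a CpG variable in only one cohort is kept as variable", {
  n <- 30
  A <- matrix(0.5, 3, n, dimnames = list(c("x", "y", "z"), NULL))
  B <- A
  A["y", ] <- 0.5 + seq(-0.01, 0.01, length.out = n)   # range 0.02 in A
  B["y", ] <- 0.5 + seq(-0.04, 0.04, length.out = n)   # range 0.08 in B
  rep_ <- nonvariable_cpgs(list(A, B))
  expect_true("y" %in% rep_$variable_ids)
  expect_setequal(rep_$nonvariable_ids, c("x", "z"))
})

test_that("reference CpG exclusion follows the bookkeeping contract", {
  m <- matrix(runif(40), 20, 2,
              dimnames = list(paste0("cg", 1:20), c("a", "b")))
  expect_identical(exclude_reference_cpgs(m, character(0)), m)
  expect_error(exclude_reference_cpgs(m, rownames(m)), "nothing remains")
  expect_equal(nrow(exclude_reference_cpgs(m, paste0("cg", 1:6))), 14)
})

test_that("principal components match a covariance-eigen oracle", {
  set.seed(21)
  X <- matrix(runif(200), 20, 10,
              dimnames = list(paste0("cg", 1:20), paste0("s", 1:10)))
  pc <- first_pcs(X, n_components = 3)
  # oracle: eigendecomposition of the sample Gram matrix of row-centred data
  Xc <- X - rowMeans(X)
  eg <- eigen(crossprod(Xc))
  for (j in 1:3) {
    oracle <- eg$vectors[, j] * sqrt(eg$values[j])
    expect_equal(abs(unname(pc$scores[, j])), abs(oracle),
                 tolerance = 1e-8)
  }
  expect_equal(pc$variance_explained,
               (eg$values / sum(eg$values))[1:3], tolerance = 1e-8)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
})

test_that("rank-1 and duplicated-sample geometries behave exactly", {
  g <- seq(0, 1, length.out = 8)
  X <- outer(runif(30), g)  # rank-1: one gradient
  rownames(X) <- paste0("cg", 1:30)
  pc <- first_pcs(X, 2)
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-9)
  set.seed(22)
  Y <- matrix(runif(60), 12, 5)
  Y <- cbind(Y, Y[, 3])  # duplicate sample
  rownames(Y) <- paste0("cg", 1:12)
  pc2 <- first_pcs(Y, 1)
  expect_equal(pc2$scores[3, 1], pc2$scores[6, 1], tolerance = 1e-10)
  expect_error(first_pcs(matrix(0.4, 5, 6)), "degenerate")
})

test_that("PC1 sign convention follows the mean-methylation gradient", {
  set.seed(23)
  # samples ordered by a global methylation gradient
  grad <- seq(0.2, 0.8, length.out = 10)
  X <- outer(rep(1, 40), grad) + matrix(rnorm(400, sd = 0.01), 40)
  rownames(X) <- paste0("cg", 1:40)
  pc <- first_pcs(X, 1)
  expect_gt(cor(pc$scores[, 1], colMeans(X)), 0)
})

test_that("3xIQR fences match hand-computed values", {
  sc <- c(1:20, 100, -100)
  names(sc) <- paste0("s", seq_along(sc))
  # sorted: -100, 1..20, 100 (n = 22); type-7 quartiles:
  # Q1 at pos 6.25 -> 5.25, Q3 at pos 16.75 -> 15.75, IQR 10.5,
  # fences [-26.25, 47.25]
  expect_setequal(pc1_outliers(sc), c("s21", "s22"))
  one <- c(rnorm(20), 50)
  names(one) <- paste0("s", 1:21)
  expect_identical(pc1_outliers(one), "s21")
  allsame <- setNames(rep(2, 10), paste0("s", 1:10))
  expect_length(pc1_outliers(allsame), 0)
})

test_that("the outlier rule flags a shifted subgroup in a cohort", {
  cfg <- cohort_config(n_samples = 60, n_cpgs = 500, n_markers = 200,
                       study_preset = "term-ITU", seed = 24)
  co <- generate_cohort(cfg)
  B <- co$betas
  shifted <- paste0("S", sprintf("%04d", 1:4))
  B[, shifted] <- pmin(B[, shifted] + 0.35, 1)  # gross aberrant subgroup
  pc <- first_pcs(B, 1)
  out <- pc1_outliers(pc$scores[, 1])
  expect_setequal(out, shifted)
  # the same samples show depressed average sample-sample correlation
  scr <- sample_correlation_screen(B)
  expect_true(all(rank(scr)[shifted] <= 8))
})

test_that("correlation screen matches hand-computed rank correlations", {
  m <- cbind(a = c(0.1, 0.5, 0.9, 0.2), b = c(0.2, 0.4, 0.8, 0.3),
             c = c(0.9, 0.1, 0.2, 0.8))
  rownames(m) <- paste0("cg", 1:4)
  scr <- sample_correlation_screen(m)
  # ranks: a and b identical orderings (rho 1); both anti-align with c
  # (rho -0.8): means (1 - 0.8)/2 = 0.1 for a and b, -0.8 for c
  expect_equal(unname(scr), c(0.1, 0.1, -0.8), tolerance = 1e-12)
  expect_length(scr, 3)
  dup <- cbind(m, d = m[, "a"])
  scr2 <- sample_correlation_screen(dup)
  expect_true(all(rank(-scr2)[c("a", "d")] <= 2))
})

test_that("PC1 tracks the true composition axis in a synthetic cohort", {
  cfg <- cohort_config(n_samples = 120, n_cpgs = 1500, n_markers = 500,
                       study_preset = "CVS-ITU", seed = 25)
  co <- generate_cohort(cfg)
  B <- exclude_reference_cpgs(co$betas, co$marker_ids)
  pc <- first_pcs(B, 1)
  axis <- prcomp(co$true_proportions)$x[, 1]
  expect_gt(abs(cor(pc$scores[, 1], axis)), 0.9)
})
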