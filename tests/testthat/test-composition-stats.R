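# Rank-based composition statistics: Spearman associations, paired
# signed-rank tests, relative effects, the permutation global test, and
# GA/sex associations.

test_that("Spearman associations reproduce exact and hand-ranked cases", {
  x <- 1:5
  A <- cbind(x = x, y = 5:1)
  res <- spearman_associations(A, A)
  expect_equal(res$rho["x", "x"], 1)
  expect_equal(res$rho["x", "y"], -1)
  expect_equal(res$p_raw["x", "y"], 0)
  # 6-point tied example against mid-rank Pearson computed by hand
  sx <- c(1, 2, 2, 3, 4, 5)
  sy <- c(2, 1, 3, 3, 5, 4)
  res2 <- spearman_associations(cbind(a = sx), cbind(b = sy))
  expect_equal(unname(res2$rho[1, 1]), 0.8088235, tolerance = 1e-7)
  # Bonferroni is a pure function of raw p and test count
  B <- matrix(rnorm(50), 10, 5)
  res3 <- spearman_associations(matrix(rnorm(30), 10, 3), B)
  expect_equal(res3$n_tests, 15)
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_raw * 15))
})

test_that("identical paired matrices give null statistics", {
  set.seed(34)
  p1 <- matrix(runif(8 * 3), 8, 3,
               dimnames = list(paste0("s", 1:8), c("A", "B", "C")))
  res <- suppressMessages(paired_celltype_tests(p1, p1))
  expect_equal(res$table$Z, rep(0, 3))
  expect_equal(res$table$p_raw, rep(1, 3))
  expect_equal(res$table$median_difference, rep(0, 3))
})

test_that("six positive differences match the enumerated signed-rank null", {
  d <- c(0.05, 0.1, 0.2, 0.07, 0.15, 0.3)
  expect_equal(exact_signed_rank_p(d, "greater"), 1 / 64)
  expect_equal(exact_signed_rank_p(d, "two.sided"), 2 / 64)
  # independent enumeration oracle written from scratch
  r <- rank(abs(d))
  grid <- expand.grid(rep(list(0:1), 6))
  W_all <- as.matrix(grid) %*% r
  expect_equal(mean(W_all >= sum(r)), 1 / 64)
  # the normal-approximation Z carries the direction (t1 larger -> Z > 0)
  t2 <- matrix(runif(6), 6, 1, dimnames = list(NULL, "A"))
  res <- paired_celltype_tests(t2 + d, t2)
  expect_gt(res$table$Z, 0)
  expect_lt(res$table$median_difference, 0)
})

test_that("exact signed-rank and Spearman p agree with stats oracles", {
  set.seed(35)
  d <- rnorm(8)
  while (any(duplicated(abs(d))) || any(d == 0)) d <- rnorm(8)
  oracle <- wilcox.test(d, exact = TRUE, correct = FALSE)$p.value
  expect_equal(exact_signed_rank_p(d), oracle, tolerance = 1e-12)
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.9)
  oracle2 <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  expect_equal(exact_spearman_p(x, y), oracle2, tolerance = 1e-12)
})

test_that("relative effects follow the mid-rank formula", {
  # identical values in both groups: exchangeable, effects exactly 0.5
  props <- matrix(rep(c(0.2, 0.5, 0.3), 2), 6, 1,
                  dimnames = list(NULL, "A"))
  eff <- relative_effects(props, rep(c("g1", "g2"), each = 3))
  expect_equal(unname(eff[, 1]), c(0.5, 0.5))
  # one group strictly above the other, n = 3 + 3: effect 0.75 by hand
  props2 <- matrix(c(10, 11, 12, 1, 2, 3), 6, 1,
                   dimnames = list(NULL, "A"))
  eff2 <- relative_effects(props2, rep(c("hi", "lo"), each = 3))
  expect_equal(unname(eff2["hi", 1]), 0.75)
  expect_equal(unname(eff2["lo", 1]), 0.25)
  # weighted mean is 0.5 per cell type; effects bounded in [0,1]
  set.seed(36)
  P <- matrix(runif(60), 20, 3)
  g <- sample(c("a", "b", "c"), 20, replace = TRUE, prob = c(.5, .3, .2))
  while (min(table(g)) < 3) g <- sample(c("a", "b", "c"), 20, TRUE)
  eff3 <- relative_effects(P, g)
  expect_true(all(eff3 >= 0 & eff3 <= 1))
  w <- as.vector(table(factor(g)))
  expect_equal(unname(colSums(eff3 * w) / sum(w)), rep(0.5, 3),
               tolerance = 1e-9)
})

test_that("the global rank test is deterministic with valid p range", {
  set.seed(37)
  P <- matrix(runif(30 * 4), 30, 4)
  g <- rep(c("a", "b"), each = 15)
  r1 <- global_rank_manova(P, g, n_permutations = 200, seed = 9)
  r2 <- global_rank_manova(P, g, n_permutations = 200, seed = 9)
  expect_identical(r1$p_permutation, r2$p_permutation)
  expect_gte(r1$p_permutation, 1 / 201)
  expect_lte(r1$p_permutation, 1)
  # identical values in all groups: statistic 0, p 1
  P0 <- matrix(0.25, 12, 2)
  r0 <- global_rank_manova(P0, rep(c("a", "b"), each = 6),
                           n_permutations = 100)
  expect_equal(r0$anova_type_statistic, 0)
  expect_equal(r0$p_permutation, 1)
  expect_error(global_rank_manova(P, rep(c("a", "b"), c(28, 2))),
               "at least 3")
})

test_that("clearly separated groups are detected", {
  set.seed(38)
  mk <- function(m, n = 20) t(vapply(seq_len(n), function(i) {
    a <- c(0.05, 0.05, 0.002, 0.05, 0.002, m)
    g <- rgamma(6, 150 * a / sum(a))
    g / sum(g)
  }, numeric(6)))
  P <- rbind(mk(0.93), mk(0.83), mk(0.66))
  g <- rep(c("x", "y", "z"), each = 20)
  r <- global_rank_manova(P, g, n_permutations = 499, seed = 10)
  expect_lt(r$p_permutation, 0.01)
  # the high-syncytio group has the largest relative effect in column 6
  expect_gt(r$relative_effects["x", 6], r$relative_effects["z", 6])
})

test_that("GA associations carry the expected signs and a clean null", {
  cfg <- cohort_config(n_samples = 1000, n_cpgs = 50, n_markers = 30,
                       study_preset = "CVS-ITU", ga_effect_size = 0.015,
                       seed = 39)
  set.seed(39)
  ph <- data.frame(sample_id = seq_len(1000),
                   gestational_age = runif(1000, 10, 15),
                   sex = rbinom(1000, 1, 0.5))
  props <- sample_proportions(cfg, ph)
  res <- ga_sex_associations(props, ph)
  tro <- res$ga[res$ga$cell_type == "Trophoblasts", ]
  syn <- res$ga[res$ga$cell_type == "Syncytiotrophoblasts", ]
  expect_lt(tro$rho, 0)
  expect_gt(syn$rho, 0)
  expect_true(tro$significant && syn$significant)
  # null calibration: no GA effect and no sex effect on proportions
  cfg0 <- cohort_config(n_samples = 300, n_cpgs = 50, n_markers = 30,
                        study_preset = "CVS-ITU", ga_effect_size = 0,
                        seed = 40)
  clean <- vapply(1:20, function(s) {
    set.seed(40 + s)
    ph0 <- data.frame(sample_id = seq_len(300),
                      gestational_age = runif(300, 10, 15),
                      sex = rbinom(300, 1, 0.5))
    p0 <- sample_proportions(cfg0, ph0)
    r0 <- ga_sex_associations(p0, ph0)
    all(r0$ga$p_bonferroni > 0.01) && !any(r0$sex$significant)
  }, logical(1))
  expect_gte(sum(clean), 19)
})
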