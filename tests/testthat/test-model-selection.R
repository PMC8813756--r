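# Design construction, repeated cross-validation, adjusted R-squared,
# per-CpG variance decomposition.

make_cv_inputs <- function(n = 60, seed = 26) {
  set.seed(seed)
  rb <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(6, c(5, 3, 1, 1, 1, 9))
    g / sum(g)
  }, numeric(6)))
  colnames(rb) <- PLACENTA_CELL_TYPES
  rf <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(3, 2)
    g / sum(g)
  }, numeric(3)))
  colnames(rf) <- paste0("C", 1:3)
  ph <- data.frame(sample_id = seq_len(n),
                   gestational_age = runif(n, 36, 41),
                   sex = rbinom(n, 1, 0.5),
                   ancestry1 = rnorm(n), ancestry2 = rnorm(n))
  list(rb = rb, rf = rf, ph = ph)
}

test_that("design matrices have the documented shapes", {
  inp <- make_cv_inputs()
  sp <- model_specs()
  expect_named(sp, c("intercept", "phenotypes", "ref_based",
                     "ref_based+phenotypes", "ref_free",
                     "ref_free+phenotypes"))
  d1 <- build_model_matrix(sp$intercept, inp$rb, inp$rf, inp$ph)
  expect_equal(ncol(d1), 1)
  expect_true(all(d1 == 1))
  d3 <- build_model_matrix(sp$ref_based, inp$rb, inp$rf, inp$ph)
  expect_equal(ncol(d3), 1 + 5)   # simplex block drops one column
  # the dropped column is the largest-mean cell type
  expect_false(any(grepl("Syncytiotrophoblasts", colnames(d3))))
  d4 <- build_model_matrix(sp$`ref_based+phenotypes`, inp$rb, inp$rf,
                           inp$ph)
  expect_equal(ncol(d4), 1 + 5 + 1 + 1 + 2)
  # complete-case removal
  ph2 <- inp$ph
  ph2$gestational_age[3] <- NA
  suppressMessages(
    d2 <- build_model_matrix(sp$phenotypes, inp$rb, inp$rf, ph2))
  expect_equal(nrow(d2), nrow(inp$ph) - 1)
  expect_false(3 %in% attr(d2, "rows_kept"))
})

test_that("adjusted R-squared matches closed-form values", {
  x <- 1:6
  y <- c(2, 1, 4, 3, 6, 5)
  # hand-solved simple regression: r^2 = cor^2 = 0.6865306,
  # adjusted = 1 - (1 - r^2) * 5 / 4 = 0.6081633
  expect_equal(adjusted_r2(y, cbind(1, x)), 0.6081633, tolerance = 1e-6)
  expect_equal(adjusted_r2(y, cbind(1, y)), 1)
  expect_equal(adjusted_r2(y, matrix(1, 6, 1)), 0)
})

test_that("unadjusted fit never degrades when predictors are added", {
  inp <- make_cv_inputs(seed = 27)
  set.seed(27)
  y <- rnorm(60)
  sp <- model_specs()
  r2_of <- function(spec) {
    X <- build_model_matrix(spec, inp$rb, inp$rf, inp$ph)
    f <- lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  expect_lte(r2_of(sp$intercept), r2_of(sp$phenotypes) + 1e-12)
  expect_lte(r2_of(sp$ref_based),
             r2_of(sp$`ref_based+phenotypes`) + 1e-12)
  expect_lte(r2_of(sp$ref_free), r2_of(sp$`ref_free+phenotypes`) + 1e-12)
})

test_that("duplicate models share partitions and ties go to the earlier", {
  inp <- make_cv_inputs(seed = 28)
  set.seed(28)
  y <- rnorm(60)
  X <- build_model_matrix(model_specs()$phenotypes, inp$rb, inp$rf, inp$ph)
  cv <- repeated_cv(y, list(first = X, second = X), folds = 5,
                    repeats = 20, seed = 28)
  # identical designs under shared partitions -> identical RMSE paths
  expect_equal(cv$rmse[, 1], cv$rmse[, 2], tolerance = 1e-12)
  expect_equal(unname(cv$wins), c(20, 0))
  expect_equal(sum(cv$wins), cv$repeats)
  expect_equal(sum(cv$win_proportions), 1)
  expect_true(all(cv$rmse >= 0))
})

test_that("intercept-only RMSE approximates the outcome SD", {
  set.seed(29)
  y <- rnorm(300)
  X <- matrix(1, 300, 1)
  cv <- repeated_cv(y, list(intercept = X), folds = 10, repeats = 20,
                    seed = 29)
  expect_equal(unname(cv$mean_rmse), sd(y), tolerance = 0.05 * sd(y))
})

test_that("data generated from a model family is won by that family", {
  inp <- make_cv_inputs(n = 200, seed = 30)
  set.seed(30)
  sp <- model_specs()
  designs <- lapply(sp, build_model_matrix, proportions_rb = inp$rb,
                    omega_rf = inp$rf, phenotypes = inp$ph)
  # truth: phenotype-driven outcome with noise at 20% of the signal SD
  Xp <- designs$phenotypes
  signal <- as.vector(Xp %*% c(0, 1, 0.8, 0.5, -0.5))
  y <- signal + rnorm(200, sd = 0.2 * sd(signal))
  cv <- repeated_cv(y, designs, folds = 10, repeats = 30, seed = 30)
  fam <- sum(cv$win_proportions[c("phenotypes", "ref_based+phenotypes",
                                  "ref_free+phenotypes")])
  expect_gte(fam, 0.7)
})

test_that("ridge fallback keeps singular folds finite", {
  set.seed(31)
  y <- rnorm(40)
  X <- cbind(1, rnorm(40))
  X <- cbind(X, X[, 2])  # exactly collinear pair
  cv <- repeated_cv(y, list(singular = X), folds = 5, repeats = 5,
                    seed = 31)
  expect_true(all(is.finite(cv$rmse)))
})

test_that("per-CpG adjusted R-squared has the documented limits", {
  inp <- make_cv_inputs(n = 200, seed = 32)
  sp <- model_specs()
  drb <- build_model_matrix(sp$ref_based, inp$rb, inp$rf, inp$ph)
  drf <- build_model_matrix(sp$ref_free, inp$rb, inp$rf, inp$ph)
  set.seed(32)
  # 1000 pure-noise CpGs plus one exact linear combination of predictors
  betas <- matrix(runif(1001 * 200), 1001, 200,
                  dimnames = list(paste0("cg", 1:1001), NULL))
  betas[1001, ] <- as.vector(drb %*% c(0.5, 0.2, 0.1, 0, 0.05, 0.1))
  r2 <- per_cpg_r2(betas, drb, drf)
  expect_equal(nrow(r2), 1001)
  expect_gt(r2$r2_ref_based[1001], 0.999)
  expect_equal(mean(r2$r2_ref_based[1:1000]), 0, tolerance = 0.01)
  expect_equal(mean(r2$r2_ref_free[1:1000]), 0, tolerance = 0.01)
})

test_that("high-R2 intersection uses a strict threshold in every set", {
  tabs <- list(c(a = 0.31, b = 0.30, c = 0.4, d = 0.5),
               c(a = 0.4, b = 0.9, c = 0.31, d = 0.1),
               c(a = 0.5, b = 0.8, c = 0.35, d = 0.9))
  expect_setequal(high_r2_intersection(tabs), c("a", "c"))
  expect_setequal(high_r2_intersection(rev(tabs)), c("a", "c"))
  # brute-force set oracle on random tables
  set.seed(33)
  rnd <- lapply(1:4, function(i)
    setNames(runif(50), paste0("cg", 1:50)))
  got <- high_r2_intersection(rnd, threshold = 0.30)
  oracle <- paste0("cg", which(Reduce(`&`, lapply(rnd, function(v)
    v > 0.30))))
  expect_setequal(got, oracle)
})
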