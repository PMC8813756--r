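# End-to-end benchmark: simulate cohorts, filter, extract PCs, deconvolve
# both ways, compare predictive models, and run the composition statistics,
# with deterministic seeds and machine-readable reports.

#' Benchmark configuration
#'
#' @param cohorts Named list of [cohort_config()] objects; defaults to the
#'   four study presets at a desk-scale size (150 samples, 2000 CpGs, 600
#'   markers each) with seeds derived from `seed`.
#' @param filter_threshold Non-variable CpG range threshold.
#' @param cv_folds,cv_repeats Cross-validation size.
#' @param k_range Candidate component counts for the reference-free fit.
#' @param n_boot Bootstrap resamples in the K selection.
#' @param n_permutations Permutations for the global group test.
#' @param alpha Significance threshold for adjusted tests.
#' @param n_paired Number of emulated paired first-trimester/term samples.
#' @param seed Master seed.
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(cohorts = NULL, filter_threshold = 0.05,
                             cv_folds = 10, cv_repeats = 100,
                             k_range = 2:5, n_boot = 3,
                             n_permutations = 999, alpha = 0.01,
                             n_paired = 85, seed = 1L) {
  if (is.null(cohorts)) {
    presets <- c("CVS-ITU", "term-ITU", "term-PREDO", "term-BET")
    cohorts <- lapply(seq_along(presets), function(i)
      cohort_config(n_samples = 150, n_cpgs = 2000, n_markers = 600,
                    study_preset = presets[i], seed = seed + i))
    names(cohorts) <- presets
  }
  stopifnot(length(cohorts) >= 1,
            all(vapply(cohorts, inherits, TRUE, "cohort_config")))
  if (is.null(names(cohorts)))
    names(cohorts) <- vapply(cohorts, `[[`, "", "study_preset")
  structure(list(cohorts = cohorts, filter_threshold = filter_threshold,
                 cv_folds = cv_folds, cv_repeats = cv_repeats,
                 k_range = k_range, n_boot = n_boot,
                 n_permutations = n_permutations, alpha = alpha,
                 n_paired = n_paired, seed = as.integer(seed)),
            class = "benchmark_config")
}

.log_stage <- function(log, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  c(log, list(entry))
}

#' Run the full benchmark
#'
#' Per cohort the stage order is: generate -> exclude reference marker
#' CpGs -> non-variable CpG filter (identified jointly across all
#' cohorts) -> PCA -> PC1 outlier removal -> recompute PCs ->
#' reference-based and reference-free deconvolution -> repeated-CV model
#' comparison -> per-CpG variance decomposition. Cross-cohort analyses
#' follow: high-R-squared CpG intersection, global rank-based comparison
#' of the term cohorts, an emulated paired first-trimester/term design,
#' and gestational-age/sex associations. Fully deterministic given the
#' configured seeds.
#'
#' @param config A [benchmark_config()].
#' @param out_dir Optional directory; when given, all stage artifacts and
#'   the JSON report are written there.
#' @param verbose Print stage progress.
#' @return Object of class `benchmark_report` (nested list of stage
#'   results plus a structured `log`).
#' @export
run_benchmark <- function(config = benchmark_config(), out_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(config, "benchmark_config"))
  say <- function(...) if (verbose) message(...)
  log <- list()
  say("generating ", length(config$cohorts), " cohort(s)")
  cohorts <- lapply(config$cohorts, generate_cohort)
  log <- .log_stage(log, "simulate", cohorts = names(cohorts),
                    seeds = vapply(config$cohorts, `[[`, 0L, "seed"))

  # joint non-variable CpG identification on marker-free matrices
  nomarker <- lapply(cohorts, function(co)
    exclude_reference_cpgs(co$betas, co$marker_ids))
  filt <- nonvariable_cpgs(nomarker, threshold = config$filter_threshold)
  log <- .log_stage(log, "filter",
                    nonvariable = length(filt$nonvariable_ids),
                    variable = length(filt$variable_ids))
  say("non-variable CpGs: ", length(filt$nonvariable_ids))

  per_cohort <- list()
  r2_tables <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    B <- nomarker[[nm]][filt$variable_ids, , drop = FALSE]
    pc0 <- first_pcs(B, n_components = 2)
    out_samples <- pc1_outliers(pc0$scores[, 1])
    keep <- setdiff(colnames(B), out_samples)
    B <- B[, keep, drop = FALSE]
    pc <- first_pcs(B, n_components = 2)
    log <- .log_stage(log, "pca", cohort = nm,
                      excluded_samples = length(out_samples),
                      pc1_variance = pc$variance_explained[1])
    say(nm, ": ", length(out_samples), " PC1 outlier(s) removed; PC1 ",
        round(100 * pc$variance_explained[1], 1), "% variance")

    dc <- deconvolve_cohort(co$betas[, keep, drop = FALSE], co$reference,
                            method = "rpc")
    ph <- co$phenotypes[match(keep, co$phenotypes$sample_id), ,
                        drop = FALSE]
    sel <- select_k(B, k_range = config$k_range, n_boot = config$n_boot,
                    n_top_variable_cpgs = 1000,
                    seed = config$seed + match(nm, names(cohorts)))
    rf <- reffree_factorize(B, sel$K, n_top_variable_cpgs = 1000,
                            seed = config$seed)
    log <- .log_stage(log, "deconvolution", cohort = nm,
                      markers_used = dc$n_markers_used, k_selected = sel$K)

    specs <- model_specs()
    designs <- lapply(specs, build_model_matrix,
                      proportions_rb = dc$proportions, omega_rf = rf$Omega,
                      phenotypes = ph)
    cv <- repeated_cv(pc$scores[, 1], designs, folds = config$cv_folds,
                      repeats = config$cv_repeats,
                      seed = config$seed + 100 + match(nm, names(cohorts)))
    say(nm, ": CV winner ", cv$winner)

    r2 <- per_cpg_r2(B, designs[["ref_based"]], designs[["ref_free"]])
    r2_tables[[nm]] <- stats::setNames(r2$r2_ref_based, r2$cpg_id)
    assoc <- ga_sex_associations(dc$proportions, ph, alpha = config$alpha)
    per_cohort[[nm]] <- list(
      n_samples = length(keep), excluded_samples = out_samples,
      pc1_variance_explained = pc$variance_explained[1],
      mean_composition = colMeans(dc$proportions),
      k_selected = sel$K, k_deviance_table = sel$deviance_table,
      cv = cv, r2_summary = c(mean = mean(r2$r2_ref_based),
                              sd = stats::sd(r2$r2_ref_based)),
      ga_sex = assoc,
      proportions = dc$proportions, omega = rf$Omega,
      pc1 = pc$scores[, 1], phenotypes = ph)
  }

  high_r2 <- high_r2_intersection(r2_tables, threshold = 0.30)
  log <- .log_stage(log, "per_cpg_r2", high_r2 = length(high_r2))

  term <- names(cohorts)[!grepl("^CVS", names(cohorts))]
  group_test <- NULL
  if (length(term) >= 2) {
    props <- do.call(rbind, lapply(term, function(nm)
      per_cohort[[nm]]$proportions))
    labels <- rep(term, vapply(term, function(nm)
      nrow(per_cohort[[nm]]$proportions), 0L))
    group_test <- global_rank_manova(props, labels,
                                     n_permutations = config$n_permutations,
                                     seed = config$seed + 500)
    log <- .log_stage(log, "group_comparison",
                      p = group_test$p_permutation)
  }

  paired <- NULL
  if (config$n_paired >= 6) {
    pp <- generate_paired_proportions(n_pairs = config$n_paired,
                                      seed = config$seed + 900)
    paired <- paired_celltype_tests(pp$t1, pp$t2, alpha = config$alpha)
    log <- .log_stage(log, "paired_comparison", n_pairs = config$n_paired)
  }

  report <- structure(list(per_cohort = per_cohort,
                           filter = list(
                             nonvariable = length(filt$nonvariable_ids),
                             variable = length(filt$variable_ids),
                             threshold = config$filter_threshold),
                           high_r2_cpgs = high_r2,
                           group_comparison = group_test,
                           paired_comparison = paired,
                           config = config, log = log),
                      class = "benchmark_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Deconvolution benchmark over ", length(x$per_cohort),
      " cohort(s)\n", sep = "")
  for (nm in names(x$per_cohort)) {
    pc <- x$per_cohort[[nm]]
    cat("  ", nm, ": n = ", pc$n_samples, ", PC1 ",
        round(100 * pc$pc1_variance_explained, 1), "% variance, K = ",
        pc$k_selected, ", CV winner ", pc$cv$winner, " (",
        round(100 * max(pc$cv$win_proportions)), "% of wins)\n", sep = "")
  }
  cat("  non-variable CpGs: ", x$filter$nonvariable,
      "; high-R2 CpGs in all cohorts: ", length(x$high_r2_cpgs), "\n",
      sep = "")
  if (!is.null(x$group_comparison))
    cat("  term-cohort group comparison p = ",
        signif(x$group_comparison$p_permutation, 3), "\n", sep = "")
  invisible(x)
}

# strip heavy matrices for the JSON report
.report_as_list <- function(report) {
  pc <- lapply(report$per_cohort, function(x) list(
    n_samples = x$n_samples,
    excluded_samples = x$excluded_samples,
    pc1_variance_explained = x$pc1_variance_explained,
    mean_composition = as.list(x$mean_composition),
    k_selected = x$k_selected,
    k_deviance_table = x$k_deviance_table,
    cv = list(wins = as.list(x$cv$wins),
              win_proportions = as.list(x$cv$win_proportions),
              mean_rmse = as.list(x$cv$mean_rmse),
              winner = x$cv$winner,
              winner_adjusted_r2 = x$cv$winner_adjusted_r2,
              folds = x$cv$folds, repeats = x$cv$repeats),
    r2_summary = as.list(x$r2_summary),
    ga = x$ga_sex$ga, sex = x$ga_sex$sex))
  out <- list(per_cohort = pc, filter = report$filter,
              n_high_r2_cpgs = length(report$high_r2_cpgs),
              log = report$log)
  if (!is.null(report$group_comparison))
    out$group_comparison <- list(
      anova_type_statistic = report$group_comparison$anova_type_statistic,
      p_permutation = report$group_comparison$p_permutation,
      relative_effects = as.data.frame(report$group_comparison$relative_effects))
  if (!is.null(report$paired_comparison))
    out$paired_comparison <- report$paired_comparison$table
  out
}

#' Write a benchmark report to disk
#'
#' Writes `report.json` plus per-cohort `proportions_<cohort>.csv`,
#' `omega_<cohort>.csv` and `pc1_<cohort>.csv` files.
#'
#' @param report A `benchmark_report`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(.report_as_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(report$per_cohort)) {
    x <- report$per_cohort[[nm]]
    tag <- gsub("[^A-Za-z0-9]+", "_", nm)
    utils::write.csv(data.frame(sample_id = rownames(x$proportions),
                                x$proportions, check.names = FALSE),
                     file.path(dir, paste0("proportions_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = rownames(x$omega), x$omega,
                                check.names = FALSE),
                     file.path(dir, paste0("omega_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = names(x$pc1), pc1 = x$pc1),
                     file.path(dir, paste0("pc1_", tag, ".csv")),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Generate an emulated paired first-trimester/term composition design
#'
#' Draws first-trimester compositions from the CVS preset, shifts each
#' individual's composition by the median first-trimester-to-term changes
#' (trophoblasts -24.8, stromal -17.4, endothelial +0.4, nRBC +3.2,
#' syncytiotrophoblasts +38.4 percentage points), floors at 1e-4,
#' renormalises, and redraws the term composition from a Dirichlet centred
#' on the shifted value — so pairs are correlated through the shared
#' first-trimester draw.
#'
#' @param n_pairs Number of individuals; default 85.
#' @param shift Named shift vector (fractions, not percent) added to the
#'   first-trimester composition.
#' @param concentration Dirichlet concentration for both draws.
#' @param seed Integer seed.
#' @return List with matrices `t1` and `t2` (samples x cell types).
#' @export
generate_paired_proportions <- function(n_pairs = 85,
                                        shift = c(Trophoblasts = -0.248,
                                                  Stromal = -0.174,
                                                  Hofbauer = 0,
                                                  Endothelial = 0.004,
                                                  nRBC = 0.032,
                                                  Syncytiotrophoblasts = 0.384),
                                        concentration = 150, seed = 1L) {
  stopifnot(n_pairs >= 6)
  set.seed(seed)
  mean_t1 <- preset_composition("CVS-ITU")
  stopifnot(identical(names(shift), names(mean_t1)))
  t1 <- .rdirichlet_rows(matrix(mean_t1 * concentration, n_pairs,
                                length(mean_t1), byrow = TRUE))
  m2 <- pmax(sweep(t1, 2, shift, `+`), 1e-4)
  m2 <- m2 / rowSums(m2)
  t2 <- .rdirichlet_rows(m2 * concentration)
  ids <- sprintf("P%04d", seq_len(n_pairs))
  dimnames(t1) <- dimnames(t2) <- list(ids, names(mean_t1))
  list(t1 = t1, t2 = t2)
}
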