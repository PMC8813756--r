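# Synthetic placental methylation cohorts with known cell composition.
#
# The generator emulates the statistical structure that downstream analyses
# assume: six placental cell types whose study-specific mean compositions and
# gestational ages follow published cohort characteristics, marker CpGs with
# cell-type-distinct methylation, a trimodal "background" beta landscape, and
# additive beta-scale noise. Ground-truth proportions are retained so every
# estimator can be checked by parameter recovery.

#' Placental cell types used throughout the package
#' @export
PLACENTA_CELL_TYPES <- c("Trophoblasts", "Stromal", "Hofbauer",
                         "Endothelial", "nRBC", "Syncytiotrophoblasts")

# Study presets: mean composition (zero entries floored at 0.002 and
# renormalised so Dirichlet parameters stay positive), gestational-age
# location/spread in weeks, and the per-week composition shift between
# trophoblasts and syncytiotrophoblasts used by default.
.study_presets <- function() {
  list(
    "CVS-ITU" = list(
      mean = c(0.26, 0.17, 0.002, 0.002, 0.002, 0.57),
      ga_mean = 12.79, ga_sd = 0.82, ga_range = c(10, 15),
      ga_effect_size = 0.015, n_samples = 264),
    "term-ITU" = list(
      mean = c(0.01, 0.01, 0.002, 0.01, 0.04, 0.93),
      ga_mean = 39.99, ga_sd = 1.55, ga_range = c(36, 43),
      ga_effect_size = 0.002, n_samples = 470),
    "term-PREDO" = list(
      mean = c(0.04, 0.04, 0.002, 0.08, 0.002, 0.83),
      ga_mean = 39.89, ga_sd = 1.43, ga_range = c(36, 43),
      ga_effect_size = 0.002, n_samples = 139),
    "term-BET" = list(
      mean = c(0.13, 0.11, 0.002, 0.11, 0.002, 0.66),
      ga_mean = 38.16, ga_sd = 1.95, ga_range = c(33, 42),
      ga_effect_size = 0.012, n_samples = 137)
  )
}

#' Mean cell-type composition of a study preset
#'
#' @param preset One of `"CVS-ITU"`, `"term-ITU"`, `"term-PREDO"`,
#'   `"term-BET"`.
#' @return Named numeric vector over the six placental cell types, summing
#'   to 1. Cell types with a reported mean of zero carry a small positive
#'   floor (0.002) so that Dirichlet sampling is well defined.
#' @export
preset_composition <- function(preset) {
  ps <- .study_presets()
  if (!preset %in% names(ps))
    stop("unknown study preset '", preset, "'; available: ",
         paste(names(ps), collapse = ", "))
  m <- ps[[preset]]$mean
  names(m) <- PLACENTA_CELL_TYPES
  m / sum(m)
}

#' Cohort generator configuration
#'
#' Bundles all knobs of the synthetic-cohort generator with validation.
#' Defaults reflect the emulated study conditions: Dirichlet concentration
#' 150 (per-type SDs of roughly 0.02-0.08 around the preset means), i.i.d.
#' Gaussian beta-scale noise with sd 0.02, a per-week gestational-age shift
#' of composition moved between trophoblasts and syncytiotrophoblasts, and a
#' +/-0.03 sex offset on 1% of CpGs.
#'
#' @param n_samples Number of samples. Defaults to the preset's cohort size.
#' @param n_cpgs Total number of CpGs (markers included).
#' @param n_markers Number of marker CpGs carried by the reference.
#' @param study_preset Study preset name or `"custom"`.
#' @param mean_composition Required when `study_preset = "custom"`: named
#'   mean composition vector summing to 1.
#' @param dirichlet_concentration Positive scalar; Dirichlet parameters are
#'   `mean * concentration`.
#' @param noise_sd Beta-scale Gaussian noise standard deviation.
#' @param contaminate_fraction Fraction of CpGs given heavy-tailed noise
#'   (sd 0.2) instead, exercising robustness of the estimators.
#' @param ga_range Gestational-age interval in weeks.
#' @param ga_mean,ga_sd Location and spread of the (truncated normal)
#'   gestational-age distribution; preset defaults.
#' @param ga_effect_size Per-week shift of the mean trophoblast fraction
#'   (downward) and syncytiotrophoblast fraction (upward).
#' @param sex_effect_cpg_fraction Fraction of CpGs carrying a +/-0.03
#'   methylation offset in males.
#' @param responsive_cpg_fraction Fraction of non-marker CpGs whose
#'   cell-type profiles deviate from the shared base value (Gaussian
#'   per-type offsets of sd `responsive_sd`), so that bulk methylation
#'   outside the reference markers also tracks composition, as in real
#'   tissue.
#' @param responsive_sd Standard deviation of the per-type offsets at
#'   responsive CpGs.
#' @param n_ancestry_components Number of ancestry covariate columns.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = NULL, n_cpgs = 2000, n_markers = 600,
                          study_preset = "CVS-ITU", mean_composition = NULL,
                          dirichlet_concentration = 150, noise_sd = 0.02,
                          contaminate_fraction = 0,
                          ga_range = NULL, ga_mean = NULL, ga_sd = NULL,
                          ga_effect_size = NULL,
                          sex_effect_cpg_fraction = 0.01,
                          responsive_cpg_fraction = 0.3,
                          responsive_sd = 0.25,
                          n_ancestry_components = 2, seed = 1L) {
  presets <- .study_presets()
  if (study_preset == "custom") {
    if (is.null(mean_composition))
      stop("study_preset = 'custom' requires mean_composition")
    if (abs(sum(mean_composition) - 1) > 1e-8)
      stop("mean_composition must sum to 1")
    mean_vec <- mean_composition
    if (is.null(names(mean_vec)))
      names(mean_vec) <- paste0("Type", seq_along(mean_vec))
    if (is.null(ga_range)) ga_range <- c(36, 42)
    if (is.null(ga_mean)) ga_mean <- mean(ga_range)
    if (is.null(ga_sd)) ga_sd <- diff(ga_range) / 4
    if (is.null(ga_effect_size)) ga_effect_size <- 0
    if (is.null(n_samples)) n_samples <- 150L
  } else {
    ps <- presets[[study_preset]]
    if (is.null(ps))
      stop("unknown study preset '", study_preset, "'")
    mean_vec <- preset_composition(study_preset)
    if (is.null(ga_range)) ga_range <- ps$ga_range
    if (is.null(ga_mean)) ga_mean <- ps$ga_mean
    if (is.null(ga_sd)) ga_sd <- ps$ga_sd
    if (is.null(ga_effect_size)) ga_effect_size <- ps$ga_effect_size
    if (is.null(n_samples)) n_samples <- ps$n_samples
  }
  stopifnot(n_markers <= n_cpgs, noise_sd >= 0,
            ga_range[1] < ga_range[2], dirichlet_concentration > 0,
            sex_effect_cpg_fraction >= 0, sex_effect_cpg_fraction <= 1,
            contaminate_fraction >= 0, contaminate_fraction <= 1,
            responsive_cpg_fraction >= 0, responsive_cpg_fraction <= 1,
            responsive_sd >= 0)
  structure(list(
    n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
    n_markers = as.integer(n_markers), study_preset = study_preset,
    mean_composition = mean_vec,
    dirichlet_concentration = dirichlet_concentration,
    noise_sd = noise_sd, contaminate_fraction = contaminate_fraction,
    ga_range = ga_range, ga_mean = ga_mean, ga_sd = ga_sd,
    ga_effect_size = ga_effect_size,
    sex_effect_cpg_fraction = sex_effect_cpg_fraction,
    responsive_cpg_fraction = responsive_cpg_fraction,
    responsive_sd = responsive_sd,
    n_ancestry_components = as.integer(n_ancestry_components),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Generate cell-type reference profiles
#'
#' Builds a full CpG-by-cell-type beta profile matrix. Non-marker CpGs share
#' a common base profile drawn from a trimodal mixture (Beta(0.5,5),
#' Beta(5,5), Beta(5,0.5)) mimicking the usual beta-value landscape. Each
#' marker CpG is assigned (round-robin) to one cell type that is uniquely
#' hyper- or hypo-methylated there, with an absolute separation of at least
#' 0.5 from the shared level of the remaining types.
#'
#' @param n_cpgs Total CpG count.
#' @param n_markers Number of marker CpGs (must be at least 10 per type).
#' @param cell_types Character vector of at least two cell-type names.
#' @param seed Integer seed.
#' @return Object of class `reference_profiles` with elements `profiles`
#'   (n_cpgs x K full matrix), `markers` (n_markers x K reference matrix for
#'   deconvolution), `marker_ids`, `cpg_ids`, `cell_types`, `base_profile`.
#' @export
make_reference_profiles <- function(n_cpgs, n_markers, cell_types,
                                    seed = 1L) {
  K <- length(cell_types)
  if (K < 1) stop("cell_types must be non-empty")
  if (n_markers < K)
    stop("invalid design: n_markers (", n_markers,
         ") is smaller than the number of cell types (", K, ")")
  if (K >= 2 && n_markers < 10 * K)
    warning("fewer than 10 markers per cell type; reference may be weak")
  if (n_markers > n_cpgs) stop("n_markers must not exceed n_cpgs")
  set.seed(seed)
  cpg_ids <- sprintf("cg%07d", seq_len(n_cpgs))
  # trimodal base landscape: mostly unmethylated / intermediate / methylated
  comp <- sample.int(3, n_cpgs, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  base <- numeric(n_cpgs)
  base[comp == 1] <- stats::rbeta(sum(comp == 1), 0.5, 5)
  base[comp == 2] <- stats::rbeta(sum(comp == 2), 5, 5)
  base[comp == 3] <- stats::rbeta(sum(comp == 3), 5, 0.5)
  profiles <- matrix(base, n_cpgs, K, dimnames = list(cpg_ids, cell_types))
  marker_idx <- seq_len(n_markers)  # markers occupy the leading block
  if (K >= 2) {
    owner <- rep_len(seq_len(K), n_markers)        # round-robin assignment
    hyper <- rep_len(c(TRUE, FALSE), n_markers)    # alternate direction
    others <- stats::runif(n_markers, 0.05, 0.20)  # shared level of others
    sep <- stats::runif(n_markers, 0.55, 0.78)     # guaranteed >= 0.5 split
    lev_others <- ifelse(hyper, others, 1 - others)
    lev_owner <- ifelse(hyper, others + sep, 1 - others - sep)
    for (j in seq_len(n_markers)) {
      profiles[j, ] <- lev_others[j]
      profiles[j, owner[j]] <- lev_owner[j]
    }
  }
  profiles <- pmin(pmax(profiles, 0), 1)
  structure(list(
    profiles = profiles,
    markers = profiles[marker_idx, , drop = FALSE],
    marker_ids = cpg_ids[marker_idx],
    cpg_ids = cpg_ids,
    cell_types = cell_types,
    base_profile = base
  ), class = "reference_profiles")
}

# Dirichlet draw: one row per row of the alpha matrix.
.rdirichlet_rows <- function(alpha) {
  g <- matrix(stats::rgamma(length(alpha), shape = alpha),
              nrow(alpha), ncol(alpha))
  # a zero row cannot occur for alpha > 0 except by underflow; guard anyway
  rs <- rowSums(g)
  bad <- rs == 0
  if (any(bad)) {
    g[bad, ] <- 1
    rs[bad] <- ncol(alpha)
  }
  g / rs
}

#' Draw ground-truth cell-type proportions
#'
#' Each sample's composition is Dirichlet with mean equal to the preset (or
#' custom) mean shifted along gestational age: per week above the preset GA
#' centre the trophoblast mean decreases and the syncytiotrophoblast mean
#' increases by `ga_effect_size`, after which the mean is floored at 1e-4
#' and renormalised.
#'
#' @param config A [cohort_config()].
#' @param phenotypes Data frame with at least a `gestational_age` column
#'   (weeks), one row per sample.
#' @return Matrix (samples x cell types) with rows on the unit simplex.
#' @export
sample_proportions <- function(config, phenotypes) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(phenotypes)
  mean_vec <- config$mean_composition
  K <- length(mean_vec)
  alpha_mean <- matrix(mean_vec, n, K, byrow = TRUE,
                       dimnames = list(phenotypes$sample_id, names(mean_vec)))
  if (config$ga_effect_size != 0 &&
      all(c("Trophoblasts", "Syncytiotrophoblasts") %in% names(mean_vec))) {
    dga <- phenotypes$gestational_age - config$ga_mean
    shift <- config$ga_effect_size * dga
    alpha_mean[, "Trophoblasts"] <- alpha_mean[, "Trophoblasts"] - shift
    alpha_mean[, "Syncytiotrophoblasts"] <-
      alpha_mean[, "Syncytiotrophoblasts"] + shift
    if (any(alpha_mean < 1e-4)) {
      warning("GA-shifted mean composition clipped at 1e-4 for ",
              sum(rowSums(alpha_mean < 1e-4) > 0), " sample(s)")
      alpha_mean <- pmax(alpha_mean, 1e-4)
    }
    alpha_mean <- alpha_mean / rowSums(alpha_mean)
  }
  p <- .rdirichlet_rows(alpha_mean * config$dirichlet_concentration)
  dimnames(p) <- dimnames(alpha_mean)
  p
}

#' Mix cell-type profiles into bulk beta values
#'
#' Bulk methylation is the convex combination of cell-type profiles weighted
#' by the sample's true proportions, plus an optional +/-0.03 sex offset on
#' a designated CpG subset and additive Gaussian noise, clipped to [0,1].
#'
#' @param profiles Full CpG x cell-type profile matrix.
#' @param true_proportions Samples x cell-type matrix, rows summing to 1.
#' @param noise_sd Gaussian noise sd on the beta scale.
#' @param sex Optional 0/1 vector (1 = male) per sample.
#' @param sex_effect_cpgs Optional integer/logical index of CpGs carrying
#'   the sex offset.
#' @param contaminate_cpgs Optional index of CpGs given heavy-tailed noise
#'   (sd 0.2) instead of `noise_sd`.
#' @return CpG x sample beta matrix in [0,1].
#' @export
synthesize_betas <- function(profiles, true_proportions, noise_sd = 0,
                             sex = NULL, sex_effect_cpgs = NULL,
                             contaminate_cpgs = NULL) {
  stopifnot(ncol(profiles) == ncol(true_proportions), noise_sd >= 0)
  betas <- profiles %*% t(true_proportions)
  if (!is.null(sex) && length(sex_effect_cpgs)) {
    idx <- sex_effect_cpgs
    off <- rep_len(c(0.03, -0.03), length(idx))   # half hyper, half hypo
    betas[idx, sex == 1] <- betas[idx, sex == 1] + off
  }
  if (noise_sd > 0)
    betas <- betas + stats::rnorm(length(betas), sd = noise_sd)
  if (length(contaminate_cpgs))
    betas[contaminate_cpgs, ] <- betas[contaminate_cpgs, ] +
      stats::rnorm(length(contaminate_cpgs) * ncol(betas), sd = 0.2)
  betas <- pmin(pmax(betas, 0), 1)
  rownames(betas) <- rownames(profiles)
  colnames(betas) <- rownames(true_proportions)
  betas
}

# truncated-normal GA draw by rejection
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a complete synthetic cohort
#'
#' Deterministically (given `config$seed`) builds reference profiles,
#' phenotypes, ground-truth proportions and the bulk beta matrix, bundled
#' with every piece needed by downstream modules.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort` with elements `betas` (CpG x
#'   sample), `true_proportions` (sample x cell type), `phenotypes` (data
#'   frame), `reference` (marker CpG x cell type), `profiles`, `marker_ids`,
#'   `sex_effect_cpgs`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3)
  ref <- make_reference_profiles(config$n_cpgs, config$n_markers,
                                 names(config$mean_composition),
                                 seed = sub_seeds[1])
  set.seed(sub_seeds[2])
  n <- config$n_samples
  phenotypes <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    gestational_age = .rtruncnorm(n, config$ga_mean, config$ga_sd,
                                  config$ga_range[1], config$ga_range[2]),
    sex = stats::rbinom(n, 1, 0.5),
    study = config$study_preset,
    stringsAsFactors = FALSE
  )
  if (config$n_ancestry_components > 0) {
    anc <- matrix(stats::rnorm(n * config$n_ancestry_components), n,
                  dimnames = list(NULL,
                    paste0("ancestry", seq_len(config$n_ancestry_components))))
    phenotypes <- cbind(phenotypes, as.data.frame(anc))
  }
  props <- sample_proportions(config, phenotypes)
  rownames(props) <- phenotypes$sample_id
  set.seed(sub_seeds[3])
  non_marker <- setdiff(seq_len(config$n_cpgs),
                        seq_len(config$n_markers))
  # composition-responsive non-marker CpGs: real bulk methylation varies
  # with cell composition well beyond the deconvolution markers
  profiles <- ref$profiles
  n_resp <- round(config$responsive_cpg_fraction * length(non_marker))
  resp_cpgs <- if (n_resp > 0 && config$responsive_sd > 0)
    sort(sample(non_marker, n_resp)) else integer(0)
  if (length(resp_cpgs)) {
    K <- ncol(profiles)
    profiles[resp_cpgs, ] <- pmin(pmax(
      profiles[resp_cpgs, ] +
        matrix(stats::rnorm(length(resp_cpgs) * K, sd = config$responsive_sd),
               length(resp_cpgs), K), 0), 1)
  }
  n_sex <- round(config$sex_effect_cpg_fraction * config$n_cpgs)
  sex_cpgs <- if (n_sex > 0 && length(non_marker))
    sort(sample(non_marker, min(n_sex, length(non_marker)))) else integer(0)
  n_cont <- round(config$contaminate_fraction * config$n_cpgs)
  cont_cpgs <- if (n_cont > 0)
    sort(sample.int(config$n_cpgs, n_cont)) else integer(0)
  betas <- synthesize_betas(profiles, props,
                            noise_sd = config$noise_sd,
                            sex = phenotypes$sex,
                            sex_effect_cpgs = sex_cpgs,
                            contaminate_cpgs = cont_cpgs)
  structure(list(
    betas = betas, true_proportions = props, phenotypes = phenotypes,
    reference = ref$markers, profiles = profiles,
    marker_ids = ref$marker_ids, sex_effect_cpgs = sex_cpgs,
    responsive_cpgs = resp_cpgs, contaminated_cpgs = cont_cpgs,
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic methylation cohort (", x$config$study_preset, ")\n",
      "  samples: ", ncol(x$betas), "  CpGs: ", nrow(x$betas),
      "  markers: ", length(x$marker_ids),
      "  cell types: ", ncol(x$true_proportions), "\n", sep = "")
  invisible(x)
}

#' Write a cohort to plain-text fixture files
#'
#' Writes `betas.tsv` (CpG x sample, first column CpG id), `reference.tsv`
#' (marker CpG x cell type), `phenotypes.csv` and `true_proportions.csv`
#' into `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("betas.tsv", "reference.tsv",
                            "phenotypes.csv", "true_proportions.csv"))
  write_beta_matrix(cohort$betas, paths[1])
  write_beta_matrix(cohort$reference, paths[2], id_column = "marker_id")
  utils::write.csv(cohort$phenotypes, paths[3], row.names = FALSE)
  utils::write.csv(data.frame(sample_id = rownames(cohort$true_proportions),
                              cohort$true_proportions,
                              check.names = FALSE),
                   paths[4], row.names = FALSE)
  invisible(paths)
}
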