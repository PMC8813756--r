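# Small in-code fixtures shared across test files.

# K-component mixture with uniform-random component methylomes and
# Dirichlet(2) proportions; independent of the cohort generator so that
# factorization tests do not inherit its structure.
make_mixture <- function(n = 150, p = 500, K = 3, noise_sd = 0, seed = 1) {
  set.seed(seed)
  profiles <- matrix(stats::runif(p * K), p, K,
                     dimnames = list(sprintf("cg%05d", seq_len(p)),
                                     paste0("T", seq_len(K))))
  props <- t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(K, 2)
    g / sum(g)
  }, numeric(K)))
  rownames(props) <- sprintf("S%03d", seq_len(n))
  betas <- synthesize_betas(profiles, props, noise_sd = noise_sd)
  list(betas = betas, profiles = profiles, proportions = props)
}

# tiny reference with exactly separable columns for deconvolution tests
make_tiny_reference <- function(n_markers = 12, K = 3, seed = 5) {
  set.seed(seed)
  ref <- matrix(stats::runif(n_markers * K), n_markers, K,
                dimnames = list(sprintf("cg%05d", seq_len(n_markers)),
                                paste0("T", seq_len(K))))
  ref
}
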