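# Shared fixture builders. Everything is generated in code at test time.

# Small beta-value dataset with iid Beta(a, b) entries in both groups.
null_beta_dataset <- function(n_features = 50, n_per_group = 10,
                              a = 10, b = 90, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_group
  values <- matrix(rbeta(n_features * n, a, b), n_features, n)
  methylation_dataset(values, rep(c(0L, 1L), each = n_per_group),
                      feature_ids = sprintf("f%04d", seq_len(n_features)),
                      sample_ids = sprintf("s%03d", seq_len(n)))
}

# Gaussian-on-the-M-scale dataset with randomly permuted labels: the
# "label-permuted Gaussian-like" null used for calibration checks.
permuted_gaussian_dataset <- function(n_features = 5000, n_samples = 100,
                                      seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * n_samples, mean = -3, sd = 0.5),
              n_features, n_samples)
  group <- sample(rep(c(0L, 1L), each = n_samples / 2))
  methylation_dataset(m_to_beta(m), group,
                      feature_ids = sprintf("f%05d", seq_len(n_features)),
                      sample_ids = sprintf("s%03d", seq_len(n_samples)))
}

# Tiny config for fast simulator-driven tests.
small_sim_config <- function(...) {
  sim_config(n_features = 600, n_samples_per_group = 50,
             n_true_per_type = 20, ...)
}
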