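# Small programmatic fixtures shared across test files.

make_counts <- function(n_genes = 3, n_samples = 2, values = NULL) {
  m <- if (is.null(values)) {
    matrix(seq_len(n_genes * n_samples), n_genes, n_samples)
  } else {
    matrix(values, n_genes, n_samples)
  }
  dimnames(m) <- list(paste0("g", seq_len(n_genes)), paste0("s", seq_len(n_samples)))
  m
}

# minimal two-genotype design covering all six stages
make_design <- function(n_reps = 2, genotypes = c("PP", "LL")) {
  df <- expand.grid(replicate = seq_len(n_reps), stage = STAGES,
                    genotype = genotypes, stringsAsFactors = FALSE)
  df$sample_id <- sprintf("%s_%s_r%d", df$genotype, df$stage, df$replicate)
  df$cross_id <- "cx1"
  df[, c("sample_id", "genotype", "stage", "replicate", "cross_id")]
}

# NB counts for a design from per-gene per-cell means
nb_counts_from_means <- function(means_fun, design, dispersion = 0.05,
                                 n_genes = 50, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n_genes, nrow(design),
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), design$sample_id))
  for (j in seq_len(nrow(design))) {
    mu <- means_fun(seq_len(n_genes), design$genotype[j], design$stage[j])
    m[, j] <- rnbinom(n_genes, size = 1 / dispersion, mu = mu)
  }
  m
}

# small pipeline-ready simulated dataset (fast)
small_sim <- function(seed = 5, ...) {
  simulate_experiment(sim_config(
    n_conserved = 40, n_heteromorphic = 30, n_heterochronic = 30,
    n_p_specific = 15, n_l_specific = 15, parental_effect_genes = 10,
    seed = seed, ...))
}
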