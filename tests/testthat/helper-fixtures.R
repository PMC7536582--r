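# Shared fixtures: all datasets are generated in code at test time.

# Small standardized dataset with simulated architecture.
make_sim_dataset <- function(N = 500, M = 200, n_chrom = 4, L = 5,
                             n_active = 3, var_main = 0.2, var_gxe = 0.05,
                             n_causal_main = NULL, n_causal_gxe = NULL,
                             n_std = NULL, var_std_main = 0.005,
                             var_std_gxe = 0.005, var_pc1 = 0, rho = 0,
                             seed = 1) {
  # default causal counts scale with the genome so tiny fixtures stay valid
  if (is.null(n_std)) n_std <- max(1, min(6, round(0.02 * M)))
  if (is.null(n_causal_main)) {
    n_causal_main <- max(2, min(round(0.2 * M), floor(M / 2) - n_std - 2))
  }
  if (is.null(n_causal_gxe)) {
    n_causal_gxe <- max(2, min(round(0.1 * M), floor(M / 2) - n_std - 2))
  }
  cfg <- sim_config(n_samples = N, n_snps = M, n_chrom = n_chrom, n_env = L,
                    n_active_env = n_active, n_causal_main = n_causal_main,
                    n_causal_gxe = n_causal_gxe, var_main = var_main,
                    var_gxe = var_gxe, n_standardized_snps = n_std,
                    var_std_main = var_std_main, var_std_gxe = var_std_gxe,
                    var_pc1 = var_pc1, rho = rho, seed = seed)
  g <- simulate_genotypes(cfg)
  E <- simulate_environments(N, L, seed = seed + 1000)
  X <- standardize_columns(g$genotypes)
  ph <- simulate_phenotype(X, E, cfg, g$variants)
  ds <- lemma:::new_dataset(rownames(X), X, g$variants, ph$y,
                            matrix(numeric(0), N, 0), E)
  attr(ds, "standardized") <- TRUE
  list(ds = ds, truth = ph$truth, cfg = cfg, variants = g$variants)
}

# Dataset wrapper around arbitrary matrices.
wrap_dataset <- function(X, y, E, C = NULL, chrom = NULL, standardized = TRUE) {
  N <- nrow(X); M <- ncol(X)
  if (is.null(C)) C <- matrix(numeric(0), N, 0)
  if (is.null(chrom)) chrom <- rep("1", M)
  variants <- data.frame(chrom = as.character(chrom),
                         id = paste0("snp", seq_len(M)), pos = seq_len(M),
                         a0 = "A", a1 = "B", maf = 0.25, info = 1,
                         stringsAsFactors = FALSE)
  ds <- lemma:::new_dataset(paste0("S", seq_len(N)), X, variants, y, C, E)
  attr(ds, "standardized") <- standardized
  ds
}

# Textbook HC3-weighted sandwich covariance, written independently of the
# package implementation (entry-by-entry, no shared code path).
brute_sandwich <- function(H, y) {
  hth_inv <- solve(t(H) %*% H)
  tau <- hth_inv %*% t(H) %*% y
  eps <- drop(y - H %*% tau)
  hat <- H %*% hth_inv %*% t(H)
  meat <- matrix(0, ncol(H), ncol(H))
  for (i in seq_len(nrow(H))) {
    w <- eps[i]^2 / (1 - hat[i, i])^2
    meat <- meat + w * (H[i, ] %o% H[i, ])
  }
  hth_inv %*% meat %*% hth_inv
}

# Closed-form ridge posterior mean for y = X b + e, b ~ N(0, se2*v I),
# e ~ N(0, se2 I).
ridge_posterior_mean <- function(X, y, v) {
  solve(crossprod(X) + diag(1 / v, ncol(X)), crossprod(X, y))
}
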