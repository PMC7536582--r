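#' Simulation configuration
#'
#' Defaults reproduce the study design the package's power and calibration
#' analyses are built around: 25,000 samples, 100,000 SNPs on 22
#' pseudo-chromosomes, 30 environments of which 6 are active, 2,500 causal
#' main effects and 1,250 causal interaction effects explaining 20% and 5%
#' of trait variance, 60 extra SNPs of standardized effect carrying 1% of
#' variance through main effects and 1% through interactions, and 1% of
#' variance on the leading genetic principal component.
#'
#' @param n_samples,n_snps,n_chrom,n_env,n_active_env Problem dimensions.
#' @param n_causal_main,n_causal_gxe Causal SNP counts (drawn from the first
#'   half of each chromosome).
#' @param var_main,var_gxe Variance fractions of the causal main and
#'   interaction components.
#' @param n_standardized_snps,var_std_main,var_std_gxe Count and variance
#'   fractions of the equal-effect power-benchmark SNPs.
#' @param var_pc1 Variance fraction on the leading genetic PC.
#' @param maf_lo,maf_hi Allele-frequency range (uniform draw per SNP).
#' @param rho First-order LD: probability of copying the previous SNP's
#'   dosage within a chromosome (0 = independent SNPs).
#' @param seed Seed making every generator a pure function of the config.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 25000, n_snps = 100000, n_chrom = 22,
                       n_env = 30, n_active_env = 6, n_causal_main = 2500,
                       n_causal_gxe = 1250, var_main = 0.20, var_gxe = 0.05,
                       n_standardized_snps = 60, var_std_main = 0.01,
                       var_std_gxe = 0.01, var_pc1 = 0.01, maf_lo = 0.05,
                       maf_hi = 0.5, rho = 0, seed = 1) {
  cfg <- as.list(environment())
  tot <- var_main + var_gxe + var_std_main + var_std_gxe + var_pc1
  if (tot >= 1) stop("variance fractions must sum to less than 1 (got ", tot, ")")
  if (n_snps < 2 * n_chrom) stop("need at least 2 SNPs per chromosome")
  eligible <- floor(n_snps / n_chrom / 2) * n_chrom
  if (n_causal_main + n_standardized_snps > eligible ||
      n_causal_gxe + n_standardized_snps > eligible) {
    stop("causal counts exceed the number of eligible (first-half) SNPs")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate genotype dosages
#'
#' Binomial(2, f) dosages with per-SNP allele frequencies drawn uniformly
#' from `[maf_lo, maf_hi]`, split evenly across pseudo-chromosomes, with
#' optional first-order LD (`rho`). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genotypes` (dosage matrix, samples in rows) and
#'   `variants` (data frame with `chrom`, `id`, `pos`, `maf`, `info`, `f`).
#' @export
simulate_genotypes <- function(config) {
  n <- config$n_samples; m <- config$n_snps
  chrom <- rep(seq_len(config$n_chrom), length.out = m)
  chrom <- sort(chrom)
  f <- with_seed(config$seed, stats::runif(m, config$maf_lo, config$maf_hi))
  X <- gen_genotypes_cpp(n, m, f, config$rho, as.integer(chrom),
                         config$seed + 1)
  rownames(X) <- paste0("S", seq_len(n))
  pos <- stats::ave(seq_len(m), chrom, FUN = seq_along)
  variants <- data.frame(chrom = as.character(chrom),
                         id = paste0("snp", seq_len(m)), pos = pos,
                         a0 = "A", a1 = "B", maf = pmin(f, 1 - f), info = 1.0,
                         f = f, stringsAsFactors = FALSE)
  colnames(X) <- variants$id
  list(genotypes = X, variants = variants)
}

#' Simulate standard-Gaussian environmental variables
#'
#' @param n_samples,L Dimensions.
#' @param seed Seed.
#' @return N x L matrix with standardized columns.
#' @export
simulate_environments <- function(n_samples, L, seed = 1) {
  if (L < 1) stop("need at least one environment")
  E <- with_seed(seed, matrix(stats::rnorm(n_samples * L), n_samples, L))
  colnames(E) <- paste0("env", seq_len(L))
  standardize_columns(E)
}

# indices of first-half-of-chromosome SNPs (eligible for causal effects)
first_half_idx <- function(chrom) {
  unlist(lapply(split(seq_along(chrom), chrom), function(idx) {
    idx[seq_len(floor(length(idx) / 2))]
  }), use.names = FALSE)
}

scale_to_var <- function(v, target) {
  if (target == 0) return(v * 0)
  v * sqrt(target / stats::var(v))
}

#' Simulate a phenotype with main, GxE, PC and residual components
#'
#' `y = X beta + (E w) * (X gamma) + c1 PC1 + eps`, with causal SNPs drawn
#' from the first half of each chromosome (the second halves stay null for
#' calibration checks), a block of standardized-effect SNPs with equal
#' per-SNP variance shares for power benchmarking, effect vectors rescaled
#' so each component's realized variance hits its target fraction exactly,
#' and the residual scaled so the total variance is 1.
#'
#' @param genotypes Standardized N x M genotype matrix.
#' @param environments Standardized N x L environment matrix.
#' @param config A [sim_config()].
#' @param variants Variant data frame carrying chromosome labels (from
#'   [simulate_genotypes()]).
#' @return List with `y` and `truth` (a `lemma_sim_truth`: causal indices and
#'   effects, active weights, the true score `eta`, the standardized-effect
#'   and null SNP index sets, and realized variance fractions).
#' @export
simulate_phenotype <- function(genotypes, environments, config, variants) {
  X <- genotypes; E <- environments
  n <- nrow(X); m <- ncol(X); L <- ncol(E)
  stopifnot(L >= config$n_active_env)
  eligible <- first_half_idx(variants$chrom)
  null_idx <- setdiff(seq_len(m), eligible)

  with_seed(config$seed + 2, {
    std_idx <- sort(sample(eligible, config$n_standardized_snps))
    pool <- setdiff(eligible, std_idx)
    main_idx <- sort(sample(pool, config$n_causal_main))
    gxe_idx <- sort(sample(pool, config$n_causal_gxe))
    w <- rep(0, L)
    active <- seq_len(config$n_active_env)
    w[active] <- 1 / sqrt(config$n_active_env)
    eta <- drop(E %*% w)

    beta <- stats::rnorm(config$n_causal_main)
    comp_main <- drop(X[, main_idx, drop = FALSE] %*% beta)
    sc <- sqrt(config$var_main / stats::var(comp_main))
    beta <- beta * sc; comp_main <- comp_main * sc

    gamma <- stats::rnorm(config$n_causal_gxe)
    comp_gxe <- eta * drop(X[, gxe_idx, drop = FALSE] %*% gamma)
    if (config$var_gxe > 0) {
      sc <- sqrt(config$var_gxe / stats::var(comp_gxe))
    } else {
      sc <- 0
    }
    gamma <- gamma * sc; comp_gxe <- comp_gxe * sc

    beta_std <- sample(c(-1, 1), config$n_standardized_snps, replace = TRUE)
    comp_std_main <- drop(X[, std_idx, drop = FALSE] %*% beta_std)
    sc <- sqrt(config$var_std_main / stats::var(comp_std_main))
    beta_std <- beta_std * sc; comp_std_main <- comp_std_main * sc

    gamma_std <- sample(c(-1, 1), config$n_standardized_snps, replace = TRUE)
    comp_std_gxe <- eta * drop(X[, std_idx, drop = FALSE] %*% gamma_std)
    if (config$var_std_gxe > 0) {
      sc <- sqrt(config$var_std_gxe / stats::var(comp_std_gxe))
    } else {
      sc <- 0
    }
    gamma_std <- gamma_std * sc; comp_std_gxe <- comp_std_gxe * sc

    if (config$var_pc1 > 0) {
      pc1 <- drop(leading_pc_cpp(X, 15, config$seed + 3))
      comp_pc <- scale_to_var(pc1, config$var_pc1)
    } else {
      comp_pc <- rep(0, n)
    }

    var_eps <- 1 - config$var_main - config$var_gxe - config$var_std_main -
      config$var_std_gxe - config$var_pc1
    eps <- scale_to_var(stats::rnorm(n), var_eps)
    y <- comp_main + comp_gxe + comp_std_main + comp_std_gxe + comp_pc + eps
  })

  vy <- stats::var(y)
  truth <- structure(list(
    main_idx = main_idx, beta = beta, gxe_idx = gxe_idx, gamma = gamma,
    std_idx = std_idx, beta_std = beta_std, gamma_std = gamma_std,
    w = w, active_env = active, eta = eta, null_idx = null_idx,
    pc = comp_pc,
    realized = c(main = stats::var(comp_main) / vy,
                 gxe = stats::var(comp_gxe) / vy,
                 std_main = stats::var(comp_std_main) / vy,
                 std_gxe = stats::var(comp_std_gxe) / vy,
                 pc1 = stats::var(comp_pc) / vy)),
    class = "lemma_sim_truth")
  list(y = y, truth = truth)
}

#' Misspecification configuration: trait depending on a heritable squared
#' environment
#'
#' @param a Strength of the squared dependence of the trait on the
#'   environmental factor.
#' @param h_tau2 Heritability of the environmental factor S.
#' @param h_beta2 Additive heritability of the trait Y.
#' @param lambda_tau,lambda_beta Causal fractions of the spike-and-slab
#'   effect priors.
#' @param seed Seed.
#' @return An object of class `misspec_config`.
#' @export
misspec_config <- function(a = 0.25, h_tau2 = 0.2, h_beta2 = 0.2,
                           lambda_tau = 0.05, lambda_beta = 0.05, seed = 1) {
  stopifnot(h_tau2 >= 0, h_tau2 < 1, h_beta2 >= 0, h_beta2 < 1,
            lambda_tau > 0, lambda_tau <= 1, lambda_beta > 0, lambda_beta <= 1)
  structure(as.list(environment()), class = "misspec_config")
}

#' Simulate a trait with non-linear dependence on a heritable environment
#'
#' The environmental factor is `S = X tau + eps_s` with spike-and-slab SNP
#' effects (slab variance `h_tau2 / (M lambda_tau)`, so Var(S) is 1 in
#' expectation) and `eps_s ~ N(0, 1 - h_tau2)`; the trait is
#' `Y = a S^2 + X beta + eps` with `eps ~ N(0, 1 - h_beta2)`.
#'
#' @param genotypes Standardized genotype matrix.
#' @param config A [misspec_config()].
#' @return List with `y`, `s`, and `truth` (tau/beta with their nonzero
#'   index sets — the heritable sites of the misspecified environment).
#' @export
simulate_misspecified <- function(genotypes, config) {
  X <- genotypes
  n <- nrow(X); m <- ncol(X)
  with_seed(config$seed, {
    v <- stats::rbinom(m, 1, config$lambda_tau)
    tau <- v * stats::rnorm(m, 0, sqrt(config$h_tau2 / (m * config$lambda_tau)))
    s <- drop(X %*% tau) + stats::rnorm(n, 0, sqrt(1 - config$h_tau2))
    u <- stats::rbinom(m, 1, config$lambda_beta)
    beta <- u * stats::rnorm(m, 0, sqrt(config$h_beta2 / (m * config$lambda_beta)))
    y <- config$a * s^2 + drop(X %*% beta) +
      stats::rnorm(n, 0, sqrt(1 - config$h_beta2))
  })
  list(y = y, s = s,
       truth = list(tau = tau, tau_idx = which(v == 1), beta = beta,
                    beta_idx = which(u == 1)))
}

#' Power and false-positive-rate summary of a GxE scan
#'
#' Power is the fraction of standardized-effect SNPs detected below `alpha`;
#' the false-positive rate is computed on the null (second-half) SNPs.
#' Binomial standard errors are attached.
#'
#' @param results Data frame from [gxe_scan()] (needs `id` and `p_gxe`).
#' @param truth A `lemma_sim_truth`.
#' @param alpha Significance threshold (default 0.01).
#' @param variants Variant data frame mapping `id` to column index; defaults
#'   to `snp<j>` naming.
#' @return List with `power`, `power_se`, `fpr`, `fpr_se`, counts.
#' @export
evaluate_power_fpr <- function(results, truth, alpha = 0.01, variants = NULL) {
  idx_of <- if (is.null(variants)) {
    function(ids) as.integer(sub("^snp", "", ids))
  } else {
    function(ids) match(ids, variants$id)
  }
  res_idx <- idx_of(results$id)
  need_std <- truth$std_idx
  need_null <- truth$null_idx
  have_null <- intersect(need_null, res_idx)
  missing_std <- setdiff(need_std, res_idx)
  if (length(missing_std) > 0) {
    stop("results are missing standardized-effect SNP(s): ",
         paste(utils::head(missing_std, 10), collapse = ", "))
  }
  if (length(have_null) == 0) stop("results contain no null SNPs")
  p <- results$p_gxe[match(need_std, res_idx)]
  p_null <- results$p_gxe[match(have_null, res_idx)]
  power <- mean(p < alpha, na.rm = TRUE)
  fpr <- mean(p_null < alpha, na.rm = TRUE)
  n_std <- sum(!is.na(p)); n_null <- sum(!is.na(p_null))
  list(power = power, power_se = sqrt(power * (1 - power) / n_std),
       fpr = fpr, fpr_se = sqrt(fpr * (1 - fpr) / n_null),
       n_standardized = n_std, n_null = n_null, alpha = alpha)
}
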