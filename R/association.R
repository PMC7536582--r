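#' Leave-one-chromosome-out residualized phenotypes
#'
#' For each chromosome, the phenotype minus fitted covariate effects and the
#' fitted main and interaction contributions of all *other* chromosomes.
#' Testing a SNP against its own chromosome's residual therefore never
#' conditions on effects fitted at nearby loci (avoids proximal
#' contamination).
#'
#' @param dataset The standardized `lemma_dataset` used for the fit.
#' @param fit A `lemma_fit`.
#' @return A `lemma_loco` object: list with `residuals` (named list, one
#'   vector per chromosome) and `es` (the fitted environmental score).
#' @export
loco_residuals <- function(dataset, fit) {
  dataset <- standardize_dataset(dataset)
  chroms <- names(dataset$chrom_index)
  if (length(chroms) < 2) {
    stop("LOCO residuals need at least 2 chromosomes; split the variants ",
         "into pseudo-chromosomes if only one is present")
  }
  X <- dataset$genotypes
  y <- dataset$phenotype
  y <- (y - mean(y)) / stats::sd(y)
  C <- dataset$covariates
  es <- fit$es
  ca <- if (length(fit$alpha_hat) > 0) drop(C %*% fit$alpha_hat) else 0
  full_fit <- drop(X %*% fit$beta_hat) + es * drop(X %*% fit$gamma_hat)
  base <- y - ca - full_fit
  residuals <- lapply(dataset$chrom_index, function(idx) {
    xc <- X[, idx, drop = FALSE]
    base + drop(xc %*% fit$beta_hat[idx]) + es * drop(xc %*% fit$gamma_hat[idx])
  })
  structure(list(residuals = residuals, es = es), class = "lemma_loco")
}

#' Single-SNP main-effect and GxE test with robust standard errors
#'
#' Regresses a (LOCO) residualized phenotype on the test SNP and its product
#' with the environmental score. The interaction is tested with a
#' heteroskedasticity-robust (Huber-White sandwich) variance that carries the
#' small-sample leverage adjustment `1/(1-h_ii)^2`, referred to chi-squared
#' with 1 df; the main effect uses an ordinary t test (N-2 df).
#'
#' @param x_test Length-N dosage vector (standardized before testing so
#'   effects are per SD of genotype).
#' @param es Length-N environmental score.
#' @param residual Length-N residualized phenotype (from the test SNP's
#'   chromosome in the LOCO set).
#' @param standardize_x Standardize `x_test` first (default `TRUE`).
#' @return List with `beta_test`, `gamma_test`, `se_beta`, `se_gamma_robust`,
#'   `p_main`, `p_gxe`, `n`, and a `flagged` indicator for degenerate
#'   designs.
#' @export
gxe_single_snp_test <- function(x_test, es, residual, standardize_x = TRUE) {
  n <- length(residual)
  x <- as.numeric(x_test)
  if (standardize_x) {
    sdx <- stats::sd(x)
    if (sdx == 0) {
      return(flagged_result(n))
    }
    x <- (x - mean(x)) / sdx
  }
  z <- es * x
  H <- cbind(x, z)
  hth <- crossprod(H)
  if (!is.finite(det(hth)) || abs(det(hth)) < 1e-10 * n^2) {
    return(flagged_result(n))
  }
  hth_inv <- solve(hth)
  tau <- unname(drop(hth_inv %*% crossprod(H, residual)))
  eps <- residual - drop(H %*% tau)
  hii <- rowSums((H %*% hth_inv) * H)
  if (any(hii >= 1 - 1e-12)) return(flagged_result(n))
  # residual numerically in the span of H: degenerate variance estimate
  if (sum(eps^2) <= 1e-20 * sum(residual^2)) return(flagged_result(n))
  sigma_diag <- eps^2 / (1 - hii)^2
  meat <- crossprod(H * sigma_diag, H)
  vrob <- hth_inv %*% meat %*% hth_inv
  se_gamma <- sqrt(vrob[2, 2])
  stat_gxe <- tau[2]^2 / vrob[2, 2]
  p_gxe <- stats::pchisq(stat_gxe, df = 1, lower.tail = FALSE)
  s2 <- sum(eps^2) / (n - 2)
  se_beta <- sqrt(s2 * hth_inv[1, 1])
  t_main <- tau[1] / se_beta
  p_main <- 2 * stats::pt(abs(t_main), df = n - 2, lower.tail = FALSE)
  list(beta_test = tau[1], gamma_test = tau[2], se_beta = se_beta,
       se_gamma_robust = se_gamma, p_main = p_main, p_gxe = p_gxe,
       n = n, flagged = FALSE)
}

flagged_result <- function(n) {
  list(beta_test = NA_real_, gamma_test = NA_real_, se_beta = NA_real_,
       se_gamma_robust = NA_real_, p_main = NA_real_, p_gxe = NA_real_,
       n = n, flagged = TRUE)
}

#' Genome scan of single-SNP GxE tests against LOCO residuals
#'
#' @param dataset The standardized `lemma_dataset`.
#' @param fit A `lemma_fit`.
#' @param snps Optional integer vector of variant indices to test (default
#'   all).
#' @param loco Optionally a precomputed [loco_residuals()] result.
#' @return Data frame with one row per tested variant: variant metadata plus
#'   `beta_test`, `se_beta`, `p_main`, `gamma_test`, `se_gamma_robust`,
#'   `p_gxe`, `n`, `flagged`.
#' @export
gxe_scan <- function(dataset, fit, snps = NULL, loco = NULL) {
  dataset <- standardize_dataset(dataset)
  if (is.null(loco)) loco <- loco_residuals(dataset, fit)
  if (is.null(snps)) snps <- seq_len(ncol(dataset$genotypes))
  chrom_of <- dataset$variants$chrom
  rows <- lapply(snps, function(j) {
    res <- gxe_single_snp_test(dataset$genotypes[, j], loco$es,
                               loco$residuals[[chrom_of[j]]],
                               standardize_x = FALSE)
    as.data.frame(res)
  })
  out <- cbind(dataset$variants[snps, c("chrom", "id", "pos", "maf"),
                                drop = FALSE],
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

# Build the F-test / robust F-test design [1, C, E, x, diag(x) E].
gxe_joint_design <- function(y, C, E, x_test) {
  E <- as.matrix(E)
  x <- as.numeric(x_test)
  C <- if (is.null(C)) matrix(numeric(0), length(x), 0) else as.matrix(C)
  H <- cbind(1, C, E, x, x * E)
  L <- ncol(E)
  idx_gamma <- (ncol(H) - L + 1):ncol(H)
  qr_h <- qr(H)
  if (qr_h$rank < ncol(H)) {
    drop_cols <- qr_h$pivot[-seq_len(qr_h$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(H)[drop_cols] %||% drop_cols, collapse = ", "))
  }
  list(H = H, idx_gamma = idx_gamma, L = L, qr = qr_h)
}

#' Multi-environment interaction F-test at a single SNP
#'
#' Tests that all L interaction coefficients of `x_test` with the columns of
#' `E` are zero in the model `y = C alpha + E alpha' + x beta + (x * E) gamma
#' + eps`, assuming homoskedastic errors. Degrees of freedom come from the
#' column ranks of the full and null designs.
#'
#' @param y Phenotype vector.
#' @param C Covariate matrix (an intercept is added; may be `NULL`).
#' @param E Environment matrix.
#' @param x_test Dosage vector of the test SNP.
#' @return List with `statistic`, `p_value`, `df1`, `df2`.
#' @export
f_test <- function(y, C, E, x_test) {
  d <- gxe_joint_design(y, C, E, x_test)
  n <- length(y)
  d1 <- d$qr$rank
  d0 <- d1 - d$L
  tau <- qr.coef(d$qr, y)
  eps <- y - drop(d$H %*% tau)
  sigma2 <- sum(eps^2) / (n - d1)
  hth_inv <- chol2inv(qr.R(d$qr))
  rtau <- tau[d$idx_gamma]
  rvr <- hth_inv[d$idx_gamma, d$idx_gamma]
  stat <- drop(crossprod(rtau, solve(rvr, rtau))) / d$L / sigma2
  list(statistic = stat,
       p_value = stats::pf(stat, d1 - d0, n - d1, lower.tail = FALSE),
       df1 = d1 - d0, df2 = n - d1)
}

#' Robust (heteroskedasticity-consistent) interaction Wald test
#'
#' Same null hypothesis and design as [f_test()], but the Wald statistic uses
#' the sandwich covariance with leverage-adjusted weights
#' `eps_i^2 / (1 - h_ii)^2` and is referred to chi-squared with L degrees of
#' freedom.
#'
#' @inheritParams f_test
#' @return List with `statistic`, `p_value`, `df`.
#' @export
robust_f_test <- function(y, C, E, x_test) {
  d <- gxe_joint_design(y, C, E, x_test)
  n <- length(y)
  tau <- qr.coef(d$qr, y)
  eps <- y - drop(d$H %*% tau)
  hth_inv <- chol2inv(qr.R(d$qr))
  hh <- d$H %*% hth_inv
  hii <- rowSums(hh * d$H)
  omega <- eps^2 / (1 - hii)^2
  vrob <- hth_inv %*% crossprod(d$H * omega, d$H) %*% hth_inv
  rtau <- tau[d$idx_gamma]
  rvr <- vrob[d$idx_gamma, d$idx_gamma]
  stat <- drop(crossprod(rtau, solve(rvr, rtau)))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = d$L, lower.tail = FALSE),
       df = d$L)
}

#' Screen environments for squared effects on the phenotype
#'
#' Each environment column is tested for a squared effect in
#' `y = 1 a0 + C a + E_l^2 b_l + eps`; environments with p below
#' `alpha / L` (Bonferroni over the L tests) are marked for inclusion and
#' their squared columns appended to the covariates.
#'
#' @param y Phenotype vector.
#' @param C Covariate matrix (may be `NULL`; an intercept is always added).
#' @param E Environment matrix with standardized columns.
#' @param alpha Family-wise level before Bonferroni division (default 0.01).
#' @return List with `report` (per-environment estimate, p-value, inclusion
#'   flag) and `covariates` (C with included squared columns appended).
#' @export
detect_squared_env <- function(y, C, E, alpha = 0.01) {
  E <- as.matrix(E)
  n <- length(y)
  C <- if (is.null(C)) matrix(numeric(0), n, 0) else as.matrix(C)
  L <- ncol(E)
  thresh <- alpha / L
  est <- p <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    el2 <- E[, l]^2
    H <- cbind(1, C, el2)
    qr_h <- qr(H)
    if (qr_h$rank < ncol(H)) {
      warning("squared environment ", l, " collinear with covariates; skipped")
      next
    }
    coefs <- qr.coef(qr_h, y)
    eps <- y - drop(H %*% coefs)
    s2 <- sum(eps^2) / (n - ncol(H))
    vc <- s2 * chol2inv(qr.R(qr_h))
    k <- ncol(H)
    est[l] <- coefs[k]
    p[l] <- 2 * stats::pt(abs(coefs[k] / sqrt(vc[k, k])), df = n - k,
                          lower.tail = FALSE)
  }
  included <- !is.na(p) & p < thresh
  report <- data.frame(environment = colnames(E) %||% paste0("E", seq_len(L)),
                       estimate = est, p_value = p, included = included)
  cov_out <- C
  if (any(included)) {
    sq <- E[, included, drop = FALSE]^2
    colnames(sq) <- paste0(report$environment[included], "_sq")
    cov_out <- cbind(C, sq)
  }
  list(report = report, covariates = cov_out)
}

#' SNP-specific interaction profile
#'
#' Least-squares estimate of per-environment interaction weights at one SNP
#' (`y = C a + x beta + (x * E) w + eps`) and the squared correlation of the
#' implied local score `E w_LS` with a genome-wide environmental score — a
#' proxy for how well the single learned score captures the interaction at
#' that locus.
#'
#' @inheritParams f_test
#' @param es The genome-wide environmental score to compare against.
#' @return List with `w_ls`, `eta_ls`, `r2_with_es`.
#' @export
snp_interaction_profile <- function(y, C, E, x_test, es) {
  E <- as.matrix(E)
  x <- as.numeric(x_test)
  C <- if (is.null(C)) matrix(numeric(0), length(x), 0) else as.matrix(C)
  H <- cbind(1, C, x, x * E)
  qr_h <- qr(H)
  if (qr_h$rank < ncol(H)) stop("rank-deficient interaction design")
  coefs <- qr.coef(qr_h, y)
  L <- ncol(E)
  w_ls <- coefs[(ncol(H) - L + 1):ncol(H)]
  eta_ls <- drop(E %*% w_ls)
  list(w_ls = w_ls, eta_ls = eta_ls,
       r2_with_es = stats::cor(eta_ls, es)^2)
}

#' Re-express environmental-score weights on a recoded environment matrix
#'
#' Projects a score onto the column space of `E1` by least squares; when the
#' column spaces agree the original weights are recovered exactly and the
#' reported residual norm is zero.
#'
#' @param es Length-N environmental score.
#' @param E1 Recoded environment matrix (full column rank).
#' @return List with `weights` and `residual_norm`.
#' @export
rescale_weights <- function(es, E1) {
  E1 <- as.matrix(E1)
  qr_e <- qr(E1)
  if (qr_e$rank < ncol(E1)) stop("rank-deficient recoded environment matrix")
  w <- qr.coef(qr_e, es)
  list(weights = w, residual_norm = sqrt(sum((es - drop(E1 %*% w))^2)))
}

#' Marginal environmental score from additive environment effects
#'
#' Fits `y` on `[1, C, E]` by least squares and combines the coefficients of
#' the E columns into a score — the additive-effects counterpart of the
#' interaction-learned score.
#'
#' @param y Phenotype vector.
#' @param C Non-environment covariates (may be `NULL`).
#' @param E Environment matrix.
#' @return The length-N marginal score.
#' @export
marginal_es <- function(y, C, E) {
  E <- as.matrix(E)
  C <- if (is.null(C)) matrix(numeric(0), length(y), 0) else as.matrix(C)
  H <- cbind(1, C, E)
  qr_h <- qr(H)
  if (qr_h$rank < ncol(H)) stop("rank-deficient covariate design")
  coefs <- qr.coef(qr_h, y)
  L <- ncol(E)
  drop(E %*% coefs[(ncol(H) - L + 1):ncol(H)])
}
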