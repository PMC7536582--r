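#' @useDynLib lemma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  expr
}

# Orthonormal basis of the fixed-effect column space [1, C, es].
fixed_effect_basis <- function(n, C, es) {
  W <- cbind(rep(1, n), C, es)
  qr_w <- qr(W)
  qr.Q(qr_w)[, seq_len(qr_w$rank), drop = FALSE]
}

proj_out <- function(Q, m) m - Q %*% crossprod(Q, m)

xsub <- function(X, idx) {
  if (length(idx) == ncol(X)) X else X[, idx, drop = FALSE]
}

#' Exact Haseman-Elston variance components (small N)
#'
#' Forms the kinship matrix `K = X X' / M` and the interaction kinship
#' `V = (es * X)(es * X)' / M` explicitly, projects the fixed effects
#' (intercept, covariates, and the environmental score) out of both sides,
#' and solves the 3x3 method-of-moments system with exact traces. Intended
#' for modest N as the oracle for the randomized solver.
#'
#' @param y Phenotype vector.
#' @param X N x M standardized genotype matrix.
#' @param es Length-N environmental score.
#' @param C Optional covariate matrix.
#' @return A `lemma_varcomp` object (fields `sigma_b2`, `sigma_g2`,
#'   `sigma_e2`, `trK_over_N`, `trV_over_N`, `n_eff`, `negative`).
#' @export
exact_rhe <- function(y, X, es, C = NULL) {
  n <- length(y)
  M <- ncol(X)
  Q <- fixed_effect_basis(n, C, es)
  P <- diag(n) - tcrossprod(Q)
  u <- drop(P %*% y)
  K <- tcrossprod(X) / M
  Z <- es * X
  V <- tcrossprod(Z) / M
  Kp <- P %*% K %*% P
  Vp <- P %*% V %*% P
  n_eff <- n - ncol(Q)
  A <- matrix(c(sum(Kp * Kp), sum(Kp * Vp), sum(diag(Kp)),
                sum(Kp * Vp), sum(Vp * Vp), sum(diag(Vp)),
                sum(diag(Kp)), sum(diag(Vp)), n_eff), 3, 3, byrow = TRUE)
  b <- c(drop(crossprod(u, K %*% u)), drop(crossprod(u, V %*% u)), sum(u^2))
  if (rcond(A) < 1e-12) stop("singular Haseman-Elston system (is the ES zero ",
                             "or proportional to the kinship structure?)")
  sol <- solve(A, b)
  new_varcomp(sigma_b2 = sol[1], sigma_g2 = sol[2], sigma_e2 = sol[3],
              trK_over_N = sum(diag(Kp)) / n_eff,
              trV_over_N = sum(diag(Vp)) / n_eff, n_eff = n_eff)
}

new_varcomp <- function(sigma_b2, sigma_g2, sigma_e2, trK_over_N, trV_over_N,
                        n_eff, partition = NULL) {
  structure(list(sigma_b2 = sigma_b2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 trK_over_N = trK_over_N, trV_over_N = trV_over_N,
                 n_eff = n_eff, partition = partition,
                 negative = any(c(sigma_b2, sigma_g2) < 0)),
            class = "lemma_varcomp")
}

#' @export
print.lemma_varcomp <- function(x, ...) {
  cat("Haseman-Elston variance components (", length(x$sigma_b2),
      " additive bin(s))\n", sep = "")
  cat("  sum sigma_b2 =", signif(sum(x$sigma_b2), 4),
      " sum sigma_g2*tr(V)/N =", signif(sum(x$sigma_g2 * x$trV_over_N), 4),
      " sigma_e2 =", signif(x$sigma_e2, 4), "\n")
  if (x$negative) cat("  note: negative component estimate(s) present\n")
  invisible(x)
}

# Shared randomized-trace engine. `bins` is a list of SNP index vectors; one
# additive and one interaction component per bin plus the residual identity.
# With jackknife_blocks > 0, delete-one-block estimates are produced in a
# second streaming pass over the block columns.
rhe_engine <- function(y, X, es, C = NULL, bins, B = 50, seed = 1,
                       jackknife_blocks = 0) {
  if (B < 2) stop("B must be at least 2 probe vectors")
  n <- length(y)
  M <- ncol(X)
  nb <- length(bins)
  Q <- fixed_effect_basis(n, C, es)
  n_eff <- n - ncol(Q)
  u <- drop(y - Q %*% crossprod(Q, y))
  eta2 <- es^2

  Zp <- with_seed(seed, matrix(stats::rnorm(n * B), n, B))
  Zp <- proj_out(Q, Zp)
  eZp <- es * Zp

  # per-column exact quantities (projected)
  xtx <- drop(col_sumsq_cpp(X))
  G1 <- crossprod(Q, X)
  csK <- xtx - colSums(G1^2)
  Qe <- Q * es
  G2 <- crossprod(Qe, X)
  csV <- drop(xsq_colsum_cpp(X, eta2)) - colSums(G2^2)
  a_main <- drop(crossprod(X, u))        # X_j' u
  a_int <- drop(crossprod(X, es * u))    # (es*X_j)' u

  probe_mats <- vector("list", 2 * nb)   # unnormalized P A_c P probes
  for (bidx in seq_len(nb)) {
    idx <- bins[[bidx]]
    Xb <- xsub(X, idx)
    probe_mats[[bidx]] <- proj_out(Q, Xb %*% crossprod(Xb, Zp))
    probe_mats[[nb + bidx]] <- proj_out(Q, es * (Xb %*% crossprod(Xb, eZp)))
  }
  m_sizes <- c(vapply(bins, length, 1L), vapply(bins, length, 1L))
  cs_all <- c(vapply(bins, function(i) sum(csK[i]), 1),
              vapply(bins, function(i) sum(csV[i]), 1))
  rhs_all <- c(vapply(bins, function(i) sum(a_main[i]^2), 1),
               vapply(bins, function(i) sum(a_int[i]^2), 1))

  assemble_solve <- function(cross, cs, rhs, sizes) {
    keep <- sizes > 0
    nc <- sum(keep)
    A <- matrix(0, nc + 1, nc + 1)
    A[seq_len(nc), seq_len(nc)] <-
      cross[keep, keep, drop = FALSE] / outer(sizes[keep], sizes[keep])
    A[nc + 1, seq_len(nc)] <- A[seq_len(nc), nc + 1] <- cs[keep] / sizes[keep]
    A[nc + 1, nc + 1] <- n_eff
    b <- c(rhs[keep] / sizes[keep], sum(u^2))
    sol <- rep(NA_real_, length(sizes) + 1)
    if (nrow(A) > 2 && rcond(A) > 1e-10) {
      s <- solve(A, b)
    } else {
      if (nrow(A) > 2) {
        warning("ill-conditioned Haseman-Elston system (rcond = ",
                signif(rcond(A), 2), "); using pseudo-inverse")
      }
      sv <- svd(A)
      pos <- sv$d > max(sv$d) * 1e-12
      if (!any(pos)) stop("singular Haseman-Elston system")
      s <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
    }
    sol[c(which(keep), length(sizes) + 1)] <- s
    sol
  }

  cross_full <- matrix(0, 2 * nb, 2 * nb)
  for (c1 in seq_len(2 * nb)) {
    for (c2 in c1:(2 * nb)) {
      cross_full[c1, c2] <- cross_full[c2, c1] <-
        sum(probe_mats[[c1]] * probe_mats[[c2]]) / B
    }
  }
  sol <- assemble_solve(cross_full, cs_all, rhs_all, m_sizes)
  # tr(P K_b P)/N_eff with K_b normalized by its own M_b (likewise for V_b)
  full <- new_varcomp(sigma_b2 = sol[seq_len(nb)],
                      sigma_g2 = sol[nb + seq_len(nb)],
                      sigma_e2 = sol[2 * nb + 1],
                      trK_over_N = cs_all[seq_len(nb)] /
                        (m_sizes[seq_len(nb)] * n_eff),
                      trV_over_N = cs_all[nb + seq_len(nb)] /
                        (m_sizes[nb + seq_len(nb)] * n_eff),
                      n_eff = n_eff)

  if (jackknife_blocks == 0) return(list(full = full, deletions = NULL))

  if (jackknife_blocks > M) stop("more jackknife blocks than SNPs")
  block_of <- ceiling(seq_len(M) / (M / jackknife_blocks))
  deletions <- vector("list", jackknife_blocks)
  for (bl in seq_len(jackknife_blocks)) {
    bcols <- which(block_of == bl)
    w_mats <- vector("list", 2 * nb)
    m_del <- numeric(2 * nb)
    cs_del <- numeric(2 * nb)
    rhs_del <- numeric(2 * nb)
    for (bidx in seq_len(nb)) {
      idx <- intersect(bins[[bidx]], bcols)
      m_del[c(bidx, nb + bidx)] <- length(idx)
      if (length(idx) > 0) {
        Xb <- X[, idx, drop = FALSE]
        w_mats[[bidx]] <- proj_out(Q, Xb %*% crossprod(Xb, Zp))
        w_mats[[nb + bidx]] <- proj_out(Q, es * (Xb %*% crossprod(Xb, eZp)))
        cs_del[bidx] <- sum(csK[idx]); cs_del[nb + bidx] <- sum(csV[idx])
        rhs_del[bidx] <- sum(a_main[idx]^2)
        rhs_del[nb + bidx] <- sum(a_int[idx]^2)
      }
    }
    cross <- cross_full
    for (c1 in seq_len(2 * nb)) {
      for (c2 in seq_len(2 * nb)) {
        v <- cross_full[c1, c2]
        if (!is.null(w_mats[[c2]])) v <- v - sum(probe_mats[[c1]] * w_mats[[c2]]) / B
        if (!is.null(w_mats[[c1]])) v <- v - sum(w_mats[[c1]] * probe_mats[[c2]]) / B
        if (!is.null(w_mats[[c1]]) && !is.null(w_mats[[c2]])) {
          v <- v + sum(w_mats[[c1]] * w_mats[[c2]]) / B
        }
        cross[c1, c2] <- v
      }
    }
    sizes_d <- m_sizes - m_del
    sol_d <- assemble_solve(cross, cs_all - cs_del, rhs_all - rhs_del, sizes_d)
    deletions[[bl]] <- new_varcomp(
      sigma_b2 = sol_d[seq_len(nb)], sigma_g2 = sol_d[nb + seq_len(nb)],
      sigma_e2 = sol_d[2 * nb + 1],
      trK_over_N = (cs_all - cs_del)[seq_len(nb)] /
        (pmax(sizes_d[seq_len(nb)], 1) * n_eff),
      trV_over_N = (cs_all - cs_del)[nb + seq_len(nb)] /
        (pmax(sizes_d[nb + seq_len(nb)], 1) * n_eff),
      n_eff = n_eff)
  }
  list(full = full, deletions = deletions)
}

#' Randomized Haseman-Elston regression (single SNP component)
#'
#' Solves the same moment system as [exact_rhe()] but estimates the matrix
#' traces with B Gaussian probe vectors (Hutchinson's estimator), never
#' forming the kinship matrices; fixed effects (intercept, covariates, ES)
#' are projected out of the phenotype, genotypes and interaction matrix
#' implicitly. Deterministic given `seed`. Runs in O(NMB) time.
#'
#' @inheritParams exact_rhe
#' @param B Number of probe vectors (default 50).
#' @param seed Seed for the probe draws.
#' @return A `lemma_varcomp`.
#' @export
randomized_rhe <- function(y, X, es, C = NULL, B = 50, seed = 1) {
  rhe_engine(y, X, es, C, bins = list(seq_len(ncol(X))), B = B,
             seed = seed)$full
}

#' Multi-component randomized Haseman-Elston regression
#'
#' One additive and one interaction variance component per partition bin
#' (2 x n_bins + 1 unknowns), solved from Hutchinson-estimated normal
#' equations; empty bins are excluded from the solve with a warning.
#'
#' @inheritParams randomized_rhe
#' @param partition A [ldms_partition()] result (or any list with an
#'   `assignment` vector of bin indices per SNP).
#' @return A `lemma_varcomp` with per-bin component vectors.
#' @export
multi_component_rhe <- function(y, X, es, C = NULL, partition, B = 50,
                                seed = 1) {
  bins <- split(seq_len(ncol(X)), factor(partition$assignment,
                                         levels = seq_len(partition$n_bins)))
  empty <- vapply(bins, length, 1L) == 0
  if (any(empty)) {
    warning(sum(empty), " empty bin(s) excluded from the solver")
    bins <- bins[!empty]
  }
  out <- rhe_engine(y, X, es, C, bins = bins, B = B, seed = seed)$full
  out$partition <- partition
  out
}

#' LD scores from a genotype matrix
#'
#' For SNP j, the sum of squared sample correlations with all SNPs within
#' `window` positions on the same chromosome, including r^2 = 1 with itself.
#'
#' @param X Standardized genotype matrix.
#' @param chrom Chromosome label per SNP (default: all one chromosome).
#' @param window Number of neighboring SNPs on each side (default 100).
#' @return Numeric vector of per-SNP LD scores.
#' @export
ld_scores <- function(X, chrom = NULL, window = 100) {
  if (window < 1) stop("window must be at least 1 SNP")
  M <- ncol(X)
  if (is.null(chrom)) chrom <- rep("1", M)
  norms <- drop(col_sumsq_cpp(X))
  scores <- numeric(M)
  bs <- 512L
  for (start in seq(1L, M, by = bs)) {
    end <- min(start + bs - 1L, M)
    lo <- max(1L, start - window)
    hi <- min(M, end + window)
    cp <- crossprod(X[, start:end, drop = FALSE], X[, lo:hi, drop = FALSE])
    r2 <- cp^2 / outer(norms[start:end], norms[lo:hi])
    for (j in start:end) {
      nb_idx <- max(lo, j - window):min(hi, j + window)
      same <- chrom[nb_idx] == chrom[j]
      scores[j] <- sum(r2[j - start + 1L, nb_idx - lo + 1L][same])
    }
  }
  scores
}

#' Partition SNPs into MAF and LD-score bins
#'
#' Five MAF bins with right-closed edges (<=0.1, then steps of 0.1 up to 0.5)
#' crossed with empirical LD-score quantiles.
#'
#' @param maf Per-SNP minor allele frequencies (or a variant data frame with
#'   a `maf` column).
#' @param ld Per-SNP LD scores from [ld_scores()].
#' @param n_ld_quantiles Number of LD-score quantile bins (default 4).
#' @param maf_edges Upper edges of the MAF bins.
#' @return A `lemma_partition`: list with `assignment` (bin index per SNP),
#'   `maf_edges`, `n_ld_quantiles`, `n_bins`.
#' @export
ldms_partition <- function(maf, ld, n_ld_quantiles = 4,
                           maf_edges = c(0.1, 0.2, 0.3, 0.4, 0.5)) {
  if (is.data.frame(maf)) maf <- maf$maf
  if (length(ld) != length(maf)) stop("maf and ld must cover the same SNPs")
  maf_bin <- cut(maf, breaks = c(-Inf, maf_edges), labels = FALSE)
  qs <- stats::quantile(ld, probs = seq(0, 1, length.out = n_ld_quantiles + 1))
  qs[1] <- -Inf
  qs[length(qs)] <- Inf
  qs <- unique(qs)
  ld_bin <- cut(ld, breaks = qs, labels = FALSE)
  nq_eff <- length(qs) - 1
  assignment <- (maf_bin - 1L) * n_ld_quantiles + ld_bin
  structure(list(assignment = assignment, maf_edges = maf_edges,
                 n_ld_quantiles = n_ld_quantiles, maf_bin = maf_bin,
                 ld_bin = ld_bin,
                 n_bins = length(maf_edges) * n_ld_quantiles),
            class = "lemma_partition")
}

#' Heritability estimates from variance components
#'
#' Additive and GxE heritability with the trace-normalized generalization
#' used when kinship columns are not exactly unit variance:
#' `h2_gxe = sum_b sigma_g2_b tr(V_b)/N / (sum_b sigma_b2_b tr(K_b)/N +
#' sum_b sigma_g2_b tr(V_b)/N + sigma_e2)`, and analogously for `h2_g`.
#'
#' @param components A `lemma_varcomp`.
#' @param se_g,se_gxe Optional jackknife standard errors to attach.
#' @return A `lemma_h2`: list with `h2_g`, `h2_gxe`, per-bin shares, and SEs
#'   when supplied.
#' @export
h2_estimates <- function(components, se_g = NA_real_, se_gxe = NA_real_) {
  tg <- components$sigma_b2 * components$trK_over_N
  tv <- components$sigma_g2 * components$trV_over_N
  # NA components correspond to bins excluded from a (delete-one) solve
  denom <- sum(tg, na.rm = TRUE) + sum(tv, na.rm = TRUE) + components$sigma_e2
  if (!is.finite(denom) || denom <= 0) {
    stop("non-positive total variance; cannot form heritability estimates")
  }
  structure(list(h2_g = sum(tg, na.rm = TRUE) / denom,
                 h2_gxe = sum(tv, na.rm = TRUE) / denom,
                 share_g = tg / denom, share_gxe = tv / denom,
                 se_g = se_g, se_gxe = se_gxe), class = "lemma_h2")
}

#' @export
print.lemma_h2 <- function(x, ...) {
  cat(sprintf("h2_G = %.4f (SE %.4f)   h2_GxE = %.4f (SE %.4f)\n",
              x$h2_g, x$se_g, x$h2_gxe, x$se_gxe))
  invisible(x)
}

#' Block-jackknife standard errors for Haseman-Elston heritability
#'
#' Re-estimates the variance components with each contiguous SNP block
#' deleted in turn and returns `sqrt((n-1)/n * sum((theta_b - mean)^2))`
#' standard errors for the heritability estimates, alongside the full-data
#' estimate.
#'
#' @inheritParams randomized_rhe
#' @param partition Optional [ldms_partition()]; `NULL` for a single
#'   component.
#' @param n_blocks Number of contiguous SNP blocks (default 100).
#' @return A `lemma_h2` with jackknife SEs attached, plus `components` and
#'   the per-deletion estimates in `jackknife`.
#' @export
jackknife_se <- function(y, X, es, C = NULL, partition = NULL, n_blocks = 100,
                         B = 50, seed = 1) {
  if (n_blocks < 2) stop("need at least 2 jackknife blocks")
  bins <- if (is.null(partition)) {
    list(seq_len(ncol(X)))
  } else {
    bl <- split(seq_len(ncol(X)),
                factor(partition$assignment, levels = seq_len(partition$n_bins)))
    bl[vapply(bl, length, 1L) > 0]
  }
  res <- rhe_engine(y, X, es, C, bins = bins, B = B, seed = seed,
                    jackknife_blocks = n_blocks)
  full_h2 <- h2_estimates(res$full)
  thetas <- vapply(res$deletions, function(vc) {
    h <- h2_estimates(vc)
    c(h$h2_g, h$h2_gxe)
  }, numeric(2))
  nb <- ncol(thetas)
  jse <- sqrt((nb - 1) / nb * rowSums((thetas - rowMeans(thetas))^2))
  out <- h2_estimates(res$full, se_g = jse[1], se_gxe = jse[2])
  out$components <- res$full
  out$jackknife <- t(thetas)
  out
}
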