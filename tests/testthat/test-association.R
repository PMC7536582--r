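test_that("single-SNP GxE test reproduces the hand-computed example", {
  # x = (1,-1,1,-1), es = (1,1,-1,-1), y = (1,0,1,0):
  # tau = (0.5, 0), leverage 0.5 everywhere, robust Var(gamma) = 0.25
  r <- gxe_single_snp_test(c(1, -1, 1, -1), c(1, 1, -1, -1), c(1, 0, 1, 0),
                           standardize_x = FALSE)
  expect_equal(r$beta_test, 0.5)
  expect_equal(r$gamma_test, 0)
  expect_equal(r$se_gamma_robust^2, 0.25)
  expect_equal(r$p_gxe, 1)
  expect_false(r$flagged)

  # residual exactly in the span of H: zero residual variance -> flagged
  x <- c(1, -1, 2, -2); es <- c(1, 2, -1, -2)
  y <- 0.3 * x + 0.1 * es * x
  r2 <- gxe_single_snp_test(x, es, y, standardize_x = FALSE)
  expect_true(r2$flagged)

  # collinear design (es * x proportional to x) -> flagged, not an error
  r3 <- gxe_single_snp_test(c(1, -1, 1, -1), rep(2, 4), rnorm(4),
                            standardize_x = FALSE)
  expect_true(r3$flagged)
})

test_that("robust variance matches brute force and an external HC3 oracle", {
  skip_if_not_installed("sandwich")
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 50
    x <- rnorm(n); es <- rnorm(n)
    y <- rnorm(n, sd = 1 + 0.3 * abs(es))
    H <- cbind(x, es * x)
    mine <- gxe_single_snp_test(x, es, y, standardize_x = FALSE)
    vb <- brute_sandwich(H, y)
    expect_equal(mine$se_gamma_robust, sqrt(vb[2, 2]), tolerance = 1e-10)
    vhc <- sandwich::vcovHC(lm(y ~ H - 1), type = "HC3")
    expect_equal(mine$se_gamma_robust, sqrt(vhc[2, 2]), tolerance = 1e-10)
  }
})

test_that("LOCO residuals satisfy the leave-one-out identities", {
  fx <- make_sim_dataset(N = 300, M = 80, n_chrom = 2, L = 3, seed = 51)
  fit <- lemma_fit(fx$ds, fit_config(seed = 1, max_passes = 30))
  loco <- loco_residuals(fx$ds, fit)
  expect_named(loco$residuals, names(fx$ds$chrom_index))

  X <- fx$ds$genotypes
  y <- fx$ds$phenotype
  y <- (y - mean(y)) / sd(y)
  es <- fit$es
  full_resid <- y - drop(X %*% fit$beta_hat) - es * drop(X %*% fit$gamma_hat)

  # residual_c - full residual equals exactly the chromosome-c contribution
  for (ch in names(fx$ds$chrom_index)) {
    idx <- fx$ds$chrom_index[[ch]]
    contrib <- drop(X[, idx] %*% fit$beta_hat[idx]) +
      es * drop(X[, idx] %*% fit$gamma_hat[idx])
    expect_equal(loco$residuals[[ch]] - full_resid, contrib, tolerance = 1e-10)
  }
  # summed over chromosomes the contributions rebuild the whole genetic part
  total <- Reduce(`+`, lapply(loco$residuals, function(r) r - full_resid))
  expect_equal(total, drop(X %*% fit$beta_hat) + es * drop(X %*% fit$gamma_hat),
               tolerance = 1e-10)

  # zero fitted effects: every chromosome's residual is y - C alpha
  fit0 <- fit
  fit0$beta_hat[] <- 0; fit0$gamma_hat[] <- 0
  loco0 <- loco_residuals(fx$ds, fit0)
  for (ch in names(loco0$residuals)) expect_equal(loco0$residuals[[ch]], y)

  ds1 <- fx$ds
  ds1$chrom_index <- ds1$chrom_index[1]
  ds1$variants$chrom <- "1"
  ds1 <- lemma:::new_dataset(ds1$sample_ids, ds1$genotypes, ds1$variants,
                             ds1$phenotype, ds1$covariates, ds1$environments)
  attr(ds1, "standardized") <- TRUE
  expect_error(loco_residuals(ds1, fit), "pseudo-chromosome")
})

test_that("GxE test is calibrated under a homoskedastic null", {
  set.seed(60)
  N <- 2000
  es <- rnorm(N)
  n_rep <- 5000
  p <- vapply(seq_len(n_rep), function(i) {
    x <- rbinom(N, 2, 0.3)
    y <- rnorm(N)
    gxe_single_snp_test(x, es, y)$p_gxe
  }, 1)
  rate <- mean(p < 0.01)
  ci <- 2.58 * sqrt(0.01 * 0.99 / n_rep)
  expect_lt(abs(rate - 0.01), ci)
})

test_that("F-test: t^2 identity, null uniformity, monotone power", {
  set.seed(61)
  n <- 300
  C <- matrix(rnorm(n), ncol = 1)
  E1 <- matrix(rnorm(n), ncol = 1)
  x <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  ft <- f_test(y, C, E1, x)
  df <- data.frame(y = y, c1 = C[, 1], e1 = E1[, 1], x = x)
  fit <- lm(y ~ c1 + e1 + x + x:e1, data = df)
  tstat <- summary(fit)$coefficients["e1:x", "t value"]
  expect_equal(ft$statistic, tstat^2, tolerance = 1e-10)
  expect_equal(ft$df1, 1)

  # null p-values are uniform (Kolmogorov-Smirnov)
  n2 <- 500; L <- 5
  E <- matrix(rnorm(n2 * L), n2)
  ps <- vapply(1:2000, function(i) {
    f_test(rnorm(n2), NULL, E, rbinom(n2, 2, 0.3))$p_value
  }, 1)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / 2000))

  # power rises with planted interaction variance
  pvals <- vapply(c(0.05, 0.2, 0.5), function(b) {
    set.seed(62)
    xs <- (x - mean(x)) / sd(x)
    yy <- 0.1 * xs + b * xs * E1[, 1] + rnorm(n)
    f_test(yy, C, E1, x)$p_value
  }, 1)
  expect_true(all(diff(pvals) < 0))

  # rank deficiency is a hard error
  expect_error(f_test(y, cbind(C, C), E1, x), "rank")
})

test_that("robust F-test: 1-df identity and asymptotic agreement", {
  set.seed(63)
  n <- 400
  E1 <- matrix(rnorm(n), ncol = 1)
  x <- rbinom(n, 2, 0.4)
  y <- rnorm(n)
  rf <- robust_f_test(y, NULL, E1, x)
  # with L = 1 the Wald statistic is the squared robust z of the coefficient
  d <- lemma:::gxe_joint_design(y, NULL, E1, x)
  tau <- qr.coef(d$qr, y)
  vb <- brute_sandwich(d$H, y)
  z2 <- unname(tau[d$idx_gamma]^2 / vb[d$idx_gamma, d$idx_gamma])
  expect_equal(rf$statistic, z2, tolerance = 1e-10)

  # homoskedastic large-N: p-values track the plain F-test closely
  set.seed(64)
  N <- 5000; L <- 3
  E <- matrix(rnorm(N * L), N)
  pp <- t(vapply(1:150, function(i) {
    xx <- rbinom(N, 2, 0.3)
    yy <- rnorm(N)
    c(f_test(yy, NULL, E, xx)$p_value, robust_f_test(yy, NULL, E, xx)$p_value)
  }, numeric(2)))
  expect_gt(cor(pp[, 1], pp[, 2]), 0.99)
})

test_that("robust F-test stays calibrated under heteroskedasticity, plain F inflates", {
  set.seed(65)
  N <- 1000
  E1 <- matrix(rnorm(N), ncol = 1)
  n_rep <- 1500
  pp <- t(vapply(seq_len(n_rep), function(i) {
    x <- rbinom(N, 2, 0.3)
    y <- rnorm(N, sd = sqrt(0.2 + E1[, 1]^2))  # variance rises with |E1|, no GxE
    c(plain = f_test(y, NULL, E1, x)$p_value,
      robust = robust_f_test(y, NULL, E1, x)$p_value)
  }, numeric(2)))
  alpha <- 0.05
  ci <- 2.58 * sqrt(alpha * (1 - alpha) / n_rep)
  expect_lt(abs(mean(pp[, "robust"] < alpha) - alpha), ci)
  expect_gt(mean(pp[, "plain"] < alpha), alpha + ci)
})

test_that("squared-environment screening detects and Bonferroni-controls", {
  set.seed(66)
  n <- 800; L <- 4
  E <- standardize_columns(matrix(rnorm(n * L), n))
  y <- E[, 1]^2 + rnorm(n, sd = 0.5)
  out <- detect_squared_env(y, NULL, E)
  expect_true(out$report$included[1])
  expect_false(any(out$report$included[-1]))
  expect_equal(ncol(out$covariates), 1)

  # adding the detected column reduces the residual variance of a refit
  rss0 <- sum(lm(y ~ E[, 1]^2 * 0 + 1)$residuals^2)
  rss1 <- sum(lm(y ~ out$covariates)$residuals^2)
  expect_lt(rss1, rss0)

  # family-wise inclusion under the null stays near the Bonferroni level
  n_rep <- 400
  any_inc <- vapply(seq_len(n_rep), function(i) {
    yy <- rnorm(200)
    EE <- standardize_columns(matrix(rnorm(200 * 10), 200))
    any(detect_squared_env(yy, NULL, EE)$report$included)
  }, TRUE)
  # familywise rate should be at most ~alpha = 0.01 up to Monte-Carlo error
  expect_lt(mean(any_inc), 0.01 + 2.58 * sqrt(0.01 * 0.99 / n_rep))
})

test_that("interaction profile concentrates on the causal environment", {
  set.seed(67)
  n <- 1500; L <- 4
  E <- standardize_columns(matrix(rnorm(n * L), n))
  x <- standardize_columns(cbind(rbinom(n, 2, 0.4)))[, 1]
  y <- 0.1 * x + 0.5 * x * E[, 1] + rnorm(n)
  prof <- snp_interaction_profile(y, NULL, E, x, es = E[, 1])
  expect_gt(abs(prof$w_ls[1]), 3 * max(abs(prof$w_ls[-1])))
  expect_gt(prof$r2_with_es, 0.9)

  # r2 = 1 when the supplied score is proportional to the local profile
  prof2 <- snp_interaction_profile(y, NULL, E, x, es = -2.5 * prof$eta_ls)
  expect_equal(prof2$r2_with_es, 1, tolerance = 1e-12)
  # and invariant to rescaling of the score
  prof3 <- snp_interaction_profile(y, NULL, E, x, es = 10 * E[, 1])
  expect_equal(prof3$r2_with_es, prof$r2_with_es, tolerance = 1e-12)
})

test_that("weight rescaling recovers and rescales exactly", {
  set.seed(68)
  n <- 200
  E <- standardize_columns(matrix(rnorm(n * 3), n))
  w <- c(0.5, -0.2, 0.1)
  es <- drop(E %*% w)
  r1 <- rescale_weights(es, E)
  expect_equal(unname(r1$weights), w, tolerance = 1e-10)
  expect_equal(r1$residual_norm, 0, tolerance = 1e-8)
  r2 <- rescale_weights(es, 2 * E)
  expect_equal(unname(r2$weights), w / 2, tolerance = 1e-10)
  r3 <- rescale_weights(es, E[, 1:2])
  expect_gt(r3$residual_norm, 0.1)
  expect_error(rescale_weights(es, cbind(E, E[, 1])), "rank")
})

test_that("marginal ES recovers additive environment effects", {
  set.seed(69)
  n <- 1000
  E <- standardize_columns(matrix(rnorm(n * 3), n))
  C <- matrix(rnorm(n), ncol = 1)
  v <- c(0.5, 0, -0.3)
  y <- drop(E %*% v) + drop(C) * 0.2 + rnorm(n, sd = 0.3)
  m <- marginal_es(y, C, E)
  expect_gt(cor(m, drop(E %*% v)), 0.99)
  y0 <- rnorm(n)
  m0 <- marginal_es(y0, C, E)
  expect_lt(sd(m0), 0.1)
})
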