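test_that("initialization is deterministic, seed-sensitive, label-ordered", {
  fx <- make_sim_dataset(N = 80, M = 30, L = 4, seed = 3)
  i1 <- initialize_state(fx$ds, fit_config(seed = 5))
  i2 <- initialize_state(fx$ds, fit_config(seed = 5))
  i3 <- initialize_state(fx$ds, fit_config(seed = 6))
  expect_identical(i1$state$mu_w, i2$state$mu_w)
  expect_false(identical(i1$state$mu_w, i3$state$mu_w))
  expect_true(all(i1$state$bbar == 0) && all(i1$state$gbar == 0))
  expect_gte(i1$phi$sigma_b1, i1$phi$sigma_b2)
  expect_gte(i1$phi$sigma_g1, i1$phi$sigma_g2)

  ds0 <- fx$ds
  ds0$environments <- matrix(numeric(0), nrow = 80, ncol = 0)
  expect_error(initialize_state(ds0, fit_config()), "at least one environ")
})

test_that("conjugate single-SNP limit: exact ridge posterior and tight ELBO", {
  set.seed(11)
  N <- 60
  x <- rnorm(N)
  y <- 0.4 * x + rnorm(N)
  # zero environment column puts the interaction block out of the model
  ds <- wrap_dataset(cbind(x), y, matrix(0, N, 1))
  phi <- hyperparameters(sigma_e2 = 1.2, sigma_b1 = 0.5, sigma_b2 = 0.5,
                         sigma_g1 = 1e-4, sigma_g2 = 1e-4, lambda_b = 1,
                         lambda_g = 0.1)
  st <- initialize_state(ds, fit_config(seed = 1))$state
  st$mu_w[] <- 0; st$s_w[] <- 1
  st <- recompute_cache(st, ds)
  st <- coordinate_ascent_pass(st, phi, ds, update_w = FALSE)
  ridge <- sum(x * y) / (sum(x^2) + 1 / 0.5)
  expect_equal(st$bbar[1], ridge, tolerance = 1e-12)

  # ELBO at the optimum equals the closed-form Gaussian log marginal
  for (i in 1:5) st <- coordinate_ascent_pass(st, phi, ds, update_w = FALSE)
  S <- 1.2 * (diag(N) + 0.5 * tcrossprod(x))
  logmarg <- -0.5 * as.numeric(determinant(S)$modulus) -
    0.5 * drop(crossprod(y, solve(S, y))) - N / 2 * log(2 * pi)
  at_opt <- compute_elbo(st, phi, ds)
  expect_equal(at_opt, logmarg, tolerance = 1e-8)

  # any non-optimal q sits strictly below the marginal likelihood
  st_bad <- st
  st_bad$mub1 <- st_bad$mub1 + 0.5
  st_bad$bbar <- st_bad$bbar + 0.5
  st_bad <- recompute_cache(st_bad, ds)
  expect_lt(compute_elbo(st_bad, phi, ds), logmarg)

  # inflating sigma_e2 away from its fitted value lowers the ELBO
  phi_bad <- phi; phi_bad$sigma_e2 <- phi$sigma_e2 * 1000
  expect_lt(compute_elbo(st, phi_bad, ds), at_opt)
})

test_that("multi-SNP conjugate limit converges to the ridge posterior mean", {
  set.seed(12)
  N <- 150; M <- 40
  X <- matrix(rnorm(N * M), N)
  beta <- rnorm(M, 0, 0.2)
  y <- drop(X %*% beta) + rnorm(N)
  ds <- wrap_dataset(X, y, matrix(0, N, 1))
  v <- 0.05
  phi <- hyperparameters(sigma_e2 = 1, sigma_b1 = v, sigma_b2 = v,
                         sigma_g1 = 1e-6, sigma_g2 = 1e-6, lambda_b = 1,
                         lambda_g = 1e-6)
  st <- initialize_state(ds, fit_config(seed = 2))$state
  st$mu_w[] <- 0; st$s_w[] <- 1
  st <- recompute_cache(st, ds)
  for (i in 1:300) st <- coordinate_ascent_pass(st, phi, ds, update_w = FALSE)
  expect_equal(st$bbar, drop(ridge_posterior_mean(X, y, v)), tolerance = 1e-6)
})

test_that("passes never decrease the ELBO and caches match recomputation", {
  for (s in 1:5) {
    fx <- make_sim_dataset(N = 120, M = 60, L = 3, n_causal_main = 10,
                           n_causal_gxe = 5, n_std = 2, seed = 20 + s)
    init <- initialize_state(fx$ds, fit_config(seed = s))
    st <- init$state
    phi <- init$phi
    prev <- -Inf
    for (p in 1:8) {
      st <- coordinate_ascent_pass(st, phi, fx$ds)
      el <- compute_elbo(st, phi, fx$ds)
      expect_gte(el, prev - 1e-8 * abs(prev))
      prev <- el
    }
    st_chk <- recompute_cache(st, fx$ds)
    expect_equal(st_chk$resid, st$resid, tolerance = 1e-6)
    expect_equal(st_chk$vb, st$vb, tolerance = 1e-6)
    expect_equal(st_chk$vg, st$vg, tolerance = 1e-6)
    expect_equal(st_chk$eta, st$eta, tolerance = 1e-10)
  }
})

test_that("no-signal phenotype shrinks posterior means toward zero", {
  set.seed(30)
  N <- 200; M <- 40
  X <- standardize_columns(matrix(rbinom(N * M, 2, 0.3) + 0.0, N))
  E <- standardize_columns(matrix(rnorm(N * 2), N))
  y <- rnorm(N)  # independent of X and E
  ds <- wrap_dataset(X, y, E)
  fit <- suppressWarnings(lemma_fit(ds, fit_config(max_passes = 40, seed = 4)))
  expect_lt(max(abs(fit$beta_hat)), 0.1)
  expect_lt(mean(abs(fit$gamma_hat)), 0.05)
  # mixture weights drift toward the sparse end on pure noise
  expect_lt(fit$phi$lambda_g, 0.1)
})

test_that("M-step is monotone, clamps lambda, and fixes sigma_a2", {
  for (s in 1:20) {
    set.seed(300 + s)
    N <- 80; M <- 30
    X <- standardize_columns(matrix(rnorm(N * M), N))
    E <- standardize_columns(matrix(rnorm(N * 2), N))
    y <- drop(X %*% rnorm(M, 0, 0.1)) + rnorm(N)
    ds <- wrap_dataset(X, y, E)
    init <- initialize_state(ds, fit_config(seed = s, sigma_a2 = 50))
    st <- coordinate_ascent_pass(init$state, init$phi, ds)
    phi_new <- maximize_hyperparameters(st, ds, sigma_a2 = init$phi$sigma_a2)
    expect_gte(compute_elbo(st, phi_new, ds),
               compute_elbo(st, init$phi, ds) - 1e-8)
    expect_identical(phi_new$sigma_a2, 50)
  }

  # all-slab responsibilities: lambda update hits the upper clamp
  st2 <- st
  st2$rb[] <- 1
  phi2 <- maximize_hyperparameters(st2, ds)
  expect_equal(phi2$lambda_b, 1 - 1e-6)
})

test_that("SQUAREM step reproduces the hand-computed cases", {
  # scalar sequence (0, 0.5, 0.75): v = -4, extrapolation returns 0
  expect_equal(squarem_step(0, 0.5, 0.75), 0)
  # equal first/second difference norms force v = -1: phi_t comes back exactly
  expect_equal(squarem_step(c(0, 1), c(1, 2), c(3, 4)), c(3, 4))
  # arithmetic progression (second difference zero) degenerates to phi_t
  expect_equal(squarem_step(1, 2, 3), 3)
  # backtracking halves v toward -1: one halving gives v = -2.5 and
  # phi = 0 - 2(-2.5)(0.5) + 6.25(-0.25) = 0.9375
  got <- squarem_step(0, 0.5, 0.75, in_domain = function(v) v > 0.7)
  expect_equal(got, 0.9375)
})

test_that("environmental score identities", {
  set.seed(31)
  E <- qr.Q(qr(matrix(rnorm(100 * 3), 100))) * sqrt(99)  # orthonormal scaled
  w <- c(0.5, -1, 2)
  expect_equal(environmental_score(E, rep(0, 3)), rep(0, 100))
  expect_equal(environmental_score(E[, 1, drop = FALSE], 1), E[, 1])
  expect_equal(sum(environmental_score(E, w)^2), sum(w^2) * 99,
               tolerance = 1e-10)
  expect_error(environmental_score(E, c(1, 2)), "dimension mismatch")
})

test_that("doubling the ELBO tolerance never increases the pass count", {
  fx <- make_sim_dataset(N = 300, M = 100, L = 3, seed = 9)
  f1 <- lemma_fit(fx$ds, fit_config(elbo_tol = 0.01, seed = 2))
  f2 <- lemma_fit(fx$ds, fit_config(elbo_tol = 0.02, seed = 2))
  f3 <- lemma_fit(fx$ds, fit_config(elbo_tol = 0.04, seed = 2))
  expect_lte(f2$n_passes, f1$n_passes)
  expect_lte(f3$n_passes, f2$n_passes)
})

test_that("identical seeds give bit-identical ELBO traces", {
  fx <- make_sim_dataset(N = 200, M = 80, L = 3, seed = 13)
  f1 <- lemma_fit(fx$ds, fit_config(seed = 7, max_passes = 30))
  f2 <- lemma_fit(fx$ds, fit_config(seed = 7, max_passes = 30))
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$w_hat, f2$w_hat)
})

test_that("environment rescaling: invariant score, prior-normalized weights", {
  # Along the w/gamma scale degeneracy the optimum balances the N(0, I)
  # prior on w against its entropy, pinning E_q||w||^2 near L. Rescaling E
  # by c therefore leaves the fitted weight vector (and the score direction)
  # essentially unchanged while the interaction effects absorb 1/c; moving
  # weights onto a recoded design is the job of least-squares re-extraction.
  fx <- make_sim_dataset(N = 800, M = 100, L = 3, var_gxe = 0.15,
                         n_causal_gxe = 30, seed = 17)
  cfg <- fit_config(seed = 3, elbo_tol = 1e-3, max_passes = 500)
  base <- lemma_fit(fx$ds, cfg)
  expect_equal(sum(base$w_hat^2 + base$w_sd^2), 3, tolerance = 0.25)
  for (cc in c(0.5, 2)) {
    ds_c <- fx$ds
    ds_c$environments <- fx$ds$environments * cc
    fit_c <- lemma_fit(ds_c, cfg)
    # the learned score is (numerically) scale-free ...
    expect_gt(abs(cor(fit_c$es, base$es)), 0.999)
    # ... the weight vector itself barely moves ...
    expect_equal(fit_c$w_hat, base$w_hat, tolerance = 0.1)
    # ... and least-squares re-extraction transfers it across scales exactly
    w_back <- rescale_weights(fit_c$es, fx$ds$environments)$weights
    expect_equal(unname(w_back), cc * fit_c$w_hat, tolerance = 1e-8)
  }
})

test_that("fitted environment weights recover the active-environment pattern", {
  fx <- make_sim_dataset(N = 2000, M = 1000, L = 5, n_active = 2,
                         var_gxe = 0.1, n_causal_main = 100,
                         n_causal_gxe = 100, seed = 23)
  fit <- lemma_fit(fx$ds, fit_config(seed = 5))
  # |correlation| with the true score; sign is unidentifiable
  expect_gt(abs(cor(fit$es, fx$truth$eta)), 0.8)
  w <- fit$w_hat * sign(cor(fit$es, fx$truth$eta))
  active <- fx$truth$active_env
  expect_gt(min(abs(w[active])), max(abs(w[-active])))
})
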