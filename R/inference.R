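#' Hyper-parameter set of the whole-genome regression
#'
#' The model has eight hyper-parameters: the residual variance, slab and spike
#' variance scales of the mixture-of-Gaussians priors on main (`sigma_b1 >=
#' sigma_b2`) and interaction (`sigma_g1 >= sigma_g2`) effects, the two
#' mixture weights, and the (fixed, large) covariate prior variance. Effect
#' prior variances are scaled by `sigma_e2`, i.e. the slab for main effects is
#' N(0, `sigma_e2 * sigma_b1`).
#'
#' @param sigma_e2 Residual variance.
#' @param sigma_b1,sigma_b2 Slab/spike variance scales for main effects.
#' @param sigma_g1,sigma_g2 Slab/spike variance scales for interaction effects.
#' @param lambda_b,lambda_g Slab mixture weights, clamped to
#'   `[1e-6, 1 - 1e-6]`.
#' @param sigma_a2 Covariate prior variance (held fixed, default 100).
#' @return An object of class `lemma_hyper`.
#' @export
hyperparameters <- function(sigma_e2 = 1, sigma_b1 = 1e-3, sigma_b2 = 1e-5,
                            sigma_g1 = 1e-4, sigma_g2 = 1e-6,
                            lambda_b = 0.1, lambda_g = 0.1, sigma_a2 = 100) {
  phi <- list(sigma_e2 = sigma_e2, sigma_b1 = sigma_b1, sigma_b2 = sigma_b2,
              sigma_g1 = sigma_g1, sigma_g2 = sigma_g2,
              lambda_b = clamp_lambda(lambda_b), lambda_g = clamp_lambda(lambda_g),
              sigma_a2 = sigma_a2)
  vars <- unlist(phi[c("sigma_e2", "sigma_b1", "sigma_b2", "sigma_g1",
                       "sigma_g2", "sigma_a2")])
  if (any(vars <= 0)) stop("all hyper-parameter variances must be positive")
  if (phi$sigma_b1 < phi$sigma_b2 || phi$sigma_g1 < phi$sigma_g2) {
    stop("labeling constraint violated: slab variance must be >= spike variance")
  }
  structure(phi, class = "lemma_hyper")
}

clamp_lambda <- function(x) min(max(x, 1e-6), 1 - 1e-6)

#' Fit configuration
#'
#' @param covariate_mode `"variational"` models covariates as random effects
#'   inside the variational approximation; `"project-out"` residualizes the
#'   phenotype on the covariates once, before fitting.
#' @param elbo_tol Convergence threshold: the fit stops when a full pass
#'   changes the ELBO by less than this (absolute), default 0.01.
#' @param max_passes Maximum number of full passes.
#' @param seed Seed for the symmetry-breaking initialization of the
#'   environment-weight means.
#' @param sigma_a2 Covariate prior variance.
#' @param use_squarem Apply SQUAREM acceleration to the hyper-parameter
#'   sequence.
#' @param update_hyper Run the variational-EM hyper-parameter updates; setting
#'   `FALSE` fixes the hyper-parameters (used for conjugate-limit checks).
#' @return An object of class `lemma_fit_config`.
#' @export
fit_config <- function(covariate_mode = c("variational", "project-out"),
                       elbo_tol = 0.01, max_passes = 200, seed = 1,
                       sigma_a2 = 100, use_squarem = TRUE,
                       update_hyper = TRUE) {
  covariate_mode <- match.arg(covariate_mode)
  stopifnot(elbo_tol > 0, max_passes >= 1)
  structure(list(covariate_mode = covariate_mode, elbo_tol = elbo_tol,
                 max_passes = max_passes, seed = seed, sigma_a2 = sigma_a2,
                 use_squarem = use_squarem, update_hyper = update_hyper),
            class = "lemma_fit_config")
}

#' Initialize the variational state and hyper-parameters
#'
#' Deterministic for a fixed seed. Posterior means of SNP effects start at
#' zero; environment-weight means are drawn N(0, 1/L) to break the symmetry
#' of the interaction term. Initial hyper-parameters put 10% expected
#' explained variance on main effects and 1% on interactions, with slab
#' weights 0.1 and spike variances 100 times smaller than the slabs.
#'
#' @param dataset A standardized `lemma_dataset`.
#' @param config A [fit_config()].
#' @return List with elements `state` and `phi`.
#' @export
initialize_state <- function(dataset, config = fit_config()) {
  X <- dataset$genotypes
  E <- dataset$environments
  C <- dataset$covariates
  y <- dataset$phenotype
  N <- nrow(X); M <- ncol(X); L <- ncol(E)
  if (L == 0) {
    stop("model requires at least one environmental variable (L = 0 reduces ",
         "to a main-effects-only regression, which is unsupported)")
  }
  lambda <- 0.1
  phi <- hyperparameters(
    sigma_e2 = 1,
    sigma_b1 = 0.1 / (M * lambda), sigma_b2 = 0.1 / (M * lambda) / 100,
    sigma_g1 = 0.01 / (M * lambda), sigma_g2 = 0.01 / (M * lambda) / 100,
    lambda_b = lambda, lambda_g = lambda, sigma_a2 = config$sigma_a2)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(config$seed)
  mu_w <- stats::rnorm(L, 0, sqrt(1 / L))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  s_w <- rep(1 / L, L)
  bvar0 <- phi$sigma_e2 * (lambda * phi$sigma_b1 + (1 - lambda) * phi$sigma_b2)
  gvar0 <- phi$sigma_e2 * (lambda * phi$sigma_g1 + (1 - lambda) * phi$sigma_g2)
  eta <- drop(E %*% mu_w)
  state <- structure(list(
    mu_alpha = rep(0, ncol(C)), s_alpha = rep(1, ncol(C)),
    mub1 = rep(0, M), mub2 = rep(0, M),
    sb1 = rep(phi$sigma_e2 * phi$sigma_b1, M),
    sb2 = rep(phi$sigma_e2 * phi$sigma_b2, M),
    rb = rep(lambda, M), bbar = rep(0, M), bvar = rep(bvar0, M),
    mug1 = rep(0, M), mug2 = rep(0, M),
    sg1 = rep(phi$sigma_e2 * phi$sigma_g1, M),
    sg2 = rep(phi$sigma_e2 * phi$sigma_g2, M),
    rg = rep(lambda, M), gbar = rep(0, M), gvar = rep(gvar0, M),
    mu_w = mu_w, s_w = s_w,
    resid = y, xg = rep(0, N),
    vb = xsq_rowsum_cpp(X, rep(bvar0, M)),
    vg = xsq_rowsum_cpp(X, rep(gvar0, M)),
    eta = eta, veta = xsq_rowsum_cpp(E, s_w),
    xtx = drop(col_sumsq_cpp(X)), ctc = drop(col_sumsq_cpp(C)),
    n = N), class = "lemma_state")
  state <- structure(canonicalize_state(state), class = "lemma_state")
  list(state = state, phi = phi)
}

#' One coordinate-ascent pass over all variational factors
#'
#' Updates each factor to its optimal closed form given the others, in the
#' order: covariates, then per SNP the main-effect and interaction factors in
#' genome order, then the environment weights. At fixed hyper-parameters a
#' pass never decreases the ELBO.
#'
#' @param state A `lemma_state`.
#' @param phi A [hyperparameters()] object.
#' @param dataset The standardized `lemma_dataset` the state was built from.
#' @param update_w Update the environment-weight factors (default `TRUE`).
#' @return The updated `lemma_state`.
#' @export
coordinate_ascent_pass <- function(state, phi, dataset, update_w = TRUE) {
  out <- coord_pass_cpp(dataset$genotypes, dataset$environments,
                        dataset$covariates, dataset$phenotype, state, phi,
                        update_w)
  structure(canonicalize_state(out), class = "lemma_state")
}

# plain unnamed numeric vectors everywhere (C++ returns N x 1 matrices)
canonicalize_state <- function(state) {
  lapply(state, function(x) if (is.numeric(x)) as.vector(x) else x)
}

#' Recompute the running caches of a state from scratch
#'
#' Used to validate the incrementally maintained residual and second-moment
#' vectors against their definitions.
#'
#' @inheritParams coordinate_ascent_pass
#' @return The state with caches rebuilt.
#' @export
recompute_cache <- function(state, dataset) {
  X <- dataset$genotypes; E <- dataset$environments; C <- dataset$covariates
  state$eta <- drop(E %*% state$mu_w)
  state$veta <- drop(xsq_rowsum_cpp(E, state$s_w))
  state$xg <- drop(X %*% state$gbar)
  ca <- if (ncol(C) > 0) drop(C %*% state$mu_alpha) else 0
  state$resid <- dataset$phenotype - ca - drop(X %*% state$bbar) -
    state$eta * state$xg
  state$vb <- drop(xsq_rowsum_cpp(X, state$bvar))
  state$vg <- drop(xsq_rowsum_cpp(X, state$gvar))
  state$xtx <- drop(col_sumsq_cpp(X))
  state$ctc <- drop(col_sumsq_cpp(C))
  structure(canonicalize_state(state), class = "lemma_state")
}

# Expected squared residual norm under q, including all variational second
# moments (the sigma_e2 M-step numerator).
expected_rss <- function(state) {
  eta2 <- state$eta^2 + state$veta
  sum(state$resid^2) +
    sum(state$s_alpha * state$ctc) +
    sum(state$vb) +
    sum(eta2 * state$vg + state$veta * state$xg^2)
}

xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# Prior-minus-entropy contribution of one mixture block (beta or gamma).
mog_elbo_term <- function(r, mu1, mu2, s1, s2, lambda, v1, v2, sigma_e2) {
  r2 <- 1 - r
  sum(r * (log(lambda) - 0.5 * log(2 * pi * sigma_e2 * v1) -
             (mu1^2 + s1) / (2 * sigma_e2 * v1) + 0.5 * log(2 * pi * exp(1) * s1)) +
      r2 * (log1p(-lambda) - 0.5 * log(2 * pi * sigma_e2 * v2) -
              (mu2^2 + s2) / (2 * sigma_e2 * v2) + 0.5 * log(2 * pi * exp(1) * s2)) -
      xlogx(r) - xlogx(r2))
}

#' Evidence lower bound of a variational state
#'
#' @inheritParams coordinate_ascent_pass
#' @return The ELBO (a scalar).
#' @export
compute_elbo <- function(state, phi, dataset = NULL) {
  N <- state$n
  erss <- expected_rss(state)
  elbo <- -N / 2 * log(2 * pi * phi$sigma_e2) - erss / (2 * phi$sigma_e2)
  if (length(state$mu_alpha) > 0) {
    elbo <- elbo + sum(-0.5 * log(2 * pi * phi$sigma_a2) -
                         (state$mu_alpha^2 + state$s_alpha) / (2 * phi$sigma_a2) +
                         0.5 * log(2 * pi * exp(1) * state$s_alpha))
  }
  elbo <- elbo + sum(-0.5 * log(2 * pi) - (state$mu_w^2 + state$s_w) / 2 +
                       0.5 * log(2 * pi * exp(1) * state$s_w))
  elbo <- elbo + mog_elbo_term(state$rb, state$mub1, state$mub2, state$sb1,
                               state$sb2, phi$lambda_b, phi$sigma_b1,
                               phi$sigma_b2, phi$sigma_e2)
  elbo <- elbo + mog_elbo_term(state$rg, state$mug1, state$mug2, state$sg1,
                               state$sg2, phi$lambda_g, phi$sigma_g1,
                               phi$sigma_g2, phi$sigma_e2)
  elbo
}

#' Variational-EM hyper-parameter update (M-step)
#'
#' Closed-form joint maximizer of the ELBO at fixed variational parameters:
#' the mixture weights become mean slab responsibilities, the residual
#' variance the expected residual sum of squares over N, and each component
#' scale the responsibility-weighted mean of the component second moment
#' divided by the new residual variance. `sigma_a2` is untouched.
#'
#' @inheritParams coordinate_ascent_pass
#' @param sigma_a2 The fixed covariate prior variance carried over.
#' @return A [hyperparameters()] object.
#' @export
maximize_hyperparameters <- function(state, dataset = NULL, sigma_a2 = 100) {
  N <- state$n
  sigma_e2 <- expected_rss(state) / N
  comp_scale <- function(r, mu1, mu2, s1, s2) {
    w1 <- sum(r); w2 <- sum(1 - r)
    v1 <- if (w1 > 0) sum(r * (mu1^2 + s1)) / (w1 * sigma_e2) else NA_real_
    v2 <- if (w2 > 0) sum((1 - r) * (mu2^2 + s2)) / (w2 * sigma_e2) else NA_real_
    if (!is.finite(v1) || v1 < 1e-10) {
      warning("empty slab responsibility mass; component variance floored")
      v1 <- 1e-10
    }
    if (!is.finite(v2) || v2 < 1e-10) v2 <- 1e-10
    c(v1, v2)
  }
  vb <- comp_scale(state$rb, state$mub1, state$mub2, state$sb1, state$sb2)
  vg <- comp_scale(state$rg, state$mug1, state$mug2, state$sg1, state$sg2)
  phi <- list(sigma_e2 = sigma_e2, sigma_b1 = vb[1], sigma_b2 = vb[2],
              sigma_g1 = vg[1], sigma_g2 = vg[2],
              lambda_b = clamp_lambda(mean(state$rb)),
              lambda_g = clamp_lambda(mean(state$rg)),
              sigma_a2 = sigma_a2)
  structure(phi, class = "lemma_hyper")
}

# Swapping prior component labels together with the matching variational
# component blocks leaves the ELBO invariant; used to keep slab >= spike.
enforce_labeling <- function(phi, state) {
  if (phi$sigma_b1 < phi$sigma_b2) {
    phi[c("sigma_b1", "sigma_b2")] <- phi[c("sigma_b2", "sigma_b1")]
    phi$lambda_b <- clamp_lambda(1 - phi$lambda_b)
    state[c("mub1", "mub2")] <- state[c("mub2", "mub1")]
    state[c("sb1", "sb2")] <- state[c("sb2", "sb1")]
    state$rb <- 1 - state$rb
  }
  if (phi$sigma_g1 < phi$sigma_g2) {
    phi[c("sigma_g1", "sigma_g2")] <- phi[c("sigma_g2", "sigma_g1")]
    phi$lambda_g <- clamp_lambda(1 - phi$lambda_g)
    state[c("mug1", "mug2")] <- state[c("mug2", "mug1")]
    state[c("sg1", "sg2")] <- state[c("sg2", "sg1")]
    state$rg <- 1 - state$rg
  }
  list(phi = phi, state = state)
}

phi_to_unconstrained <- function(phi) {
  c(log(phi$sigma_e2), log(phi$sigma_b1), log(phi$sigma_b2),
    log(phi$sigma_g1), log(phi$sigma_g2),
    stats::qlogis(phi$lambda_b), stats::qlogis(phi$lambda_g))
}

phi_from_unconstrained <- function(v, sigma_a2) {
  structure(list(sigma_e2 = exp(v[1]), sigma_b1 = exp(v[2]), sigma_b2 = exp(v[3]),
                 sigma_g1 = exp(v[4]), sigma_g2 = exp(v[5]),
                 lambda_b = clamp_lambda(stats::plogis(v[6])),
                 lambda_g = clamp_lambda(stats::plogis(v[7])),
                 sigma_a2 = sigma_a2), class = "lemma_hyper")
}

#' SQUAREM extrapolation step
#'
#' Squared-extrapolation acceleration of a fixed-point (EM-type) sequence.
#' Given three successive iterates (numeric vectors on an unconstrained
#' scale), computes the step size `v = min(-1, -||d1||^2 / ||d2||^2)` with
#' `d1 = phi_t1 - phi_t2` and `d2 = phi_t - 2 phi_t1 + phi_t2` and returns
#' `phi_t2 - 2 v d1 + v^2 d2`. At `v = -1` this is exactly `phi_t`. If an
#' `in_domain` predicate is supplied and rejects the extrapolation, the
#' distance between `v` and -1 is halved, up to `max_backtrack` times,
#' falling back to `phi_t`.
#'
#' @param phi_t2,phi_t1,phi_t Three successive iterates (oldest first).
#' @param in_domain Optional predicate on the candidate vector.
#' @param max_backtrack Maximum halvings (default 5).
#' @return The extrapolated iterate (a numeric vector).
#' @export
squarem_step <- function(phi_t2, phi_t1, phi_t, in_domain = NULL,
                         max_backtrack = 5) {
  d1 <- phi_t1 - phi_t2
  d2 <- phi_t - 2 * phi_t1 + phi_t2
  nd2 <- sum(d2^2)
  if (nd2 == 0) return(phi_t)
  v <- min(-1, -sum(d1^2) / nd2)
  extrap <- function(v) phi_t2 - 2 * v * d1 + v^2 * d2
  cand <- extrap(v)
  if (!is.null(in_domain)) {
    tries <- 0
    while (!isTRUE(in_domain(cand)) && tries < max_backtrack) {
      v <- (v + (-1)) / 2
      cand <- extrap(v)
      tries <- tries + 1
    }
    if (!isTRUE(in_domain(cand))) return(phi_t)
  }
  cand
}

#' Fit the whole-genome GxE regression by variational inference
#'
#' Alternates full coordinate-ascent passes with variational-EM
#' hyper-parameter updates, applying SQUAREM acceleration to the
#' hyper-parameter sequence (on the log/logit scale, with an ELBO guard), and
#' stops when a full pass changes the ELBO by less than `config$elbo_tol`.
#' The phenotype is centered and scaled before fitting.
#'
#' @param dataset A `lemma_dataset`; standardized on the fly if needed.
#' @param config A [fit_config()].
#' @return A `lemma_fit` object: posterior means `alpha_hat`, `beta_hat`,
#'   `gamma_hat`, `w_hat` (with posterior SDs `w_sd`), the environmental
#'   score `es`, slab responsibilities `rb`/`rg`, final hyper-parameters
#'   `phi`, `elbo_trace`, `n_passes`, `converged`, and the final `state`.
#' @export
lemma_fit <- function(dataset, config = fit_config()) {
  dataset <- standardize_dataset(dataset)
  y <- dataset$phenotype
  dataset$phenotype <- (y - mean(y)) / stats::sd(y)
  if (config$covariate_mode == "project-out" && ncol(dataset$covariates) > 0) {
    qr_c <- qr(cbind(1, dataset$covariates))
    dataset$phenotype <- qr.resid(qr_c, dataset$phenotype)
    dataset$covariates <- matrix(numeric(0), nrow = nrow(dataset$genotypes),
                                 ncol = 0)
  }
  init <- initialize_state(dataset, config)
  state <- init$state
  phi <- init$phi
  phi_trace <- list(phi)
  elbo_trace <- numeric(0)
  buf <- list()
  converged <- FALSE
  n_passes <- 0
  phi_fallback <- NULL  # unaccelerated EM estimate backing a SQUAREM try
  state_before <- NULL
  squarem_domain <- function(v) {
    all(is.finite(v)) && all(abs(v) < 600) && v[2] >= v[3] && v[4] >= v[5]
  }
  for (t in seq_len(config$max_passes)) {
    n_passes <- t
    if (!is.null(phi_fallback)) state_before <- state
    state <- coordinate_ascent_pass(state, phi, dataset)
    elbo_t <- compute_elbo(state, phi)
    if (!is.null(phi_fallback)) {
      # an accelerated phi is on trial: accept only if the pass it produced
      # kept the ELBO sequence non-decreasing, else redo with the EM update
      prev <- elbo_trace[length(elbo_trace)]
      if (!is.finite(elbo_t) || elbo_t < prev - 1e-8 * abs(prev)) {
        phi <- phi_fallback
        state <- coordinate_ascent_pass(state_before, phi, dataset)
        elbo_t <- compute_elbo(state, phi)
        buf <- list(phi_to_unconstrained(phi))
      }
      phi_fallback <- NULL
    }
    if (config$update_hyper) {
      phi_em <- maximize_hyperparameters(state, dataset, phi$sigma_a2)
      lab <- enforce_labeling(phi_em, state)
      phi_em <- lab$phi
      state <- lab$state
      phi_new <- phi_em
      if (config$use_squarem) {
        buf[[length(buf) + 1]] <- phi_to_unconstrained(phi_em)
        if (length(buf) >= 3) {
          nb <- length(buf)
          cand_u <- squarem_step(buf[[nb - 2]], buf[[nb - 1]], buf[[nb]],
                                 in_domain = squarem_domain)
          cand <- phi_from_unconstrained(cand_u, phi$sigma_a2)
          if (!identical(cand_u, buf[[nb]])) {
            phi_new <- cand
            phi_fallback <- phi_em  # judged after the next pass
          }
          buf <- list()
        }
      }
      phi <- phi_new
      phi_trace[[length(phi_trace) + 1]] <- phi
    }
    elbo_trace <- c(elbo_trace, elbo_t)
    if (t >= 2 && is.null(phi_fallback) &&
        abs(elbo_trace[t] - elbo_trace[t - 1]) < config$elbo_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("variational fit did not converge in ", config$max_passes,
            " passes")
  }
  es <- unname(drop(dataset$environments %*% state$mu_w))
  structure(list(
    alpha_hat = state$mu_alpha, beta_hat = state$bbar, gamma_hat = state$gbar,
    w_hat = state$mu_w, w_sd = sqrt(state$s_w), es = es,
    rb = state$rb, rg = state$rg,
    phi = phi, phi_trace = phi_trace, elbo_trace = elbo_trace,
    n_passes = n_passes, converged = converged, state = state,
    covariate_mode = config$covariate_mode),
    class = "lemma_fit")
}

#' @export
print.lemma_fit <- function(x, ...) {
  cat("lemma_fit:", x$n_passes, "passes,",
      if (x$converged) "converged" else "NOT converged",
      sprintf("(final ELBO %.3f)\n", utils::tail(x$elbo_trace, 1)))
  cat("  lambda_b =", signif(x$phi$lambda_b, 3),
      " lambda_g =", signif(x$phi$lambda_g, 3),
      " sigma_e2 =", signif(x$phi$sigma_e2, 3), "\n")
  invisible(x)
}

#' Environmental score from environments and weights
#'
#' @param environments N x L environment matrix.
#' @param w_hat Length-L weight vector.
#' @return The length-N score `E %*% w_hat`.
#' @export
environmental_score <- function(environments, w_hat) {
  environments <- as.matrix(environments)
  if (ncol(environments) != length(w_hat)) {
    stop("dimension mismatch: ", ncol(environments), " environments but ",
         length(w_hat), " weights")
  }
  drop(environments %*% w_hat)
}
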