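// Compiled kernels: one coordinate-ascent pass of the variational algorithm,
// in-place column standardization, a fast binomial genotype generator, and
// weighted column/row sum-of-squares helpers used for cache bookkeeping.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x > 35.0) return 1.0;
  if (x < -35.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Borrow an R matrix as an arma view without copying.
static arma::mat borrow(SEXP m) {
  NumericMatrix mm(m);
  return arma::mat(mm.begin(), mm.nrow(), mm.ncol(), false, true);
}

// One full pass: q(alpha_c) for all covariates, then per SNP q(beta_j, u_j)
// followed by q(gamma_j, v_j) in genome order, then q(w_l) for all
// environments.  State vectors are copied on entry and the updated copies
// returned, together with the running caches.
//
// Maintained caches (definitions the R side can re-derive from scratch):
//   resid = y - C a_bar - X b_bar - eta_bar * (X g_bar)   (elementwise *)
//   xg    = X g_bar
//   vb_i  = sum_j X_ij^2 Var(beta_j),  vg_i = sum_j X_ij^2 Var(gamma_j)
//   eta   = E w_bar,  veta_i = sum_l E_il^2 s_w[l]
// [[Rcpp::export]]
List coord_pass_cpp(SEXP Xs, SEXP Es, SEXP Cs, const arma::vec& y,
                    List state, List phi, bool update_w = true) {
  arma::mat X = borrow(Xs), E = borrow(Es), C = borrow(Cs);
  const arma::uword N = X.n_rows, M = X.n_cols, L = E.n_cols, Lc = C.n_cols;

  const double se2 = phi["sigma_e2"], sa2 = phi["sigma_a2"];
  const double sb1 = phi["sigma_b1"], sb2 = phi["sigma_b2"];
  const double sg1 = phi["sigma_g1"], sg2 = phi["sigma_g2"];
  const double lb = phi["lambda_b"], lg = phi["lambda_g"];

  arma::vec mu_alpha = as<arma::vec>(state["mu_alpha"]);
  arma::vec s_alpha  = as<arma::vec>(state["s_alpha"]);
  arma::vec mub1 = as<arma::vec>(state["mub1"]), mub2 = as<arma::vec>(state["mub2"]);
  arma::vec sb1v = as<arma::vec>(state["sb1"]),  sb2v = as<arma::vec>(state["sb2"]);
  arma::vec rb   = as<arma::vec>(state["rb"]);
  arma::vec bbar = as<arma::vec>(state["bbar"]), bvar = as<arma::vec>(state["bvar"]);
  arma::vec mug1 = as<arma::vec>(state["mug1"]), mug2 = as<arma::vec>(state["mug2"]);
  arma::vec sg1v = as<arma::vec>(state["sg1"]),  sg2v = as<arma::vec>(state["sg2"]);
  arma::vec rg   = as<arma::vec>(state["rg"]);
  arma::vec gbar = as<arma::vec>(state["gbar"]), gvar = as<arma::vec>(state["gvar"]);
  arma::vec mu_w = as<arma::vec>(state["mu_w"]), s_w = as<arma::vec>(state["s_w"]);
  arma::vec resid = as<arma::vec>(state["resid"]), xg = as<arma::vec>(state["xg"]);
  arma::vec vb = as<arma::vec>(state["vb"]), vg = as<arma::vec>(state["vg"]);
  arma::vec eta = as<arma::vec>(state["eta"]), veta = as<arma::vec>(state["veta"]);
  arma::vec xtx = as<arma::vec>(state["xtx"]), ctc = as<arma::vec>(state["ctc"]);

  const double log_odds_prior_b = std::log(lb) - std::log1p(-lb);
  const double log_odds_prior_g = std::log(lg) - std::log1p(-lg);

  // covariate factors (Gaussian prior N(0, sigma_a2), not scaled by sigma_e2)
  for (arma::uword c = 0; c < Lc; ++c) {
    const double prec = ctc[c] / se2 + 1.0 / sa2;
    const double lin = (arma::dot(C.col(c), resid) + ctc[c] * mu_alpha[c]) / se2;
    const double mu_new = lin / prec, s_new = 1.0 / prec;
    if (!std::isfinite(mu_new))
      stop("non-finite update for covariate factor %d", (int)(c + 1));
    resid -= C.col(c) * (mu_new - mu_alpha[c]);
    mu_alpha[c] = mu_new;
    s_alpha[c] = s_new;
  }

  arma::vec eta2 = arma::square(eta) + veta;  // E_q[eta_i^2], fixed over SNP loop

  for (arma::uword j = 0; j < M; ++j) {
    const arma::vec xj = X.col(j);  // no-copy would alias; col() copies (N doubles)
    const arma::vec xj2 = arma::square(xj);

    // -- main effect beta_j with two-component Gaussian mixture prior --
    {
      const double lin = arma::dot(xj, resid) + xtx[j] * bbar[j];
      const double d1 = xtx[j] + 1.0 / sb1, d2 = xtx[j] + 1.0 / sb2;
      const double m1 = lin / d1, m2 = lin / d2;
      const double s1 = se2 / d1, s2 = se2 / d2;
      const double lo = log_odds_prior_b +
        0.5 * (std::log(s1 / (se2 * sb1)) + m1 * m1 / s1) -
        0.5 * (std::log(s2 / (se2 * sb2)) + m2 * m2 / s2);
      const double r = sigmoid(lo);
      const double bb = r * m1 + (1.0 - r) * m2;
      const double eb2 = r * (m1 * m1 + s1) + (1.0 - r) * (m2 * m2 + s2);
      const double bv = eb2 - bb * bb;
      if (!std::isfinite(bb))
        stop("non-finite update for main-effect factor at SNP %d", (int)(j + 1));
      resid -= xj * (bb - bbar[j]);
      vb += xj2 * (bv - bvar[j]);
      mub1[j] = m1; mub2[j] = m2; sb1v[j] = s1; sb2v[j] = s2; rb[j] = r;
      bbar[j] = bb; bvar[j] = bv;
    }

    // -- interaction effect gamma_j (design column eta * x_j in expectation) --
    {
      const double dj = arma::dot(eta2, xj2);
      const double lin = arma::dot(xj, eta % resid - veta % xg) + dj * gbar[j];
      const double d1 = dj + 1.0 / sg1, d2 = dj + 1.0 / sg2;
      const double m1 = lin / d1, m2 = lin / d2;
      const double s1 = se2 / d1, s2 = se2 / d2;
      const double lo = log_odds_prior_g +
        0.5 * (std::log(s1 / (se2 * sg1)) + m1 * m1 / s1) -
        0.5 * (std::log(s2 / (se2 * sg2)) + m2 * m2 / s2);
      const double r = sigmoid(lo);
      const double gb = r * m1 + (1.0 - r) * m2;
      const double eg2 = r * (m1 * m1 + s1) + (1.0 - r) * (m2 * m2 + s2);
      const double gv = eg2 - gb * gb;
      if (!std::isfinite(gb))
        stop("non-finite update for interaction factor at SNP %d", (int)(j + 1));
      resid -= (eta % xj) * (gb - gbar[j]);
      xg += xj * (gb - gbar[j]);
      vg += xj2 * (gv - gvar[j]);
      mug1[j] = m1; mug2[j] = m2; sg1v[j] = s1; sg2v[j] = s2; rg[j] = r;
      gbar[j] = gb; gvar[j] = gv;
    }
  }

  if (update_w) {
    // environment weights, prior w_l ~ N(0, 1)
    const arma::vec g = arma::square(xg) + vg;  // E_q[(X gamma)_i^2]
    for (arma::uword l = 0; l < L; ++l) {
      const arma::vec el = E.col(l);
      const double ql = arma::dot(arma::square(el), g);
      const double bl = arma::dot(el, xg % resid - eta % vg) + ql * mu_w[l];
      const double prec = 1.0 + ql / se2;
      const double s_new = 1.0 / prec;
      const double mu_new = (bl / se2) / prec;
      if (!std::isfinite(mu_new))
        stop("non-finite update for environment weight %d", (int)(l + 1));
      const double dmu = mu_new - mu_w[l];
      eta += el * dmu;
      veta += arma::square(el) * (s_new - s_w[l]);
      resid -= (el * dmu) % xg;
      mu_w[l] = mu_new;
      s_w[l] = s_new;
    }
  }

  return List::create(
    _["mu_alpha"] = mu_alpha, _["s_alpha"] = s_alpha,
    _["mub1"] = mub1, _["mub2"] = mub2, _["sb1"] = sb1v, _["sb2"] = sb2v,
    _["rb"] = rb, _["bbar"] = bbar, _["bvar"] = bvar,
    _["mug1"] = mug1, _["mug2"] = mug2, _["sg1"] = sg1v, _["sg2"] = sg2v,
    _["rg"] = rg, _["gbar"] = gbar, _["gvar"] = gvar,
    _["mu_w"] = mu_w, _["s_w"] = s_w,
    _["resid"] = resid, _["xg"] = xg, _["vb"] = vb, _["vg"] = vg,
    _["eta"] = eta, _["veta"] = veta, _["xtx"] = xtx, _["ctc"] = ctc,
    _["n"] = (double)N);
}

// [[Rcpp::export]]
arma::vec col_sumsq_cpp(SEXP Xs) {
  arma::mat X = borrow(Xs);
  return arma::sum(arma::square(X), 0).t();
}

// sum_j X_ij^2 w_j for each row i (no X^2 temporary)
// [[Rcpp::export]]
arma::vec xsq_rowsum_cpp(SEXP Xs, const arma::vec& w) {
  arma::mat X = borrow(Xs);
  arma::vec out(X.n_rows, arma::fill::zeros);
  for (arma::uword j = 0; j < X.n_cols; ++j)
    if (w[j] != 0.0) out += arma::square(X.col(j)) * w[j];
  return out;
}

// sum_i w_i X_ij^2 for each column j
// [[Rcpp::export]]
arma::vec xsq_colsum_cpp(SEXP Xs, const arma::vec& w) {
  arma::mat X = borrow(Xs);
  arma::vec out(X.n_cols);
  for (arma::uword j = 0; j < X.n_cols; ++j)
    out[j] = arma::dot(w, arma::square(X.col(j)));
  return out;
}

// Destructive: standardize columns of an R matrix in place (mean 0, sample
// variance 1, n-1 denominator).  Only called on freshly created matrices.
// [[Rcpp::export]]
void standardize_inplace_cpp(SEXP Xs) {
  arma::mat X = borrow(Xs);
  const arma::uword N = X.n_rows;
  for (arma::uword j = 0; j < X.n_cols; ++j) {
    double mu = arma::mean(X.col(j));
    X.col(j) -= mu;
    double sd = std::sqrt(arma::dot(X.col(j), X.col(j)) / (double)(N - 1));
    if (sd <= 0.0 || !std::isfinite(sd))
      stop("column %d is constant; cannot standardize", (int)(j + 1));
    X.col(j) /= sd;
  }
}

// Binomial(2, f_j) dosages with optional first-order LD: with probability rho
// an individual's dosage is copied from the previous SNP on the same
// chromosome.  Deterministic given `seed` (own mt19937_64 stream, independent
// of R's RNG so multi-gigabyte draws stay fast).
// [[Rcpp::export]]
NumericMatrix gen_genotypes_cpp(int n, int m, const arma::vec& f, double rho,
                                const arma::ivec& chrom, double seed) {
  NumericMatrix out(n, m);
  std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + 1ULL);
  // one 64-bit draw per genotype: each 32-bit half is an allele Bernoulli
  for (int j = 0; j < m; ++j) {
    double* col = &out(0, j);
    const uint32_t thresh = (uint32_t)(f[j] * 4294967296.0);
    const bool chain = rho > 0.0 && j > 0 && chrom[j] == chrom[j - 1];
    const double* prev = chain ? &out(0, j - 1) : nullptr;
    const uint64_t rho_thresh = (uint64_t)(rho * 18446744073709551615.0);
    for (int i = 0; i < n; ++i) {
      if (chain && rng() < rho_thresh) {
        col[i] = prev[i];
      } else {
        const uint64_t r = rng();
        col[i] = (double)(((uint32_t)r < thresh) +
                          ((uint32_t)(r >> 32) < thresh));
      }
    }
  }
  return out;
}

// Leading left singular vector of a centered/standardized matrix by power
// iteration on XX^T; enough accuracy for a simulated PC1 covariate.
// [[Rcpp::export]]
arma::vec leading_pc_cpp(SEXP Xs, int iters, double seed) {
  arma::mat X = borrow(Xs);
  std::mt19937_64 rng((uint64_t)seed * 88172645463325252ULL + 7ULL);
  std::normal_distribution<double> norm(0.0, 1.0);
  arma::vec v(X.n_rows);
  for (arma::uword i = 0; i < X.n_rows; ++i) v[i] = norm(rng);
  v /= arma::norm(v);
  for (int it = 0; it < iters; ++it) {
    arma::vec u = X.t() * v;
    v = X * u;
    v /= arma::norm(v);
  }
  return v;
}
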