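---
title: "Modeling genome-wide gene-environment interaction with a learned environmental score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling genome-wide gene-environment interaction with a learned environmental score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Quantitative traits in large cohorts are shaped both by additive genetic
effects and, for some traits substantially, by gene-environment (GxE)
interactions. Testing each SNP against each measured environment separately
is underpowered and leaves the joint structure of the exposures on the
table. This package fits a Bayesian whole-genome regression in which a
*single linear combination of environments* — the environmental score (ES)
— interacts with SNPs genome wide:

$$
y = C\alpha + X\beta + \eta \odot X\gamma + \epsilon,\qquad
\eta = E w,\qquad w \sim N(0, I_L),
$$

where $y$ is the centered and scaled phenotype ($N$ samples), $C$ the
covariates ($L'$ columns, which must contain the $L$ environment columns of
$E$), $X$ the column-standardized genotype matrix ($M$ SNPs), and $\odot$
the element-wise product of $\eta$ with each column of $X$. Main effects
$\beta_j$ and interaction effects $\gamma_j$ each carry a two-component
mixture-of-Gaussians (slab/spike) prior scaled by the residual variance,

$$
\beta_j \sim \lambda_\beta N(0, \sigma_e^2\sigma_{\beta,1}^2) +
(1-\lambda_\beta) N(0, \sigma_e^2\sigma_{\beta,2}^2),
$$

and likewise for $\gamma_j$ with $(\lambda_\gamma, \sigma_{\gamma,k}^2)$;
covariate effects have a flat Gaussian prior $N(0, \sigma_\alpha^2)$ with
$\sigma_\alpha^2$ held at a large constant (default 100). The prior variance
of $w$ is pinned to the identity because a free scale there would be
absorbed by $\sigma_{\gamma,k}^2$ and unidentifiable.

## Variational inference and the derived coordinate updates

The posterior over $\theta = \{\alpha, \beta, \gamma, w\}$ is approximated
by a fully factorized (mean-field) distribution — one factor per covariate,
per environment weight, and per SNP one joint factor for the effect and its
mixture indicator — optimized by cyclic coordinate ascent on the evidence
lower bound (ELBO). The closed-form updates are standard conjugate
Gaussian/mixture updates, with two wrinkles worth recording because the
interaction term is bilinear in $w$ and $\gamma$:

* The update of $q(\gamma_j)$ uses the *expected squared score*
  $\mathbb{E}[\eta_i^2] = \bar\eta_i^2 + \sum_l E_{il}^2 s_{w_l}$ in its
  quadratic coefficient, not $\bar\eta_i^2$ alone.
* The update of $q(w_l)$ uses
  $\mathbb{E}[(X\gamma)_i^2] = (X\bar\gamma)_i^2 + \sum_j X_{ij}^2
  \mathrm{Var}(\gamma_j)$, so posterior uncertainty in the SNP interaction
  effects correctly tempers the environment weights.

Each SNP's slab/spike responsibility is a logistic function of the
difference in per-component evidence. A full pass visits the covariate
factors, then SNP pairs $(\beta_j, \gamma_j)$ in genome order, then the
environment weights; residuals and the second-moment accumulators are
maintained incrementally (the test suite checks them against from-scratch
recomputation). Passes never decrease the ELBO at fixed hyper-parameters.

Hyper-parameters are updated after every pass by a variational EM step.
Profiling the ELBO shows the joint maximizer is
$\sigma_e^2 \leftarrow \mathbb{E}_q\lVert y - C\alpha - X\beta - \eta\odot
X\gamma\rVert^2 / N$ (including all variational second moments) together
with responsibility-weighted second moments for the mixture scales divided
by the *new* $\sigma_e^2$ — because the effect priors are scaled by
$\sigma_e^2$, the scale parameters absorb it and the M-step stays an exact
joint maximizer, which is why EM monotonicity holds to machine precision.
Component labels are kept identifiable by swapping slab and spike (together
with their variational blocks, which leaves the ELBO unchanged) whenever an
M-step inverts their order, and mixture weights are clamped to
$[10^{-6}, 1-10^{-6}]$.

The hyper-parameter sequence is accelerated with SQUAREM on the
unconstrained scale (log variances, logit weights), with the recommended
step size $v_t = \min(-1, -\lVert\Delta\varphi_{t-1}\rVert^2 /
\lVert\Delta^2\varphi_t\rVert^2)$, up to five halvings of the distance
between $v_t$ and $-1$ when the extrapolation leaves the domain (including
a slab-spike order violation), and a fall-back to the unaccelerated
estimate whenever the extrapolated ELBO is worse. Convergence is declared
when a full pass changes the ELBO by less than 0.01 (absolute), the
convention of comparable whole-genome regression software.

### Initialization and numerical choices

The model itself does not pin down an initialization; the package's
recipe is: SNP-effect means start at zero, environment-weight means are
drawn $N(0, 1/L)$ from a seeded generator purely to break the sign/rotation
symmetry of the interaction term, and the initial hyper-parameters put 10%
expected explained variance on main effects and 1% on interactions
($\lambda_\beta = \lambda_\gamma = 0.1$, spike variances 100 times smaller
than slabs, $\sigma_e^2 = 1$). Identical seeds give bit-identical ELBO
traces. The ES sign is not identifiable (flipping $w$ and $\gamma$ together
leaves the likelihood unchanged); downstream comparisons use $|r|$.

The magnitudes of $w$ and $\gamma$ are separately identified only through
their priors: the likelihood depends on them via the product
$\eta \odot X\gamma$. Because the mixture scales on $\gamma$ are free
(learned) while the prior on $w$ is pinned at $N(0, I_L)$, the optimum
balances the $w$ prior against its entropy and normalizes
$\mathbb{E}_q\lVert w\rVert^2 \approx L$. A practical consequence the test
suite verifies at $c \in \{0.5, 2\}$: rescaling all environment columns by
$c$ leaves the fitted weight vector and the score direction essentially
unchanged (the interaction effects absorb the scale), so weights are read
on the standardized-environment scale, and transferring them onto any
recoded design is done by least-squares re-extraction
(`rescale_weights()`), which is exact whenever the column spaces agree.

Covariates can be modeled inside the variational approximation (default)
or projected out of the phenotype once before fitting (`"project-out"`);
the former is preferred because the interaction design changes every pass,
so a one-shot projection cannot orthogonalize the full model.

## Single-SNP testing

After the fit, single-SNP tests use leave-one-chromosome-out (LOCO)
residuals $y - C\hat\alpha - X_{\mathrm{LOCO}}\hat\beta - \hat\eta \odot
X_{\mathrm{LOCO}}\hat\gamma$, so the test SNP is conditioned on the
polygenic and polygenic-interaction background of all other chromosomes
without proximal contamination. Each SNP is regressed (OLS) on
$H = [x, \hat\eta \odot x]$. Because GxE effects elsewhere in the genome
make trait variance depend on the environment, the interaction coefficient
is tested with a heteroskedasticity-robust (Huber-White sandwich) variance
carrying the small-sample leverage adjustment
$\hat\Sigma_{ii} = \hat\epsilon_i^2 / (1 - h_{ii})^2$, referred to
$\chi^2_1$; the main effect uses an ordinary two-sided t test with $N - 2$
degrees of freedom. The leverage used in the adjustment is that of the
two-column design $H$, as the test is defined on the residualized
phenotype. Rank-deficient designs at a SNP (e.g. a constant score) yield a
flagged row rather than aborting a scan. Raw p-values are reported;
genome-wide thresholds are a reporting convention, not a filter.

Two fixed-effect comparators operate on the unresidualized phenotype with
the full design $[1, C, E, x, x \odot E]$: the standard F-test of all $L$
interaction coefficients, and a robust Wald version using the same
leverage-adjusted sandwich covariance, referred to $\chi^2_L$. A screening
regression `detect_squared_env()` tests each environment's squared effect
($y = 1\alpha_0 + C\alpha + E_l^2 b_l + \epsilon$) and appends significant
squared columns (Bonferroni: $p < 0.01/L$ — the package reads the
correction as dividing the level by $L$) to the covariates; this guards
the interaction tests against smooth non-linear dependence on a heritable
environment masquerading as GxE.

## Heritability estimation

Variance explained by additive and ES-interaction effects is estimated by
randomized Haseman-Elston (HE) regression: a method-of-moments solve of

$$
\begin{pmatrix}
\mathrm{tr}(K^2) & \mathrm{tr}(KV) & \mathrm{tr}(K)\\
\mathrm{tr}(KV) & \mathrm{tr}(V^2) & \mathrm{tr}(V)\\
\mathrm{tr}(K) & \mathrm{tr}(V) & N
\end{pmatrix}
\begin{pmatrix}\sigma_\beta^2\\ \sigma_\gamma^2\\ \sigma_e^2\end{pmatrix}
=
\begin{pmatrix}y^\top K y\\ y^\top V y\\ y^\top y\end{pmatrix},
\qquad K = \tfrac{XX^\top}{M},\;
V = \tfrac{Z(\hat\eta)Z(\hat\eta)^\top}{M},
$$

with traces estimated by Hutchinson probes ($B = 50$ by default) so the
kinship matrices are never formed; all matrix-vector products stream
through the genotype matrix in $O(NMB)$. The intercept, covariates and the
fitted ES are treated as fixed effects and projected out of the phenotype,
genotypes and interaction matrix implicitly (the projector is applied to
probe and data vectors, never to $X$ itself), with $N_{\mathrm{eff}} = N -
q$ replacing $N$. Heritability uses the trace-normalized form
$\hat h^2_{GxE} = \sum_b \hat\sigma^2_{\gamma,b}\,\mathrm{tr}(V_b)/N \,/\,
(\sum_b \hat\sigma^2_{\beta,b}\,\mathrm{tr}(K_b)/N + \sum_b
\hat\sigma^2_{\gamma,b}\,\mathrm{tr}(V_b)/N + \hat\sigma_e^2)$, which is
required because the columns of the interaction matrix are not guaranteed
unit variance even when $X$ is standardized. Negative method-of-moments
estimates are reported, flagged, and never truncated.

The multi-component (MAF/LD-stratified) variant assigns each SNP to one of
5 MAF bins ($\le 0.1$, then right-closed steps of 0.1) crossed with LD-score
quantiles (4 by default), one additive and one interaction component per
bin. LD scores are in-sample, unadjusted $r^2$ sums over a fixed window of
100 SNPs on each side within chromosome — the window size and the
unadjusted estimator are package defaults, chosen for desk-scale data;
standard-error estimation uses the block jackknife over 100 contiguous SNP
blocks (both counts configurable), computed in a second streaming pass
that subtracts each block's contribution from the cached probe products
rather than refitting from scratch.

## The synthetic-data generator

No external dataset ships with the package; the simulation module generates
the study conditions end to end. Genotypes are Binomial(2, $f_j$) dosages
with $f_j \sim U(0.05, 0.5)$, split evenly over pseudo-chromosomes, with
optional first-order LD by per-individual copying of the previous SNP's
dosage (probability $\rho$, reset at chromosome boundaries); with copying
enabled the marginal frequencies become mixtures of neighboring
frequencies, so frequency assertions in the tests are made at $\rho = 0$.
Environments are i.i.d. standard Gaussians. Phenotypes follow
$y = X\beta + (Ew) \odot (X\gamma) + c_1\,\mathrm{PC1} + \epsilon$ with, by
default, 2,500 causal main effects (20% of variance), 1,250 causal
interaction effects (5%), 60 standardized-effect SNPs carrying 1% of
variance through main and 1% through interaction effects in equal per-SNP
shares, and 1% of variance on the leading genetic principal component
(computed by power iteration on the standardized genotypes — a stand-in
for the ancestry structure of real cohort genotypes, which the generator
cannot otherwise reproduce). Active environments get equal weights
$1/\sqrt{n_\mathrm{active}}$; effect vectors are drawn $N(0,1)$ and
rescaled so each component's realized variance hits its target exactly.
All causal SNPs sit in the first half of each chromosome, leaving the
second halves as certified nulls for calibration. Every generator is a
pure function of its seed.

The misspecification generator draws a heritable environmental factor
$S = X\tau + \epsilon_s$ with spike-and-slab $\tau$ (slab variance
$h_\tau^2 / (M\lambda_\tau)$, taking the slab normalizer equal to $M$ so
$\mathrm{Var}(S) = 1$ by construction) and a trait $Y = aS^2 + X\beta +
\epsilon$; it exists to demonstrate that non-linear dependence on a
heritable environment inflates GxE tests at the environment's own causal
sites, and that screening squared effects into the covariates repairs the
calibration.

What the generator does *not* emulate: realistic LD (only a first-order
chain), MAF-dependent LD or selection-driven architecture, relatedness,
or missing-data structure. Tests passing on these simulations therefore
certify the estimators' internal consistency and calibration under the
stated model, not robustness to every feature of real cohort data.

## Problem sizes and test design

The test suite exercises every estimator at sizes a single desktop core
handles comfortably: oracle equivalences at $N, M \le 1000$; calibration
suites with a few thousand replicate tests; recovery of $h^2_G = 0.2$ and
$h^2_{GxE} = 0.05$ at $N = 10{,}000$, $M = 20{,}000$ with the known
simulated score; a 20-replicate HE recovery study at the same size; and a
power comparison of the fitted-ES test against the robust F-test at
$N = 5{,}000$, $M = 20{,}000$, $L = 10$. For the MAF/LD stratification
check, causal SNPs are planted in a low-MAF, LD-free block while the rest
of the genome carries strong first-order LD, which reproduces the
well-known downward bias of single-component estimates under
architecture-LD mismatch and the robustness of the stratified estimator;
LD scores there are computed on a random subsample of individuals, the
usual LD-reference practice.

## Known limitations

* A single ES: loci interacting with an environment combination orthogonal
  to the genome-wide score are invisible to the scan (the SNP-specific
  interaction profile `snp_interaction_profile()` is the diagnostic).
* Mean-field variational posteriors understate uncertainty; the package
  follows the two-stage design of fitting the ES variationally and handing
  it to method-of-moments heritability estimation and OLS-based tests
  rather than reading variances off the variational fit.
* Testing SNPs that also informed the ES induces mild anti-conservatism;
  at the simulated scales the suite verifies the robust test's type-I
  error stays near nominal, but the two-stage optimism grows as $L$ rises.
* Missing environment or covariate values cost whole samples
  (complete-case analysis); genotype missingness is mean-imputed.
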