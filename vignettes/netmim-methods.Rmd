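---
title: "Model, priors and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, priors and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmim)
```

## The model

`netmim()` fits a two-layer hierarchical regression that integrates
promoter DNA methylation (M-values, $N \times J$), gene expression
($N \times K$) and clinical covariates ($N \times L$, with an intercept)
against a clinical outcome. The *mechanistic* layer decomposes each gene's
expression into a methylation-driven part and a residual part:

$$\mathbf E = \mathbf E^M + \mathbf E^{\bar M}, \qquad
  \mathbf E^M = \mathbf M\,\Omega,$$

where $\omega_{jk}$ is nonzero only for probes $j$ mapped to gene $k$
(cis/promoter probes; the probe-to-gene map is many-to-one). The
*clinical* layer regresses a latent continuous outcome on the covariates
and both expression components:

$$\mathbf Y^\ast = \mathbf C\beta^C + \mathbf E^M\beta^M +
  \mathbf E^{\bar M}\beta^{\bar M} + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2 I).$$

Separating $\beta^M$ ("type M" effects, acting through
methylation-regulated expression) from $\beta^{\bar M}$ ("type $\bar M$"
effects) is what makes selected biomarkers mechanistically interpretable.

Sparsity comes from Dirac spike-and-slab priors at both layers:

$$\omega_{jk} \mid z_{jk} \sim (1 - z_{jk})\,\delta_0 +
  z_{jk}\, N(0, \tau_k^{-1}\sigma_k^2), \qquad
  \beta_k^M \mid \gamma_k^M \sim (1-\gamma_k^M)\,\delta_0 +
  \gamma_k^M\, N(0, \tau^{-1}\sigma^2),$$

and analogously for $\beta^{\bar M}_k$. The point mass makes excluded
coefficients *exactly* zero in every draw — the package asserts this
bitwise in its tests. Probe indicators get $z_{jk} \sim
\mathrm{Bern}(\pi_k)$ with $\pi_k \sim \mathrm{Beta}(a, b)$; variances get
inverse-gamma priors $\sigma^{-2}, \sigma_k^{-2} \sim
\mathrm{Ga}(\delta_1, \delta_2)$.

A gene is *effective* when either effect type is active,
$\gamma_k = \gamma_k^M \vee \gamma_k^{\bar M}$, and a Markov random field
prior over a known gene–gene network couples these OR indicators:

$$p(\gamma_k \mid \gamma_{-k}) =
  \frac{\exp\!\big(\gamma_k (d + f \sum_{k' \in N_k} \gamma_{k'})\big)}
       {1 + \exp\!\big(d + f \sum_{k' \in N_k} \gamma_{k'}\big)}.$$

$d < 0$ controls sparsity (an isolated gene has prior inclusion
probability $\mathrm{logit}^{-1}(d)$: about 0.05 at $d=-3$, 0.02 at
$d=-4$), and $f \ge 0$ rewards jointly selected neighbours. We implement
the joint unnormalized log-prior as $d\sum_k\gamma_k + f\sum_{(j,l) \in
E} \gamma_j\gamma_l$ with each undirected edge counted once; this is the
unique normalization under which the conditional above equals the ratio
of joint densities, a consistency the tests verify by exhaustive
enumeration on small graphs. Because the MRF can phase-transition into
near-complete inclusion for large $f$, small values are advisable; the default is
$f = 0.5$ and no automatic guard is attempted.

### Missing omics blocks

Subjects may lack *all* of one omics matrix (block missingness, common in
multi-platform cohorts); a subject must retain at least one block.
Missing rows are sampled inside the MCMC (data augmentation) from their
full conditionals:

* missing expression cells combine the mechanistic law
  $e_{nk} \sim N(m_{n,\mathcal J_k}\,\omega_k, \sigma_k^2)$ with the
  clinical observation through $\beta_k^{\bar M}$;
* missing methylation cells combine a $N(0, (\sigma^m_j)^2)$ prior
  ($\sigma^m_j = 1$ for M-values standardized to unit variance) with the
  mechanistic likelihood of the observed expression through
  $\omega_{jk}$ and the clinical likelihood through
  $\omega_{jk}(\beta^M_k - \beta^{\bar M}_k)$.

The mechanistic-only laws are what the imputation *model* states; the
clinical terms are what the joint model's full conditionals require, and
including them is the only choice that leaves the stated joint
distribution invariant. Setting `modular_imputation = TRUE` in
`netmim_mcmc()` restores the literal mechanistic-only draws, and the
tests verify the exact collapse when $\beta^{\bar M}_k = 0$.

### Binary and survival outcomes

Binary outcomes use the probit augmentation $y_n = 1 \iff y_n^\ast > 0$
with $\sigma^2$ fixed at 1 (the usual probit identifiability convention —
the model is silent on this, so it is recorded here as a package
decision). Right-censored survival outcomes use the accelerated failure
time formulation: $y_n^\ast = \log y_n$ exactly for events, and for
censored records $y_n^\ast$ is drawn from $N(\mu_n, \sigma^2)$ truncated
to $(\log y_n, \infty)$. Truncated-normal draws invert the normal CDF in
log space, so even truncation points 38 standard deviations into the
tail give finite, accurate draws (verified against the asymptotic tail
mean in the tests).

## The sampler

One sweep updates, in order: (1) latent outcomes; (2) missing omics rows;
(3) per gene, the probe indicators $z_{\cdot k}$ by single-site Gibbs
with $\omega_{\cdot k}$ integrated out analytically, then a conjugate
multivariate-normal redraw of the active $\omega_{\cdot k}$, then
$\pi_k$ and $\sigma_k^2$; (4) per gene, the pair
$(\gamma_k^M, \gamma_k^{\bar M})$ by enumerating its four configurations
with the active $\beta$'s integrated out, then $\beta^C$ jointly and
$\sigma^2$. Swapping (3) and (4) is also a valid scan, available as
`clinical_first`; a test checks both orders agree within Monte-Carlo
error.

Two modelling subtleties deserve mention:

* **Joint coupling.** Because $Y^\ast$ depends on $\omega_{\cdot k}$
  through $(\mathbf M\Omega)_{\cdot k}(\beta^M_k - \beta^{\bar M}_k)$,
  the probe-level updates include the clinical likelihood, making
  inference fully joint. `modular_mechanistic = TRUE` disables this
  coupling (a two-stage flavour in the iBAG tradition); default off.
* **Within-gene allocation.** The MRF constrains only the OR of the two
  effect indicators. The conditional prior split of an active gene over
  the three active configurations $\{10, 01, 11\}$ is not implied by the
  MRF; the package gives them equal weight (1/3 each) by default and
  exposes the triple as `alloc` in `netmim_prior()`. Updating the pair
  by 4-state enumeration (rather than one indicator at a time) is what
  makes this prior exact.

The sweep is implemented in C++ (RcppArmadillo) with all randomness drawn
through R's RNG, so `set.seed()` makes entire runs bit-reproducible; a
test asserts draw-for-draw equality of repeated runs. Default chains
start from a deterministic state (indicators off, least-squares
$\beta^C$, data-based variances); additional chains randomize their
starting points. The per-gene linear algebra works on $|\mathcal J_k|$-
sized systems via Cholesky factorizations; the posterior precision is
positive definite whenever $\tau_k > 0$, so no ridge fudge is needed.

### Correctness checks

The test suite validates the sampler at three levels rather than trusting
the conjugate algebra:

1. **Exhaustive enumeration.** On instances with $\le 8$ samples and
   $\le 3$ indicators, the stationary distribution of the indicator
   Gibbs chains (mechanistic with the clinical block frozen, and the
   4-configuration gene updates including an MRF edge) is compared with
   posteriors computed by brute-force enumeration using direct
   $2N \times 2N$ multivariate-normal marginal densities — an
   independent code path. Total variation must stay below 0.02 over 50k
   sweeps. The *joint* posterior over both layers' indicators is not
   enumerable in closed form (the likelihood is bilinear in
   $\Omega, \beta$), which is why the enumeration fixes one block.
2. **Successive-conditional simulation.** Alternating parameter sweeps
   with regeneration of $(\mathbf E, Y)$ from the current parameters
   must leave every prior marginal invariant; the tests check
   $P(z=1) = a/(a+b)$, the 2-gene MRF marginal, $E[\sigma^2] =
   \delta_2/(\delta_1 - 1)$, and the mean and variance of $\beta^C$
   against batch-means Monte-Carlo errors. This check uses
   $\delta_1 = \delta_2 = 3$ so the prior moments exist; the analysis
   default $\delta_1 = \delta_2 = 0.001$ has no prior mean to test
   against.
3. **Parameter recovery.** On simulated studies the effective genes are
   recovered with feature-selection AUC near 1 under the default
   conditions, and prediction error approaches the generative noise.

## Posterior summaries and prediction

Posterior inclusion probabilities (PPIs) are inclusion frequencies over
kept draws, pooled across chains. Selection uses the median probability
model (strict PPI $> 0.5$) by default; `bayes_fdr_threshold()` instead
returns the smallest cutoff whose estimated Bayesian false discovery
rate, $\sum_k (1-p_k)\mathbb 1\{p_k \ge t\} / \#\{p_k \ge t\}$, stays
below a target level. Prediction is Bayesian model averaging: each kept
draw predicts $\hat y_i = C\hat\beta^C_i + (M\hat\Omega_i)\hat\beta^M_i +
(E - M\hat\Omega_i)\hat\beta^{\bar M}_i$ and the draws are averaged.
Binary fits additionally report $\Phi(\hat y)$; survival predictions are
mean posterior log-times, so *larger predicted values mean lower risk* —
the concordance index in `c_index()` is oriented accordingly (this
orientation is a package decision and is stated in the output metadata).
Prediction error is reported as root mean squared error
$\sqrt{\sum_i (y_i - \hat y_i)^2 / N_v}$.

## The simulation generator

`netmim_sim()` generates studies with a fully known truth, used by the
tests and the replication experiments: $L = 3$ standard-normal clinical
covariates; $J$ probes randomly allocated to $K$ genes with at least one
probe each (300 over 100 genes gives exactly 3 on average); half the
genes methylation-regulated with $z_{jk} \sim \mathrm{Bern}(1/2)$ and
active $\omega_{jk} \sim \pm\mathrm{Unif}(0.5, 1)$; residual expression
$N(0,1)$; fifteen outcome genes — five acting through both components,
five only through $E^M$, five only through $E^{\bar M}$ — with effects
$\pm\mathrm{Unif}(1, 1.5)$, covariate and intercept coefficients 1, and
noise sd $\sigma \in \{1,2,3\}$; a network with $\mathrm{Bern}(0.1)$
edges among the effective genes and an equal number placed uniformly
among ineffective genes; and an independent complete validation set of
100 subjects. Missingness scenarios remove whole blocks: a fraction of
subjects lose expression (II) or methylation (III), or half the subjects
lose exactly one block (IV).

Choices the generator had to make where the recipe is open, with our
resolutions:

* **Methylation correlation.** Real 450k probes are correlated; to stay
  self-contained the generator draws within-gene blocks of exchangeable
  Gaussians (correlation `rho`, default 0.5, unit variance by
  construction so the standardized-M-value convention
  $\sigma^m_j = 1$ holds in law). It does not emulate beta-value
  marginals, LD-like decay across genes, or batch effects — so passing
  tests certify the estimator under the stated generative law, not
  robustness to real-array artefacts.
* **Sign choice.** Each $\omega$ and each effective $\beta$ picks the
  positive or negative range by a fair coin.
* **Degenerate regulation draws.** A "regulated" gene whose
  $\mathrm{Bern}(1/2)$ probe draws all come up empty is redrawn once and
  then forced to keep one active probe, so regulated genes are genuinely
  regulated.
* **Effective-gene placement.** The ten genes carrying type-M effects
  are forced into the regulated half (a type-M effect through an
  all-zero $\omega_{\cdot k}$ would be vacuous); the remaining regulated
  genes are sampled at random.
* **Survival generation.** Log censoring times are drawn from the same
  AFT law shifted by $-\Phi^{-1}(\text{cens\_rate})\sqrt 2\,\sigma$,
  giving the target censoring fraction (default 0.3) on average.

## Baselines and the missing-data cross-validation

`mimic_penalized()` is the frequentist mirror of the decomposition:
per-gene lasso/elastic-net of $E_k$ on its probes (5-fold CV penalty),
then a penalized outcome regression on $[C, \hat E^M, \hat E^{\bar M}]$.
Genes with a single probe use ordinary least squares in stage 1 — a
cross-validated penalty path over one predictor is not meaningful.
`vanilla_penalized()` concatenates $[C, E, M]$ in one penalized
regression. The elastic-net mixing parameter is fixed at 0.5. Both are
continuous-outcome comparators.

`netmim_cv()` answers "keep or drop incomplete subjects?" empirically:
five folds stratified to preserve the missingness pattern; per fold the
full-data fit (with augmentation) and the complete-case fit are scored by
PMSE on held-out *complete* subjects only; the arm with the smaller mean
PMSE is refit on everything, ties keeping the full-data arm. Fold fits
default to half-length chains (`cv_iter`) to keep the scheme tractable;
the fold table records what was run.

## Default problem sizes

The replication experiments shipped with the package run at desk scale:
$K = 100$ genes, $N = 100$ subjects, chains of 2,000 iterations with
1,000 burn-in, and 10–20 replicates per condition — enough for the
qualitative comparisons (network prior on versus off, full data versus
complete cases, Bayesian versus penalized baselines) to stabilize, while
a full study sweep ($K$ up to 500, four chains of 10,000) remains the
documented default of `netmim_mcmc()` for real analyses.

## Known limitations

* The gene network is taken as given and correct; $d$ and $f$ are fixed
  hyperparameters, not estimated, and large $f$ can phase-transition.
* Only two omics layers are integrated, with strictly cis probe-to-gene
  maps; trans effects and additional layers (miRNA, SNPs) are out of
  scope.
* Missingness is whole-block and assumed ignorable; scattered NA cells
  within an observed row are rejected rather than imputed, and
  informative missingness is not modelled.
* The probit layer fixes $\sigma^2 = 1$; whether the variance should
  instead be free is a modelling question the package resolves by
  convention.
* Penalized baselines cover continuous outcomes only.
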