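# netmim

Network-based Bayesian integration of DNA methylation and gene expression
for biomarker selection and outcome prediction, with principled handling
of subjects missing a whole omics block.

## The problem

In vertical multi-omics studies, DNA methylation influences clinical
outcomes mostly *through* gene expression. Treating the two matrices as
interchangeable predictor columns throws that mechanism away, and the two
standard practical headaches — thousands of correlated features, and
cohorts where many subjects were profiled on only one platform — are
usually "solved" by ad-hoc filtering and by dropping incomplete subjects.

`netmim` fits a two-layer Bayesian hierarchical model instead. A
mechanistic layer splits each gene's expression into a part driven by its
promoter probes and a residual part:

    E = E^M + E^Mbar,   E^M = M Ω,

and a clinical layer regresses the (possibly latent) outcome on clinical
covariates and both components:

    Y* = C β^C + E^M β^M + E^Mbar β^Mbar + ε,   ε ~ N(0, σ² I).

Dirac spike-and-slab priors on `Ω`, `β^M` and `β^Mbar` give exactly-zero
coefficients and posterior inclusion probabilities (PPIs) per probe and
per gene; a Markov random field prior over a known gene–gene network
(parameters `d` for sparsity, `f` for smoothness) encourages jointly
selected network neighbours, which makes the selected biomarkers line up
with pathways. Subjects missing all of `E` or all of `M` are kept: the
missing block is sampled inside the Gibbs sampler (data augmentation), as
are latent outcomes for binary (probit) and right-censored survival
(accelerated failure time) responses. Prediction is Bayesian model
averaging over the kept draws; selection uses the median probability
model (PPI > 0.5) or a Bayesian-FDR-derived cutoff.

The sampler core is RcppArmadillo; a 100-subject, 100-gene, 300-probe fit
runs a 2,000-iteration chain in about one second.

## Worked example

Simulate a study in which 30% of subjects lack methylation, fit the model
with two chains, and evaluate against the known truth:

```r
library(netmim)

sim <- netmim_sim(n = 100, n_genes = 100, n_probes = 300, sigma = 1,
                  scenario = "III", missing_ratio = 0.3, seed = 1)
fit <- netmim(sim$data,
              prior = netmim_prior(d = -3, f = 0.5),
              mcmc  = netmim_mcmc(n_iter = 2000, burnin = 1000,
                                  chains = 2, seed = 1),
              newdata = sim$validation)
print(fit)
#> Two-layer Bayesian integrative model (continuous outcome)
#>   100 subjects (0 missing E, 30 missing M), 100 genes, 300 probes
#>   2 chain(s) x 2000 iterations (burn-in 1000, thin 1)
#>   selected at PPI > 0.5: 4 type-M only, 3 type-Mbar only, 7 both

summary(fit)
#> Clinical coefficients (posterior mean):
#> (Intercept)          x1          x2          x3
#>      0.6532      0.7301      1.1873      1.2729
#>
#> Residual variance sigma^2 (posterior mean): 1.0554
#>
#> Top genes by PPI (threshold 0.50):
#>  gene  PPI_M PPI_Mbar     beta_M   beta_Mbar selected_M selected_Mbar
#>    g1 0.9370    1.000 -0.7253539  1.45615114       TRUE          TRUE
#>    g2 1.0000    1.000  1.1180515 -0.92668520       TRUE          TRUE
#>    ...

pmse(sim$validation$outcome$y, predict(fit))
#> [1] 1.619
selection_auc(c(fit$ppi$gamma_Mbar, fit$ppi$gamma_M),
              c(sim$truth$gamma_Mbar, sim$truth$gamma_M))
#> [1] 0.9988889
cross_chain_ppi_cor(fit)$gamma[1, 2]
#> [1] 0.999
```

The generator plants 15 outcome-relevant genes (5 acting through both
expression components, 5 through the methylation-driven part only, 5
through the residual part only); the fit ranks them essentially perfectly
(AUC 0.999) despite a third of the cohort lacking methylation, the
residual variance concentrates near the generative σ² = 1, and the two
independent chains agree on the selection (PPI correlation 0.999). The
PMSE of 1.62 sits between the noise floor (1.0) and what a
complete-case fit achieves at this missingness level (see the
experiments below).

Everything is also scriptable from a shell through the thin CLI:

```sh
Rscript inst/cli/netmim.R simulate --out=study --n=100 --seed=1
Rscript inst/cli/netmim.R fit --dir=study --out=study/fit --n_iter=2000 \
    --burnin=1000 --chains=2 --seed=1
```

Replicated method comparisons (model with/without the network prior,
complete-case variants, penalized two-stage and concatenation baselines,
and a five-fold scheme that decides empirically whether to keep
incomplete subjects) are available through `netmim_experiment()` and
`netmim_cv()`.

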