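#' Prior hyperparameters
#'
#' Collects the hyperparameters of the hierarchical model. The defaults are
#' the values used throughout the simulation study: a sparse MRF prior
#' (`d = -3`, giving an isolated gene a prior inclusion probability of about
#' 0.05, and a small smoothness `f = 0.5` to stay clear of the MRF phase
#' transition), unit slab precision scales, a Beta(0.2, 0.8) prior on the
#' probe-inclusion probabilities (20% expected prior inclusion) and vague
#' inverse-gamma priors on the variances.
#'
#' @param d MRF sparsity parameter (real, typically negative).
#' @param f MRF smoothness parameter (real, `>= 0`).
#' @param tau slab precision scale for the clinical effects (slab is
#'   `N(0, sigma^2 / tau)`).
#' @param tau_k slab precision scale for the probe effects (slab is
#'   `N(0, sigma_k^2 / tau_k)`); scalar, recycled over genes.
#' @param tau_c prior precision scale for clinical covariates
#'   (`beta^C ~ N(0, sigma^2 / tau_c)`); the default 0.01 is weak.
#' @param a,b Beta prior parameters for the probe inclusion probability.
#' @param delta1,delta2 inverse-gamma shape/rate for `sigma^2` and
#'   `sigma_k^2`.
#' @param sigma_m imputation standard deviation per methylation probe;
#'   1 is appropriate for M-values normalized to mean 0, variance 1.
#'   Scalar or length-J vector.
#' @param alloc length-3 positive weights giving the conditional prior split
#'   of an active gene over the configurations (M only, Mbar only, both);
#'   normalized internally. The MRF prior constrains only the OR of the two
#'   indicators, so this split is a modelling choice.
#' @return A list of class `netmim_prior`.
#' @export
netmim_prior <- function(d = -3, f = 0.5, tau = 1, tau_k = 1, tau_c = 0.01,
                         a = 0.2, b = 0.8, delta1 = 0.001, delta2 = 0.001,
                         sigma_m = 1, alloc = c(1, 1, 1) / 3) {
  stopifnot(f >= 0, tau > 0, tau_k > 0, tau_c > 0, a > 0, b > 0,
            delta1 > 0, delta2 > 0, all(sigma_m > 0),
            length(alloc) == 3, all(alloc > 0))
  structure(list(d = d, f = f, tau = tau, tau_k = tau_k, tau_c = tau_c,
                 a = a, b = b, delta1 = delta1, delta2 = delta2,
                 sigma_m = sigma_m, alloc = alloc / sum(alloc)),
            class = "netmim_prior")
}

#' MCMC settings
#'
#' @param n_iter total iterations per chain.
#' @param burnin burn-in iterations discarded from every chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of independent chains. Chain 1 starts from the
#'   deterministic initialization; later chains (or all chains when
#'   `init = "random"`) start from randomized states.
#' @param seed integer seed; each chain uses `seed + chain - 1`.
#' @param store_omega store the probe-effect draws (needed by
#'   [predict.netmim()] on new data after fitting).
#' @param verbose emit progress with the current model size to stderr.
#' @param modular_mechanistic if `TRUE`, drop the clinical-likelihood term
#'   from the probe-indicator and probe-effect updates (two-stage flavour);
#'   the default `FALSE` is the fully joint model.
#' @param modular_imputation if `TRUE`, impute missing omics rows from the
#'   mechanistic/prior laws only, without the clinical-likelihood term.
#' @param clinical_first update the clinical block before the mechanistic
#'   block in each sweep (either order is a valid Gibbs scan).
#' @param init `"deterministic"` (indicators zero, least-squares clinical
#'   coefficients, data-based variances) or `"random"`.
#' @return A list of class `netmim_mcmc`.
#' @export
netmim_mcmc <- function(n_iter = 10000, burnin = 5000, thin = 1, chains = 4,
                        seed = NULL, store_omega = TRUE, verbose = FALSE,
                        modular_mechanistic = FALSE,
                        modular_imputation = FALSE,
                        clinical_first = FALSE,
                        init = c("deterministic", "random")) {
  stopifnot(burnin >= 0, burnin < n_iter, thin >= 1, chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), chains = as.integer(chains),
                 seed = seed, store_omega = store_omega, verbose = verbose,
                 modular_mechanistic = modular_mechanistic,
                 modular_imputation = modular_imputation,
                 clinical_first = clinical_first,
                 init = match.arg(init)),
            class = "netmim_mcmc")
}
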