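#' Fit the network-based two-layer integrative model
#'
#' Runs the Gibbs sampler for the hierarchical model
#' \deqn{E = E^M + E^{\bar M}, \quad E^M = M \Omega,}
#' \deqn{Y^* = C\beta^C + E^M \beta^M + E^{\bar M}\beta^{\bar M} + \epsilon,}
#' with Dirac spike-and-slab priors on the probe effects \eqn{\omega_{jk}}
#' and the gene effects \eqn{\beta^M_k, \beta^{\bar M}_k}, an MRF prior over
#' the gene network on \eqn{\gamma_k = \gamma^M_k \vee \gamma^{\bar M}_k},
#' data augmentation of whole-sample missing omics rows, and latent-variable
#' handling of binary (probit) and right-censored (accelerated failure
#' time) outcomes. Indicator updates are single-site (probe level) or
#' four-configuration (gene level) Gibbs moves with the coefficients
#' integrated out analytically, so zero coefficients are exact.
#'
#' @param data a [momics_data] object.
#' @param prior a [netmim_prior()] list.
#' @param mcmc a [netmim_mcmc()] list.
#' @param newdata optional held-out data for per-iteration Bayesian model
#'   averaged prediction: a [momics_data] object or a list with elements
#'   `C`, `E`, `M` (complete rows only).
#' @return An object of class `netmim` with components `chains` (per-chain
#'   draw matrices), `ppi` (pooled posterior inclusion probabilities for
#'   gene-level indicators and probe indicators), posterior means, and (when
#'   `newdata` is supplied) `prediction` with the BMA predictions.
#' @references Two-layer mechanistic/clinical decompositions of expression
#'   follow the integrative Bayesian analysis of genomics (iBAG) tradition.
#' @seealso [summary.netmim()], [predict.netmim()], [select_features()]
#' @export
netmim <- function(data, prior = netmim_prior(), mcmc = netmim_mcmc(),
                   newdata = NULL) {
  stopifnot(inherits(data, "momics_data"))
  viol <- validate_momics(data)
  if (nrow(viol)) stop("invalid dataset: ", paste(viol$violation, collapse = "; "))

  K <- ncol(data$E); J <- ncol(data$M); N <- nrow(data$E)
  outcome_type <- match(data$outcome$kind,
                        c("continuous", "binary", "survival")) - 1L
  event <- if (is.null(data$outcome$event)) integer(N) else data$outcome$event

  Jk0 <- lapply(data$probe_sets, function(v) as.integer(v - 1L))
  nbr0 <- lapply(seq_len(K),
                 function(k) as.integer(which(data$network[k, ] == 1) - 1L))
  tau_k <- rep_len(prior$tau_k, K)
  sigma_m <- rep_len(prior$sigma_m, J)

  E0 <- data$E; M0 <- data$M
  E0[is.na(E0)] <- 0; M0[is.na(M0)] <- 0

  nd <- .prep_newdata(newdata, data)

  seed <- if (is.null(mcmc$seed)) sample.int(2^30, 1) else as.integer(mcmc$seed)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(seed + ch - 1L)
    random_init <- mcmc$init == "random" || ch > 1
    st <- .init_state(data, E0, prior, tau_k, outcome_type, random_init)
    chains[[ch]] <- cpp_run_netmim(
      C = data$C, E = E0, M = M0,
      y_obs = data$outcome$y, event = event, outcome_type = outcome_type,
      Jk_list = Jk0, nbr_list = nbr0,
      uE = data$U_E, uM = data$U_M,
      d = prior$d, f = prior$f, tau = prior$tau, tau_k = tau_k,
      tau_c = prior$tau_c, a = prior$a, b = prior$b,
      d1 = prior$delta1, d2 = prior$delta2, sigma_m = sigma_m,
      alloc = prior$alloc,
      T = mcmc$n_iter, Tb = mcmc$burnin, thin = mcmc$thin,
      store_omega = mcmc$store_omega,
      modular_mech = mcmc$modular_mechanistic,
      modular_imp = mcmc$modular_imputation,
      clin_first = mcmc$clinical_first, geweke = FALSE,
      z = st$z, omega = st$omega, sigma2_k = st$sigma2_k, pi_k = st$pi_k,
      gamma_M = st$gamma_M, gamma_B = st$gamma_B,
      beta_M = st$beta_M, beta_B = st$beta_B, beta_C = st$beta_C,
      sigma2 = st$sigma2,
      C_new = nd$C, E_new = nd$E, M_new = nd$M,
      verbose = mcmc$verbose)
  }

  pool <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  gM <- pool("gamma_M"); gB <- pool("gamma_Mbar"); zd <- pool("z")
  genes <- colnames(data$E); probes <- colnames(data$M)
  ppi <- list(gamma_M = stats::setNames(colMeans(gM), genes),
              gamma_Mbar = stats::setNames(colMeans(gB), genes),
              gamma = stats::setNames(colMeans((gM + gB) > 0), genes),
              z = stats::setNames(colMeans(zd), probes))
  post_mean <- list(beta_C = stats::setNames(colMeans(pool("beta_C")),
                                             colnames(data$C)),
                    beta_M = stats::setNames(colMeans(pool("beta_M")), genes),
                    beta_Mbar = stats::setNames(colMeans(pool("beta_Mbar")),
                                                genes),
                    sigma2 = mean(pool_vec(chains, "sigma2")),
                    sigma2_k = stats::setNames(colMeans(pool("sigma2_k")),
                                               genes),
                    pi_k = stats::setNames(colMeans(pool("pi_k")), genes))
  if (mcmc$store_omega)
    post_mean$omega <- stats::setNames(colMeans(pool("omega")), probes)

  prediction <- NULL
  if (!is.null(nd$keep) && nd$keep) {
    yh <- pool("yhat")
    prediction <- list(fit = colMeans(yh), draws = yh)
    if (data$outcome$kind == "binary")
      prediction$prob <- colMeans(pnorm(yh))
  }

  structure(list(call = match.call(),
                 outcome_kind = data$outcome$kind,
                 dims = c(N = N, K = K, J = J, L = ncol(data$C)),
                 genes = genes, probes = probes,
                 probe_map = data$probe_map,
                 prior = prior, mcmc = mcmc, seed = seed,
                 chains = chains, ppi = ppi, post_mean = post_mean,
                 prediction = prediction,
                 n_missing = c(E = sum(data$U_E), M = sum(data$U_M))),
            class = "netmim")
}

pool_vec <- function(chains, name) unlist(lapply(chains, `[[`, name))

.prep_newdata <- function(newdata, data) {
  if (is.null(newdata))
    return(list(C = matrix(0, 0, ncol(data$C)),
                E = matrix(0, 0, ncol(data$E)),
                M = matrix(0, 0, ncol(data$M)), keep = FALSE))
  if (inherits(newdata, "momics_data")) {
    if (any(newdata$U_E == 1) || any(newdata$U_M == 1))
      stop("prediction requires complete omics rows in newdata")
    return(list(C = newdata$C, E = newdata$E, M = newdata$M, keep = TRUE))
  }
  C <- as.matrix(newdata$C)
  if (ncol(C) == ncol(data$C) - 1) C <- cbind(1, C)
  E <- as.matrix(newdata$E); M <- as.matrix(newdata$M)
  if (anyNA(E) || anyNA(M))
    stop("prediction requires complete omics rows in newdata")
  stopifnot(ncol(C) == ncol(data$C), ncol(E) == ncol(data$E),
            ncol(M) == ncol(data$M))
  list(C = C, E = E, M = M, keep = TRUE)
}

.init_state <- function(data, E0, prior, tau_k, outcome_type, random) {
  K <- ncol(data$E); J <- ncol(data$M); N <- nrow(data$E)
  y0 <- switch(data$outcome$kind,
               continuous = data$outcome$y,
               binary = rep(0, N),
               survival = log(data$outcome$y))
  obsE <- data$U_E == 0
  sigma2_k <- vapply(seq_len(K), function(k) {
    v <- var(E0[obsE, k]); if (!is.finite(v) || v <= 0) 1 else v
  }, 0)
  beta_C <- tryCatch(drop(qr.coef(qr(data$C), y0)), error = function(e) NULL)
  if (is.null(beta_C) || anyNA(beta_C)) beta_C <- numeric(ncol(data$C))
  sigma2 <- if (outcome_type == 1) 1 else max(var(y0), 1e-3)
  st <- list(z = integer(J), omega = numeric(J),
             sigma2_k = sigma2_k, pi_k = rep(prior$a / (prior$a + prior$b), K),
             gamma_M = integer(K), gamma_B = integer(K),
             beta_M = numeric(K), beta_B = numeric(K),
             beta_C = beta_C, sigma2 = sigma2)
  if (random) {
    st$z <- rbinom(J, 1, 0.5)
    st$omega <- st$z * rnorm(J, 0, sqrt(sigma2_k[1] / tau_k[1]))
    st$gamma_M <- rbinom(K, 1, 0.1)
    st$gamma_B <- rbinom(K, 1, 0.1)
    st$beta_M <- st$gamma_M * rnorm(K, 0, sqrt(sigma2 / prior$tau))
    st$beta_B <- st$gamma_B * rnorm(K, 0, sqrt(sigma2 / prior$tau))
    st$sigma2_k <- sigma2_k * exp(rnorm(K, 0, 0.25))
    st$sigma2 <- if (outcome_type == 1) 1 else sigma2 * exp(rnorm(1, 0, 0.25))
    st$pi_k <- rbeta(K, prior$a, prior$b)
  }
  st
}

#' Pairwise cross-chain correlation of posterior inclusion probabilities
#'
#' Convergence diagnostic: Pearson correlations of the PPI vectors between
#' every pair of chains, computed separately for the gene-level indicators
#' (`gamma`, the OR of the two effect types) and the probe indicators (`z`).
#' Consistently high correlations indicate that independent chains agree on
#' the selection.
#'
#' @param fit a fitted [netmim] object with at least two chains, or a list
#'   of fitted objects (one chain each).
#' @return A list with correlation matrices `gamma` and `z`. An undefined
#'   correlation (a constant PPI vector in some chain) is reported as `NA`.
#' @export
cross_chain_ppi_cor <- function(fit) {
  chains <- if (inherits(fit, "netmim")) fit$chains
            else unlist(lapply(fit, `[[`, "chains"), recursive = FALSE)
  if (length(chains) < 2) stop("need at least two chains")
  ppi_g <- vapply(chains, function(ch)
    colMeans((ch$gamma_M + ch$gamma_Mbar) > 0), numeric(ncol(chains[[1]]$gamma_M)))
  ppi_z <- vapply(chains, function(ch) colMeans(ch$z),
                  numeric(ncol(chains[[1]]$z)))
  safe_cor <- function(m) {
    n <- ncol(m)
    out <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) next
      out[i, j] <- cor(m[, i], m[, j])
    }
    out
  }
  list(gamma = safe_cor(ppi_g), z = safe_cor(ppi_z))
}

# internal: successive-conditional simulator used by the
# "getting it right" correctness checks; keeps M and C fixed and
# regenerates E and Y from the current parameters after every sweep
netmim_geweke <- function(data, prior = netmim_prior(delta1 = 3, delta2 = 3),
                          n_iter = 20000, thin = 5, seed = 1) {
  K <- ncol(data$E); J <- ncol(data$M); N <- nrow(data$E)
  Jk0 <- lapply(data$probe_sets, function(v) as.integer(v - 1L))
  nbr0 <- lapply(seq_len(K),
                 function(k) as.integer(which(data$network[k, ] == 1) - 1L))
  tau_k <- rep_len(prior$tau_k, K)
  set.seed(seed)
  st <- .init_state(data, data$E, prior, tau_k, 0L, random = FALSE)
  cpp_run_netmim(
    C = data$C, E = data$E, M = data$M,
    y_obs = data$outcome$y, event = integer(N), outcome_type = 0L,
    Jk_list = Jk0, nbr_list = nbr0, uE = integer(N), uM = integer(N),
    d = prior$d, f = prior$f, tau = prior$tau, tau_k = tau_k,
    tau_c = prior$tau_c, a = prior$a, b = prior$b,
    d1 = prior$delta1, d2 = prior$delta2,
    sigma_m = rep_len(prior$sigma_m, J), alloc = prior$alloc,
    T = as.integer(n_iter), Tb = 0L, thin = as.integer(thin),
    store_omega = TRUE, modular_mech = FALSE, modular_imp = FALSE,
    clin_first = FALSE, geweke = TRUE,
    z = st$z, omega = st$omega, sigma2_k = st$sigma2_k, pi_k = st$pi_k,
    gamma_M = st$gamma_M, gamma_B = st$gamma_B,
    beta_M = st$beta_M, beta_B = st$beta_B, beta_C = st$beta_C,
    sigma2 = st$sigma2,
    C_new = matrix(0, 0, ncol(data$C)), E_new = matrix(0, 0, K),
    M_new = matrix(0, 0, J), verbose = FALSE)
}
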