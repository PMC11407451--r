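# independent oracles: exhaustive enumeration of indicator posteriors using
# direct multivariate-normal marginal densities (2N x 2N covariances), a
# code path sharing nothing with the sampler's conjugate algebra

ldmvnorm0 <- function(x, V) {
  L <- chol(V)
  w <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w * w)
}

# exact posterior over all 2^p probe-indicator configurations for one gene,
# with the probe effects integrated out; clinical coupling enters through
# Rk ~ N(bk * Mk omega, sigma2 I)
mech_enum_posterior <- function(Mk, Ek, Rk, bk, sig2k, sigma2, pik, tau_k) {
  p <- ncol(Mk); N <- nrow(Mk)
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  logw <- apply(configs, 1, function(z) {
    S <- which(z == 1)
    prior <- sum(z) * log(pik) + (p - sum(z)) * log(1 - pik)
    Ms <- Mk[, S, drop = FALSE]
    Vee <- (sig2k / tau_k) * tcrossprod(Ms)
    V <- rbind(cbind(Vee + sig2k * diag(N), bk * Vee),
               cbind(bk * Vee, bk^2 * Vee + sigma2 * diag(N)))
    prior + ldmvnorm0(c(Ek, Rk), V)
  })
  w <- exp(logw - max(logw))
  stats::setNames(w / sum(w), apply(configs, 1, paste, collapse = ""))
}

# drive the sampler's own single-gene mechanistic update as a Gibbs chain
# with pi_k / sigma_k^2 held fixed; returns visit frequencies per z config
mech_gibbs_freq <- function(Mk, Ek, Rk, bk, sig2k, sigma2, pik, tau_k,
                            sweeps = 50000, seed = 1) {
  set.seed(seed)
  p <- ncol(Mk)
  z <- integer(p); om <- numeric(p)
  counts <- integer(2^p)
  for (s in seq_len(sweeps)) {
    up <- netmim:::cpp_mech_gene_update(Mk, Ek, Rk, z, om, sig2k, pik,
                                        bk, sigma2, TRUE, tau_k,
                                        1, 1, 1, 1, FALSE, FALSE)
    z <- up$z; om <- up$omega
    counts[sum(z * 2^(seq_len(p) - 1)) + 1] <- counts[sum(z * 2^(seq_len(p) - 1)) + 1] + 1L
  }
  counts / sweeps
}

# exact joint posterior over the 4^K gene-effect configurations with the
# effects integrated out; MRF prior on the OR indicators plus the active-
# configuration allocation weights
clin_enum_posterior <- function(xM_list, xB_list, y0, G, d, f, alloc, tau,
                                sigma2) {
  K <- length(xM_list); N <- length(y0)
  cfgs <- as.matrix(expand.grid(rep(list(0:3), K)))
  logw <- apply(cfgs, 1, function(cf) {
    X <- NULL; la <- 0; gam <- integer(K)
    for (k in seq_len(K)) {
      cc <- cf[k]
      if (cc >= 1) { gam[k] <- 1; la <- la + log(alloc[cc]) }
      if (cc == 1 || cc == 3) X <- cbind(X, xM_list[[k]])
      if (cc == 2 || cc == 3) X <- cbind(X, xB_list[[k]])
    }
    prior <- d * sum(gam) + f * drop(crossprod(gam, G %*% gam)) / 2 + la
    V <- if (is.null(X)) sigma2 * diag(N)
         else sigma2 * (tcrossprod(X) / tau + diag(N))
    prior + ldmvnorm0(y0, V)
  })
  w <- exp(logw - max(logw))
  stats::setNames(w / sum(w), apply(cfgs, 1, paste, collapse = ""))
}

# drive the sampler's gene-level clinical update over K genes as a Gibbs
# chain with everything else frozen; returns visit frequencies per config
clin_gibbs_freq <- function(xM_list, xB_list, y0, G, d, f, alloc, tau,
                            sigma2, sweeps = 50000, seed = 1) {
  K <- length(xM_list)
  set.seed(seed)
  gM <- integer(K); gB <- integer(K)
  bM <- numeric(K); bB <- numeric(K)
  r <- y0
  counts <- integer(4^K)
  for (s in seq_len(sweeps)) {
    for (k in seq_len(K)) {
      sres <- r + bM[k] * xM_list[[k]] + bB[k] * xB_list[[k]]
      g_or <- as.integer(gM | gB)
      logit <- d + f * sum(G[k, ] * g_or) - f * G[k, k] * g_or[k]
      up <- netmim:::cpp_clin_gene_update(xM_list[[k]], xB_list[[k]], sres,
                                          logit, log(alloc), tau, sigma2)
      gM[k] <- up$gamma_M; gB[k] <- up$gamma_Mbar
      bM[k] <- up$beta_M; bB[k] <- up$beta_Mbar
      r <- sres - bM[k] * xM_list[[k]] - bB[k] * xB_list[[k]]
    }
    cfg <- gM + 2L * gB   # 0,1,2,3 per gene
    idx <- sum(cfg * 4^(seq_len(K) - 1)) + 1L
    counts[idx] <- counts[idx] + 1L
  }
  counts / sweeps
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# batch-means standard error for autocorrelated MCMC output
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  bs <- floor(n / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(b) mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  sd(means) / sqrt(n_batch)
}
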