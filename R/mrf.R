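#' MRF prior: conditional log-odds of including one gene
#'
#' Under the Markov random field prior on gene inclusion indicators,
#' `p(gamma_k = 1 | gamma_-k)` is the logistic transform of
#' `d + f * sum(gamma[neighbours of k])`. `d < 0` encourages sparsity, and
#' `f >= 0` encourages joint inclusion of network neighbours. A gene without
#' neighbours reduces to a Bernoulli prior with probability
#' `plogis(d)` = `exp(d)/(1 + exp(d))`.
#'
#' @param k gene index.
#' @param gamma binary inclusion vector (the value at position `k` is
#'   ignored).
#' @param network K x K binary symmetric adjacency matrix.
#' @param d sparsity parameter (typically negative).
#' @param f smoothness parameter (non-negative).
#' @return The conditional log-odds of inclusion (a scalar); apply
#'   [stats::plogis()] for the probability.
#' @examples
#' G <- matrix(0, 3, 3)
#' plogis(mrf_conditional_logit(1, c(0, 0, 0), G, d = -3, f = 0.5)) # ~0.047
#' @export
mrf_conditional_logit <- function(k, gamma, network, d, f) {
  nb <- which(network[k, ] == 1)
  d + f * sum(gamma[nb])
}

#' MRF prior: unnormalized joint log-density
#'
#' Evaluates `d * sum(gamma) + f * sum over linked pairs with both ends
#' active`, the log of the joint MRF prior up to its intractable
#' normalizing constant. Each unordered edge contributes `f` once, which is
#' the normalization under which flipping one indicator changes this
#' quantity by exactly the conditional log-odds of
#' [mrf_conditional_logit()]. Only differences of this quantity are ever
#' used by the sampler.
#'
#' @inheritParams mrf_conditional_logit
#' @return Unnormalized joint log prior (a scalar).
#' @export
mrf_log_prior <- function(gamma, network, d, f) {
  gamma <- as.numeric(gamma)
  d * sum(gamma) + f * drop(crossprod(gamma, network %*% gamma)) / 2
}
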