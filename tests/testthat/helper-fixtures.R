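# small hand-built datasets used across tests (all generated in code)

toy_ds <- function(N = 8, psets = list(1:2, 3), seed = 1,
                   outcome = "continuous", edges = NULL, n_cov = 1,
                   y = NULL) {
  set.seed(seed)
  K <- length(psets)
  J <- max(unlist(psets))
  genes <- paste0("g", seq_len(K))
  probes <- paste0("cg", seq_len(J))
  gene_of <- integer(J)
  for (k in seq_len(K)) gene_of[psets[[k]]] <- k
  M <- matrix(rnorm(N * J), N, J, dimnames = list(NULL, probes))
  E <- matrix(rnorm(N * K), N, K, dimnames = list(NULL, genes))
  C <- matrix(rnorm(N * n_cov), N, n_cov,
              dimnames = list(NULL, paste0("x", seq_len(n_cov))))
  if (is.null(y)) {
    y <- switch(outcome,
                continuous = rnorm(N),
                binary = rbinom(N, 1, 0.5),
                survival = cbind(time = rexp(N) + 0.1,
                                 event = rbinom(N, 1, 0.7)))
  }
  pm <- data.frame(probe = probes, gene = genes[gene_of])
  net <- if (is.null(edges)) data.frame(gene_a = character(),
                                        gene_b = character())
         else edges
  momics_data(E = E, M = M, C = C, outcome = y, outcome_kind = outcome,
              probe_map = pm, network = net,
              sample_ids = paste0("s", seq_len(N)))
}

# write a toy dataset's file set into a temp dir, returning the paths
toy_files <- function(ds, dir = tempfile("momics")) {
  write_momics(ds, dir)
  list(clinical = file.path(dir, "clinical.tsv"),
       expression = file.path(dir, "expression.tsv"),
       methylation = file.path(dir, "methylation.tsv"),
       probe_map = file.path(dir, "probe_map.tsv"),
       network = file.path(dir, "network.tsv"),
       dir = dir)
}

quick_mcmc <- function(n_iter = 600, burnin = 300, seed = 1, ...) {
  netmim_mcmc(n_iter = n_iter, burnin = burnin, chains = 1, seed = seed,
              ...)
}
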