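#' Simulate a multi-omics study with known ground truth
#'
#' Generates benchmark studies with a fully known ground truth for
#' evaluating feature selection and prediction: `N` subjects with `L` standard-normal
#' clinical covariates, `J` methylation probes randomly allocated to `K`
#' genes (each gene at least one probe), half the genes methylation-
#' regulated with probe indicators `z ~ Bern(1/2)` and probe effects drawn
#' from `±Unif(0.5, 1)`, residual expression `N(0, 1)`, and fifteen
#' outcome-relevant genes: genes 1-5 act through both expression
#' components, genes 6-10 only through the methylation-regulated part and
#' genes 11-15 only through the rest, with clinical-model effects
#' `±Unif(1, 1.5)`, clinical covariate and intercept coefficients 1, and
#' outcome noise standard deviation `sigma`. A gene network places
#' `Bern(0.1)` edges among the 15 effective genes and an equal number of
#' edges uniformly among the ineffective genes. Methylation is drawn as
#' within-gene blocks of exchangeable-correlation Gaussians (unit variance,
#' correlation `rho`), playing the role of normalized M-values. Scenarios
#' II-IV additionally remove whole omics blocks for a subset of subjects.
#' An independent complete validation set of `n_validation` subjects is
#' generated from the same law.
#'
#' @param n training-sample size.
#' @param n_genes number of genes K (typically 100, 200 or 500).
#' @param n_probes number of probes J (must be `>= n_genes`).
#' @param n_covariates number of clinical covariates L (excluding the
#'   intercept).
#' @param sigma outcome noise standard deviation (typically 1, 2 or 3).
#' @param rho within-gene exchangeable methylation correlation; 0 gives
#'   independent probes.
#' @param outcome outcome kind to generate.
#' @param scenario `"I"` complete data; `"II"` a fraction `missing_ratio`
#'   of subjects missing expression; `"III"` the same for methylation;
#'   `"IV"` half of all subjects missing exactly one block, a fraction
#'   `missing_split` of them missing expression.
#' @param missing_ratio fraction in `[0, 1)` of subjects with a missing
#'   block (scenarios II and III).
#' @param missing_split scenario IV only: fraction of the missing half that
#'   lacks expression (the rest lack methylation).
#' @param n_validation size of the complete validation set.
#' @param cens_rate target censoring fraction for survival outcomes.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return A list of class `netmim_sim` with elements `data` (a
#'   [momics_data] with any scenario missingness applied), `validation`
#'   (complete [momics_data]), and `truth` (list with `z`, `omega`,
#'   `gamma_M`, `gamma_Mbar`, `beta_M`, `beta_Mbar`, `beta_C`, `regulated`,
#'   `effective`, `E_M`, `E_Mbar`, the network, and the missingness masks).
#' @export
netmim_sim <- function(n = 100, n_genes = 100, n_probes = 300,
                       n_covariates = 3, sigma = 1, rho = 0.5,
                       outcome = c("continuous", "binary", "survival"),
                       scenario = c("I", "II", "III", "IV"),
                       missing_ratio = 0, missing_split = 0.5,
                       n_validation = 100, cens_rate = 0.3, seed = NULL) {
  outcome <- match.arg(outcome)
  scenario <- match.arg(scenario)
  if (n_probes < n_genes) stop("need n_probes >= n_genes")
  if (n_genes < 20)
    stop("need n_genes >= 20 (15 effective genes plus a regulated half)")
  if (missing_ratio < 0 || missing_ratio >= 1) stop("missing_ratio in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  K <- n_genes; J <- n_probes; L <- n_covariates

  genes <- paste0("g", seq_len(K))
  probes <- paste0("cg", seq_len(J))

  # probe allocation: every gene >= 1 probe, remainder uniform
  gene_of <- c(seq_len(K), sample.int(K, J - K, replace = TRUE))
  gene_of <- sample(gene_of)   # shuffle so probe order carries no signal
  probe_map <- data.frame(probe = probes, gene = genes[gene_of])
  psets <- split(seq_len(J), factor(gene_of, levels = seq_len(K)))

  # methylation-regulated genes: half of all genes; genes 1-10 carry
  # type-M outcome effects and must be regulated, the rest are sampled
  n_reg <- floor(K / 2)
  regulated <- sort(c(1:10, sample(setdiff(seq_len(K), 1:10), n_reg - 10)))

  z <- integer(J); omega <- numeric(J)
  for (k in regulated) {
    jj <- psets[[k]]
    zk <- rbinom(length(jj), 1, 0.5)
    if (sum(zk) == 0) {
      zk <- rbinom(length(jj), 1, 0.5)   # one redraw, then force one probe
      if (sum(zk) == 0) zk[sample.int(length(jj), 1)] <- 1L
    }
    z[jj] <- zk
  }
  act <- which(z == 1)
  omega[act] <- runif(length(act), 0.5, 1) *
    sample(c(-1, 1), length(act), replace = TRUE)

  # effective genes: 1-5 both effects, 6-10 type M only, 11-15 type Mbar only
  gamma_M <- integer(K); gamma_B <- integer(K)
  gamma_M[1:10] <- 1L
  gamma_B[c(1:5, 11:15)] <- 1L
  eff <- which(gamma_M == 1 | gamma_B == 1)
  pm_sign <- function(m) runif(m, 1, 1.5) * sample(c(-1, 1), m, replace = TRUE)
  beta_M <- numeric(K); beta_B <- numeric(K)
  beta_M[gamma_M == 1] <- pm_sign(sum(gamma_M))
  beta_B[gamma_B == 1] <- pm_sign(sum(gamma_B))
  beta_C <- rep(1, L + 1)  # intercept and clinical covariates all 1

  G <- sim_gene_network(eff, K, prob = 0.1)
  dimnames(G) <- list(genes, genes)

  draw_block <- function(nr) {
    # exchangeable within-gene correlation rho, unit variance
    M <- matrix(0, nr, J)
    for (k in seq_len(K)) {
      jj <- psets[[k]]
      shared <- rnorm(nr)
      M[, jj] <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(rnorm(nr * length(jj)), nr)
    }
    M
  }
  gen <- function(nr) {
    C <- matrix(rnorm(nr * L), nr)
    M <- draw_block(nr)
    E_M <- matrix(0, nr, K)
    for (k in seq_len(K)) {
      jj <- psets[[k]]
      E_M[, k] <- M[, jj, drop = FALSE] %*% omega[jj]
    }
    E_B <- matrix(rnorm(nr * K), nr)  # sigma_k^2 = 1
    E <- E_M + E_B
    mu <- cbind(1, C) %*% beta_C + E_M %*% beta_M + E_B %*% beta_B
    list(C = C, M = M, E = E, E_M = E_M, E_B = E_B, mu = drop(mu))
  }

  make_outcome <- function(mu, nr) {
    switch(outcome,
      continuous = list(y = mu + sigma * rnorm(nr), event = NULL),
      binary = list(y = as.integer(mu + sigma * rnorm(nr) > 0), event = NULL),
      survival = {
        logt <- mu + sigma * rnorm(nr)
        # censoring offset tuned so P(t > c) ~ cens_rate
        offset <- -qnorm(cens_rate) * sqrt(2) * sigma
        logc <- mu + offset + sigma * rnorm(nr)
        list(y = exp(pmin(logt, logc)),
             event = as.integer(logt <= logc))
      })
  }

  tr <- gen(n); va <- gen(n_validation)
  ytr <- make_outcome(tr$mu, n); yva <- make_outcome(va$mu, n_validation)

  as_ds <- function(g, yy, ids) {
    dimnames(g$E) <- list(ids, genes); dimnames(g$M) <- list(ids, probes)
    colnames(g$C) <- paste0("x", seq_len(L))
    oc <- if (outcome == "survival") cbind(time = yy$y, event = yy$event)
          else yy$y
    momics_data(E = g$E, M = g$M, C = g$C, outcome = oc,
                outcome_kind = outcome, probe_map = probe_map,
                network = G, sample_ids = ids)
  }
  ds <- as_ds(tr, ytr, sprintf("s%03d", seq_len(n)))
  val <- as_ds(va, yva, sprintf("v%03d", seq_len(n_validation)))

  if (scenario != "I")
    ds <- inject_missingness(ds, scenario, ratio = missing_ratio,
                             split = missing_split)

  truth <- list(z = z, omega = omega, gamma_M = gamma_M, gamma_Mbar = gamma_B,
                beta_M = beta_M, beta_Mbar = beta_B, beta_C = beta_C,
                regulated = regulated, effective = eff,
                sigma = sigma, network = G,
                E_M = tr$E_M, E_Mbar = tr$E_B,
                U_E = ds$U_E, U_M = ds$U_M,
                probe_map = probe_map)
  structure(list(data = ds, validation = val, truth = truth,
                 scenario = scenario, outcome = outcome),
            class = "netmim_sim")
}

#' Simulate a gene network around a known effective set
#'
#' Places undirected edges among the effective genes independently with
#' probability `prob`, then places the same number of edges uniformly at
#' random among the ineffective genes (capped at that stratum's capacity).
#'
#' @param effective integer indices of the effective genes.
#' @param n_genes total number of genes K.
#' @param prob edge probability among effective genes.
#' @return A K x K binary symmetric adjacency matrix with zero diagonal.
#' @export
sim_gene_network <- function(effective, n_genes, prob = 0.1) {
  G <- matrix(0L, n_genes, n_genes)
  eff <- as.integer(effective)
  if (length(eff) >= 2) {
    pairs <- utils::combn(eff, 2)
    on <- rbinom(ncol(pairs), 1, prob) == 1
    for (i in which(on)) {
      G[pairs[1, i], pairs[2, i]] <- 1L
      G[pairs[2, i], pairs[1, i]] <- 1L
    }
  }
  n_eff_edges <- sum(G) / 2
  ineff <- setdiff(seq_len(n_genes), eff)
  if (n_eff_edges > 0 && length(ineff) >= 2) {
    cap <- choose(length(ineff), 2)
    m <- min(n_eff_edges, cap)
    if (m < n_eff_edges)
      message("ineffective stratum capacity reached; placing ", m, " edges")
    pairs <- utils::combn(ineff, 2)
    pick <- sample.int(ncol(pairs), m)
    for (i in pick) {
      G[pairs[1, i], pairs[2, i]] <- 1L
      G[pairs[2, i], pairs[1, i]] <- 1L
    }
  }
  G
}

#' Remove whole omics blocks from a complete dataset
#'
#' Applies the block-missingness patterns of the simulation scenarios:
#' scenario II removes expression for a uniformly random fraction `ratio`
#' of subjects, scenario III removes methylation likewise, and scenario IV
#' makes half of all subjects missing exactly one block, a fraction
#' `split` of them missing expression. No subject ever loses both blocks.
#'
#' @param ds a complete [momics_data] object.
#' @param scenario `"II"`, `"III"` or `"IV"`.
#' @param ratio missing fraction for scenarios II/III.
#' @param split scenario IV: fraction of the missing half lacking
#'   expression.
#' @return The dataset with `U_E`/`U_M` set and the hidden rows `NA`.
#' @export
inject_missingness <- function(ds, scenario = c("II", "III", "IV"),
                               ratio = 0.3, split = 0.5) {
  scenario <- match.arg(scenario)
  N <- length(ds$sample_ids)
  if (any(ds$U_E == 1) || any(ds$U_M == 1))
    stop("dataset already has missingness")
  if (scenario %in% c("II", "III")) {
    m <- round(N * ratio)
    idx <- sample.int(N, m)
    if (scenario == "II") ds$U_E[idx] <- 1L else ds$U_M[idx] <- 1L
  } else {
    m <- round(N / 2)
    idx <- sample.int(N, m)
    mE <- round(m * split)
    ds$U_E[idx[seq_len(mE)]] <- 1L
    if (mE < m) ds$U_M[idx[(mE + 1):m]] <- 1L
  }
  if (any(ds$U_E * ds$U_M == 1)) stop("a subject lost both blocks")
  ds$E[ds$U_E == 1, ] <- NA_real_
  ds$M[ds$U_M == 1, ] <- NA_real_
  ds
}

#' @exportS3Method base::print
print.netmim_sim <- function(x, ...) {
  cat("Simulated multi-omics study (scenario ", x$scenario, ", ",
      x$outcome, " outcome)\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Decompose expression into its regulated and residual parts
#'
#' Given probe effects, returns `E_M = M Omega` and the residual
#' `E_Mbar = E - E_M`; their sum reproduces `E` exactly.
#'
#' @param E expression matrix (N x K).
#' @param M methylation matrix (N x J).
#' @param omega length-J probe-effect vector (probe j acts on its mapped
#'   gene), or a J x K matrix.
#' @param probe_sets list of per-gene probe index vectors (needed when
#'   `omega` is a vector).
#' @return A list with matrices `E_M` and `E_Mbar`.
#' @export
decompose_expression <- function(E, M, omega, probe_sets = NULL) {
  E <- as.matrix(E); M <- as.matrix(M)
  if (is.matrix(omega)) {
    if (nrow(omega) != ncol(M) || ncol(omega) != ncol(E))
      stop("omega dimensions do not match M columns x E columns")
    E_M <- M %*% omega
  } else {
    stopifnot(!is.null(probe_sets), length(omega) == ncol(M))
    E_M <- matrix(0, nrow(E), ncol(E))
    for (k in seq_along(probe_sets)) {
      jj <- probe_sets[[k]]
      E_M[, k] <- M[, jj, drop = FALSE] %*% omega[jj]
    }
  }
  list(E_M = E_M, E_Mbar = E - E_M)
}
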