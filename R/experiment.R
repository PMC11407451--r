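#' Replicated simulation experiment over a condition grid
#'
#' For every grid cell and replicate: simulate a study, fit the requested
#' methods, and score feature selection (AUC and AUCPR of the concatenated
#' gene-level scores against the ground truth) and prediction (PMSE on the
#' complete validation set). Per-cell failures are recorded and the run
#' continues.
#'
#' @param grid data.frame with columns among `scenario`, `n_genes`,
#'   `sigma`, `missing_ratio` (defaults fill in scenario "I", 100 genes,
#'   sigma 1, ratio 0).
#' @param replicates replicates per cell.
#' @param methods character subset of `"netmim"`, `"netmim_nomrf"`,
#'   `"netmim_cc"`, `"mimic_lasso"`, `"mimic_enet"`, `"lasso"`, `"enet"`.
#' @param n_iter,burnin MCMC length for the Bayesian fits.
#' @param chains MCMC chains per Bayesian fit (pooled for PPIs).
#' @param seed base seed; replicate r of cell c uses a deterministic
#'   offset.
#' @param ... further arguments passed to [netmim_sim()].
#' @return A data.frame with one row per cell x replicate x method and
#'   columns `auc`, `aucpr`, `pmse` (and `error` for failed fits).
#' @export
netmim_experiment <- function(grid = data.frame(scenario = "I"),
                              replicates = 2,
                              methods = c("netmim", "netmim_nomrf",
                                          "mimic_enet"),
                              n_iter = 2000, burnin = 1000, chains = 1,
                              seed = 1, ...) {
  grid <- as.data.frame(grid)
  if (is.null(grid$scenario)) grid$scenario <- "I"
  if (is.null(grid$n_genes)) grid$n_genes <- 100
  if (is.null(grid$sigma)) grid$sigma <- 1
  if (is.null(grid$missing_ratio)) grid$missing_ratio <- 0
  out <- list()
  for (ci in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      sim_seed <- seed + 1000L * (ci - 1L) + r
      sim <- netmim_sim(scenario = grid$scenario[ci],
                        n_genes = grid$n_genes[ci],
                        sigma = grid$sigma[ci],
                        missing_ratio = grid$missing_ratio[ci],
                        seed = sim_seed, ...)
      for (m in methods) {
        res <- tryCatch(
          .run_method(m, sim, n_iter, burnin, chains, sim_seed),
          error = function(e) list(auc = NA, aucpr = NA, pmse = NA,
                                   error = conditionMessage(e)))
        out[[length(out) + 1]] <- data.frame(
          scenario = grid$scenario[ci], n_genes = grid$n_genes[ci],
          sigma = grid$sigma[ci], missing_ratio = grid$missing_ratio[ci],
          replicate = r, method = m,
          auc = res$auc, aucpr = res$aucpr, pmse = res$pmse,
          error = if (is.null(res$error)) NA_character_ else res$error)
      }
    }
  }
  do.call(rbind, out)
}

# gene-level selection scores concatenated as (type Mbar, type M),
# scored against the simulation truth
.sel_metrics <- function(score_M, score_B, truth) {
  sc <- c(score_B, score_M)
  tr <- c(truth$gamma_Mbar, truth$gamma_M)
  list(auc = selection_auc(sc, tr), aucpr = selection_aucpr(sc, tr))
}

.run_method <- function(method, sim, n_iter, burnin, chains, seed) {
  ds <- sim$data; val <- sim$validation; truth <- sim$truth
  yv <- if (sim$outcome == "survival") log(val$outcome$y) else val$outcome$y
  if (method %in% c("netmim", "netmim_nomrf", "netmim_cc")) {
    prior <- netmim_prior(f = if (method == "netmim_nomrf") 0 else 0.5)
    mc <- netmim_mcmc(n_iter = n_iter, burnin = burnin, chains = chains,
                      seed = seed, store_omega = FALSE)
    dsm <- if (method == "netmim_cc") complete_cases(ds) else ds
    fit <- netmim(dsm, prior, mc, newdata = val)
    m <- .sel_metrics(fit$ppi$gamma_M, fit$ppi$gamma_Mbar, truth)
    list(auc = m$auc, aucpr = m$aucpr,
         pmse = pmse(yv, fit$prediction$fit))
  } else if (method %in% c("mimic_lasso", "mimic_enet")) {
    fit <- mimic_penalized(ds, sub("mimic_", "", method))
    m <- .sel_metrics(fit$score_M, fit$score_Mbar, truth)
    list(auc = m$auc, aucpr = m$aucpr,
         pmse = pmse(yv, predict(fit, val)))
  } else if (method %in% c("lasso", "enet")) {
    fit <- vanilla_penalized(ds, method)
    co <- as.numeric(coef(fit$fit, s = "lambda.min"))[-1]
    L <- fit$n_covariates; K <- fit$n_genes
    scE <- abs(co[L + seq_len(K)])
    m <- list(auc = selection_auc(scE, truth$gamma_M | truth$gamma_Mbar),
              aucpr = selection_aucpr(scE,
                                      truth$gamma_M | truth$gamma_Mbar))
    list(auc = m$auc, aucpr = m$aucpr,
         pmse = pmse(yv, predict(fit, val)))
  } else stop("unknown method: ", method)
}
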