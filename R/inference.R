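#' Posterior inclusion probabilities
#'
#' The PPI of an indicator is the fraction of kept post-burn-in draws
#' (pooled over chains) in which it equals one.
#'
#' @param fit a fitted [netmim] object.
#' @return A list with components `gamma_M`, `gamma_Mbar`, `gamma` (the OR
#'   of the two) and `z` (probe-level), each a named numeric vector in
#'   `[0, 1]`.
#' @export
ppi <- function(fit) {
  stopifnot(inherits(fit, "netmim"))
  fit$ppi
}

#' Select features by thresholding PPIs
#'
#' A gene is selected for a type-M effect iff `PPI(gamma_M) > threshold`
#' (strictly), and analogously for the type-Mbar effect and the probe
#' indicators. The default 0.5 is the median probability model, which tends
#' to give a reasonable Bayesian FDR.
#'
#' @param x a fitted [netmim] object or a [summary.netmim].
#' @param threshold selection threshold in (0, 1).
#' @return A list with gene-name vectors `M_only`, `Mbar_only`, `both`,
#'   `genes` (the union) and `probes` (selected probe ids).
#' @export
select_features <- function(x, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (inherits(x, "netmim")) {
    pM <- x$ppi$gamma_M; pB <- x$ppi$gamma_Mbar; pz <- x$ppi$z
    genes <- x$genes; probes <- x$probes
  } else {
    pM <- x$genes$PPI_M; pB <- x$genes$PPI_Mbar; pz <- x$probes$PPI_Z
    genes <- x$genes$gene; probes <- x$probes$probe
  }
  sM <- pM > threshold; sB <- pB > threshold
  list(M_only = genes[sM & !sB],
       Mbar_only = genes[!sM & sB],
       both = genes[sM & sB],
       genes = genes[sM | sB],
       probes = probes[pz > threshold])
}

#' Bayesian FDR threshold for PPIs
#'
#' Returns the smallest PPI cutoff `t` such that the estimated Bayesian
#' false discovery rate of the selection `{p_k >= t}`,
#' `sum((1 - p_k) * 1(p_k >= t)) / #(p_k >= t)`, does not exceed `alpha`.
#' Selecting by `p >= t` at the returned cutoff controls the estimated FDR
#' at level `alpha`. If no cutoff qualifies, 1 is returned (select none).
#'
#' @param ppi numeric vector of posterior inclusion probabilities.
#' @param alpha target Bayesian FDR in (0, 1).
#' @return The PPI cutoff (a scalar in (0, 1]).
#' @export
bayes_fdr_threshold <- function(ppi, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, all(ppi >= 0), all(ppi <= 1))
  ts <- sort(unique(ppi[ppi > 0]), decreasing = TRUE)
  best <- 1
  for (t in ts) {
    sel <- ppi >= t
    fdr <- sum(1 - ppi[sel]) / sum(sel)
    if (fdr <= alpha) best <- t else break
  }
  best
}

#' Root-mean-square prediction error
#'
#' `sqrt(sum((y - yhat)^2) / N_v)` over a validation set of size `N_v`.
#'
#' @param y_true,y_pred numeric vectors of equal positive length.
#' @return A non-negative scalar.
#' @export
pmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1)
  sqrt(mean((y_true - y_pred)^2))
}

#' Feature-selection AUC
#'
#' Rank-based area under the ROC curve of a score vector (for example PPIs)
#' against a binary ground truth, with ties handled by average ranks. This
#' equals the probability that a randomly chosen truly active feature
#' scores above a randomly chosen inactive one (ties counted half).
#'
#' @param score numeric scores, higher meaning more likely active.
#' @param truth binary vector (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
selection_auc <- function(score, truth) {
  truth <- as.integer(truth != 0)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("truth must contain both classes")
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Feature-selection area under the precision-recall curve
#'
#' Step-interpolated (average-precision style) area under the
#' precision-recall curve, sweeping the score thresholds from high to low;
#' tied scores enter as a single threshold step.
#'
#' @inheritParams selection_auc
#' @return AUCPR in `(0, 1]`.
#' @export
selection_aucpr <- function(score, truth) {
  truth <- as.integer(truth != 0)
  n1 <- sum(truth == 1)
  if (n1 == 0 || n1 == length(truth)) stop("truth must contain both classes")
  ts <- sort(unique(score), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in ts) {
    sel <- score >= t
    prec <- sum(truth[sel]) / sum(sel)
    rec <- sum(truth[sel]) / n1
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

#' Harrell concordance index for survival predictions
#'
#' The proportion of admissible subject pairs whose predicted ordering
#' agrees with the observed survival ordering. A pair is admissible when
#' the smaller observed time is an event; predictions are on the log-time
#' scale (a larger predicted value means longer predicted survival, that is
#' lower risk). Tied predictions count one half; pairs with tied observed
#' times are not compared.
#'
#' @param time observed times `min(t, c)`, strictly positive.
#' @param event event indicators (1 = event, 0 = censored).
#' @param pred predicted log-times (or any monotone survival score).
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(time, event, pred) {
  stopifnot(length(time) == length(event), length(time) == length(pred))
  conc <- 0; n_adm <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    s <- if (time[i] < time[j]) i else j
    l <- if (time[i] < time[j]) j else i
    if (event[s] != 1) next
    n_adm <- n_adm + 1
    if (pred[s] < pred[l]) conc <- conc + 1
    else if (pred[s] == pred[l]) conc <- conc + 0.5
  }
  if (n_adm == 0) stop("no admissible pairs")
  conc / n_adm
}

#' Write posterior summaries, selections and metrics to disk
#'
#' Writes the gene PPI table, probe-selection table, coefficient posterior
#' means, optional prediction table and a machine-readable metrics JSON
#' under `out_dir`, all as tab-separated text. Reruns with the same fitted
#' object produce byte-identical files.
#'
#' @param fit a fitted [netmim] object.
#' @param out_dir output directory (created if needed).
#' @param threshold PPI selection threshold.
#' @param y_true optional observed outcomes matching the stored predictions,
#'   used to add a PMSE to the metrics file.
#' @return `out_dir`, invisibly.
#' @export
write_netmim_results <- function(fit, out_dir, threshold = 0.5,
                                 y_true = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit, threshold = threshold)
  wt <- function(df, name)
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  wt(s$genes, "ppi_genes.tsv")
  wt(s$probes, "ppi_probes.tsv")
  wt(data.frame(coefficient = names(coef(fit)), mean = unname(coef(fit))),
     "coefficients.tsv")
  sel <- select_features(fit, threshold)
  sel_df <- data.frame(
    gene = c(sel$M_only, sel$Mbar_only, sel$both),
    effect = rep(c("M_only", "Mbar_only", "both"),
                 c(length(sel$M_only), length(sel$Mbar_only),
                   length(sel$both))))
  wt(sel_df, "selected_genes.tsv")
  metrics <- list(threshold = threshold,
                  n_selected_M = length(sel$M_only),
                  n_selected_Mbar = length(sel$Mbar_only),
                  n_selected_both = length(sel$both),
                  sigma2 = s$sigma2,
                  seed = fit$seed,
                  package_version = as.character(utils::packageVersion("netmim")))
  if (!is.null(fit$prediction)) {
    wt(data.frame(sample = seq_along(fit$prediction$fit),
                  prediction = fit$prediction$fit), "predictions.tsv")
    if (!is.null(y_true))
      metrics$pmse <- pmse(y_true, fit$prediction$fit)
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
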