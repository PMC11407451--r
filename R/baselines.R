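#' Two-stage penalized baseline mimicking the mechanistic decomposition
#'
#' Frequentist comparator for continuous outcomes. Stage 1 regresses each
#' gene's expression on its own promoter probes with a lasso or elastic-net
#' penalty (5-fold cross-validated), giving `Ehat^M = fitted` and
#' `Ehat^Mbar = E - Ehat^M`; stage 2 penalized-regresses the outcome on the
#' clinical covariates and the two estimated components. Only complete-case
#' subjects are used. Single-probe genes get their stage-1 coefficient from
#' ordinary least squares (a penalty path over one predictor is not
#' meaningful).
#'
#' @param ds a [momics_data] object with a continuous outcome.
#' @param variant `"lasso"` (alpha = 1) or `"enet"` (alpha = 0.5).
#' @param nfolds folds for the penalty cross-validation.
#' @return An object of class `mimic_fit` with per-gene stage-1 coefficient
#'   vectors, the stage-2 `cv.glmnet` fit, and selection scores
#'   (`score_M`, `score_Mbar`, absolute stage-2 coefficients usable for
#'   feature-ranking).
#' @export
mimic_penalized <- function(ds, variant = c("lasso", "enet"), nfolds = 5) {
  variant <- match.arg(variant)
  if (ds$outcome$kind != "continuous")
    stop("penalized baselines are implemented for continuous outcomes")
  alpha <- if (variant == "lasso") 1 else 0.5
  cc <- complete_cases(ds)
  N <- length(cc$sample_ids); K <- ncol(cc$E)

  stage1 <- vector("list", K)
  EM <- matrix(0, N, K)
  for (k in seq_len(K)) {
    jj <- ds$probe_sets[[k]]
    Mk <- cc$M[, jj, drop = FALSE]
    if (length(jj) >= 2 && any(apply(Mk, 2, sd) > 0)) {
      cvf <- glmnet::cv.glmnet(Mk, cc$E[, k], alpha = alpha,
                               nfolds = nfolds)
      co <- as.numeric(coef(cvf, s = "lambda.min"))
    } else if (sd(Mk[, 1]) > 0) {
      fit <- lm(cc$E[, k] ~ Mk[, 1])
      co <- c(coef(fit)[1], coef(fit)[2], rep(0, length(jj) - 1))
    } else {
      co <- c(mean(cc$E[, k]), rep(0, length(jj)))  # zero-variance probes
    }
    stage1[[k]] <- list(probes = jj, intercept = co[1], w = co[-1])
    EM[, k] <- co[1] + Mk %*% co[-1]
  }
  EB <- cc$E - EM
  Cc <- cc$C[, setdiff(colnames(cc$C), "(Intercept)"), drop = FALSE]
  X <- cbind(Cc, EM, EB)
  cvf2 <- glmnet::cv.glmnet(X, cc$outcome$y, alpha = alpha, nfolds = nfolds)
  co2 <- as.numeric(coef(cvf2, s = "lambda.min"))[-1]
  L <- ncol(Cc)
  structure(list(variant = variant, stage1 = stage1, stage2 = cvf2,
                 n_covariates = L,
                 score_M = abs(co2[L + seq_len(K)]),
                 score_Mbar = abs(co2[L + K + seq_len(K)])),
            class = "mimic_fit")
}

#' @export
predict.mimic_fit <- function(object, newdata, ...) {
  nd <- .baseline_newdata(newdata)
  K <- length(object$stage1)
  EM <- matrix(0, nrow(nd$E), K)
  for (k in seq_len(K)) {
    s1 <- object$stage1[[k]]
    EM[, k] <- s1$intercept +
      nd$M[, s1$probes, drop = FALSE] %*% s1$w
  }
  X <- cbind(nd$C, EM, nd$E - EM)
  drop(predict(object$stage2, newx = X, s = "lambda.min"))
}

#' One-stage penalized baseline on concatenated omics
#'
#' Penalized regression of the outcome on the clinical covariates and the
#' raw expression and methylation matrices side by side, with 5-fold
#' cross-validated penalty. Complete cases only.
#'
#' @inheritParams mimic_penalized
#' @return An object of class `vanilla_fit`.
#' @export
vanilla_penalized <- function(ds, variant = c("lasso", "enet"), nfolds = 5) {
  variant <- match.arg(variant)
  if (ds$outcome$kind != "continuous")
    stop("penalized baselines are implemented for continuous outcomes")
  alpha <- if (variant == "lasso") 1 else 0.5
  cc <- complete_cases(ds)
  Cc <- cc$C[, setdiff(colnames(cc$C), "(Intercept)"), drop = FALSE]
  X <- cbind(Cc, cc$E, cc$M)
  cvf <- glmnet::cv.glmnet(X, cc$outcome$y, alpha = alpha, nfolds = nfolds)
  structure(list(variant = variant, fit = cvf, n_covariates = ncol(Cc),
                 n_genes = ncol(cc$E)),
            class = "vanilla_fit")
}

#' @export
predict.vanilla_fit <- function(object, newdata, ...) {
  nd <- .baseline_newdata(newdata)
  drop(predict(object$fit, newx = cbind(nd$C, nd$E, nd$M),
               s = "lambda.min"))
}

.baseline_newdata <- function(newdata) {
  if (inherits(newdata, "momics_data")) {
    list(C = newdata$C[, setdiff(colnames(newdata$C), "(Intercept)"),
                       drop = FALSE],
         E = newdata$E, M = newdata$M)
  } else {
    list(C = as.matrix(newdata$C), E = as.matrix(newdata$E),
         M = as.matrix(newdata$M))
  }
}

#' Cross-validated choice between full-data and complete-case fits
#'
#' Decides by five-fold cross-validation whether subjects missing an omics
#' block should be kept (full-data fit with augmentation) or dropped
#' (complete-case fit). Folds are stratified to preserve the missingness
#' pattern; in each fold both variants are trained on the remaining
#' subjects and scored by PMSE on the held-out subjects with complete data
#' only. The variant with the smaller mean PMSE is refit on all training
#' data (ties keep the full-data fit).
#'
#' @param ds a [momics_data] object with block missingness.
#' @param prior a [netmim_prior()].
#' @param mcmc a [netmim_mcmc()] used for the final fit.
#' @param cv_iter MCMC iterations inside CV folds (default half of
#'   `mcmc$n_iter`, halving burn-in likewise) to keep the scheme tractable.
#' @param folds number of folds.
#' @return A list of class `netmim_cv`: `choice` (`"full"` or
#'   `"complete_case"`), `cv_table` (per-fold PMSE of both arms), and
#'   `fit` (the final refit [netmim] object).
#' @export
netmim_cv <- function(ds, prior = netmim_prior(), mcmc = netmim_mcmc(),
                      cv_iter = NULL, folds = 5) {
  if (is.null(cv_iter)) cv_iter <- max(200L, mcmc$n_iter %/% 2L)
  cv_burn <- cv_iter %/% 2L
  N <- length(ds$sample_ids)
  strata <- interaction(ds$U_E, ds$U_M, drop = TRUE)
  fold <- integer(N)
  seedbase <- if (is.null(mcmc$seed)) 0L else as.integer(mcmc$seed)
  set.seed(seedbase + 7L)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  cmp <- which(ds$U_E == 0 & ds$U_M == 0)

  tab <- data.frame(fold = seq_len(folds), pmse_full = NA_real_,
                    pmse_cc = NA_real_, n_valid = NA_real_)
  for (fd in seq_len(folds)) {
    hold <- which(fold == fd)
    val <- intersect(hold, cmp)
    if (length(val) == 0)
      stop("fold ", fd, " has no complete-data validation subjects; ",
           "stratification: ", paste(table(strata, fold)[, fd], collapse = "/"))
    train <- setdiff(seq_len(N), hold)
    tr_full <- momics_subset(ds, train)
    tr_cc <- complete_cases(tr_full)
    va <- momics_subset(ds, val)
    mc <- mcmc
    mc$n_iter <- as.integer(cv_iter); mc$burnin <- as.integer(cv_burn)
    mc$chains <- 1L; mc$store_omega <- FALSE
    mc$seed <- seedbase + fd
    f_full <- netmim(tr_full, prior, mc, newdata = va)
    f_cc <- netmim(tr_cc, prior, mc, newdata = va)
    yv <- if (ds$outcome$kind == "survival") log(va$outcome$y)
          else va$outcome$y
    tab$pmse_full[fd] <- pmse(yv, f_full$prediction$fit)
    tab$pmse_cc[fd] <- pmse(yv, f_cc$prediction$fit)
    tab$n_valid[fd] <- length(val)
  }
  choice <- if (mean(tab$pmse_full) <= mean(tab$pmse_cc)) "full"
            else "complete_case"
  final_ds <- if (choice == "full") ds else complete_cases(ds)
  fit <- netmim(final_ds, prior, mcmc)
  structure(list(choice = choice, cv_table = tab, fit = fit),
            class = "netmim_cv")
}

#' @exportS3Method base::print
print.netmim_cv <- function(x, ...) {
  cat("Cross-validated missing-data decision:", x$choice, "\n")
  cat(sprintf("  mean PMSE full-data %.4f vs complete-case %.4f\n",
              mean(x$cv_table$pmse_full), mean(x$cv_table$pmse_cc)))
  invisible(x)
}
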