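#' @exportS3Method base::print
print.netmim <- function(x, ...) {
  cat("Two-layer Bayesian integrative model (", x$outcome_kind,
      " outcome)\n", sep = "")
  cat(sprintf("  %d subjects (%d missing E, %d missing M), %d genes, %d probes\n",
              x$dims["N"], x$n_missing["E"], x$n_missing["M"],
              x$dims["K"], x$dims["J"]))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d, thin %d)\n",
              x$mcmc$chains, x$mcmc$n_iter, x$mcmc$burnin, x$mcmc$thin))
  sel <- select_features(x, threshold = 0.5)
  cat(sprintf("  selected at PPI > 0.5: %d type-M only, %d type-Mbar only, %d both\n",
              length(sel$M_only), length(sel$Mbar_only), length(sel$both)))
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' Tabulates posterior inclusion probabilities and posterior-mean
#' coefficients, with selection flags at the given PPI threshold.
#'
#' @param object a fitted [netmim] object.
#' @param threshold PPI selection threshold (strict `>`); the conventional
#'   median-probability-model value 0.5 is the default.
#' @param ... unused.
#' @return A list of class `summary.netmim` with data.frames `genes`
#'   (PPI_M, PPI_Mbar, posterior-mean effects, selection flags) and
#'   `probes` (probe PPIs and posterior-mean probe effects), the clinical
#'   coefficient means, and the noise-variance posterior mean.
#' @exportS3Method base::summary
summary.netmim <- function(object, threshold = 0.5, ...) {
  pm <- object$post_mean
  genes <- data.frame(
    gene = object$genes,
    PPI_M = unname(object$ppi$gamma_M),
    PPI_Mbar = unname(object$ppi$gamma_Mbar),
    beta_M = unname(pm$beta_M),
    beta_Mbar = unname(pm$beta_Mbar),
    selected_M = unname(object$ppi$gamma_M > threshold),
    selected_Mbar = unname(object$ppi$gamma_Mbar > threshold))
  probes <- data.frame(
    probe = object$probes,
    gene = object$probe_map$gene[match(object$probes, object$probe_map$probe)],
    PPI_Z = unname(object$ppi$z),
    selected = unname(object$ppi$z > threshold))
  if (!is.null(pm$omega)) probes$omega <- unname(pm$omega)
  structure(list(genes = genes, probes = probes,
                 beta_C = pm$beta_C, sigma2 = pm$sigma2,
                 threshold = threshold,
                 outcome_kind = object$outcome_kind),
            class = "summary.netmim")
}

#' @exportS3Method base::print
print.summary.netmim <- function(x, n = 10, ...) {
  cat("Clinical coefficients (posterior mean):\n")
  print(round(x$beta_C, 4))
  cat(sprintf("\nResidual variance sigma^2 (posterior mean): %.4f\n", x$sigma2))
  ord <- order(pmax(x$genes$PPI_M, x$genes$PPI_Mbar), decreasing = TRUE)
  cat(sprintf("\nTop genes by PPI (threshold %.2f):\n", x$threshold))
  print(head(x$genes[ord, ], n), row.names = FALSE)
  invisible(x)
}

#' @export
coef.netmim <- function(object, ...) {
  c(object$post_mean$beta_C,
    stats::setNames(object$post_mean$beta_M,
                    paste0(object$genes, ":M")),
    stats::setNames(object$post_mean$beta_Mbar,
                    paste0(object$genes, ":Mbar")))
}

#' Bayesian model averaged prediction
#'
#' For each kept draw `i`, predicts
#' `yhat_i = C beta^C_i + (M Omega_i) beta^M_i + (E - M Omega_i) beta^Mbar_i`
#' and averages over draws. Binary fits also report the probit probability
#' `pnorm(yhat)`; survival predictions are on the log-time scale (larger
#' predicted values mean longer predicted survival).
#'
#' @param object a fitted [netmim] object with stored probe-effect draws
#'   (`store_omega = TRUE`).
#' @param newdata a [momics_data] object or list with `C`, `E`, `M`
#'   (complete rows only).
#' @param type `"response"` (BMA mean; probability for binary fits) or
#'   `"link"` (BMA mean of the linear predictor).
#' @param ... unused.
#' @return Numeric vector of predictions, with the per-iteration prediction
#'   matrix attached as attribute `"draws"`.
#' @export
predict.netmim <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (is.null(object$prediction))
      stop("no stored predictions; supply newdata")
    out <- if (type == "response" && object$outcome_kind == "binary")
      object$prediction$prob else object$prediction$fit
    attr(out, "draws") <- object$prediction$draws
    return(out)
  }
  if (inherits(newdata, "momics_data")) {
    if (any(newdata$U_E == 1) || any(newdata$U_M == 1))
      stop("prediction requires complete omics rows")
    C <- newdata$C; E <- newdata$E; M <- newdata$M
  } else {
    C <- as.matrix(newdata$C); E <- as.matrix(newdata$E)
    M <- as.matrix(newdata$M)
    if (ncol(C) == object$dims["L"] - 1) C <- cbind(1, C)
    if (anyNA(E) || anyNA(M)) stop("prediction requires complete omics rows")
  }
  first <- object$chains[[1]]
  if (is.null(first$omega))
    stop("probe-effect draws were not stored; refit with store_omega = TRUE")
  psets <- split(seq_along(object$probes),
                 factor(match(object$probe_map$gene[
                   match(object$probes, object$probe_map$probe)],
                   object$genes), levels = seq_along(object$genes)))
  draws <- lapply(object$chains, function(ch) {
    n_keep <- nrow(ch$beta_M)
    yh <- matrix(0, n_keep, nrow(E))
    base <- ch$beta_C %*% t(C)
    for (i in seq_len(n_keep)) {
      om <- ch$omega[i, ]
      xM <- matrix(0, nrow(E), length(object$genes))
      act <- which(ch$beta_M[i, ] != 0 | ch$beta_Mbar[i, ] != 0)
      for (k in act) {
        jj <- psets[[k]]
        xM[, k] <- M[, jj, drop = FALSE] %*% om[jj]
      }
      yh[i, ] <- base[i, ] +
        xM[, act, drop = FALSE] %*% ch$beta_M[i, act] +
        (E[, act, drop = FALSE] - xM[, act, drop = FALSE]) %*%
          ch$beta_Mbar[i, act]
    }
    yh
  })
  yh <- do.call(rbind, draws)
  out <- colMeans(yh)
  if (type == "response" && object$outcome_kind == "binary")
    out <- colMeans(pnorm(yh))
  attr(out, "draws") <- yh
  out
}

#' @export
fitted.netmim <- function(object, ...) {
  if (is.null(object$prediction))
    stop("no stored predictions; use predict() with newdata")
  object$prediction$fit
}

#' Trace and PPI plots for a fitted model
#'
#' `type = "trace"` draws traces of the residual variance, the model size
#' (number of active gene effects) and the unnormalized log joint density;
#' `type = "ppi"` draws the gene-level PPIs.
#'
#' @param x a fitted [netmim] object.
#' @param type `"trace"` or `"ppi"`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.netmim <- function(x, type = c("trace", "ppi"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    op <- par(mfrow = c(3, 1), mar = c(3, 4, 1, 1))
    on.exit(par(op))
    for (nm in c("sigma2", "model_size", "log_post")) {
      first <- TRUE
      for (ch in seq_along(x$chains)) {
        v <- x$chains[[ch]][[nm]]
        if (first) {
          plot(v, type = "l", col = ch, ylab = nm, xlab = "", ...)
          first <- FALSE
        } else lines(v, col = ch)
      }
    }
  } else {
    plot(x$ppi$gamma_M, type = "h", col = "steelblue", ylim = c(0, 1),
         ylab = "PPI", xlab = "gene index", ...)
    points(seq_along(x$ppi$gamma_Mbar), x$ppi$gamma_Mbar,
           col = "firebrick", pch = 16, cex = 0.5)
    abline(h = 0.5, lty = 2)
    legend("topright", legend = c("type M", "type Mbar"),
           col = c("steelblue", "firebrick"), lty = c(1, NA),
           pch = c(NA, 16), bty = "n")
  }
  invisible(x)
}

#' @export
residuals.netmim <- function(object, y = NULL, ...) {
  if (is.null(object$prediction))
    stop("residuals need stored predictions; fit with newdata or pass y and use predict()")
  if (is.null(y)) stop("supply the observed outcome vector y")
  y - object$prediction$fit
}
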