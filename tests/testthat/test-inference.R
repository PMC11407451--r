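test_that("PPIs are inclusion proportions over kept draws", {
  sim <- netmim_sim(n = 30, n_genes = 20, n_probes = 25, seed = 71,
                    n_validation = 5)
  fit <- netmim(sim$data, netmim_prior(), quick_mcmc(n_iter = 210,
                                                     burnin = 200,
                                                     seed = 21))
  ch <- fit$chains[[1]]
  expect_equal(unname(fit$ppi$gamma_M), unname(colMeans(ch$gamma_M)))
  expect_equal(unname(fit$ppi$z), unname(colMeans(ch$z)))
  expect_true(all(fit$ppi$gamma >= pmax(fit$ppi$gamma_M,
                                        fit$ppi$gamma_Mbar) - 1e-12))
  # hand-counted: 10 draws, 4 inclusions -> 0.4
  expect_equal(mean(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)), 0.4)
})

test_that("selection thresholds follow the strict-> rule and set logic", {
  s <- list(genes = data.frame(gene = c("a", "b", "c"),
                               PPI_M = c(0.6, 0.4, 0.7),
                               PPI_Mbar = c(0.2, 0.9, 0.8)),
            probes = data.frame(probe = "p1", PPI_Z = 0.5))
  sel <- select_features(s, 0.5)
  expect_identical(sel$M_only, "a")
  expect_identical(sel$Mbar_only, "b")
  expect_identical(sel$both, "c")
  expect_identical(sel$probes, character(0))  # PPI exactly 0.5 excluded
})

test_that("the Bayesian FDR cutoff matches hand enumeration", {
  expect_equal(bayes_fdr_threshold(c(0.99, 0.98, 0.50), 0.05), 0.98)
  # (0.01 + 0.02) / 2 = 0.015 <= 0.05 but adding 0.5 gives 0.177
  expect_equal(bayes_fdr_threshold(rep(1, 5), 0.01), 1)     # FDR 0, all in
  expect_equal(bayes_fdr_threshold(rep(0, 5), 0.1), 1)      # select none
  ppis <- c(0.95, 0.9, 0.8, 0.3)
  t <- bayes_fdr_threshold(ppis, 0.15)
  expect_equal(t, 0.8)
  expect_equal(sum(1 - ppis[ppis >= t]) / 3, 0.35 / 3)
})

test_that("PMSE is the root mean squared prediction error", {
  expect_equal(pmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pmse(c(0, 0), c(1, 1)), 1)
  expect_equal(pmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(pmse(1:3, 1:2))
})

test_that("rank AUC equals the explicit threshold sweep and brute force", {
  expect_equal(selection_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(selection_auc(c(0.1, 0.3, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(72)
  for (i in 1:5) {
    sc <- round(runif(40), 2)     # rounded to force ties
    tr <- rbinom(40, 1, 0.4)
    if (sum(tr) %in% c(0, 40)) next
    # brute force over all pairs
    pos <- sc[tr == 1]; neg <- sc[tr == 0]
    bf <- mean(outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(selection_auc(sc, tr), bf)
    # explicit TPR/FPR sweep (trapezoid over unique thresholds)
    ts <- c(Inf, sort(unique(sc), decreasing = TRUE))
    tpr <- vapply(ts, function(t) mean(sc[tr == 1] >= t), 0)
    fpr <- vapply(ts, function(t) mean(sc[tr == 0] >= t), 0)
    sweep_auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    expect_equal(selection_auc(sc, tr), sweep_auc)
  }
  # null property: permuted scores hover around 0.5
  set.seed(73)
  aucs <- replicate(200, {
    tr2 <- rbinom(30, 1, 0.5)
    if (sum(tr2) %in% c(0, 30)) 0.5 else selection_auc(runif(30), tr2)
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("AUCPR agrees with an independent reference on random inputs", {
  skip_if_not_installed("pROC")
  expect_equal(selection_aucpr(c(0.9, 0.8, 0.3), c(1, 1, 0)), 1)
  set.seed(74)
  sc <- runif(50); tr <- rbinom(50, 1, 0.3)
  # average precision computed naively from the sorted scores
  o <- order(sc, decreasing = TRUE)
  hits <- tr[o]; ap <- 0; rec_prev <- 0
  for (i in seq_along(hits)) {
    rec <- cumsum(hits)[i] / sum(tr)
    prec <- cumsum(hits)[i] / i
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  expect_equal(selection_aucpr(sc, tr), ap, tolerance = 1e-10)
})

test_that("the rank AUC matches pROC on untied data", {
  skip_if_not_installed("pROC")
  set.seed(75)
  sc <- rnorm(60); tr <- rbinom(60, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    tr, sc, direction = "<", quiet = TRUE))))
  expect_equal(selection_auc(sc, tr), ref)
})

test_that("the C-index matches brute force and the survival package", {
  # predictions equal to event times, no censoring -> perfect concordance
  tm <- c(2, 5, 1, 8); ev <- c(1, 1, 1, 1)
  expect_equal(c_index(tm, ev, log(tm)), 1)
  expect_equal(c_index(tm, ev, -log(tm)), 0)
  # 4-record toy with one censored record, enumerated by hand:
  # admissible pairs exclude those whose shorter time is censored
  tm2 <- c(2, 4, 3, 6); ev2 <- c(1, 0, 1, 1); pr <- c(0.5, 2.1, 0.9, 1.7)
  # pairs: (1,2)+ (1,3)+ (1,4)+ (3,2)x? t3<t2,ev3=1 -> pr3<pr2 concordant;
  # (3,4)+ concordant; (2,4): shorter is 4? t2=4<6, ev2=0 -> inadmissible
  expect_equal(c_index(tm2, ev2, pr), 5 / 5)
  pr_bad <- c(2, 0.1, 1.5, 0.2)   # every admissible pair reversed
  expect_equal(c_index(tm2, ev2, pr_bad), 0)
  skip_if_not_installed("survival")
  set.seed(76)
  tm3 <- rexp(40) + 0.1; ev3 <- rbinom(40, 1, 0.7); pr3 <- rnorm(40)
  ref <- survival::concordance(survival::Surv(tm3, ev3) ~ pr3)$concordance
  # survival orients concordance against risk; our pr3 is a longevity score
  expect_equal(c_index(tm3, ev3, pr3), ref)
})

test_that("BMA prediction reduces correctly and beats the intercept", {
  sim <- netmim_sim(n = 80, n_genes = 20, n_probes = 30, seed = 77,
                    n_validation = 40)
  fit <- netmim(sim$data, netmim_prior(),
                quick_mcmc(n_iter = 1000, burnin = 500, seed = 22),
                newdata = sim$validation)
  # averaging per-iteration predictions equals the stored BMA mean
  expect_equal(unname(colMeans(fit$prediction$draws)),
               unname(fit$prediction$fit))
  # post-hoc prediction from stored omega draws agrees with the
  # in-sampler prediction path
  post <- predict(fit, sim$validation)
  expect_equal(as.numeric(post), unname(fit$prediction$fit),
               tolerance = 1e-10)
  yv <- sim$validation$outcome$y
  expect_lt(pmse(yv, fit$prediction$fit), pmse(yv, rep(mean(yv), 40)))
})
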