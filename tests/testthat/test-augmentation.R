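test_that("truncated-normal draws respect their bounds and moments", {
  set.seed(51)
  lo <- netmim:::cpp_rtnorm_lower(100000, 0, 1, 0)
  expect_true(all(lo > 0))
  # half-normal mean sqrt(2/pi) ~ 0.7979
  expect_equal(mean(lo), sqrt(2 / pi), tolerance = 0.01)
  hi <- netmim:::cpp_rtnorm_upper(100000, 0, 1, 0)
  expect_true(all(hi <= 0))
  expect_equal(mean(hi), -sqrt(2 / pi), tolerance = 0.01)
  # inactive truncation: bound far below the mean
  far <- netmim:::cpp_rtnorm_lower(100000, 5, 1, -20)
  expect_equal(mean(far), 5, tolerance = 0.01)
  expect_equal(sd(far), 1, tolerance = 0.02)
  # deep-tail truncation stays finite and accurate:
  # E[Z | Z > a] ~ a + 1/a for large a
  deep <- netmim:::cpp_rtnorm_lower(20000, 0, 1, 38)
  expect_true(all(is.finite(deep)) && all(deep > 38))
  expect_equal(mean(deep), 38 + 1 / 38, tolerance = 0.001)
})

test_that("missing-expression conditional collapses to the mechanistic law when beta_Mbar = 0", {
  mom <- netmim:::cpp_impute_e_moments(0.7, 1.3, 0, 2.5, 1, FALSE)
  expect_equal(unname(mom), c(0.7, 1.3), tolerance = 1e-14)
  set.seed(52)
  dr <- netmim:::cpp_impute_e_draws(100000, 0.7, 1.3, 0, 2.5, 1, FALSE)
  expect_equal(mean(dr), 0.7, tolerance = 0.01)
  expect_equal(var(dr), 1.3, tolerance = 0.02)
  # modular switch forces the same reduction even with nonzero beta_Mbar
  mom_mod <- netmim:::cpp_impute_e_moments(0.7, 1.3, 2, 2.5, 1, TRUE)
  expect_equal(unname(mom_mod), c(0.7, 1.3), tolerance = 1e-14)
})

test_that("clinical coupling gives the precision-weighted two-Gaussian form", {
  # one gene, mechanistic mean m with variance s2k, clinical obs rho with
  # coefficient b and variance s2
  m <- 0.4; s2k <- 2; b <- 1.5; rho <- 3; s2 <- 0.5
  mom <- netmim:::cpp_impute_e_moments(m, s2k, b, rho, s2, FALSE)
  prec <- 1 / s2k + b^2 / s2
  expect_equal(unname(mom["var"]), 1 / prec)
  expect_equal(unname(mom["mean"]), (m / s2k + b * rho / s2) / prec)
})

test_that("missing-methylation conditional combines prior, mechanistic and clinical terms", {
  # inactive probe: the prior N(0, sm^2) exactly
  mom0 <- netmim:::cpp_impute_m_moments(1, 0, 1, 5, 2, 5, 1, FALSE)
  expect_equal(unname(mom0), c(0, 1), tolerance = 1e-14)
  # one-probe-one-gene with omega = 1, unit variances, betas 0:
  # precision 2, mean e/2
  mom1 <- netmim:::cpp_impute_m_moments(1, 1, 1, 0.8, 0, 0, 1, FALSE)
  expect_equal(unname(mom1), c(0.4, 0.5))
  # full coupling
  sm2 <- 1; om <- 0.9; s2k <- 1.2; ep <- 0.8; bk <- -1.1; rho <- 0.3
  s2 <- 0.7
  mom2 <- netmim:::cpp_impute_m_moments(sm2, om, s2k, ep, bk, rho, s2,
                                        FALSE)
  prec <- 1 / sm2 + om^2 / s2k + (om * bk)^2 / s2
  mean_ <- (om * ep / s2k + om * bk * rho / s2) / prec
  expect_equal(unname(mom2), c(mean_, 1 / prec))
})

test_that("augmentation is a no-op for complete data with continuous outcome", {
  ds <- toy_ds(N = 20, psets = list(1:2, 3), seed = 53)
  f1 <- netmim(ds, netmim_prior(), quick_mcmc(seed = 11))
  f2 <- netmim(ds, netmim_prior(),
               quick_mcmc(seed = 11, modular_imputation = TRUE))
  expect_identical(f1$chains[[1]]$beta_M, f2$chains[[1]]$beta_M)
  expect_identical(f1$chains[[1]]$omega, f2$chains[[1]]$omega)
  expect_identical(f1$chains[[1]]$sigma2, f2$chains[[1]]$sigma2)
})

test_that("uncensored survival records pin the latent outcome at log y", {
  # all-events survival on y = exp(v) reproduces, draw for draw, the
  # continuous fit on v: Y* = log y exactly and no truncation draws occur
  set.seed(54)
  v <- rnorm(15)
  ds_surv <- toy_ds(N = 15, psets = list(1:2, 3), seed = 55,
                    outcome = "survival",
                    y = cbind(time = exp(v), event = rep(1, 15)))
  ds_cont <- ds_surv
  ds_cont$outcome <- list(kind = "continuous", y = v, event = NULL)
  f_surv <- netmim(ds_surv, netmim_prior(), quick_mcmc(seed = 12))
  f_cont <- netmim(ds_cont, netmim_prior(), quick_mcmc(seed = 12))
  # identical up to log(exp(v)) rounding in the last ulp
  expect_equal(f_surv$chains[[1]]$beta_C, f_cont$chains[[1]]$beta_C,
               tolerance = 1e-12)
  expect_equal(f_surv$chains[[1]]$sigma2, f_cont$chains[[1]]$sigma2,
               tolerance = 1e-12)
  expect_identical(f_surv$chains[[1]]$gamma_M, f_cont$chains[[1]]$gamma_M)
})

test_that("probit augmentation recovers a strong binary signal", {
  set.seed(56)
  N <- 120
  ds <- toy_ds(N = N, psets = list(1), seed = 56, outcome = "binary")
  # outcome driven by the single gene's residual part
  ds$outcome$y <- as.integer(2 * ds$E[, 1] + rnorm(N) > 0)
  fit <- netmim(ds, netmim_prior(),
                quick_mcmc(n_iter = 1500, burnin = 500, seed = 13))
  expect_gt(max(fit$ppi$gamma_M[1], fit$ppi$gamma_Mbar[1]), 0.9)
})
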