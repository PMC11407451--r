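test_that("the generator reproduces the study's exact counts", {
  sim <- netmim_sim(n = 100, n_genes = 100, n_probes = 300, seed = 81)
  tr <- sim$truth
  expect_equal(sum(tr$gamma_M), 10)
  expect_equal(sum(tr$gamma_Mbar), 10)
  expect_identical(which(tr$gamma_M == 1 & tr$gamma_Mbar == 1), 1:5)
  expect_identical(which(tr$gamma_M == 1 & tr$gamma_Mbar == 0), 6:10)
  expect_identical(which(tr$gamma_M == 0 & tr$gamma_Mbar == 1), 11:15)
  expect_equal(length(tr$regulated), 50)         # 50% regulated at K = 100
  expect_true(all(1:10 %in% tr$regulated))
  # J = 300 probes over K = 100 genes: mean 3 probes per gene, all >= 1
  sizes <- lengths(sim$data$probe_sets)
  expect_equal(mean(sizes), 3)
  expect_true(all(sizes >= 1))
})

test_that("effect sizes respect the stated ranges and conservation holds", {
  sim <- netmim_sim(n = 50, n_genes = 40, n_probes = 80, seed = 82)
  tr <- sim$truth
  act <- tr$omega[tr$z == 1]
  expect_true(all(abs(act) >= 0.5 & abs(act) <= 1))
  expect_true(all(tr$omega[tr$z == 0] == 0))
  bact <- c(tr$beta_M[tr$gamma_M == 1], tr$beta_Mbar[tr$gamma_Mbar == 1])
  expect_true(all(abs(bact) >= 1 & abs(bact) <= 1.5))
  expect_true(all(tr$beta_C == 1))
  # E = E_M + E_Mbar exactly, E_M = M Omega
  de <- decompose_expression(sim$data$E, sim$data$M, tr$omega,
                             sim$data$probe_sets)
  expect_equal(de$E_M, tr$E_M, ignore_attr = TRUE)
  expect_equal(tr$E_M + tr$E_Mbar, unname(sim$data$E))
  # regulated genes genuinely carry at least one active probe
  for (k in tr$regulated) {
    expect_gte(sum(tr$z[sim$data$probe_sets[[k]]]), 1)
  }
  # unregulated genes carry none
  for (k in setdiff(seq_len(40), tr$regulated))
    expect_equal(sum(tr$z[sim$data$probe_sets[[k]]]), 0)
})

test_that("the network has Bern(0.1) effective edges matched among ineffective genes", {
  eff_counts <- numeric(40); ineff_counts <- numeric(40)
  for (i in 1:40) {
    set.seed(i + 830)
    G <- sim_gene_network(1:15, 100, prob = 0.1)
    expect_identical(G, t(G))
    expect_true(all(diag(G) == 0))
    eff_counts[i] <- sum(G[1:15, 1:15]) / 2
    ineff_counts[i] <- sum(G[16:100, 16:100]) / 2
    expect_equal(sum(G) / 2, eff_counts[i] + ineff_counts[i]) # no cross edges
    expect_equal(ineff_counts[i], eff_counts[i])   # equal-count rule
  }
  # E[effective edges] = 0.1 * choose(15, 2) = 10.5; sd ~ 3/sqrt(40)
  expect_equal(mean(eff_counts), 10.5, tolerance = 0.15)
  # zero effective edges -> zero ineffective edges
  found0 <- FALSE
  for (i in 1:200) {
    set.seed(i + 5000)
    G <- sim_gene_network(1:3, 10, prob = 0.05)
    if (sum(G[1:3, 1:3]) == 0) {
      found0 <- TRUE
      expect_equal(sum(G), 0)
      break
    }
  }
  expect_true(found0)
})

test_that("missingness injection follows the scenario definitions exactly", {
  base <- netmim_sim(n = 100, n_genes = 20, n_probes = 30, seed = 84)
  set.seed(84)
  d2 <- inject_missingness(base$data, "II", ratio = 0.3)
  expect_equal(sum(d2$U_E), 30); expect_equal(sum(d2$U_M), 0)
  expect_true(all(is.na(d2$E[d2$U_E == 1, ])))
  d3 <- inject_missingness(base$data, "III", ratio = 0.5)
  expect_equal(sum(d3$U_M), 50); expect_equal(sum(d3$U_E), 0)
  d4 <- inject_missingness(base$data, "IV", split = 0.5)
  expect_equal(sum(d4$U_E), 25)
  expect_equal(sum(d4$U_M), 25)
  expect_equal(sum(d4$U_E == 0 & d4$U_M == 0), 50)
  expect_true(all(d4$U_E * d4$U_M == 0))
  # validation sets are always complete
  sim <- netmim_sim(n = 60, n_genes = 20, n_probes = 30, scenario = "IV",
                    missing_ratio = 0.5, seed = 85)
  expect_equal(sum(sim$validation$U_E) + sum(sim$validation$U_M), 0)
})

test_that("the same seed reproduces the dataset and truth exactly", {
  s1 <- netmim_sim(n = 30, n_genes = 20, n_probes = 30, seed = 86,
                   scenario = "III", missing_ratio = 0.2)
  s2 <- netmim_sim(n = 30, n_genes = 20, n_probes = 30, seed = 86,
                   scenario = "III", missing_ratio = 0.2)
  expect_identical(s1$data$E, s2$data$E)
  expect_identical(s1$data$M, s2$data$M)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$validation$outcome$y, s2$validation$outcome$y)
})

test_that("methylation probes have unit scale and within-gene correlation rho", {
  sim <- netmim_sim(n = 4000, n_genes = 20, n_probes = 44, rho = 0.5,
                    seed = 87, n_validation = 5)
  M <- sim$data$M
  expect_equal(mean(apply(M, 2, var)), 1, tolerance = 0.05)
  expect_equal(mean(colMeans(M)), 0, tolerance = 0.05)
  # average within-gene pairwise correlation close to rho
  cors <- c()
  for (k in seq_len(20)) {
    jj <- sim$data$probe_sets[[k]]
    if (length(jj) >= 2) {
      cm <- cor(M[, jj])
      cors <- c(cors, cm[upper.tri(cm)])
    }
  }
  expect_equal(mean(cors), 0.5, tolerance = 0.05)
  # rho = 0 recovers independence
  sim0 <- netmim_sim(n = 4000, n_genes = 20, n_probes = 44, rho = 0,
                     seed = 88, n_validation = 5)
  cors0 <- c()
  for (k in seq_len(20)) {
    jj <- sim0$data$probe_sets[[k]]
    if (length(jj) >= 2) {
      cm <- cor(sim0$data$M[, jj])
      cors0 <- c(cors0, cm[upper.tri(cm)])
    }
  }
  expect_lt(abs(mean(cors0)), 0.05)
})
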