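test_that("row absence in an omics file defines block missingness", {
  ds <- toy_ds(N = 4, seed = 11)
  # drop s3 from the methylation file only
  dir <- tempfile()
  write_momics(ds, dir)
  meth <- read.delim(file.path(dir, "methylation.tsv"))
  write.table(meth[meth$sample_id != "s3", ],
              file.path(dir, "methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rd <- read_momics(file.path(dir, "clinical.tsv"),
                    file.path(dir, "expression.tsv"),
                    file.path(dir, "methylation.tsv"),
                    file.path(dir, "probe_map.tsv"),
                    file.path(dir, "network.tsv"))
  expect_identical(rd$U_M, c(0L, 0L, 1L, 0L))
  expect_identical(rd$U_E, c(0L, 0L, 0L, 0L))
  expect_true(all(is.na(rd$M[3, ])))
})

test_that("a sample absent from both omics matrices is rejected", {
  ds <- toy_ds(N = 4, seed = 12)
  dir <- tempfile()
  write_momics(ds, dir)
  for (f in c("expression.tsv", "methylation.tsv")) {
    m <- read.delim(file.path(dir, f))
    write.table(m[m$sample_id != "s2", ], file.path(dir, f), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  expect_error(
    read_momics(file.path(dir, "clinical.tsv"),
                file.path(dir, "expression.tsv"),
                file.path(dir, "methylation.tsv"),
                file.path(dir, "probe_map.tsv"),
                file.path(dir, "network.tsv")),
    "at least one type of omics data")
})

test_that("an edge list builds a symmetric adjacency", {
  ds <- toy_ds(N = 5, psets = list(1, 2, 3), seed = 13,
               edges = data.frame(gene_a = "g1", gene_b = "g2"))
  expect_identical(ds$network["g1", "g2"], 1L)
  expect_identical(ds$network["g2", "g1"], 1L)
  expect_equal(sum(ds$network), 2L)
  expect_error(toy_ds(N = 5, psets = list(1, 2), seed = 13,
                      edges = data.frame(gene_a = "g1", gene_b = "gX")),
               "not in expression columns")
})

test_that("probe-map violations are rejected at construction", {
  set.seed(2)
  E <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("g1", "g2")))
  M <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("cg", 1:3)))
  C <- matrix(rnorm(4), 4, 1)
  net <- data.frame(a = character(), b = character())
  good <- data.frame(probe = paste0("cg", 1:3), gene = c("g1", "g1", "g2"))
  expect_s3_class(momics_data(E, M, C, rnorm(4), "continuous", good, net),
                  "momics_data")
  no_map <- good[-2, ]
  expect_error(momics_data(E, M, C, rnorm(4), "continuous", no_map, net),
               "without a gene mapping")
  empty_gene <- data.frame(probe = paste0("cg", 1:3), gene = "g1")
  expect_error(momics_data(E, M, C, rnorm(4), "continuous", empty_gene, net),
               "no mapped probe")
})

test_that("validate_momics reports violations without mutating", {
  ds <- toy_ds(N = 6, seed = 14, outcome = "survival")
  expect_identical(nrow(validate_momics(ds)), 0L)
  bad <- ds
  bad$outcome$y[2] <- 0
  bad$network[1, 2] <- 1L   # asymmetric by hand
  v <- validate_momics(bad)
  expect_true(any(grepl("non-positive survival time", v$violation)))
  expect_true(any(grepl("not symmetric", v$violation)))
  expect_identical(bad$outcome$y[2], 0)  # unchanged
})

test_that("write/read round trip preserves matrices and missingness", {
  ds <- toy_ds(N = 6, psets = list(1:2, 3:4), seed = 15)
  ds <- inject_missingness(ds, "III", ratio = 1 / 3)
  f <- toy_files(ds)
  rd <- read_momics(f$clinical, f$expression, f$methylation, f$probe_map,
                    f$network)
  expect_identical(rd$U_M, ds$U_M)
  expect_identical(rd$U_E, ds$U_E)
  obs <- ds$U_M == 0
  expect_equal(rd$M[obs, ], ds$M[obs, ], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rd$E, ds$E, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rd$network, ds$network)
})

test_that("permuting file row order does not change the aligned dataset", {
  ds <- toy_ds(N = 6, seed = 16)
  f <- toy_files(ds)
  em <- read.delim(f$expression)
  write.table(em[sample(nrow(em)), ], f$expression, sep = "\t",
              quote = FALSE, row.names = FALSE)
  rd <- read_momics(f$clinical, f$expression, f$methylation, f$probe_map,
                    f$network)
  expect_identical(rd$sample_ids, ds$sample_ids)
  expect_equal(rd$E, ds$E, ignore_attr = TRUE)
})

test_that("results writer emits stable, deterministic tables", {
  sim <- netmim_sim(n = 40, n_genes = 20, n_probes = 30, seed = 17,
                    n_validation = 10)
  fit <- netmim(sim$data, netmim_prior(), quick_mcmc(seed = 5),
                newdata = sim$validation)
  d1 <- tempfile(); d2 <- tempfile()
  write_netmim_results(fit, d1, y_true = sim$validation$outcome$y)
  write_netmim_results(fit, d2, y_true = sim$validation$outcome$y)
  ppi_tab <- read.delim(file.path(d1, "ppi_genes.tsv"))
  expect_identical(nrow(ppi_tab), 20L)
  expect_identical(names(ppi_tab)[1:3], c("gene", "PPI_M", "PPI_Mbar"))
  for (fl in list.files(d1))
    expect_identical(readLines(file.path(d1, fl)),
                     readLines(file.path(d2, fl)))
  met <- jsonlite::read_json(file.path(d1, "metrics.json"))
  expect_true(is.numeric(met$pmse))
})
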