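#' Assemble a multi-omics dataset
#'
#' Bundles expression, methylation, clinical covariates, an outcome, a
#' probe-to-gene map and a gene network into a validated container used by
#' [netmim()]. Subjects missing a whole omics block are flagged through
#' `U_E` / `U_M`; the corresponding matrix rows hold `NA`. A subject must be
#' observed in at least one omics block.
#'
#' @param E numeric matrix, samples x genes (column names are gene ids).
#'   Rows for subjects without expression data are all-`NA`.
#' @param M numeric matrix, samples x probes (column names are probe ids),
#'   methylation on the M-value scale. Rows for subjects without methylation
#'   are all-`NA`.
#' @param C numeric matrix of clinical covariates (samples x L). An
#'   all-ones intercept column is prepended unless one is already present.
#' @param outcome for a continuous outcome, a numeric vector; for binary, a
#'   0/1 vector; for survival, a two-column matrix or data.frame
#'   `(time, event)` with strictly positive times.
#' @param outcome_kind one of `"continuous"`, `"binary"`, `"survival"`.
#' @param probe_map data.frame with columns `probe`, `gene`; a many-to-one
#'   map covering every probe in `M`, every gene receiving at least one
#'   probe.
#' @param network either a two-column data.frame / matrix edge list of gene
#'   ids, or a K x K binary symmetric adjacency matrix with zero diagonal.
#' @param sample_ids character vector of subject identifiers.
#'
#' @return An object of class `momics_data`.
#' @seealso [read_momics()], [validate_momics()], [netmim()]
#' @export
momics_data <- function(E, M, C, outcome,
                        outcome_kind = c("continuous", "binary", "survival"),
                        probe_map, network, sample_ids = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  E <- as.matrix(E); M <- as.matrix(M); C <- as.matrix(C)
  N <- nrow(E)
  if (nrow(M) != N || nrow(C) != N)
    stop("E, M and C must have the same number of rows")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(E)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(N))
  }
  if (is.null(colnames(E))) colnames(E) <- paste0("g", seq_len(ncol(E)))
  if (is.null(colnames(M))) colnames(M) <- paste0("p", seq_len(ncol(M)))

  if (!("(Intercept)" %in% colnames(C)) &&
      !(ncol(C) > 0 && all(C[, 1] == 1))) {
    C <- cbind("(Intercept)" = 1, C)
  }
  cn <- colnames(C)
  if (is.null(cn)) cn <- rep("", ncol(C))
  cn[1] <- "(Intercept)"
  blank <- which(cn == "")
  cn[blank] <- paste0("x", blank - 1)
  colnames(C) <- cn

  U_E <- as.integer(apply(E, 1, function(r) all(is.na(r))))
  U_M <- as.integer(apply(M, 1, function(r) all(is.na(r))))
  if (any(U_E * U_M == 1))
    stop("subject(s) ", paste(sample_ids[U_E * U_M == 1], collapse = ", "),
         " absent from both omics blocks; each subject must have at least ",
         "one type of omics data (U^E * U^M != 1)")

  probe_map <- as.data.frame(probe_map)
  names(probe_map)[1:2] <- c("probe", "gene")
  probe_map$probe <- as.character(probe_map$probe)
  probe_map$gene <- as.character(probe_map$gene)
  miss <- setdiff(colnames(M), probe_map$probe)
  if (length(miss))
    stop("probe(s) without a gene mapping: ", paste(head(miss), collapse = ", "))
  if (anyDuplicated(probe_map$probe))
    stop("probe map is not many-to-one: duplicated probe entries")
  extra_genes <- setdiff(probe_map$gene, colnames(E))
  if (length(extra_genes))
    stop("probe map gene(s) not in expression columns: ",
         paste(head(extra_genes), collapse = ", "))
  empty <- setdiff(colnames(E), probe_map$gene)
  if (length(empty))
    stop("gene(s) with no mapped probe: ", paste(head(empty), collapse = ", "))

  G <- .as_adjacency(network, colnames(E))

  ds <- structure(list(
    sample_ids = as.character(sample_ids),
    outcome = .as_outcome(outcome, outcome_kind),
    C = C, E = E, M = M,
    U_E = U_E, U_M = U_M,
    probe_map = probe_map,
    probe_sets = .probe_sets(probe_map, colnames(E), colnames(M)),
    network = G), class = "momics_data")
  viol <- validate_momics(ds)
  if (nrow(viol)) stop("invalid dataset: ", paste(viol$violation, collapse = "; "))
  ds
}

.as_outcome <- function(outcome, kind) {
  if (kind == "survival") {
    outcome <- as.matrix(as.data.frame(outcome))
    if (ncol(outcome) != 2) stop("survival outcome needs (time, event)")
    list(kind = kind, y = as.numeric(outcome[, 1]),
         event = as.integer(outcome[, 2]))
  } else {
    list(kind = kind, y = as.numeric(outcome), event = NULL)
  }
}

.as_adjacency <- function(network, genes) {
  K <- length(genes)
  if (is.matrix(network) && nrow(network) == ncol(network) &&
      nrow(network) == K && !is.character(network[1, 1])) {
    G <- (as.matrix(network) != 0) * 1L
    dimnames(G) <- list(genes, genes)
    return(G)
  }
  edges <- as.matrix(as.data.frame(network))
  G <- matrix(0L, K, K, dimnames = list(genes, genes))
  if (nrow(edges)) {
    a <- as.character(edges[, 1]); bn <- as.character(edges[, 2])
    unknown <- setdiff(c(a, bn), genes)
    if (length(unknown))
      stop("network gene(s) not in expression columns: ",
           paste(head(unknown), collapse = ", "))
    for (i in seq_along(a)) {
      if (a[i] == bn[i]) next
      G[a[i], bn[i]] <- 1L
      G[bn[i], a[i]] <- 1L
    }
  }
  G
}

.probe_sets <- function(probe_map, genes, probes) {
  idx <- match(probe_map$gene, genes)
  pidx <- match(probe_map$probe, probes)
  sets <- split(pidx, factor(idx, levels = seq_along(genes)))
  lapply(sets, function(v) sort(as.integer(v)))
}

#' Read a multi-omics dataset from delimited text files
#'
#' All matrix files are tab-separated with a header row of feature ids and a
#' first column of sample ids. The clinical table defines the master sample
#' list and ordering; omics matrices may omit samples entirely, which is how
#' block missingness is encoded on disk.
#'
#' @param clinical path to the clinical TSV. Must contain `sample_id`,
#'   covariate columns, and the outcome columns: `y` (continuous), `label`
#'   (binary) or `time` + `event` (survival).
#' @param expression,methylation paths to samples x features TSV matrices.
#' @param probe_map path to a two-column TSV (`probe`, `gene`).
#' @param network path to a two-column TSV edge list (`gene_a`, `gene_b`).
#' @param outcome_kind one of `"continuous"`, `"binary"`, `"survival"`.
#' @return A [momics_data] object.
#' @export
read_momics <- function(clinical, expression, methylation, probe_map,
                        network,
                        outcome_kind = c("continuous", "binary", "survival")) {
  outcome_kind <- match.arg(outcome_kind)
  for (p in c(clinical, expression, methylation, probe_map, network))
    if (!file.exists(p)) stop("file not found: ", p)
  clin <- read.delim(clinical, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(clin)) stop("clinical table needs 'sample_id'")
  ids <- as.character(clin$sample_id)

  oc_cols <- switch(outcome_kind, continuous = "y", binary = "label",
                    survival = c("time", "event"))
  if (!all(oc_cols %in% names(clin)))
    stop("clinical table lacks outcome column(s): ",
         paste(setdiff(oc_cols, names(clin)), collapse = ", "))
  outcome <- if (outcome_kind == "survival") clin[, c("time", "event")]
             else clin[[oc_cols]]
  Cmat <- as.matrix(clin[, setdiff(names(clin), c("sample_id", oc_cols)),
                         drop = FALSE])

  read_mat <- function(path) {
    x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- as.character(x[[1]])
    storage.mode(m) <- "double"
    m
  }
  Em <- read_mat(expression)
  Mm <- read_mat(methylation)
  unknown <- setdiff(c(rownames(Em), rownames(Mm)), ids)
  if (length(unknown))
    stop("omics sample(s) not in clinical table: ",
         paste(head(unknown), collapse = ", "))

  expand <- function(m, ids) {
    out <- matrix(NA_real_, length(ids), ncol(m),
                  dimnames = list(ids, colnames(m)))
    out[intersect(ids, rownames(m)), ] <- m[intersect(ids, rownames(m)), ]
    out
  }
  pm <- read.delim(probe_map, stringsAsFactors = FALSE)
  net <- read.delim(network, stringsAsFactors = FALSE)

  momics_data(E = expand(Em, ids), M = expand(Mm, ids), C = Cmat,
              outcome = outcome, outcome_kind = outcome_kind,
              probe_map = pm, network = net, sample_ids = ids)
}

#' Write a multi-omics dataset as delimited text files
#'
#' Inverse of [read_momics()]: writes `clinical.tsv`, `expression.tsv`,
#' `methylation.tsv`, `probe_map.tsv` and `network.tsv` under `dir`.
#' Subjects missing an omics block are simply absent from that matrix file.
#'
#' @param ds a [momics_data] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_momics <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  oc <- switch(ds$outcome$kind,
               continuous = data.frame(y = ds$outcome$y),
               binary = data.frame(label = ds$outcome$y),
               survival = data.frame(time = ds$outcome$y,
                                     event = ds$outcome$event))
  covs <- ds$C[, setdiff(colnames(ds$C), "(Intercept)"), drop = FALSE]
  clin <- cbind(data.frame(sample_id = ds$sample_ids), covs, oc)
  write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  wm <- function(m, keep, path) {
    df <- data.frame(sample_id = ds$sample_ids[keep],
                     m[keep, , drop = FALSE], check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(ds$E, ds$U_E == 0, file.path(dir, "expression.tsv"))
  wm(ds$M, ds$U_M == 0, file.path(dir, "methylation.tsv"))
  write.table(ds$probe_map, file.path(dir, "probe_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ut <- which(upper.tri(ds$network) & ds$network == 1, arr.ind = TRUE)
  el <- data.frame(gene_a = rownames(ds$network)[ut[, 1]],
                   gene_b = colnames(ds$network)[ut[, 2]])
  write.table(el, file.path(dir, "network.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Diagnostic validation of a multi-omics dataset
#'
#' Checks every structural invariant of the container (missingness pattern,
#' probe-map partition, network symmetry, outcome coding) and reports the
#' violations without mutating or stopping.
#'
#' @param ds a [momics_data] object (possibly hand-built).
#' @return A data.frame with one row per violated invariant (zero rows for a
#'   valid dataset), with columns `check` and `violation`.
#' @export
validate_momics <- function(ds) {
  bad <- list()
  add <- function(check, msg) bad[[length(bad) + 1]] <<- c(check, msg)

  if (any(ds$U_E * ds$U_M == 1))
    add("missingness", "subject missing both omics blocks")
  obsE <- which(ds$U_E == 0); obsM <- which(ds$U_M == 0)
  if (length(obsE) && anyNA(ds$E[obsE, ]))
    add("missingness", "scattered NA cells inside an observed expression row")
  if (length(obsM) && anyNA(ds$M[obsM, ]))
    add("missingness", "scattered NA cells inside an observed methylation row")
  if (anyNA(ds$C)) add("clinical", "NA in clinical covariates")

  sets <- ds$probe_sets
  allp <- sort(unlist(sets, use.names = FALSE))
  if (!identical(allp, seq_len(ncol(ds$M))))
    add("probe_map", "probe sets do not partition the probes")
  if (any(lengths(sets) == 0))
    add("probe_map", "gene with no mapped probe")

  G <- ds$network
  if (!isTRUE(all.equal(G, t(G), check.attributes = FALSE)))
    add("network", "network not symmetric")
  if (any(diag(G) != 0)) add("network", "nonzero network diagonal")
  if (!all(G %in% c(0, 1))) add("network", "adjacency entries not in {0,1}")
  if (nrow(G) != ncol(ds$E)) add("network", "network dimension != gene count")

  y <- ds$outcome$y
  if (ds$outcome$kind == "binary" && !all(y %in% c(0, 1)))
    add("outcome", "binary values not 0/1")
  if (ds$outcome$kind == "survival") {
    if (any(y <= 0)) add("outcome", "non-positive survival time")
    if (!all(ds$outcome$event %in% c(0, 1)))
      add("outcome", "event indicator not 0/1")
  }
  if (anyNA(y)) add("outcome", "NA outcome")

  if (length(bad) == 0)
    return(data.frame(check = character(), violation = character()))
  data.frame(check = vapply(bad, `[`, "", 1),
             violation = vapply(bad, `[`, "", 2))
}

#' @exportS3Method base::print
print.momics_data <- function(x, ...) {
  cat("Multi-omics dataset:", length(x$sample_ids), "subjects,",
      ncol(x$E), "genes,", ncol(x$M), "probes,",
      ncol(x$C) - 1, "clinical covariates\n")
  cat("Outcome:", x$outcome$kind, "\n")
  cat("Missing expression rows:", sum(x$U_E),
      " missing methylation rows:", sum(x$U_M), "\n")
  cat("Network edges:", sum(x$network) / 2, "\n")
  invisible(x)
}

# row subset keeping all structure; used by complete-case fits and CV folds
momics_subset <- function(ds, idx) {
  out <- ds
  out$sample_ids <- ds$sample_ids[idx]
  out$C <- ds$C[idx, , drop = FALSE]
  out$E <- ds$E[idx, , drop = FALSE]
  out$M <- ds$M[idx, , drop = FALSE]
  out$U_E <- ds$U_E[idx]
  out$U_M <- ds$U_M[idx]
  out$outcome$y <- ds$outcome$y[idx]
  if (!is.null(ds$outcome$event)) out$outcome$event <- ds$outcome$event[idx]
  out
}

#' Restrict a dataset to complete cases
#'
#' Drops every subject missing an omics block, giving the complete-case
#' dataset used by the `_CC` variants of the model.
#'
#' @param ds a [momics_data] object.
#' @return A [momics_data] object containing only subjects with both blocks.
#' @export
complete_cases <- function(ds) {
  momics_subset(ds, which(ds$U_E == 0 & ds$U_M == 0))
}
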