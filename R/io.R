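# Readers and writers for the plain-text formats the tool exchanges:
# expression matrices (TSV), directed edge lists (TSV / SIF), adjacency
# matrices (CSV), fitted models (CSV + JSON sidecar) and stability reports
# (JSON + long CSV).

#' Write / read an expression matrix as TSV
#'
#' Genes in rows, time points in columns, a leading `gene` column with the
#' identifiers and the time labels as header. Values are written with 15
#' significant digits so a round trip is exact to at least 12.
#'
#' @param data Expression matrix.
#' @param path File path.
#' @return `read_expression` returns a numeric matrix with gene and time
#'   labels.
#' @export
write_expression <- function(data, path) {
  if (!is.matrix(data)) stop("`data` must be a matrix", call. = FALSE)
  if (is.null(rownames(data))) rownames(data) <- default_gene_labels(nrow(data))
  if (is.null(colnames(data)))
    colnames(data) <- paste0("t", seq_len(ncol(data)) - 1L)
  df <- data.frame(gene = rownames(data),
                   apply(data, 2L, formatC, digits = 15, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write / read a directed network as an edge list
#'
#' `format = "tsv"` writes a two-column table (`regulator`, `target`) with
#' a header; `format = "sif"` writes the three-column SIF dialect
#' `regulator<TAB>regulates<TAB>target` without a header.
#'
#' @param net Binary connectivity matrix.
#' @param path File path.
#' @param format `"tsv"` or `"sif"`.
#' @param gene_labels For reading: the full gene universe, so that genes
#'   without edges keep their row/column. Defaults to the sorted labels
#'   seen in the file.
#' @return `read_edge_list` returns a binary connectivity matrix.
#' @export
write_edge_list <- function(net, path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  net <- check_connectivity(net)
  idx <- which(net == 1L, arr.ind = TRUE)
  reg <- rownames(net)[idx[, 1L]]
  tgt <- colnames(net)[idx[, 2L]]
  if (format == "tsv") {
    write.table(data.frame(regulator = reg, target = tgt), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(data.frame(reg, "regulates", tgt), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, gene_labels = NULL,
                           format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE)
    reg <- as.character(df[[1L]]); tgt <- as.character(df[[2L]])
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    reg <- as.character(df[[1L]]); tgt <- as.character(df[[3L]])
  }
  if (is.null(gene_labels)) gene_labels <- sort(unique(c(reg, tgt)))
  if (!all(c(reg, tgt) %in% gene_labels))
    stop("edge list contains genes outside `gene_labels`", call. = FALSE)
  net <- matrix(0L, length(gene_labels), length(gene_labels),
                dimnames = list(gene_labels, gene_labels))
  net[cbind(match(reg, gene_labels), match(tgt, gene_labels))] <- 1L
  net
}

#' Write / read a binary adjacency matrix as CSV
#'
#' Header row and first column carry the gene labels (regulators in rows,
#' targets in columns).
#'
#' @param net Binary connectivity matrix.
#' @param path File path.
#' @export
write_adjacency <- function(net, path) {
  net <- check_connectivity(net)
  write.csv(net, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
  storage.mode(m) <- "integer"
  check_connectivity(m)
}

#' Write a fitted MVAR model
#'
#' The coefficient matrix goes to `beta.csv` (regulator rows, target
#' columns) and the metadata (penalty, per-target lambda, alpha, degrees of
#' freedom, residual variance) to `model.json`.
#'
#' @param model An `mvar_model`.
#' @param dir Output directory (created if needed).
#' @return `read_mvar_model` returns the `mvar_model`.
#' @export
write_mvar_model <- function(model, dir) {
  stopifnot(inherits(model, "mvar_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(model$beta_hat, file.path(dir, "beta.csv"), quote = FALSE)
  meta <- model[c("penalty", "lambda", "alpha", "dof", "resid_sigma2",
                  "n_obs", "rank_deficient")]
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_mvar_model
#' @export
read_mvar_model <- function(dir) {
  beta <- as.matrix(read.csv(file.path(dir, "beta.csv"), row.names = 1L,
                             check.names = FALSE))
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  lab <- colnames(beta)
  new_mvar_model(beta, penalty = meta$penalty,
                 lambda = setNames(meta$lambda, lab),
                 alpha = setNames(meta$alpha, lab),
                 dof = setNames(as.integer(meta$dof), lab),
                 resid_sigma2 = setNames(meta$resid_sigma2, lab),
                 n_obs = meta$n_obs,
                 rank_deficient = isTRUE(meta$rank_deficient))
}

#' Edge table of a fitted model
#'
#' One row per detected edge (`|beta| > epsilon`) with the coefficient
#' and, when a significance result is supplied, the p-value and the FDR
#' decision.
#'
#' @param model An `mvar_model`.
#' @param significance Optional [coefficient_pvalues()] result.
#' @param epsilon Detection cutoff.
#' @return A data frame with columns `regulator`, `target`, `beta`, `p`,
#'   `significant`.
#' @export
edge_table <- function(model, significance = NULL, epsilon = 1e-4) {
  net <- detect_edges(model, epsilon)
  idx <- which(net == 1L, arr.ind = TRUE)
  beta <- if (inherits(model, "mvar_model")) model$beta_hat else model
  data.frame(regulator = rownames(net)[idx[, 1L]],
             target = colnames(net)[idx[, 2L]],
             beta = beta[idx],
             p = if (is.null(significance)) NA_real_ else
               significance$pvalues[idx],
             significant = if (is.null(significance)) NA else
               significance$significant[idx] == 1L,
             stringsAsFactors = FALSE)
}

#' Write a stability report
#'
#' The overall and pairwise stabilities go to JSON; the per-edge stability
#' goes to a long-format CSV (`regulator`, `target`, `stability`) covering
#' every edge ever observed.
#'
#' @param report A `stability_report`.
#' @param json_path Optional JSON output path.
#' @param edges_csv_path Optional CSV output path.
#' @export
write_stability_report <- function(report, json_path = NULL,
                                   edges_csv_path = NULL) {
  stopifnot(inherits(report, "stability_report"))
  if (!is.null(json_path))
    jsonlite::write_json(list(overall = report$overall,
                              n_networks = report$n_networks,
                              pairwise = report$pairwise),
                         json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(edges_csv_path)) {
    es <- report$edge_stability
    idx <- which(es > 0, arr.ind = TRUE)
    df <- data.frame(regulator = rownames(es)[idx[, 1L]],
                     target = colnames(es)[idx[, 2L]],
                     stability = es[idx])
    write.csv(df, edges_csv_path, quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
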