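#' Construct an expression dataset
#'
#' Wraps a samples x genes expression matrix (log-scale values) with ids and
#' the ingestion transform used by all fits: every gene column is
#' mean-centered and, by default, unit-scaled. The model has no intercept, so
#' centering stands in for it; coefficients from downstream fits are reported
#' on the original expression scale.
#'
#' @param values numeric matrix, samples as rows, genes as columns.
#' @param gene_ids,sample_ids character vectors; default to dimnames.
#' @param scale logical; unit-scale columns (default `TRUE`).
#' @return An `expression_dataset`: `values` (original), `x` (transformed),
#'   `centers`, `scales`, `gene_ids`, `sample_ids`.
#' @export
expression_dataset <- function(values, gene_ids = colnames(values),
                               sample_ids = rownames(values), scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(gene_ids) != ncol(values) || length(sample_ids) != nrow(values))
    stop("id lengths do not match the expression matrix")
  if (nrow(values) < 2) stop("need at least 2 samples")
  if (!all(is.finite(values)))
    stop("expression matrix contains missing or non-finite values")
  centers <- colMeans(values)
  x <- sweep(values, 2, centers)
  if (scale) {
    scales <- apply(x, 2, stats::sd)
    if (any(scales == 0)) {
      zero <- gene_ids[scales == 0]
      stop("constant expression column(s): ", paste(zero, collapse = ", "))
    }
    x <- sweep(x, 2, scales, "/")
  } else {
    scales <- rep(1, ncol(values))
  }
  dimnames(x) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, x = x, centers = centers, scales = scales,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("Expression dataset:", length(x$sample_ids), "samples x",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

# Response and regulator matrix (transformed scale) for one target gene;
# the target's own column is excluded (no self-edge).
target_design <- function(data, target_gene) {
  j <- match(target_gene, data$gene_ids)
  if (is.na(j)) stop("unknown target gene: ", target_gene)
  list(y = data$x[, j], R = data$x[, -j, drop = FALSE],
       regulators = data$gene_ids[-j], target_index = j)
}

#' Construct a modulator profile
#'
#' @param m numeric vector of modulator values (one per sample), named by
#'   sample id or aligned with `sample_ids`.
#' @param sample_ids character vector of sample ids.
#' @return A `modulator_profile`: `m` (named numeric), `sample_ids`.
#' @export
modulator_profile <- function(m, sample_ids = names(m)) {
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(m))
  if (length(m) != length(sample_ids))
    stop("modulator length does not match sample ids")
  if (!all(is.finite(m))) stop("modulator values must be finite")
  structure(list(m = setNames(as.numeric(m), sample_ids),
                 sample_ids = sample_ids),
            class = "modulator_profile")
}

#' Read an expression matrix from delimited text
#'
#' Expects a header row and a first column of ids. With `genes_as = "cols"`
#' (default), rows are samples and columns are genes; `"rows"` reads the
#' transposed layout.
#'
#' @param path file path (TSV by default).
#' @param genes_as `"cols"` or `"rows"`.
#' @param sep field separator.
#' @param scale passed to [expression_dataset()].
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, genes_as = c("cols", "rows"), sep = "\t",
                            scale = TRUE) {
  genes_as <- match.arg(genes_as)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(suppressWarnings(array(as.numeric(mat), dim(mat)))) |
                 is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing cell at row ", ids[bad[1, 1]],
         ", column ", colnames(mat)[bad[1, 2]], " of ", path)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (genes_as == "rows") mat <- t(mat)
  expression_dataset(mat, scale = scale)
}

#' Write an expression dataset as delimited text
#'
#' @param data an [expression_dataset()] (original-scale values are written).
#' @param path output file.
#' @param sep field separator.
#' @export
write_expression <- function(data, path, sep = "\t") {
  df <- data.frame(sample_id = data$sample_ids, data$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column modulator file (sample id, value)
#'
#' @param path file path.
#' @param sep field separator.
#' @return A [modulator_profile()].
#' @export
read_modulator <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("modulator file needs two columns (id, value)")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(v)) stop("non-numeric modulator value at row ", which(is.na(v))[1])
  modulator_profile(v, as.character(df[[1]]))
}

#' Construct an edge table
#'
#' @param regulator,target character vectors (equal length).
#' @param weight numeric edge weights.
#' @return An `edge_table` data frame with columns regulator, target, weight.
#' @export
edge_table <- function(regulator = character(), target = character(),
                       weight = numeric()) {
  df <- data.frame(regulator = as.character(regulator),
                   target = as.character(target),
                   weight = as.numeric(weight),
                   stringsAsFactors = FALSE)
  if (any(df$regulator == df$target)) stop("self-edges are not allowed")
  if (anyDuplicated(df[, c("regulator", "target")]))
    stop("duplicate (regulator, target) pairs")
  if (!all(is.finite(df$weight))) stop("edge weights must be finite")
  class(df) <- c("edge_table", "data.frame")
  df
}

# Deterministic row order: target, then |weight| descending, then regulator.
sort_edges <- function(t) {
  t[order(t$target, -abs(t$weight), t$regulator), , drop = FALSE]
}

#' Write an edge list as TSV
#'
#' Columns `regulator`, `target`, `weight` (weights at 6 significant digits),
#' rows ordered by target, then absolute weight descending, then regulator,
#' so repeated writes are byte-identical.
#'
#' @param t an [edge_table()].
#' @param path output file.
#' @export
write_edge_list <- function(t, path) {
  t <- sort_edges(t)
  t$weight <- signif(t$weight, 6)
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#'
#' @param path file path.
#' @return An [edge_table()].
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  edge_table(df$regulator, df$target, df$weight)
}

#' Export an edge table as GraphML
#'
#' Directed regulator -> target edges with a `weight` attribute, for use in
#' external network viewers. Requires the `igraph` package.
#'
#' @param t an [edge_table()].
#' @param path output file.
#' @export
write_graphml <- function(t, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the igraph package")
  t <- sort_edges(t)
  g <- igraph::graph_from_data_frame(
    data.frame(from = t$regulator, to = t$target, weight = t$weight),
    directed = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
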