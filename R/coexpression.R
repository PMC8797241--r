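#' Filter lowly expressed and invariant genes
#'
#' Applied to raw counts before correlation: a gene is removed iff (a) it
#' has fewer than 10 reads in more than 90% of samples, or (b) fewer than 10
#' reads in more than 80% of samples and fewer than 50 reads in all samples,
#' or (c) its counts have standard deviation 0. The fraction comparisons are
#' strict.
#'
#' @param data A [count_dataset()] or a counts matrix.
#' @return Character vector of retained gene identifiers.
#' @export
filter_genes <- function(data) {
  counts <- if (inherits(data, "count_dataset")) data$counts else data
  frac_low <- rowMeans(counts < 10)
  max_count <- apply(counts, 1, max)
  sd0 <- apply(counts, 1, stats::sd) == 0
  drop <- (frac_low > 0.9) | (frac_low > 0.8 & max_count < 50) | sd0
  rownames(counts)[!drop]
}

#' Gene-gene correlation matrix
#'
#' Standard product-moment correlation between genes (rows); Spearman is
#' computed as Pearson on mid-ranks (ties receive the average rank).
#' Constant genes must have been removed beforehand.
#'
#' @param mat An `expr_matrix` or plain genes x samples matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(tolower(method), c("pearson", "spearman"))
  values <- if (inherits(mat, "expr_matrix")) mat$values else mat
  if (ncol(values) < 3) stop("need at least 3 samples")
  sds <- apply(values, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant gene '%s' must be filtered before correlation",
                 rownames(values)[which(sds == 0)[1]]))
  cm <- stats::cor(t(values), method = method)
  diag(cm) <- 1
  cm
}

#' Extract top-K neighbor sets from a correlation matrix
#'
#' For every gene X, the K genes with the highest correlation to X (set_X),
#' excluding X itself. Ties are broken by descending correlation then
#' ascending gene identifier, for bit-reproducibility.
#'
#' @param cor_mat Square symmetric correlation matrix with gene dimnames.
#' @param k Neighbors per gene (default 100); must be `< nrow(cor_mat)`.
#' @param method Correlation measure used (recorded in the network).
#' @param workflow Optional named list or character describing the
#'   processing workflow that produced the correlations.
#' @return An object of class `coexpression_network`: list with `gene_ids`,
#'   `neighbors` (k x n integer matrix of indices into `gene_ids`, one
#'   column per gene), `correlations` (matching correlation values), `k`,
#'   `correlation_method` and `workflow`.
#' @export
top_k_neighbors <- function(cor_mat, k = 100, method = "pearson",
                            workflow = NULL) {
  stopifnot(is.matrix(cor_mat), nrow(cor_mat) == ncol(cor_mat))
  n <- nrow(cor_mat)
  if (k >= n) stop("k must be smaller than the number of genes")
  gene_ids <- rownames(cor_mat)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(n))
  neighbors <- matrix(0L, k, n)
  corvals <- matrix(NA_real_, k, n)
  id_rank <- rank(gene_ids)  # integer tie-break key: ascending gene id
  for (x in seq_len(n)) {
    v <- cor_mat[, x]
    v[x] <- -Inf
    ord <- order(-v, id_rank)[seq_len(k)]
    neighbors[, x] <- ord
    corvals[, x] <- v[ord]
  }
  structure(list(gene_ids = gene_ids, neighbors = neighbors,
                 correlations = corvals, k = as.integer(k),
                 correlation_method = method, workflow = workflow),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network: %d genes, k = %d, %s correlation\n",
              length(x$gene_ids), x$k, x$correlation_method))
  invisible(x)
}

#' Run one processing workflow on one dataset
#'
#' Convenience pipeline: low-expression gene filter on raw counts,
#' normalization, pseudocount log transform (skipped for the simplified
#' regularized log, which is already log scale), batch correction per
#' confounding block, removal of genes that became constant, correlation
#' and top-K neighbor extraction.
#'
#' @param data A [count_dataset()].
#' @param normalization,correction,correlation Workflow components (see
#'   [normalize_counts()], [correct_batch()], [correlation_matrix()]).
#' @param k Neighbors per gene.
#' @return A `coexpression_network`.
#' @export
build_network <- function(data, normalization, correction = "none",
                          correlation = "pearson", k = 100) {
  keep <- filter_genes(data)
  sub <- count_dataset(data$counts[keep, , drop = FALSE], data$samples)
  expr <- normalize_counts(sub, normalization)
  if (!expr$log_scale) expr <- log_transform(expr)
  expr <- correct_batch(expr, sub$samples, correction)
  sds <- apply(expr$values, 1, stats::sd)
  values <- expr$values[sds > 0, , drop = FALSE]
  cm <- correlation_matrix(values, correlation)
  top_k_neighbors(cm, k = min(k, nrow(cm) - 1), method = correlation,
                  workflow = list(normalization = normalization,
                                  correction = correction,
                                  correlation = correlation))
}

#' Write / read a co-expression network as TSV
#'
#' Columns: `gene_id`, `rank` (1..K), `neighbor_id`, `correlation`. The
#' round trip is lossless for the neighbor structure.
#'
#' @param net A `coexpression_network`.
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network` a
#'   `coexpression_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "coexpression_network"))
  n <- length(net$gene_ids)
  df <- data.frame(
    gene_id = rep(net$gene_ids, each = net$k),
    rank = rep(seq_len(net$k), n),
    neighbor_id = net$gene_ids[as.vector(net$neighbors)],
    correlation = as.vector(net$correlations))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, method = "pearson", workflow = NULL) {
  df <- utils::read.delim(path, colClasses = c("character", "integer",
                                               "character", "numeric"))
  gene_ids <- unique(df$gene_id)
  k <- max(df$rank)
  idx <- match(df$neighbor_id, gene_ids)
  ord <- order(match(df$gene_id, gene_ids), df$rank)
  structure(list(gene_ids = gene_ids,
                 neighbors = matrix(idx[ord], k, length(gene_ids)),
                 correlations = matrix(df$correlation[ord], k,
                                       length(gene_ids)),
                 k = as.integer(k), correlation_method = method,
                 workflow = workflow),
            class = "coexpression_network")
}
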