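#' Expression matrix with processing provenance
#'
#' Internal constructor for the real-valued genes x samples matrix produced
#' by normalization and downstream steps. `provenance` records the ordered
#' processing steps applied; `log_scale` marks matrices already on a
#' log-like scale (the simplified regularized log), which the pseudocount
#' log transform must not re-log.
#'
#' @param values Numeric matrix, genes x samples, with dimnames.
#' @param provenance Character vector of processing steps.
#' @param log_scale Logical: values already on log scale.
#' @param pseudocount Pseudocount used by [log_transform()], or `NULL`.
#' @return An object of class `expr_matrix`.
#' @keywords internal
expr_matrix <- function(values, provenance, log_scale = FALSE,
                        pseudocount = NULL) {
  stopifnot(is.matrix(values), length(provenance) >= 1)
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(list(values = values, provenance = provenance,
                 log_scale = log_scale, pseudocount = pseudocount),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples\n  provenance: %s\n",
              nrow(x$values), ncol(x$values),
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# linear-interpolation quantile of the non-zero values of one sample
nonzero_quantile <- function(x, p, sample_id) {
  nz <- x[x > 0]
  if (length(nz) == 0)
    stop(sprintf("sample '%s' has no non-zero counts", sample_id))
  stats::quantile(nz, p, type = 7, names = FALSE)
}

#' Between-sample normalization of read counts
#'
#' Implements the six between-sample normalization procedures compared by
#' the workflow grid:
#' \describe{
#'   \item{CPM}{counts per million: each column scaled by `1e6 / total`.}
#'   \item{UQ}{column divided by the 75th percentile of its non-zero
#'     counts.}
#'   \item{Med}{column divided by the median of its non-zero counts.}
#'   \item{Quantile}{every column's sorted values replaced by the
#'     across-sample mean of sorted values; tied ranks receive the mean of
#'     the values they span.}
#'   \item{TMM}{trimmed mean of M-values: genes with < 1 CPM in all samples
#'     are removed, then a per-sample scaling factor is computed from
#'     trimmed, precision-weighted log ratios against a reference sample and
#'     applied to CPM-scaled counts (standard TMM defaults: 30% M-trim, 5%
#'     A-trim, inverse asymptotic binomial variance weights).}
#'   \item{Rlog}{simplified regularized log: median-of-ratios size factors,
#'     `v = log2(count/s + 0.5)`, then per-gene shrinkage of `v` toward the
#'     gene's mean with weight `m/(m + 10)` where `m` is the gene's mean
#'     normalized count, so that low-count genes are pulled toward their
#'     across-sample average. Output is already log scale.}
#' }
#'
#' Quantile percentiles use linear interpolation between order statistics
#' (type 7). All methods leave identical columns identical.
#'
#' @param data A [count_dataset()].
#' @param method One of `"TMM"`, `"CPM"`, `"UQ"`, `"Med"`, `"Rlog"`,
#'   `"Quantile"` (case-insensitive).
#' @return An `expr_matrix`. TMM output contains only the genes passing the
#'   1-CPM filter.
#' @export
normalize_counts <- function(data, method) {
  stopifnot(inherits(data, "count_dataset"))
  methods <- c("TMM", "CPM", "UQ", "Med", "Rlog", "Quantile")
  m <- methods[match(tolower(method), tolower(methods))]
  if (is.na(m)) stop(sprintf("unknown normalization method '%s'", method))
  counts <- data$counts
  values <- switch(m,
    CPM = {
      tot <- colSums(counts)
      if (any(tot == 0))
        stop(sprintf("sample '%s' has zero total count",
                     colnames(counts)[which(tot == 0)[1]]))
      sweep(counts, 2, 1e6 / tot, `*`)
    },
    UQ = {
      div <- vapply(seq_len(ncol(counts)), function(j)
        nonzero_quantile(counts[, j], 0.75, colnames(counts)[j]), numeric(1))
      sweep(counts, 2, div, `/`)
    },
    Med = {
      div <- vapply(seq_len(ncol(counts)), function(j)
        nonzero_quantile(counts[, j], 0.5, colnames(counts)[j]), numeric(1))
      sweep(counts, 2, div, `/`)
    },
    Quantile = quantile_normalize(counts),
    TMM = tmm_normalize(counts),
    Rlog = rlog_simple(counts))
  expr_matrix(values, provenance = sprintf("normalize:%s", m),
              log_scale = (m == "Rlog"))
}

# every column gets the across-column mean of sorted values at its ranks;
# fractional (tied) ranks interpolate between adjacent means
quantile_normalize <- function(counts) {
  sorted <- apply(counts, 2, sort)
  means <- rowMeans(sorted)
  out <- apply(counts, 2, function(x) {
    r <- rank(x, ties.method = "average")
    (means[floor(r)] + means[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(counts)
  out
}

# TMM scaling factors with the published defaults; returns CPM on effective
# library sizes, restricted to genes with >= 1 CPM in at least one sample
tmm_normalize <- function(counts) {
  cpm0 <- sweep(counts, 2, 1e6 / colSums(counts), `*`)
  keep <- rowSums(cpm0 >= 1) > 0
  if (!any(keep)) stop("no genes pass the 1-CPM filter")
  y <- counts[keep, , drop = FALSE]
  lib <- colSums(y)
  f <- tmm_factors(y, lib)
  sweep(y, 2, 1e6 / (lib * f), `*`)
}

tmm_factors <- function(y, lib, logratio_trim = 0.3, sum_trim = 0.05) {
  f75 <- apply(sweep(y, 2, lib, `/`), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(y[, j], y[, ref], lib[j], lib[ref],
                    logratio_trim, sum_trim)
  }, numeric(1))
  # center factors so they multiply to 1
  f / exp(mean(log(f)))
}

tmm_pair_factor <- function(obs, ref, nO, nR, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  logR <- log2((obs / nO) / (ref / nR))
  absE <- (log2(obs / nO) + log2(ref / nR)) / 2
  v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0 || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  fct <- sum(logR[keep2] / v[keep2], na.rm = TRUE) /
    sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(fct)) return(1)
  2^fct
}

# simplified regularized log; size factors by median of ratios
rlog_simple <- function(counts, shrink_const = 10) {
  logg <- rowMeans(log(counts))
  sf <- vapply(seq_len(ncol(counts)), function(j) {
    r <- log(counts[, j]) - logg
    r <- r[is.finite(r)]
    if (length(r) == 0)
      stop(sprintf("sample '%s' shares no always-expressed genes",
                   colnames(counts)[j]))
    exp(stats::median(r))
  }, numeric(1))
  norm <- sweep(counts, 2, sf, `/`)
  v <- log2(norm + 0.5)
  mu <- rowMeans(v)
  w <- rowMeans(norm) / (rowMeans(norm) + shrink_const)
  out <- mu + w * (v - mu)
  dimnames(out) <- dimnames(counts)
  out
}

#' Pseudocount log transform
#'
#' Adds a small pseudocount, defined as the 1st percentile of the pooled
#' non-zero values of the whole normalized matrix, and takes log2. Matrices
#' already on log scale (simplified regularized log output) are rejected.
#'
#' @param mat An `expr_matrix` produced by [normalize_counts()].
#' @return An `expr_matrix` on log2 scale with the pseudocount recorded.
#' @export
log_transform <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$log_scale)
    stop("matrix is already on log scale")
  nz <- mat$values[mat$values > 0]
  if (length(nz) == 0) stop("all-zero matrix cannot be log transformed")
  p <- stats::quantile(nz, 0.01, type = 7, names = FALSE)
  expr_matrix(log2(mat$values + p),
              provenance = c(mat$provenance, sprintf("log2(+%.6g)", p)),
              log_scale = TRUE, pseudocount = p)
}

#' Write / read an expression matrix with provenance header
#'
#' The TSV carries the provenance as leading comment lines prefixed `#`.
#'
#' @param mat An `expr_matrix`.
#' @param path File path.
#' @return `write_expr_matrix` returns `path` invisibly; `read_expr_matrix`
#'   an `expr_matrix`.
#' @export
write_expr_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", mat$provenance), con)
  writeLines(sprintf("# log_scale: %s", mat$log_scale), con)
  if (!is.null(mat$pseudocount))
    writeLines(sprintf("# pseudocount: %.17g", mat$pseudocount), con)
  df <- data.frame(gene_id = rownames(mat$values), mat$values,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  prov <- sub("^# provenance: ", "", hdr[startsWith(hdr, "# provenance:")])
  log_scale <- any(grepl("^# log_scale: TRUE", hdr))
  pc_line <- hdr[startsWith(hdr, "# pseudocount:")]
  pc <- if (length(pc_line)) as.numeric(sub("^# pseudocount: ", "", pc_line))
        else NULL
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  expr_matrix(values, provenance = prov, log_scale = log_scale,
              pseudocount = pc)
}
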