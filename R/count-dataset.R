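#' Assemble a count dataset
#'
#' Bundles a genes x samples matrix of non-negative integer read counts with
#' its sample metadata. This is the raw input of every processing workflow:
#' one dataset corresponds to one cell type or tissue, whose samples may come
#' from several studies (batches).
#'
#' @param counts Numeric matrix of non-negative integers, genes in rows and
#'   samples in columns. Row names are gene identifiers, column names sample
#'   identifiers; both must be unique.
#' @param samples Data frame with columns `sample_id`, `batch_id` and
#'   `biology_id`, one row per column of `counts` (matched by `sample_id`).
#' @return An object of class `count_dataset`: a list with elements `counts`
#'   and `samples` (reordered to match the count columns).
#' @export
count_dataset <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers")
  if (!all(is.finite(counts)))
    stop("counts must be finite")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  req <- c("sample_id", "batch_id", "biology_id")
  if (!all(req %in% names(samples)))
    stop("samples must have columns sample_id, batch_id, biology_id")
  samples <- as.data.frame(samples)
  if (!setequal(samples$sample_id, colnames(counts)) ||
      nrow(samples) != ncol(counts))
    stop("samples$sample_id must match the count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_dataset")
}

#' @export
print.count_dataset <- function(x, ...) {
  cat(sprintf(
    "count_dataset: %d genes x %d samples, %d batch(es), %d biology label(s)\n",
    nrow(x$counts), ncol(x$counts),
    length(unique(x$samples$batch_id)),
    length(unique(x$samples$biology_id))))
  invisible(x)
}

#' @export
dim.count_dataset <- function(x) dim(x$counts)

#' Write / read a count dataset as TSV
#'
#' The counts file has gene identifiers in the first column (`gene_id`) and
#' one column per sample; the metadata file has columns `sample_id`,
#' `batch_id`, `biology_id`.
#'
#' @param data A [count_dataset()].
#' @param counts_path,meta_path File paths for the count matrix and the
#'   sample metadata.
#' @return `write_count_dataset` returns the paths invisibly;
#'   `read_count_dataset` returns a `count_dataset`.
#' @export
write_count_dataset <- function(data, counts_path, meta_path) {
  stopifnot(inherits(data, "count_dataset"))
  df <- data.frame(gene_id = rownames(data$counts), data$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(counts_path, meta_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  samples <- utils::read.delim(meta_path, colClasses = "character")
  count_dataset(counts, samples)
}

#' Write / read gene sets in GMT format
#'
#' GMT is the tab-separated gene-set format: one set per line with the set
#' name, a description, then the member gene identifiers.
#'
#' @param sets Named list of character vectors (term -> member genes).
#' @param path File path.
#' @param description Description field written for every set.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` a named list.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)] else character(0))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
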