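#' Names of the eight quality-measure columns
#' @return Character vector in canonical order.
#' @export
quality_measure_columns <- function() {
  c("enrichment_mf", "enrichment_bp", "enrichment_cc", "enrichment_tfbs",
    "accuracy_mf", "accuracy_bp", "accuracy_cc", "accuracy_tfbs")
}

#' Combine the eight quality measures into the scalar Quality score
#'
#' Across a collection of networks, the eight measures are standardized to
#' mean 0 and sd 1, a PCA is computed by eigen-decomposition of their 8x8
#' correlation matrix, and the projection on the first principal component
#' is min-max rescaled to `[0, 1]`: Quality 0 is the worst network of the
#' collection and 1 the best. The PC1 sign is oriented so that it correlates
#' positively with the mean of the eight measures ("higher = better").
#' Quality is therefore collection-relative.
#'
#' @param measures Data frame containing the columns of
#'   [quality_measure_columns()]; any other columns are carried through as
#'   metadata.
#' @return An object of class `quality_score_table`: list with `table` (the
#'   input plus `pc1` and `quality` columns), `loadings` (named PC1
#'   loadings), `var_fraction` (variance fractions of all 8 PCs), `center`,
#'   `scale`, and `pc1_range` (used by [project_quality()]).
#' @export
combine_quality <- function(measures) {
  measures <- as.data.frame(measures)
  cols <- quality_measure_columns()
  missing_cols <- setdiff(cols, names(measures))
  if (length(missing_cols))
    stop("missing measure columns: ", paste(missing_cols, collapse = ", "))
  M <- as.matrix(measures[, cols])
  if (nrow(M) < 3) stop("need at least 3 networks to combine quality")
  if (anyNA(M)) stop("missing values in quality measures")
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop(sprintf("measure '%s' is constant across networks",
                 cols[which(sds == 0)[1]]))
  ctr <- colMeans(M)
  Z <- scale(M, center = ctr, scale = sds)
  C <- stats::cor(M)
  eig <- eigen(C, symmetric = TRUE)
  v1 <- eig$vectors[, 1]
  scores <- as.vector(Z %*% v1)
  if (stats::cor(scores, rowMeans(Z)) < 0) {
    v1 <- -v1
    scores <- -scores
  }
  rng <- range(scores)
  quality <- (scores - rng[1]) / (rng[2] - rng[1])
  out <- measures
  out$pc1 <- scores
  out$quality <- quality
  structure(list(table = out,
                 loadings = stats::setNames(v1, cols),
                 var_fraction = eig$values / sum(eig$values),
                 center = stats::setNames(ctr, cols),
                 scale = stats::setNames(sds, cols),
                 pc1_range = rng),
            class = "quality_score_table")
}

#' @export
print.quality_score_table <- function(x, ...) {
  cat(sprintf(
    "quality_score_table: %d networks; PC1 explains %.1f%% of variance\n",
    nrow(x$table), 100 * x$var_fraction[1]))
  invisible(x)
}

#' Project new networks onto a stored Quality model
#'
#' Quality is defined relative to the collection it was computed on. For a
#' network outside that collection, its measures are standardized with the
#' stored center/scale, projected on the stored PC1 loadings, rescaled with
#' the stored PC1 range and clamped to `[0, 1]`. The clamp is a pragmatic
#' extension: networks beyond the original collection's range cannot be
#' distinguished further on this scale.
#'
#' @param measures Data frame with the eight measure columns.
#' @param score_table A `quality_score_table` from [combine_quality()].
#' @return Numeric vector of Quality values in `[0, 1]`.
#' @export
project_quality <- function(measures, score_table) {
  stopifnot(inherits(score_table, "quality_score_table"))
  cols <- quality_measure_columns()
  M <- as.matrix(as.data.frame(measures)[, cols])
  Z <- scale(M, center = score_table$center[cols],
             scale = score_table$scale[cols])
  scores <- as.vector(Z %*% score_table$loadings[cols])
  rng <- score_table$pc1_range
  pmin(pmax((scores - rng[1]) / (rng[2] - rng[1]), 0), 1)
}

#' Write / read the Quality model sidecar
#'
#' Stores loadings, variance fractions, centering and PC1 range as JSON so
#' a Quality model can be reused to score new networks.
#'
#' @param score_table A `quality_score_table`.
#' @param path JSON file path.
#' @return `write_quality_model` returns `path` invisibly;
#'   `read_quality_model` a reduced `quality_score_table` (no `table`)
#'   usable with [project_quality()].
#' @export
write_quality_model <- function(score_table, path) {
  stopifnot(inherits(score_table, "quality_score_table"))
  jsonlite::write_json(
    list(loadings = as.list(score_table$loadings),
         var_fraction = score_table$var_fraction,
         center = as.list(score_table$center),
         scale = as.list(score_table$scale),
         pc1_range = score_table$pc1_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_quality_model
#' @export
read_quality_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = NULL,
                 loadings = unlist(x$loadings),
                 var_fraction = x$var_fraction,
                 center = unlist(x$center),
                 scale = unlist(x$scale),
                 pc1_range = x$pc1_range),
            class = "quality_score_table")
}
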