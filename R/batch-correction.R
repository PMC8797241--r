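#' Partition samples into confounding blocks
#'
#' Batch correction can only retain biological covariates when batch and
#' biology are not completely confounded. Samples are partitioned into the
#' connected components of the bipartite graph whose nodes are batch ids and
#' biology ids, with an edge whenever a batch contains a sample of that
#' biology. Correction is applied within each component separately and the
#' corrected pieces are merged back. Components containing a single batch
#' carry no estimable batch effect and are flagged uncorrectable (passed
#' through unchanged by the correctors).
#'
#' @param samples Data frame with columns `sample_id`, `batch_id`,
#'   `biology_id`.
#' @return A list of blocks; each block is a list with elements `batches`,
#'   `biologies`, `sample_ids` and `correctable` (logical).
#' @export
partition_confounding_blocks <- function(samples) {
  stopifnot(all(c("sample_id", "batch_id", "biology_id") %in% names(samples)))
  batches <- unique(samples$batch_id)
  bios <- unique(samples$biology_id)
  # union-find over batch and biology nodes
  nodes <- c(paste0("batch:", batches), paste0("bio:", bios))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_len(nrow(samples))) {
    i <- find(paste0("batch:", samples$batch_id[k]))
    j <- find(paste0("bio:", samples$biology_id[k]))
    if (i != j) parent[i] <- j
  }
  root_of_batch <- vapply(paste0("batch:", batches), find, numeric(1))
  comp_ids <- unique(root_of_batch)
  lapply(comp_ids, function(r) {
    bb <- batches[root_of_batch == r]
    sel <- samples$batch_id %in% bb
    list(batches = bb,
         biologies = unique(samples$biology_id[sel]),
         sample_ids = samples$sample_id[sel],
         correctable = length(bb) > 1)
  })
}

# design pieces used by both correctors (within one block)
batch_biology_factors <- function(samples, sample_ids) {
  sel <- match(sample_ids, samples$sample_id)
  list(batch = factor(samples$batch_id[sel]),
       biology = factor(samples$biology_id[sel]))
}

#' Remove batch effects by linear regression
#'
#' Per gene, ordinary least squares of log expression on biology indicator
#' columns plus batch indicator columns under a sum-to-zero constraint; the
#' fitted batch component is subtracted, so the grand level and the
#' biology-attributable variation are preserved. Applied separately within
#' each confounding block; single-batch blocks are passed through, and a
#' block in which batch is completely aliased with biology is skipped with a
#' warning.
#'
#' @param mat An `expr_matrix` on log scale.
#' @param samples Sample metadata data frame (`sample_id`, `batch_id`,
#'   `biology_id`).
#' @return An `expr_matrix` with the batch component removed.
#' @export
remove_batch_linear <- function(mat, samples) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (!mat$log_scale) stop("batch correction expects log-scale expression")
  out <- mat$values
  for (blk in partition_confounding_blocks(samples)) {
    if (!blk$correctable) next
    idx <- match(blk$sample_ids, colnames(out))
    fac <- batch_biology_factors(samples, blk$sample_ids)
    Xbio <- if (nlevels(fac$biology) > 1)
      stats::model.matrix(~fac$biology)
    else matrix(1, length(fac$biology), 1)
    cb <- stats::contr.sum(nlevels(fac$batch))
    Xb <- cb[as.integer(fac$batch), , drop = FALSE]
    X <- cbind(Xbio, Xb)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      warning(sprintf(
        "batch aliased with biology in block {%s}; correction skipped",
        paste(blk$batches, collapse = ",")))
      next
    }
    beta <- qr.coef(qrX, t(out[, idx, drop = FALSE]))
    bcols <- ncol(Xbio) + seq_len(ncol(Xb))
    out[, idx] <- out[, idx, drop = FALSE] -
      t(Xb %*% beta[bcols, , drop = FALSE])
  }
  expr_matrix(out, provenance = c(mat$provenance, "correct:linear"),
              log_scale = TRUE, pseudocount = mat$pseudocount)
}

#' Empirical-Bayes location-scale batch correction
#'
#' Parametric empirical-Bayes adjustment of per-batch per-gene location
#' (gamma) and scale (delta^2) on log expression, in the style of the
#' standard location-scale batch adjustment: (1) per gene, OLS fit of grand
#' mean plus biology effects together with batch means, and standardization
#' of the data to mean 0, variance 1 per gene; (2) per batch per gene,
#' location and scale estimates; (3) shrinkage of the location estimates
#' toward a moment-matched normal prior and of the scale estimates toward a
#' moment-matched inverse-gamma prior, by the standard fixed-point
#' iteration, until the maximum absolute change falls below `tol`
#' (cap `max_iter` iterations); (4) back-transformation. Applied per
#' confounding block, single-batch blocks passed through.
#'
#' The per-block EB model (raw and shrunken estimates plus hyperparameters)
#' is attached as attribute `"eb_models"` of the returned object.
#'
#' @param mat An `expr_matrix` on log scale.
#' @param samples Sample metadata data frame.
#' @param tol,max_iter Fixed-point convergence tolerance and iteration cap.
#' @return An `expr_matrix` with batch locations and scales adjusted.
#' @export
combat_adjust <- function(mat, samples, tol = 1e-6, max_iter = 500) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (!mat$log_scale) stop("batch correction expects log-scale expression")
  out <- mat$values
  models <- list()
  for (blk in partition_confounding_blocks(samples)) {
    if (!blk$correctable) next
    idx <- match(blk$sample_ids, colnames(out))
    fac <- batch_biology_factors(samples, blk$sample_ids)
    fit <- combat_block(out[, idx, drop = FALSE], fac$batch, fac$biology,
                        tol, max_iter)
    out[, idx] <- fit$adjusted
    models[[paste(blk$batches, collapse = ",")]] <- fit$model
  }
  res <- expr_matrix(out, provenance = c(mat$provenance, "correct:combat"),
                     log_scale = TRUE, pseudocount = mat$pseudocount)
  attr(res, "eb_models") <- models
  res
}

combat_block <- function(dat, batch, biology, tol, max_iter) {
  n_batch <- nlevels(batch)
  n_array <- ncol(dat)
  sizes <- as.vector(table(batch))
  if (any(sizes < 2))
    stop(sprintf("batch '%s' has fewer than 2 samples",
                 levels(batch)[which(sizes < 2)[1]]))
  batchmod <- stats::model.matrix(~ 0 + batch)
  mod <- if (nlevels(droplevels(biology)) > 1)
    stats::model.matrix(~biology)[, -1, drop = FALSE]
  else NULL
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design))
    stop("biology aliased with batch inside a confounding block")

  B_hat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand_mean <- crossprod(sizes / n_array, B_hat[seq_len(n_batch), , drop = FALSE])
  var_pooled <- rowMeans((dat - t(design %*% B_hat))^2)
  if (any(var_pooled == 0)) stop("constant gene encountered; filter first")
  stand_mean <- matrix(grand_mean, nrow(dat), n_array)
  if (!is.null(mod))
    stand_mean <- stand_mean +
      t(design[, -seq_len(n_batch), drop = FALSE] %*%
          B_hat[-seq_len(n_batch), , drop = FALSE])
  sdv <- sqrt(var_pooled)
  s_data <- (dat - stand_mean) / sdv

  gamma_hat <- t(solve(crossprod(batchmod), crossprod(batchmod, t(s_data))))
  delta2_hat <- sapply(levels(batch), function(b)
    apply(s_data[, batch == b, drop = FALSE], 1, stats::var))
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta2_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta2_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (b in seq_len(n_batch)) {
    sel <- batch == levels(batch)[b]
    n_b <- sizes[b]
    sd_b <- s_data[, sel, drop = FALSE]
    g_old <- gamma_hat[, b]
    d_old <- delta2_hat[, b]
    it <- 0
    repeat {
      it <- it + 1
      g_new <- (t2[b] * n_b * gamma_hat[, b] + d_old * gamma_bar[b]) /
        (t2[b] * n_b + d_old)
      sum2 <- rowSums((sd_b - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[b]) / (n_b / 2 + a_prior[b] - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
      if (it >= max_iter)
        stop(sprintf(
          "EB fixed point did not converge for batch '%s' (%d iterations, last change %.3g)",
          levels(batch)[b], it, change))
    }
    gamma_star[, b] <- g_old
    delta2_star[, b] <- d_old
  }

  adjusted <- s_data
  for (b in seq_len(n_batch)) {
    sel <- batch == levels(batch)[b]
    adjusted[, sel] <- (s_data[, sel, drop = FALSE] - gamma_star[, b]) /
      sqrt(delta2_star[, b])
  }
  adjusted <- adjusted * sdv + stand_mean
  model <- list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                gamma_star = gamma_star, delta2_star = delta2_star,
                hyperparams = list(gamma_bar = gamma_bar, t2 = t2,
                                   a_prior = a_prior, b_prior = b_prior),
                batches = levels(batch))
  list(adjusted = adjusted, model = model)
}

#' Apply a batch correction method by name
#'
#' Dispatch helper used by the workflow grid: `"none"` returns the input
#' unchanged (with provenance noted), `"linear"` calls
#' [remove_batch_linear()], `"combat"` calls [combat_adjust()].
#'
#' @param mat An `expr_matrix` on log scale.
#' @param samples Sample metadata data frame.
#' @param method One of `"none"`, `"linear"`, `"combat"`.
#' @return An `expr_matrix`.
#' @export
correct_batch <- function(mat, samples, method = c("none", "linear", "combat")) {
  method <- match.arg(method)
  switch(method,
         none = expr_matrix(mat$values,
                            provenance = c(mat$provenance, "correct:none"),
                            log_scale = mat$log_scale,
                            pseudocount = mat$pseudocount),
         linear = remove_batch_linear(mat, samples),
         combat = combat_adjust(mat, samples))
}

#' Report confounding blocks as a table
#'
#' @param samples Sample metadata data frame.
#' @return Data frame with one row per block: block id, batches, biologies,
#'   sample count and whether the block is correctable.
#' @export
block_report <- function(samples) {
  blocks <- partition_confounding_blocks(samples)
  data.frame(
    block = seq_along(blocks),
    batches = vapply(blocks, function(b) paste(b$batches, collapse = ","),
                     character(1)),
    biologies = vapply(blocks, function(b) paste(b$biologies, collapse = ","),
                       character(1)),
    n_samples = vapply(blocks, function(b) length(b$sample_ids), integer(1)),
    correctable = vapply(blocks, `[[`, logical(1), "correctable"))
}
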