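#' Significantly enriched terms in one gene set
#'
#' One-sided hypergeometric (Fisher) over-representation test of every
#' annotation term in `set_x` against the gene universe, with
#' Benjamini-Hochberg control across the tested terms of the domain. A term
#' is tested only if its size within the universe is at least
#' `min_term_size` and at most `max_term_size`.
#'
#' @param set_x Character vector of genes (a subset of `universe`).
#' @param term_sets Named list: term -> character vector of member genes.
#' @param universe Character vector: the gene universe (network genes).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param min_term_size,max_term_size Term size bounds within the universe;
#'   `max_term_size` defaults to half the universe.
#' @return Character vector of enriched term names (may be empty).
#' @export
enriched_terms <- function(set_x, term_sets, universe, alpha = 0.05,
                           min_term_size = 5, max_term_size = NULL) {
  if (length(universe) == 0) stop("empty gene universe")
  if (is.null(max_term_size)) max_term_size <- floor(length(universe) / 2)
  restricted <- lapply(term_sets, intersect, universe)
  sizes <- lengths(restricted)
  tested <- restricted[sizes >= min_term_size & sizes <= max_term_size]
  if (length(tested) == 0) return(character(0))
  N <- length(universe)
  n_draw <- length(set_x)
  p <- vapply(tested, function(genes) {
    q <- length(intersect(set_x, genes))
    stats::phyper(q - 1, length(genes), N - length(genes), n_draw,
                  lower.tail = FALSE)
  }, numeric(1))
  padj <- stats::p.adjust(p, method = "BH")
  names(tested)[padj <= alpha]
}

# incidence matrices and tested-term bookkeeping for one domain
domain_incidence <- function(term_sets, universe, min_term_size,
                             max_term_size) {
  restricted <- lapply(term_sets, intersect, universe)
  sizes <- lengths(restricted)
  keep <- sizes >= min_term_size & sizes <= max_term_size
  restricted <- restricted[keep]
  if (length(restricted) == 0) return(NULL)
  gidx <- lapply(restricted, match, universe)
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(gidx), lengths(gidx)),
    j = unlist(gidx), x = 1,
    dims = c(length(gidx), length(universe)),
    dimnames = list(names(restricted), universe))
  list(A = A, sizes = lengths(restricted))
}

#' The eight network quality measures
#'
#' For each of the four annotation domains (GO Molecular Function,
#' Biological Process, Cellular Component, and TFBS motifs):
#' *Enrichment_d* is the fraction of network genes X whose set_X (the top-K
#' correlated genes) contains at least one significantly enriched term of
#' the domain; *Accuracy_d* is the fraction of network genes whose own
#' annotations overlap the enriched terms of their set_X. By construction
#' each accuracy is bounded by its enrichment.
#'
#' Enrichment testing follows [enriched_terms()] (one-sided hypergeometric,
#' BH per set_X within domain, term size bounds), vectorized over all genes.
#'
#' @param net A `coexpression_network`.
#' @param annots Named list over domains `MF`, `BP`, `CC`, `TFBS`, each a
#'   named list term -> genes (e.g. from [generate_annotations()] or
#'   [read_gmt()]).
#' @param alpha Adjusted-p threshold.
#' @param min_term_size,max_term_size Term size bounds within the network
#'   universe (`max_term_size` defaults to half the universe).
#' @param accuracy_denominator `"all"` (default): accuracies are fractions
#'   of all network genes; `"enriched"`: fractions of genes that have at
#'   least one enriched term.
#' @return One-row data frame with `enrichment_mf` .. `accuracy_tfbs`,
#'   `n_genes`, and `n_terms_<domain>` (the number of tested terms).
#' @export
network_quality_measures <- function(net, annots, alpha = 0.05,
                                     min_term_size = 5,
                                     max_term_size = NULL,
                                     accuracy_denominator = c("all",
                                                              "enriched")) {
  stopifnot(inherits(net, "coexpression_network"))
  accuracy_denominator <- match.arg(accuracy_denominator)
  universe <- net$gene_ids
  N <- length(universe)
  if (is.null(max_term_size)) max_term_size <- floor(N / 2)
  k_eff <- net$k
  Bmat <- Matrix::sparseMatrix(
    i = as.vector(net$neighbors),
    j = rep(seq_len(N), each = k_eff), x = 1, dims = c(N, N))
  res <- list(n_genes = N)
  for (d in annotation_domains()) {
    dn <- tolower(d)
    inc <- domain_incidence(annots[[d]], universe, min_term_size,
                            max_term_size)
    if (is.null(inc)) {
      res[[paste0("enrichment_", dn)]] <- 0
      res[[paste0("accuracy_", dn)]] <- 0
      res[[paste0("n_terms_", dn)]] <- 0L
      next
    }
    O <- as.matrix(inc$A %*% Bmat)               # terms x genes overlaps
    m <- inc$sizes                               # recycles down columns
    P <- stats::phyper(O - 1, m, N - m, k_eff, lower.tail = FALSE)
    Padj <- apply(P, 2, stats::p.adjust, method = "BH")
    if (is.null(dim(Padj))) Padj <- matrix(Padj, nrow = 1)
    E <- Padj <= alpha                           # enriched indicator
    own <- as.matrix(inc$A) > 0
    has_enr <- colSums(E) > 0
    hit <- colSums(E & own) > 0
    denom <- if (accuracy_denominator == "all") N else max(sum(has_enr), 1L)
    res[[paste0("enrichment_", dn)]] <- mean(has_enr)
    res[[paste0("accuracy_", dn)]] <- sum(hit) / denom
    res[[paste0("n_terms_", dn)]] <- nrow(inc$A)
  }
  ord <- c(paste0("enrichment_", tolower(annotation_domains())),
           paste0("accuracy_", tolower(annotation_domains())),
           "n_genes", paste0("n_terms_", tolower(annotation_domains())))
  as.data.frame(res)[, ord]
}

#' Ground-truth neighbor precision of a network
#'
#' For simulated data with known modules: the mean over module genes of the
#' fraction of set_X that belongs to X's true module. Used to validate that
#' the enrichment-based quality measures track actual co-expression
#' recovery.
#'
#' @param net A `coexpression_network`.
#' @param module_of_gene Named integer vector (gene -> module id, `NA` for
#'   background genes), as returned in the `truth` of [generate_dataset()].
#' @return Mean neighbor precision over module genes in the network.
#' @export
neighbor_precision <- function(net, module_of_gene) {
  mods <- module_of_gene[net$gene_ids]
  in_mod <- which(!is.na(mods))
  if (length(in_mod) == 0) return(NA_real_)
  prec <- vapply(in_mod, function(x) {
    nb <- net$neighbors[, x]
    mean(!is.na(mods[nb]) & mods[nb] == mods[x])
  }, numeric(1))
  mean(prec)
}
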