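# Feed-forward-loop motif detection between the master TF and its regulated
# miRNAs, and detection of genes convergently targeted by regulated miRNAs.

#' Three-node feed-forward loop test for one miRNA
#'
#' Tests whether a miRNA and the master regulator share more common target
#' genes than expected: upper-tail hypergeometric with the miRNA's targets
#' as the draw and the master-regulated genes as the successes.
#'
#' @param mirna_targets Gene ids targeted by the miRNA (confidence-retained).
#' @param master_regulated Master-regulated gene ids.
#' @param universe All assessable gene ids (population).
#' @return List with `statistic` (overlap size), `p_value`, `member_genes`.
#' @export
three_node_ffl <- function(mirna_targets, master_regulated, universe) {
  if (length(universe) == 0) stop("Empty universe")
  mirna_targets <- intersect(mirna_targets, universe)
  master_regulated <- intersect(master_regulated, universe)
  common <- intersect(mirna_targets, master_regulated)
  list(statistic = length(common),
       p_value = hypergeom_upper(length(common), length(mirna_targets),
                                 length(master_regulated), length(universe)),
       member_genes = common)
}

# Number of PPI edges with one endpoint in `set_a` and the other in `set_b`.
ppi_cross_links <- function(ppi, set_a, set_b) {
  sum((ppi$gene_id_a %in% set_a & ppi$gene_id_b %in% set_b) |
        (ppi$gene_id_b %in% set_a & ppi$gene_id_a %in% set_b))
}

#' Four-node feed-forward loop permutation test for one miRNA
#'
#' The primary targets are the miRNA's targets that are master-correlated
#' but not master-regulated; the secondary targets are the master-regulated
#' genes. The statistic is the number of PPI edges connecting primary to
#' secondary. The null redraws same-size primary sets from the
#' master-correlated pool (excluding regulated genes) and the empirical
#' p-value is the proportion of draws whose PPI count exceeds the observed
#' one.
#'
#' @param primary Primary target gene ids (subset of `correlated_pool`).
#' @param secondary Secondary (master-regulated) gene ids.
#' @param ppi PPI edge `data.frame` (`gene_id_a`, `gene_id_b`).
#' @param correlated_pool Master-correlated, non-regulated gene ids to draw
#'   nulls from.
#' @param B Number of random draws, or `"all"` for exhaustive enumeration of
#'   every same-size subset (small pools only).
#' @param plus_one If `TRUE`, report `(b + 1) / (B + 1)` instead of `b / B`
#'   so the minimum attainable p-value is positive.
#' @param seed Optional integer; when given, makes the draws reproducible.
#' @return List with `statistic`, `p_value`, `member_pairs` (observed
#'   connecting edges).
#' @export
four_node_ffl <- function(primary, secondary, ppi, correlated_pool, B = 1000,
                          plus_one = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  primary <- unique(primary)
  if (length(correlated_pool) < length(primary))
    stop("Correlated pool smaller than the primary set")
  obs <- ppi_cross_links(ppi, primary, secondary)
  # per-gene link counts to the secondary set make draws a vector sum
  pool_links <- vapply(correlated_pool, function(g)
    ppi_cross_links(ppi, g, secondary), numeric(1))
  k <- length(primary)
  if (identical(B, "all")) {
    draws <- utils::combn(length(correlated_pool), k,
                          function(i) sum(pool_links[i]))
    B_eff <- length(draws)
  } else {
    draws <- vapply(seq_len(B), function(b)
      sum(sample(pool_links, k)), numeric(1))
    B_eff <- B
  }
  exceed <- sum(draws > obs)
  p <- if (plus_one) (exceed + 1) / (B_eff + 1) else exceed / B_eff
  hit <- (ppi$gene_id_a %in% primary & ppi$gene_id_b %in% secondary) |
    (ppi$gene_id_b %in% primary & ppi$gene_id_a %in% secondary)
  list(statistic = obs, p_value = p, member_pairs = ppi[hit, , drop = FALSE])
}

#' Genes enriched as targets of regulated miRNAs
#'
#' For each regulated gene, tests whether the miRNAs targeting it are
#' enriched for master-regulated miRNAs (upper-tail hypergeometric over the
#' miRNA universe), with Benjamini-Hochberg correction across the
#' regulated-gene list.
#'
#' @param regulated_genes Gene ids to assess (with their regulation sign if
#'   `repressed_genes` given).
#' @param regulated_mirnas Master-regulated miRNA ids.
#' @param target_edges Retained target edges (`data.frame` with `mirna_id`,
#'   `gene_id`).
#' @param all_mirnas All miRNA ids in the target graph universe.
#' @param alpha FDR threshold (default 0.05).
#' @param repressed_genes Optional character vector of master-repressed gene
#'   ids, used to report the repressed fraction of significant genes.
#' @return List with `table` (`data.frame` gene_id / n_targeting /
#'   n_regulated_targeting / p_value / adj_p / significant), `significant`
#'   (gene ids) and `repressed_fraction` (`NA` unless `repressed_genes`
#'   supplied).
#' @export
enriched_target_test <- function(regulated_genes, regulated_mirnas,
                                 target_edges, all_mirnas, alpha = 0.05,
                                 repressed_genes = NULL) {
  if (!all(regulated_mirnas %in% all_mirnas))
    stop("regulated_mirnas must be a subset of all_mirnas")
  edges <- target_edges[target_edges$mirna_id %in% all_mirnas, ]
  by_gene <- split(edges$mirna_id, edges$gene_id)
  n_pop <- length(all_mirnas)
  n_succ <- length(regulated_mirnas)
  rows <- lapply(regulated_genes, function(g) {
    tg <- unique(by_gene[[g]])
    n_t <- length(tg)
    k <- length(intersect(tg, regulated_mirnas))
    p <- if (n_t == 0) 1 else hypergeom_upper(k, n_t, n_succ, n_pop)
    data.frame(gene_id = g, n_targeting = n_t, n_regulated_targeting = k,
               p_value = p, flagged = n_t == 0, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$adj_p <- stats::p.adjust(tab$p_value, method = "BH")
  tab$significant <- tab$adj_p < alpha
  sig <- tab$gene_id[tab$significant]
  rf <- if (is.null(repressed_genes) || length(sig) == 0) NA_real_ else
    mean(sig %in% repressed_genes)
  list(table = tab, significant = sig, repressed_fraction = rf)
}
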