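# Direct target calling: bound (ChIP) AND rank-correlated with the master
# regulator on two independent expression platforms; the indirect layer is
# reached through regulated transcription factors.

#' Spearman correlation of every gene with the master regulator, dual platform
#'
#' Correlations are computed per platform over the samples shared by the two
#' matrices, with average ranks for ties. A gene is called correlated
#' (`sign = +1`) when rho >= `threshold` on *both* platforms, anti-correlated
#' (`-1`) when rho <= `-threshold` on both, else `0`. Genes measured on only
#' one platform, and genes with zero rank variance on either platform, get
#' sign 0 and are flagged.
#'
#' @param expr_a,expr_b Expression matrices (genes x samples) for the two
#'   platforms.
#' @param master_id Row name of the master regulator (must be in both).
#' @param threshold Absolute-correlation cutoff (default 0.3).
#' @return `data.frame` with `gene_id`, `rho_a`, `rho_b`, `sign`, `flagged`.
#' @export
correlate_with_master <- function(expr_a, expr_b, master_id, threshold = 0.3) {
  if (!master_id %in% rownames(expr_a) || !master_id %in% rownames(expr_b))
    stop("Master regulator absent from an expression matrix")
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  if (length(shared) < 10) stop("Fewer than 10 shared samples")
  genes <- union(rownames(expr_a), rownames(expr_b))
  genes <- setdiff(genes, master_id)
  rho_platform <- function(expr) {
    e <- expr[, shared, drop = FALSE]
    m <- e[master_id, ]
    r <- rep(NA_real_, length(genes))
    present <- genes %in% rownames(e)
    if (any(present)) {
      sub <- e[genes[present], , drop = FALSE]
      const <- apply(sub, 1, function(x) stats::sd(x) == 0) | stats::sd(m) == 0
      r[present] <- suppressWarnings(
        as.numeric(stats::cor(t(sub), m, method = "spearman")))
      r[present][const] <- NA_real_
    }
    r
  }
  rho_a <- rho_platform(expr_a)
  rho_b <- rho_platform(expr_b)
  sgn <- integer(length(genes))
  ok <- !is.na(rho_a) & !is.na(rho_b)
  sgn[ok & rho_a >= threshold & rho_b >= threshold] <- 1L
  sgn[ok & rho_a <= -threshold & rho_b <= -threshold] <- -1L
  data.frame(gene_id = genes, rho_a = rho_a, rho_b = rho_b, sign = sgn,
             flagged = !ok, stringsAsFactors = FALSE)
}

#' Call regulated genes from binding and correlation evidence
#'
#' Direct targets are bound AND correlated: `activated` = bound with sign +1,
#' `repressed` = bound with sign -1. Genes with only one kind of evidence are
#' `correlated_only` / `bound_only`; the rest are `none`. The five statuses
#' partition the gene set.
#'
#' @param correlations Output of [correlate_with_master()].
#' @param bound_genes Character vector of bound gene ids.
#' @return `data.frame` of calls with a `status` column, plus attribute
#'   `"counts"` (named status tally).
#' @export
call_regulated_genes <- function(correlations, bound_genes) {
  bound <- correlations$gene_id %in% bound_genes
  status <- rep("none", nrow(correlations))
  status[bound] <- "bound_only"
  status[!bound & correlations$sign != 0] <- "correlated_only"
  status[bound & correlations$sign == 1] <- "activated"
  status[bound & correlations$sign == -1] <- "repressed"
  calls <- data.frame(correlations, bound = bound, status = status,
                      stringsAsFactors = FALSE)
  attr(calls, "counts") <- table(factor(status, levels = c(
    "activated", "repressed", "correlated_only", "bound_only", "none")))
  calls
}

#' Link correlated-only genes to regulated transcription factors
#'
#' For each gene correlated with the master but not bound by it, finds the
#' regulated TFs whose expression satisfies the same dual-platform rule
#' (|rho| >= threshold on both platforms), supporting an indirect route. Each
#' TF is also tested for whether its |rho| with correlated genes exceeds its
#' |rho| with non-correlated genes (one-sided Wilcoxon rank-sum).
#'
#' @param calls Output of [call_regulated_genes()].
#' @param regulated_tfs Character vector of regulated genes flagged as TFs.
#' @param expr_a,expr_b Platform expression matrices.
#' @param threshold Dual-platform correlation cutoff.
#' @return List with `links` (`data.frame` gene_id / tf_id / rho per
#'   platform), `coverage` (fraction of correlated_only genes linked to >= 1
#'   TF) and `tf_tests` (`data.frame` tf_id / p_value).
#' @export
infer_indirect_layer <- function(calls, regulated_tfs, expr_a, expr_b,
                                 threshold = 0.3) {
  co_genes <- calls$gene_id[calls$status == "correlated_only"]
  non_co <- calls$gene_id[calls$sign == 0]
  if (length(regulated_tfs) == 0) {
    warning("No regulated TFs: indirect coverage is 0")
    return(list(links = data.frame(gene_id = character(0), tf_id = character(0)),
                coverage = 0, tf_tests = data.frame(tf_id = character(0),
                                                    p_value = numeric(0))))
  }
  shared <- intersect(colnames(expr_a), colnames(expr_b))
  rho_mat <- function(expr, rows, cols) {
    rows <- intersect(rows, rownames(expr)); cols <- intersect(cols, rownames(expr))
    suppressWarnings(stats::cor(t(expr[rows, shared, drop = FALSE]),
                                t(expr[cols, shared, drop = FALSE]),
                                method = "spearman"))
  }
  ra <- rho_mat(expr_a, co_genes, regulated_tfs)
  rb <- rho_mat(expr_b, co_genes, regulated_tfs)
  common_g <- intersect(rownames(ra), rownames(rb))
  common_t <- intersect(colnames(ra), colnames(rb))
  ra <- ra[common_g, common_t, drop = FALSE]
  rb <- rb[common_g, common_t, drop = FALSE]
  hit <- which((ra >= threshold & rb >= threshold) |
                 (ra <= -threshold & rb <= -threshold), arr.ind = TRUE)
  links <- data.frame(gene_id = rownames(ra)[hit[, 1]],
                      tf_id = colnames(ra)[hit[, 2]],
                      rho_a = ra[hit], rho_b = rb[hit],
                      stringsAsFactors = FALSE)
  coverage <- if (length(common_g) == 0) 0 else
    length(unique(links$gene_id)) / length(common_g)
  ra_nc <- rho_mat(expr_a, non_co, regulated_tfs)
  tf_tests <- data.frame(tf_id = common_t, p_value = vapply(common_t, function(tf) {
    x <- abs(ra[, tf]); y <- abs(ra_nc[, tf])
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y, alternative = "greater")$p.value)
  }, numeric(1)), stringsAsFactors = FALSE, row.names = NULL)
  list(links = links, coverage = coverage, tf_tests = tf_tests)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' @param k Observed successes in the draw.
#' @param draws Draw size.
#' @param successes Successes in the population.
#' @param population Population size.
#' @return Upper-tail probability.
#' @export
hypergeom_upper <- function(k, draws, successes, population) {
  if (population <= 0) stop("Empty universe")
  stats::phyper(k - 1, successes, population - successes, draws,
                lower.tail = FALSE)
}

#' Over-representation of transcription factors among regulated genes
#'
#' Upper-tail hypergeometric test of whether the regulated-gene set contains
#' more TF-flagged genes than expected from the annotated universe.
#'
#' @param regulated_genes Character vector of regulated gene ids.
#' @param tf_universe Character vector of all TF-flagged genes.
#' @param universe Character vector of all annotated genes.
#' @return List with `k` (regulated TFs), `p_value`.
#' @export
tf_overrepresentation <- function(regulated_genes, tf_universe, universe) {
  if (length(universe) == 0) stop("Empty universe")
  regulated_genes <- intersect(regulated_genes, universe)
  tf_universe <- intersect(tf_universe, universe)
  k <- length(intersect(regulated_genes, tf_universe))
  list(k = k, p_value = hypergeom_upper(k, length(regulated_genes),
                                        length(tf_universe), length(universe)))
}
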