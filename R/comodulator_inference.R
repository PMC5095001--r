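# Conditional-correlation inference of co-modulators of the master
# regulator: for each candidate regulator, samples are stratified by the
# regulator's expression, the master-target Spearman correlation is computed
# within each stratum, the per-gene Fisher-z difference d_g is formed, and
# the d_g distribution of co-bound genes is compared with that of all
# master-bound genes by a KS test on both platforms.

#' Stratify samples by a regulator's expression
#'
#' Returns the top and bottom `fraction` of samples ranked by the
#' regulator's expression; the middle samples are unused. Ties are broken by
#' stable sample order.
#'
#' @param expr Expression matrix.
#' @param regulator_id Row name of the stratifying regulator.
#' @param fraction Fraction of samples per stratum, in (0, 0.5].
#' @return List with `high` and `low` (character sample ids).
#' @export
stratify_samples <- function(expr, regulator_id, fraction = 0.35) {
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  if (!regulator_id %in% rownames(expr)) stop("Regulator absent: ", regulator_id)
  x <- expr[regulator_id, ]
  if (stats::sd(x) == 0) stop("Regulator constant across samples: ", regulator_id)
  n <- length(x)
  k <- ceiling(fraction * n)
  if (k < 10) stop("Stratum size ", k, " < 10: too few samples")
  ord <- order(x, decreasing = TRUE)  # stable: ties keep sample order
  list(high = colnames(expr)[ord[seq_len(k)]],
       low = colnames(expr)[ord[seq(n - k + 1, n)]])
}

#' Fisher z-transformation for Spearman correlations
#'
#' `z(r) = atanh(r) * sqrt((N - 3) / 1.06)`; 1.06 is the variance inflation
#' of Spearman's rho relative to Pearson's r under the Fisher transform, so
#' z is approximately standard normal under independence.
#'
#' @param r Correlation(s), |r| < 1.
#' @param n Sample count (>= 4).
#' @return z-score(s).
#' @export
fisher_z <- function(r, n) {
  if (any(n < 4)) stop("n must be >= 4")
  if (any(abs(r) >= 1)) stop("|r| must be < 1 (transform diverges)")
  atanh(r) * sqrt((n - 3) / 1.06)
}

#' Conditional correlation difference of one gene
#'
#' `d_g = z(rho(master, g | high)) - z(rho(master, g | low))`, the shift in
#' master-gene coupling between high- and low-regulator strata.
#'
#' @param expr Expression matrix.
#' @param master_id,gene_id Row names.
#' @param high,low Disjoint sample-id vectors (strata).
#' @return `d_g`, or `NA` (with a warning) when the gene or master is
#'   constant within a stratum.
#' @export
correlation_difference <- function(expr, master_id, gene_id, high, low) {
  if (length(intersect(high, low)) > 0) stop("Strata overlap")
  rho_in <- function(s) {
    x <- expr[master_id, s]; y <- expr[gene_id, s]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  rh <- rho_in(high); rl <- rho_in(low)
  if (is.na(rh) || is.na(rl)) {
    warning("Constant expression within a stratum for ", gene_id, "; skipped")
    return(NA_real_)
  }
  fisher_z(rh, length(high)) - fisher_z(rl, length(low))
}

# Vectorized d_g over many genes for one platform/stratification.
# Returns a named numeric vector; genes constant in a stratum come back NA.
# With orient = TRUE each d_g is multiplied by the sign of the gene's
# overall (all-sample) master correlation, so that "coupling strengthens
# with the regulator" maps to d > 0 for activated and repressed targets
# alike. This also cancels the common-mode term shared by all
# master-coupled genes (a chance difference in master spread between the
# two strata moves every |rho| together), which would otherwise confound a
# sign-imbalanced co-bound subset against a mixed reference set.
correlation_difference_set <- function(expr, master_id, gene_ids, high, low,
                                       orient = FALSE) {
  gene_ids <- intersect(gene_ids, rownames(expr))
  d <- rep(NA_real_, length(gene_ids))
  names(d) <- gene_ids
  for (strat in list(high, low)) {
    m <- expr[master_id, strat]
    if (stats::sd(m) == 0) return(d)
  }
  rho_stratum <- function(s) {
    sub <- expr[gene_ids, s, drop = FALSE]
    keep <- apply(sub, 1, stats::sd) > 0 & stats::sd(expr[master_id, s]) > 0
    r <- suppressWarnings(as.numeric(
      stats::cor(t(sub), expr[master_id, s], method = "spearman")))
    r[!keep] <- NA_real_
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    r
  }
  rh <- rho_stratum(high); rl <- rho_stratum(low)
  ok <- !is.na(rh) & !is.na(rl)
  d[ok] <- fisher_z(rh[ok], length(high)) - fisher_z(rl[ok], length(low))
  if (orient) {
    all_s <- union(high, low)
    r_all <- suppressWarnings(as.numeric(
      stats::cor(t(expr[gene_ids, all_s, drop = FALSE]),
                 expr[master_id, all_s], method = "spearman")))
    s <- sign(r_all)
    s[is.na(s) | s == 0] <- 1
    d <- d * s
  }
  d
}

# One-sided two-sample KS p-values of x vs reference y, both directions.
# "greater" = x stochastically greater than y (its ECDF lies below).
ks_shift_p <- function(x, y) {
  p_greater <- suppressWarnings(
    stats::ks.test(x, y, alternative = "less")$p.value)
  p_less <- suppressWarnings(
    stats::ks.test(x, y, alternative = "greater")$p.value)
  c(greater = p_greater, less = p_less)
}

#' Infer co-modulators of the master regulator
#'
#' For each candidate regulator: stratify samples by its expression (per
#' platform), compute d_g for every master-bound gene, and run one-sided KS
#' tests (both directions) comparing the d_g of genes co-bound by the master
#' and the regulator against the d_g of all master-bound genes. A regulator
#' is reported when the same shift direction is significant on both
#' platforms; the direction gives its sign (positive = co-bound correlations
#' strengthen with regulator expression).
#'
#' @param expr_a,expr_b Platform expression matrices.
#' @param master_id Master regulator row name.
#' @param candidates Character vector of candidate regulator ids (must be
#'   rows of both matrices to be assessed).
#' @param bound_genes Master-bound gene ids (the d_g reference set).
#' @param cobound_map Named list: regulator id -> gene ids bound by both the
#'   master and that regulator (subset of `bound_genes`).
#' @param fraction Stratum fraction (default 0.35).
#' @param alpha Per-platform KS significance level (default 0.05).
#' @param min_cobound Minimum co-bound genes to assess a regulator.
#' @param disjoint If `TRUE`, compare co-bound genes against the *remaining*
#'   bound genes instead of the full bound set.
#' @return `data.frame` with one row per assessed regulator: KS p-values and
#'   shift directions per platform, `sign` (`positive` / `negative` /
#'   `none`), `consistent`, `n_cobound`.
#' @export
infer_comodulators <- function(expr_a, expr_b, master_id, candidates,
                               bound_genes, cobound_map, fraction = 0.35,
                               alpha = 0.05, min_cobound = 5,
                               disjoint = FALSE) {
  platform_stats <- function(expr, reg) {
    strat <- stratify_samples(expr, reg, fraction)
    d_all <- correlation_difference_set(expr, master_id, bound_genes,
                                        strat$high, strat$low, orient = TRUE)
    d_all <- d_all[!is.na(d_all)]
    cb <- intersect(cobound_map[[reg]], names(d_all))
    ref <- if (disjoint) d_all[setdiff(names(d_all), cb)] else d_all
    if (length(cb) < min_cobound || length(ref) < min_cobound) return(NULL)
    p <- ks_shift_p(d_all[cb], ref)
    dir <- names(p)[which.min(p)]
    list(p = p, direction = dir)
  }
  rows <- lapply(candidates, function(reg) {
    if (!reg %in% rownames(expr_a) || !reg %in% rownames(expr_b)) return(NULL)
    if (is.null(cobound_map[[reg]]) ||
        length(cobound_map[[reg]]) < min_cobound) return(NULL)
    sa <- tryCatch(platform_stats(expr_a, reg), error = function(e) NULL)
    sb <- tryCatch(platform_stats(expr_b, reg), error = function(e) NULL)
    if (is.null(sa) || is.null(sb)) return(NULL)
    consistent <- sa$direction == sb$direction &&
      sa$p[sa$direction] < alpha && sb$p[sb$direction] < alpha
    sign <- if (!consistent) "none" else
      if (sa$direction == "greater") "positive" else "negative"
    data.frame(regulator_id = reg,
               ks_p_greater_a = sa$p["greater"], ks_p_less_a = sa$p["less"],
               ks_p_greater_b = sb$p["greater"], ks_p_less_b = sb$p["less"],
               direction_a = sa$direction, direction_b = sb$direction,
               sign = sign, consistent = consistent,
               n_cobound = length(cobound_map[[reg]]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(regulator_id = character(0), sign = character(0)))
  do.call(rbind, rows)
}
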