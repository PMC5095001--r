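# Small-RNA count normalization, empirical differential-expression
# probability, filters, and integration of miRNA-target databases into
# confidence-scored edges.

#' Upper-quartile normalization of a count table
#'
#' Each library is scaled so that the 75th percentile of its nonzero counts
#' equals the geometric mean of the per-library 75th percentiles; relative
#' within-sample ratios are preserved and the operation is idempotent.
#'
#' @param counts Features x samples matrix of non-negative counts.
#' @return Normalized matrix of the same shape.
#' @export
upper_quartile_normalize <- function(counts) {
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) stop("All-zero sample in count table")
    stats::quantile(nz, 0.75, names = FALSE)
  })
  target <- exp(mean(log(uq)))
  sweep(counts, 2, uq / target, "/")
}

#' log2 fold-change of two normalized means
#'
#' @param mean_a,mean_b Normalized mean counts (vectorized); `mean_b` is the
#'   denominator.
#' @return `log2(mean_a / mean_b)`; `NA` where `mean_b` is 0.
#' @export
compute_log2fc <- function(mean_a, mean_b) {
  ifelse(mean_b > 0, log2(mean_a / mean_b), NA_real_)
}

#' Empirical differential-expression probability per feature
#'
#' For each feature the between-condition signal is the pair
#' `(M, D) = (log2 ratio of condition means, difference of condition means)`.
#' The noise distribution pools the `(m, d)` contrasts of every
#' within-condition replicate pair across all features. The probability of
#' differential expression is the fraction of noise points strictly
#' dominated by the signal, i.e. with `|m| < |M|` and `|d| < |D|`. A 0.5
#' pseudocount is added before ratios.
#'
#' @param norm_counts Normalized count matrix (features x samples).
#' @param conditions Character vector per sample with exactly two levels;
#'   the first level encountered is the numerator ("treatment").
#' @param pseudocount Added to every value before M is formed.
#' @return `data.frame` with `mirna_id`, `mean_treatment`, `mean_control`,
#'   `log2fc`, `M`, `D`, `probability`.
#' @export
diffexp_probability <- function(norm_counts, conditions, pseudocount = 0.5) {
  lev <- unique(conditions)
  if (length(lev) != 2) stop("Exactly two conditions required")
  idx1 <- which(conditions == lev[1]); idx2 <- which(conditions == lev[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("At least two replicates per condition required")
  m1 <- rowMeans(norm_counts[, idx1, drop = FALSE])
  m2 <- rowMeans(norm_counts[, idx2, drop = FALSE])
  M <- log2((m1 + pseudocount) / (m2 + pseudocount))
  D <- m1 - m2
  noise_m <- numeric(0); noise_d <- numeric(0)
  for (idx in list(idx1, idx2)) {
    pairs <- utils::combn(idx, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- norm_counts[, pairs[1, j]]; b <- norm_counts[, pairs[2, j]]
      noise_m <- c(noise_m, log2((a + pseudocount) / (b + pseudocount)))
      noise_d <- c(noise_d, a - b)
    }
  }
  prob <- vapply(seq_along(M), function(i) {
    mean(abs(noise_m) < abs(M[i]) & abs(noise_d) < abs(D[i]))
  }, numeric(1))
  allzero <- m1 == 0 & m2 == 0
  prob[allzero] <- 0
  data.frame(mirna_id = rownames(norm_counts),
             mean_treatment = m1, mean_control = m2,
             log2fc = compute_log2fc(m1, m2), M = M, D = D,
             probability = prob, stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter differential-expression records
#'
#' Retains features with probability >= `prob_min` and a two-condition mean
#' normalized count >= `count_min`, and tallies up/down calls by the sign of
#' the log2 fold-change.
#'
#' @param records Output of [diffexp_probability()].
#' @param prob_min Probability threshold (default 0.6).
#' @param count_min Mean-count threshold (default 100).
#' @return List with `records` (filtered `data.frame`), `n_up`, `n_down`.
#' @export
select_diffexp <- function(records, prob_min = 0.6, count_min = 100) {
  keep <- records$probability >= prob_min &
    (records$mean_treatment + records$mean_control) / 2 >= count_min
  sel <- records[keep, , drop = FALSE]
  list(records = sel,
       n_up = sum(sel$log2fc > 0, na.rm = TRUE),
       n_down = sum(sel$log2fc < 0, na.rm = TRUE))
}

#' Integrate miRNA-target sources into confidence-scored edges
#'
#' Edges are deduplicated across sources. A pair present in the validated
#' (literature-curated) source scores 1; otherwise n distinct prediction
#' sources give n/10, capped at 1. The default retention threshold,
#' confidence > 0.3, is equivalent to support by >= 4 prediction databases.
#'
#' @param sources Named list of `data.frame`s with columns
#'   `mirna_id, gene_id`; names are source names.
#' @param validated_source Name of the validated source.
#' @param conf_min Exclusive retention threshold (default 0.3); set below 0
#'   to keep everything.
#' @return List with `edges` (`data.frame` mirna_id / gene_id /
#'   n_predicted_sources / validated / confidence / retained) and
#'   `targets_per_mirna` (named count of retained targets).
#' @export
score_targets <- function(sources, validated_source = "validated",
                          conf_min = 0.3) {
  if (length(sources) == 0) stop("No target sources supplied")
  if (is.null(names(sources)) || anyDuplicated(names(sources)))
    stop("Sources must have unique names")
  if (!validated_source %in% names(sources))
    stop("Validated source not found: ", validated_source)
  all_edges <- do.call(rbind, lapply(names(sources), function(nm) {
    s <- unique(sources[[nm]][, c("mirna_id", "gene_id")])
    data.frame(s, source = nm, stringsAsFactors = FALSE)
  }))
  key <- paste(all_edges$mirna_id, all_edges$gene_id, sep = "\r")
  validated <- key %in% key[all_edges$source == validated_source]
  n_pred <- tapply(all_edges$source != validated_source, key, sum)
  first <- !duplicated(key)
  edges <- data.frame(
    mirna_id = all_edges$mirna_id[first],
    gene_id = all_edges$gene_id[first],
    n_predicted_sources = as.integer(n_pred[key[first]]),
    validated = validated[first],
    stringsAsFactors = FALSE)
  edges$confidence <- target_confidence(edges$validated,
                                        edges$n_predicted_sources)
  edges$retained <- edges$confidence > conf_min
  kept <- edges[edges$retained, ]
  list(edges = edges,
       targets_per_mirna = table(kept$mirna_id))
}
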