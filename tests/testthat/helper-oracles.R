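# Independent oracles used across the suite. These deliberately use the
# slowest, most literal computation available (enumeration, brute force) and
# share no code with the implementation paths they check.

# Upper-tail hypergeometric by exhaustive enumeration of all draws.
enum_hypergeom_upper <- function(k, draws, successes, population) {
  subsets <- utils::combn(population, draws)
  succ_set <- seq_len(successes)
  hits <- apply(subsets, 2, function(s) sum(s %in% succ_set) >= k)
  mean(hits)
}

# Two-sided Fisher exact p by enumeration of all tables with fixed margins,
# summing the probabilities of tables no more probable than the observed one.
enum_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sample KS statistic as the literal maximal ECDF gap.
enum_ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# Spearman correlation as rank-then-Pearson with average ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Cross-set PPI link count by a literal double loop.
brute_cross_links <- function(ppi, set_a, set_b) {
  n <- 0
  for (i in seq_len(nrow(ppi))) {
    a <- ppi$gene_id_a[i]; b <- ppi$gene_id_b[i]
    if ((a %in% set_a && b %in% set_b) || (b %in% set_a && a %in% set_b))
      n <- n + 1
  }
  n
}

# Tiny three-gene annotation on one chromosome, plus strand mix.
tiny_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"), symbol = c("gA", "gB", "gC"),
    chrom = "chr1", tss = c(50000, 150000, 250000),
    strand = c("+", "-", "+"),
    start = c(50000, 140000, 250000), end = c(60000, 150000, 260000),
    is_tf = c(FALSE, TRUE, FALSE), gene_class = "protein_coding",
    stringsAsFactors = FALSE)
}

peaks_gr <- function(starts, ends, source = "MASTER", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
  S4Vectors::mcols(gr)$source <- source
  S4Vectors::mcols(gr)$score <- 1
  gr
}

# Small simulated bundle shared by pipeline-level tests (cheap config).
small_config <- function() {
  sim_config(n_genes = 200, n_samples = 80, n_direct_pos = 15,
             n_direct_neg = 20, n_indirect_tfs = 2, n_indirect_per_tf = 5,
             n_cobound = 12, n_mirna = 20, n_mirna_up = 3, n_mirna_down = 3,
             n_bound_null_mirna = 2, n_host_rule_mirna = 2, n_ffl3 = 2,
             n_ffl4 = 1, ffl3_planted = 8, ffl4_planted = 5,
             n_convergent = 4, convergent_mirnas = 5, ppi_background = 120)
}
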