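# Peak filtering, TSS-distance profiling, promoter-window assignment and
# ChIP-qPCR arithmetic. All interval work is delegated to GenomicRanges.

#' Partition peaks by co-binding support
#'
#' A focal-regulator peak is "positive" when it overlaps (>= 1 bp) at least
#' one site of a *different* regulator in the multi-regulator catalog;
#' remaining peaks are "negative". Overlap of high-confidence binding with
#' independent regulator occupancy is the filter used to discard likely
#' artifactual enrichment.
#'
#' @param peaks `GRanges` of focal-regulator peaks (see [read_bed()]).
#' @param catalog `GRanges` site catalog with a `source` metadata column
#'   naming each site's regulator.
#' @param focal Name of the focal regulator, excluded from the catalog before
#'   overlap (default `"MASTER"`; sites with source `"."` count as other
#'   regulators).
#' @return List with `positive` and `negative` `GRanges`; their union is the
#'   input set.
#' @export
filter_positive_peaks <- function(peaks, catalog, focal = "MASTER") {
  src <- S4Vectors::mcols(catalog)$source
  if (is.null(src)) src <- rep(".", length(catalog))
  other <- catalog[src != focal]
  if (length(other) == 0) {
    warning("Empty co-binding catalog: all peaks classified negative")
    return(list(positive = peaks[0], negative = peaks))
  }
  hit <- GenomicRanges::countOverlaps(peaks, other, ignore.strand = TRUE) > 0
  list(positive = peaks[hit], negative = peaks[!hit])
}

# Signed stranded distance from each peak midpoint to its nearest TSS.
# Returns a data.frame (one row per peak-TSS assignment; equidistant ties
# produce one row per tied gene with weight 1/n_ties).
peak_tss_distances <- function(peaks, annotation) {
  if (nrow(annotation) == 0) stop("No annotated TSS")
  mid <- floor((GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2)
  pk_chr <- as.character(GenomicRanges::seqnames(peaks))
  out <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    same <- which(annotation$chrom == pk_chr[i])
    if (length(same) == 0) next
    gd <- mid[i] - annotation$tss[same]
    a <- abs(gd)
    tie <- same[a == min(a)]
    signed <- (mid[i] - annotation$tss[tie]) *
      ifelse(annotation$strand[tie] == "-", -1, 1)
    out[[i]] <- data.frame(peak = i, gene_id = annotation$gene_id[tie],
                           distance = signed, weight = 1 / length(tie),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Profile peak occurrence around transcription start sites
#'
#' Histogram of signed stranded distances from peak midpoints to their
#' nearest TSS, in fixed-width bins across `[-flank, +flank)`, normalized to
#' unit mass. Distances are flipped for minus-strand genes so that positive
#' values are always downstream of the TSS. A peak equidistant from several
#' TSSs contributes fractional weight to each.
#'
#' @param peaks `GRanges` of peaks.
#' @param annotation Gene annotation `data.frame` (see [read_annotation()]).
#' @param flank Half-width of the profiled region in bp.
#' @param bin Bin width in bp; must divide `flank`.
#' @return `data.frame` with `bin_start`, `bin_end` (bp relative to TSS) and
#'   `occurrence` (relative frequency; sums to 1 when any peak falls in range).
#' @export
tss_distance_profile <- function(peaks, annotation, flank = 5000, bin = 200) {
  if (flank %% bin != 0) stop("flank must be divisible by bin")
  d <- peak_tss_distances(peaks, annotation)
  edges <- seq(-flank, flank, by = bin)
  keep <- d$distance >= -flank & d$distance < flank
  idx <- findInterval(d$distance[keep], edges, rightmost.closed = FALSE)
  w <- tapply(d$weight[keep], factor(idx, levels = seq_len(length(edges) - 1)), sum)
  w[is.na(w)] <- 0
  occ <- as.numeric(w)
  if (sum(occ) > 0) occ <- occ / sum(occ)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1],
             occurrence = occ)
}

# Stranded promoter windows [TSS - upstream, TSS + downstream] as GRanges.
promoter_windows <- function(annotation, upstream = 10000, downstream = 2000) {
  minus <- annotation$strand == "-"
  lo <- ifelse(minus, annotation$tss - downstream, annotation$tss - upstream)
  hi <- ifelse(minus, annotation$tss + upstream, annotation$tss + downstream)
  GenomicRanges::GRanges(annotation$chrom,
                         IRanges::IRanges(pmax(lo, 1), hi),
                         strand = annotation$strand,
                         gene_id = annotation$gene_id)
}

#' Assign peaks to genes by promoter-window overlap
#'
#' A gene is "bound" when at least one peak overlaps its stranded window
#' `[TSS - upstream, TSS + downstream]` (upstream/downstream measured along
#' the gene's direction of transcription). A peak may bind several genes.
#'
#' @param peaks `GRanges` of peaks.
#' @param annotation Gene annotation `data.frame`.
#' @param upstream,downstream Window extents in bp (defaults 10 kb / 2 kb).
#' @return List with `bound_genes` (character vector) and `assignments`
#'   (`data.frame` of gene_id / peak index pairs).
#' @export
assign_peaks_to_genes <- function(peaks, annotation,
                                  upstream = 10000, downstream = 2000) {
  if (upstream < 0 || downstream < 0) stop("Window extents must be >= 0")
  win <- promoter_windows(annotation, upstream, downstream)
  ov <- GenomicRanges::findOverlaps(win, peaks, ignore.strand = TRUE)
  assignments <- data.frame(
    gene_id = annotation$gene_id[S4Vectors::queryHits(ov)],
    peak = S4Vectors::subjectHits(ov), stringsAsFactors = FALSE)
  list(bound_genes = unique(assignments$gene_id), assignments = assignments)
}

#' Identify focal-regulator-bound miRNAs
#'
#' A miRNA is flagged bound when a peak overlaps its promoter, defined as the
#' stranded span from 10 kb upstream of the predicted TSS to the precursor
#' start site, or when its host gene is itself bound. Provenance records
#' which rule fired. miRNAs with neither a predicted TSS nor a host gene are
#' reported as unassessable.
#'
#' @param peaks `GRanges` of peaks.
#' @param mirnas miRNA annotation `data.frame` (see [read_mirna_annotation()]).
#' @param bound_genes Character vector of bound gene ids (host-gene rule).
#' @param upstream Promoter extent upstream of the predicted TSS (bp).
#' @return `data.frame` with `mirna_id`, `bound`, `via_promoter`, `via_host`,
#'   `assessable`.
#' @export
assign_mirna_regulation <- function(peaks, mirnas, bound_genes,
                                    upstream = 10000) {
  n <- nrow(mirnas)
  has_tss <- !is.na(mirnas$predicted_tss)
  has_host <- !is.na(mirnas$host_gene_id) & nzchar(ifelse(is.na(mirnas$host_gene_id), "", mirnas$host_gene_id))
  via_promoter <- rep(FALSE, n)
  if (any(has_tss)) {
    minus <- mirnas$strand == "-"
    lo <- ifelse(minus, mirnas$precursor_start, mirnas$predicted_tss - upstream)
    hi <- ifelse(minus, mirnas$predicted_tss + upstream, mirnas$precursor_start)
    idx <- which(has_tss)
    win <- GenomicRanges::GRanges(
      if ("chrom" %in% names(mirnas)) mirnas$chrom[idx] else "chr1",
      IRanges::IRanges(pmax(lo[idx], 1), pmax(hi[idx], pmax(lo[idx], 1))))
    via_promoter[idx] <- GenomicRanges::countOverlaps(win, peaks,
                                                      ignore.strand = TRUE) > 0
  }
  via_host <- has_host & mirnas$host_gene_id %in% bound_genes
  data.frame(mirna_id = mirnas$mirna_id,
             bound = via_promoter | via_host,
             via_promoter = via_promoter, via_host = via_host,
             assessable = has_tss | has_host,
             stringsAsFactors = FALSE)
}

#' Compare peak-to-TSS distance distributions between gene classes
#'
#' Two-sample Kolmogorov-Smirnov test on absolute distances to the TSS,
#' e.g. activated-gene versus repressed-gene promoters: a class whose
#' binding concentrates nearer the TSS yields a significant KS statistic.
#'
#' @param distances_a,distances_b Numeric vectors of signed or absolute
#'   distances for the two classes (>= 2 values each).
#' @param class_names Labels used in error messages.
#' @return List with `statistic` (D) and `p_value`.
#' @export
compare_distance_distributions <- function(distances_a, distances_b,
                                           class_names = c("a", "b")) {
  if (length(distances_a) < 2) stop("Too few distances in class ", class_names[1])
  if (length(distances_b) < 2) stop("Too few distances in class ", class_names[2])
  kt <- suppressWarnings(stats::ks.test(abs(distances_a), abs(distances_b)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' ChIP-qPCR fold enrichment
#'
#' Fold enrichment of an antibody relative to the isotype (IgG) control:
#' `2^-(Ct_antibody - Ct_igg)`.
#'
#' @param ct_antibody,ct_igg Cycle-threshold readouts (finite numerics,
#'   vectorized).
#' @return Fold enrichment.
#' @export
qpcr_fold_enrichment <- function(ct_antibody, ct_igg) {
  if (any(!is.finite(ct_antibody)) || any(!is.finite(ct_igg)))
    stop("Ct values must be finite")
  2^(-(ct_antibody - ct_igg))
}
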