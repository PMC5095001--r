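# E-box usage in promoter-associated binding sequences. Presence/absence per
# promoter (either strand) feeds a per-motif 2x2 Fisher exact test between
# regulation classes.

#' Enumerate E-box variants
#'
#' The 16 CANNTG hexamers, plus the non-canonical CACGCG, which is a known
#' high-affinity Myc-family binding motif and is reported alongside the
#' canonical variants.
#'
#' @return Character vector of 17 motifs; `CACGCG` last.
#' @export
enumerate_ebox_variants <- function() {
  nts <- c("A", "C", "G", "T")
  grid <- expand.grid(n1 = nts, n2 = nts, stringsAsFactors = FALSE)
  unique(c(paste0("CA", grid$n1, grid$n2, "TG"), "CACGCG"))
}

#' Reverse complement of DNA strings
#' @param x Character vector over ACGTN.
#' @return Reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Scan promoter sequences for motif presence by regulation class
#'
#' A promoter "contains" a motif when the motif or its reverse complement
#' occurs as a substring (boolean presence; palindromes are not
#' double-counted). Counts are tallied per regulation class.
#'
#' @param sequences Named character vector of uppercase promoter sequences
#'   (names are gene ids).
#' @param classes Named character vector mapping gene ids to regulation
#'   classes (e.g. activated / repressed / no_effect).
#' @param motifs Character vector of motifs (default all E-box variants).
#' @return `data.frame` with `motif`, `class`, `contains`, `lacks`.
#' @export
scan_promoter_sequences <- function(sequences, classes,
                                    motifs = enumerate_ebox_variants()) {
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stop("Non-ACGTN character in sequence: ",
                     names(sequences)[which(bad)[1]])
  common <- intersect(names(sequences), names(classes))
  sequences <- sequences[common]
  cls <- classes[common]
  rc <- reverse_complement(motifs)
  rows <- lapply(seq_along(motifs), function(i) {
    present <- grepl(motifs[i], sequences, fixed = TRUE) |
      grepl(rc[i], sequences, fixed = TRUE)
    agg <- tapply(present, cls, function(p) c(sum(p), sum(!p)))
    data.frame(motif = motifs[i], class = names(agg),
               contains = vapply(agg, `[`, numeric(1), 1),
               lacks = vapply(agg, `[`, numeric(1), 2),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Per-motif enrichment between two regulation classes
#'
#' Two-sided Fisher's exact test on the 2x2 presence table of each motif
#' between `class_a` and `class_b`. P-values are reported per motif without
#' multiplicity correction.
#'
#' @param counts Output of [scan_promoter_sequences()].
#' @param class_a,class_b Class labels to compare.
#' @return `data.frame` with `motif`, `odds_ratio` (conditional MLE),
#'   `p_value`.
#' @export
motif_enrichment_test <- function(counts, class_a, class_b) {
  for (cl in c(class_a, class_b))
    if (!cl %in% counts$class) stop("Class absent from counts: ", cl)
  motifs <- unique(counts$motif)
  res <- lapply(motifs, function(m) {
    a <- counts[counts$motif == m & counts$class == class_a, ]
    b <- counts[counts$motif == m & counts$class == class_b, ]
    tab <- matrix(c(a$contains, a$lacks, b$contains, b$lacks), nrow = 2,
                  byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(motif = m, odds_ratio = unname(ft$estimate),
               p_value = ft$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
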