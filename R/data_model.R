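#' @importFrom GenomicRanges GRanges findOverlaps seqnames start end strand mcols
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols<-
NULL

# Internal convention: intervals live in GRanges (1-based, closed), the native
# Bioconductor representation; BED I/O converts from/to 0-based half-open at
# the boundary. Annotation TSVs carry 1-based TSS coordinates.

#' Read a BED3+ file of peaks
#'
#' Columns beyond the third are interpreted as, in order, name (used as the
#' `source` regulator label) and score. Coordinates are validated before any
#' object is built; malformed lines are reported by line number.
#'
#' @param path Path to a whitespace/tab-delimited BED file.
#' @return A `GRanges` with metadata columns `source` (regulator name, `"."`
#'   when absent) and `score` (non-negative, 0 when absent).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#",
                           fill = TRUE)
  if (ncol(raw) < 3) stop("BED file needs >= 3 columns: ", path)
  start0 <- suppressWarnings(as.numeric(raw[[2]]))
  end0 <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start0) | is.na(end0) | start0 != floor(start0) |
                 end0 != floor(end0) | start0 >= end0 | !nzchar(raw[[1]]))
  if (length(bad) > 0) {
    stop("Malformed BED coordinates in ", path, " at line ", bad[1],
         ": '", paste(unlist(raw[bad[1], 1:3]), collapse = "\t"), "'")
  }
  src <- if (ncol(raw) >= 4) raw[[4]] else rep(".", nrow(raw))
  src[is.na(src) | !nzchar(src)] <- "."
  score <- if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else rep(0, nrow(raw))
  score[is.na(score)] <- 0
  if (any(score < 0)) stop("Negative peak score in ", path)
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("*", nrow(raw))
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(raw[[1]], IRanges::IRanges(start0 + 1, end0),
                               strand = strand)
  S4Vectors::mcols(gr)$source <- src
  S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write peaks to a BED file
#'
#' Inverse of [read_bed()]: emits 0-based half-open coordinates with the
#' `source` metadata column as the BED name field and `score` as the score.
#'
#' @param peaks A `GRanges`, typically with `source`/`score` metadata columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  src <- if ("source" %in% names(mc)) mc$source else rep(".", length(peaks))
  score <- if ("score" %in% names(mc)) mc$score else rep(0, length(peaks))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = src,
    score = score,
    strand = as.character(GenomicRanges::strand(peaks)),
    stringsAsFactors = FALSE
  )
  df$strand[df$strand == "*"] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Expects columns `gene_id, symbol, chrom, tss, strand, start, end, is_tf,
#' gene_class`; `tss`, `start`, `end` are 1-based. Validates uniqueness of
#' `gene_id`, strand values, and that each TSS lies within 2 Mb of its gene
#' interval.
#'
#' @param path Path to a tab-delimited annotation file with a header.
#' @return A `data.frame` with logical `is_tf`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "symbol", "chrom", "tss", "strand", "start", "end",
           "is_tf", "gene_class")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) stop("Annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("Duplicate gene_id in annotation")
  if (!all(ann$strand %in% c("+", "-"))) stop("Annotation strand must be + or -")
  if (any(ann$start >= ann$end)) stop("Annotation has start >= end")
  if (any(abs(ann$tss - pmax(ann$start, pmin(ann$end, ann$tss))) > 2e6))
    stop("TSS further than 2 Mb from gene interval")
  ann$is_tf <- as.logical(ann$is_tf)
  ann
}

#' Read an expression matrix
#'
#' First column is the gene identifier; remaining columns are samples.
#'
#' @param path Tab-delimited file with header.
#' @return Numeric matrix, genes in rows (rownames = gene ids).
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("Duplicate gene ids in expression matrix: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("Non-finite expression values in ", path)
  rownames(m) <- ids
  m
}

#' Write an expression-style matrix
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA count table with condition labels
#'
#' The header encodes conditions as `<condition>.<replicate>` (e.g.
#' `treatment.1`, `control.2`); the first column holds mature miRNA ids.
#'
#' @param path Tab-delimited file.
#' @return A list with `counts` (matrix) and `condition` (character vector per
#'   sample, `"treatment"` or `"control"`).
#' @export
read_counts <- function(path) {
  m <- read_expression(path)
  cond <- sub("\\..*$", "", colnames(m))
  if (any(m < 0)) stop("Negative counts in ", path)
  if (length(unique(cond)) < 2) stop("Count table needs two conditions in header")
  list(counts = m, condition = cond)
}

#' Read a survival / sample-metadata table
#'
#' Expects columns `sample_id, efs_time, efs_event, mycn_amplified, risk`.
#'
#' @param path Tab-delimited file.
#' @return `data.frame` with logical `efs_event` and `mycn_amplified`.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "efs_time", "efs_event", "mycn_amplified", "risk")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("Survival table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$efs_time < 0)) stop("Negative survival time")
  df$efs_event <- as.logical(df$efs_event)
  df$mycn_amplified <- as.logical(df$mycn_amplified)
  df
}

#' Read a PPI edge list
#'
#' Undirected; self-loops are rejected and duplicate unordered pairs collapsed.
#'
#' @param path Tab-delimited file with columns `gene_id_a, gene_id_b`.
#' @return `data.frame` of unique unordered pairs.
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("PPI table needs two columns")
  names(df)[1:2] <- c("gene_id_a", "gene_id_b")
  if (any(df$gene_id_a == df$gene_id_b)) stop("PPI self-loop found")
  key <- ifelse(df$gene_id_a < df$gene_id_b,
                paste(df$gene_id_a, df$gene_id_b),
                paste(df$gene_id_b, df$gene_id_a))
  df[!duplicated(key), c("gene_id_a", "gene_id_b"), drop = FALSE]
}

#' Read a miRNA annotation table
#'
#' Columns: `mirna_id, stemloops` (comma-separated precursor ids),
#' `predicted_tss` (1-based bp or NA), `precursor_start`, `host_gene_id`
#' (or NA), `strand`.
#'
#' @param path Tab-delimited file.
#' @return `data.frame`; `stemloops` remains a comma-separated string.
#' @export
read_mirna_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna_id", "stemloops", "predicted_tss", "precursor_start",
           "host_gene_id", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) stop("miRNA annotation missing columns: ", paste(miss, collapse = ", "))
  no_stem <- !nzchar(df$stemloops) | is.na(df$stemloops)
  if (any(no_stem)) stop("miRNA without stem-loop: ", df$mirna_id[which(no_stem)[1]])
  tss_no_prec <- !is.na(df$predicted_tss) & is.na(df$precursor_start)
  if (any(tss_no_prec)) stop("predicted_tss without precursor_start: ",
                             df$mirna_id[which(tss_no_prec)[1]])
  df
}

#' Confidence score of a miRNA-target edge
#'
#' A validated (literature-curated) interaction scores 1; otherwise the score
#' is n/10 for support by n prediction databases, capped at 1.
#'
#' @param validated Logical vector.
#' @param n_predicted Integer vector of distinct predicted sources.
#' @return Numeric confidence in \[0, 1\].
#' @export
target_confidence <- function(validated, n_predicted) {
  ifelse(validated, 1, pmin(n_predicted, 10) / 10)
}

#' Read a bundle of pipeline inputs
#'
#' Loads and cross-validates all inputs from a named list of paths (fields:
#' `peaks`, `catalog`, `annotation`, `expr_a`, `expr_b`, `counts`, `survival`,
#' `ppi`, `mirna_annotation`, `targets` (directory of per-source TSVs),
#' `promoters` (FASTA)). Samples present in the expression matrices but absent
#' from the survival table (or vice versa) are dropped from joint analyses
#' with a warning; expression matrices are reduced to their shared samples.
#'
#' @param paths Named list/character vector of file paths.
#' @param validated_source Name of the validated target source (file base name).
#' @return A list of typed inputs (class `"mycnreg_bundle"`).
#' @export
read_bundle <- function(paths, validated_source = "validated") {
  b <- list(
    peaks = read_bed(paths$peaks),
    catalog = read_bed(paths$catalog),
    annotation = read_annotation(paths$annotation),
    expr_a = read_expression(paths$expr_a),
    expr_b = read_expression(paths$expr_b),
    mirna_annotation = read_mirna_annotation(paths$mirna_annotation),
    survival = read_survival(paths$survival),
    ppi = read_ppi(paths$ppi)
  )
  cnt <- read_counts(paths$counts)
  b$counts <- cnt$counts
  b$condition <- cnt$condition
  shared <- intersect(colnames(b$expr_a), colnames(b$expr_b))
  extra <- union(setdiff(colnames(b$expr_a), shared), setdiff(colnames(b$expr_b), shared))
  if (length(extra) > 0)
    warning("Samples absent from one platform dropped: ", paste(extra, collapse = ", "))
  b$expr_a <- b$expr_a[, shared, drop = FALSE]
  b$expr_b <- b$expr_b[, shared, drop = FALSE]
  no_surv <- setdiff(shared, b$survival$sample_id)
  if (length(no_surv) > 0)
    warning("Expression samples missing from survival table: ",
            paste(no_surv, collapse = ", "))
  src_files <- sort(list.files(paths$targets, pattern = "\\.tsv$", full.names = TRUE))
  if (length(src_files) == 0) stop("No target source files in ", paths$targets)
  b$target_sources <- lapply(src_files, function(f)
    utils::read.delim(f, stringsAsFactors = FALSE))
  names(b$target_sources) <- sub("\\.tsv$", "", basename(src_files))
  b$validated_source <- validated_source
  orphan <- vapply(b$target_sources, function(s)
    sum(!s$gene_id %in% b$annotation$gene_id), integer(1))
  b$n_orphan_target_edges <- sum(orphan)
  if (b$n_orphan_target_edges > 0)
    warning(b$n_orphan_target_edges,
            " target edges reference genes absent from the annotation")
  if (!is.null(paths$promoters)) b$promoters <- read_fasta(paths$promoters)
  class(b) <- "mycnreg_bundle"
  b
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write per-stage result tables and a run manifest
#'
#' Each element of `results` that is a data.frame is written as
#' `<name>.tsv` with a header (an empty data.frame yields a header-only
#' file). A JSON manifest records parameters, the seed and input digests.
#'
#' @param results Named list of data.frames.
#' @param out_dir Output directory, created if needed.
#' @param params Named list of parameters to record.
#' @param seed Integer seed used for the run.
#' @param inputs Named character vector of input file paths to digest (md5).
#' @return Invisible character vector of files written.
#' @export
write_results <- function(results, out_dir, params = list(), seed = NA,
                          inputs = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (!is.data.frame(x)) next
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "mycnreg",
                   version = as.character(utils::packageVersion("mycnreg")),
                   seed = seed, params = params, input_md5 = digests,
                   outputs = basename(written),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(written, mf))
}
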