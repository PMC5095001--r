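# Bundled reference tables: the printed differential-expression results of
# the master-regulator knockdown small-RNA experiment and the list of
# regulated miRNAs with their FFL statistics. Used as worked inputs for the
# arithmetic and bookkeeping checks and as real-shaped demo data.

#' Printed miRNA knockdown differential-expression table
#'
#' 45 differentially expressed mature miRNAs from the master-regulator
#' knockdown experiment, with average normalized read counts under
#' knockdown and control, the printed log2 fold-change
#' (knockdown/control) and the differential-expression probability.
#' Stem-loop (precursor) identifiers are comma-separated.
#'
#' @return `data.frame` with columns `mirna_id`, `stemloops`,
#'   `mean_knockdown`, `mean_control`, `log2fc`, `probability`.
#' @export
mirna_knockdown_table <- function() {
  utils::read.delim(system.file("extdata", "mirna_knockdown_diffexp.tsv",
                                package = "mycnreg"),
                    stringsAsFactors = FALSE)
}

#' Printed table of regulated miRNAs and FFL statistics
#'
#' The 24 mature miRNAs called as direct transcriptional targets of the
#' master regulator, with the direction of regulation (`R` = repression,
#' `A` = activation), retained target counts and 3-/4-node feed-forward
#' loop overlap statistics with their significance flags.
#'
#' @return `data.frame` with columns `mirna_id`, `stemloops`, `regulation`,
#'   `n_targets`, `three_node`, `three_node_sig`, `four_node`,
#'   `four_node_sig`.
#' @export
regulated_mirna_table <- function() {
  utils::read.delim(system.file("extdata", "regulated_mirnas.tsv",
                                package = "mycnreg"),
                    stringsAsFactors = FALSE)
}

#' Count distinct stem-loop loci in a miRNA table
#'
#' @param tab A table with a comma-separated `stemloops` column.
#' @return Number of distinct precursor identifiers.
#' @export
count_stemloop_loci <- function(tab) {
  length(unique(unlist(strsplit(tab$stemloops, ","))))
}
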