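# Bundled reference tables from the white-vs-brown alpaca skin study the
# pipeline re-implements: used as worked-example inputs and arithmetic
# checks, not as fitted results.

#' Published differential-expression table for alpaca skin miRNAs
#'
#' The 48 significantly differential conserved miRNAs between white and brown
#' alpaca skin: normalized expression level (reads per million clean reads)
#' in each library, the printed fold change, and the enriched condition.
#'
#' @return data frame with `mirna_id`, `nel_brown`, `nel_white`, `fc`,
#'   `direction`.
#' @export
alpaca_de_table <- function() {
  read.delim(system.file("extdata", "alpaca_skin_de_table.tsv",
                         package = "mirskin"),
             stringsAsFactors = FALSE)
}

#' Published novel miRNA sequences with MFEI values
#'
#' The 22 novel miRNA candidates retained at the MFEI >= 0.97 cutoff in
#' alpaca skin, with their mature sequences and MFEI values. (One name
#' appears twice with two MFEI values in the source table; the 22-row count
#' is kept as printed.)
#'
#' @return data frame with `name`, `sequence`, `mfei`.
#' @export
alpaca_novel_table <- function() {
  read.delim(system.file("extdata", "alpaca_skin_novel_mfei.tsv",
                         package = "mirskin"),
             stringsAsFactors = FALSE)
}
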