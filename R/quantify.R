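#' Convert counts to TPM
#'
#' Transcripts per million: per sample, each gene's count is divided by
#' its effective length in kilobases to give a rate, and rates are scaled
#' to sum to one million. Every TPM column therefore sums to 1e6 exactly
#' (up to floating point), which downstream code relies on.
#'
#' @param counts An [expression_matrix()] with `unit = "counts"` and
#'   positive gene lengths.
#' @return An `expr_matrix` with `unit = "TPM"`.
#' @export
counts_to_tpm <- function(counts) {
  stop_unless_counts(counts)
  len_kb <- counts$gene_lengths / 1000
  rate <- counts$values / len_kb
  totals <- colSums(rate)
  zero <- totals == 0
  if (any(zero)) {
    stop("zero total length-normalized rate in sample(s): ",
         paste(colnames(counts$values)[zero], collapse = ", "))
  }
  tpm <- sweep(rate, 2, totals, "/") * 1e6
  expression_matrix(tpm, unit = "TPM", gene_lengths = counts$gene_lengths)
}

#' Convert counts to FPKM
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM = 1e9 * count / (length_nt * library_size)` with library size the
#' column sum of counts. Unlike TPM, FPKM columns do not sum to a fixed
#' constant; rescaling each FPKM column to sum to 1e6 recovers TPM.
#'
#' @inheritParams counts_to_tpm
#' @return An `expr_matrix` with `unit = "FPKM"`.
#' @export
counts_to_fpkm <- function(counts) {
  stop_unless_counts(counts)
  lib <- colSums(counts$values)
  zero <- lib == 0
  if (any(zero)) {
    stop("empty library (zero column sum) in sample(s): ",
         paste(colnames(counts$values)[zero], collapse = ", "))
  }
  fpkm <- 1e9 * sweep(counts$values / counts$gene_lengths, 2, lib, "/")
  expression_matrix(fpkm, unit = "FPKM", gene_lengths = counts$gene_lengths)
}

stop_unless_counts <- function(em) {
  if (!inherits(em, "expr_matrix")) {
    stop("input must be an expr_matrix")
  }
  if (em$unit != "counts") {
    stop("input unit is '", em$unit, "'; raw counts required")
  }
  if (is.null(em$gene_lengths)) {
    stop("gene lengths are required for length normalization")
  }
  invisible(em)
}
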