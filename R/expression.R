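#' Allele-corrected expression (corrTPM)
#'
#' Rescales the gene-level TPM by the mutant read fraction observed at the
#' variant locus in the tumor RNA-seq:
#' \deqn{corrTPM = TPM \times \frac{mut + 0.1}{mut + wt + 0.1}}
#' The 0.1 pseudocount keeps the value defined (and equal to TPM) when the
#' locus has no RNA coverage at all, and is deliberately asymmetric — it is
#' added once to the mutant count and once to the denominator sum, so
#' corrTPM equals TPM exactly whenever no wild-type reads are seen.
#' corrTPM never exceeds TPM.
#'
#' @param tpm Gene-level TPM (non-negative). Vectorized.
#' @param rna_mut_reads,rna_wt_reads Mutant / wild-type read counts at the
#'   variant locus in the tumor RNA (non-negative integers).
#' @return corrTPM, same length as the inputs.
#' @examples
#' corr_tpm(10, 0, 0)   # 10: no coverage leaves TPM untouched
#' corr_tpm(20, 5, 5)   # 20 * 5.1/10.1
#' @export
corr_tpm <- function(tpm, rna_mut_reads, rna_wt_reads) {
  bad <- !is.finite(tpm) | tpm < 0 | !is.finite(rna_mut_reads) |
    rna_mut_reads < 0 | !is.finite(rna_wt_reads) | rna_wt_reads < 0
  if (any(bad))
    stop("corr_tpm: inputs must be finite and non-negative")
  tpm * (rna_mut_reads + 0.1) / (rna_mut_reads + rna_wt_reads + 0.1)
}

#' RNA-coverage down-weighting factor (WF)
#'
#' An integer multiplier in 1..5 penalizing candidates whose mutation lacks
#' direct RNA support. The clauses, in order of precedence:
#' \enumerate{
#'   \item mutant RNA reads present — no penalty (TPM and wild-type reads
#'     are ignored);
#'   \item no RNA reads at the locus but the gene is expressed
#'     (TPM >= `tpm_floor`);
#'   \item only wild-type reads at the locus, gene expressed;
#'   \item no reads at the locus and the gene not expressed;
#'   \item only wild-type reads and the gene not expressed.
#' }
#' Exactly one clause fires for any input; the TPM boundary is inclusive
#' (TPM = 0.50 counts as expressed at the default floor).
#'
#' @inheritParams corr_tpm
#' @param tpm_floor Expression boundary (default 0.50).
#' @return Integer vector of weighting factors in `{1, 2, 3, 4, 5}`.
#' @export
weighting_factor <- function(tpm, rna_mut_reads, rna_wt_reads,
                             tpm_floor = 0.50) {
  bad <- !is.finite(tpm) | tpm < 0 | !is.finite(rna_mut_reads) |
    rna_mut_reads < 0 | !is.finite(rna_wt_reads) | rna_wt_reads < 0
  if (any(bad))
    stop("weighting_factor: inputs must be finite and non-negative")
  ifelse(rna_mut_reads > 0, 1L,
    ifelse(rna_wt_reads == 0 & tpm >= tpm_floor, 2L,
      ifelse(rna_wt_reads > 0 & tpm >= tpm_floor, 3L,
        ifelse(rna_wt_reads == 0, 4L, 5L))))
}

#' Read and write the expression TSV dialect
#'
#' Tab-separated with header: `variant_id, gene_id, tpm, rna_mut_reads,
#' rna_wt_reads`. One row per variant; a variant annotated to more than one
#' gene is an error (multi-gene overlaps must be resolved upstream).
#'
#' @param path File path.
#' @param expression Expression data frame.
#' @return `read_expression_tsv` returns the expression data frame with
#'   derived columns `corr_tpm` and `wf` appended.
#' @param tpm_floor Passed to [weighting_factor()].
#' @export
read_expression_tsv <- function(path, tpm_floor = 0.50) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "gene_id", "tpm", "rna_mut_reads", "rna_wt_reads")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("expression table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$variant_id))
    stop("expression table has duplicated variant_id(s): ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]),
               collapse = ", "))
  tab$corr_tpm <- corr_tpm(tab$tpm, tab$rna_mut_reads, tab$rna_wt_reads)
  tab$wf <- weighting_factor(tab$tpm, tab$rna_mut_reads, tab$rna_wt_reads,
                             tpm_floor)
  tab
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(expression, path) {
  cols <- c("variant_id", "gene_id", "tpm", "rna_mut_reads", "rna_wt_reads")
  utils::write.table(expression[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
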