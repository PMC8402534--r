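RANKED_COLUMNS <- c("final_position", "peptide_id", "variant_id", "sequence",
                    "tumor_mf", "corr_tpm", "tpm", "rna_mut_reads",
                    "rna_wt_reads", "best_ic50_nm", "best_allele", "r_freq",
                    "r_expr", "r_ic50", "k", "wf", "rsum")

#' Run the full prioritization pipeline on one patient
#'
#' End to end: validate and filter the somatic variants, construct candidate
#' neo-peptides (centered 25-mers for missense variants; tailored
#' frameshift-peptide 25-mers for indels), join the expression evidence
#' (corrTPM, WF) and the binding predictions (best mutant-containing IC50
#' per peptide), and rank everything with [venus_score()]. No record is
#' dropped silently: the returned object carries a machine-readable drop log
#' with one reason per discarded variant, and
#' `n_in == n_ranked_variants + n_dropped` always holds.
#'
#' @param variant_file Variant TSV (see [read_variant_tsv()]).
#' @param protein_fasta,cds_fasta Wild-type protein / CDS FASTA pair.
#' @param expression_file Expression TSV (see [read_expression_tsv()]).
#' @param prediction_file Prediction TSV (see [read_prediction_tsv()]);
#'   epitopes are matched by sequence, so it must cover every
#'   mutant-containing epitope of every buildable peptide.
#' @param output_file Optional path for the ranked TSV
#'   ([write_ranked_tsv()]).
#' @param config A [venus_config()].
#' @return A list of class `venus_run`: `ranking` (a `venus_ranking`),
#'   `dropped` (data frame `variant_id, stage, reason`), `n_in`,
#'   `n_candidates`.
#' @export
run_pipeline <- function(variant_file, protein_fasta, cds_fasta,
                         expression_file, prediction_file,
                         output_file = NULL, config = venus_config()) {
  variants <- read_variant_tsv(variant_file)
  drop_ingest <- attr(variants, "dropped")
  n_in <- nrow(variants) + nrow(drop_ingest)

  decisions <- apply_somatic_filters(variants, config$filter)
  drop_filter <- data.frame(
    variant_id = decisions$variant_id[!decisions$passed],
    reason = paste0("failed somatic filter: ",
                    decisions$failed_criteria[!decisions$passed]),
    stringsAsFactors = FALSE)
  variants <- variants[decisions$passed, , drop = FALSE]

  contexts <- read_contexts(protein_fasta, cds_fasta)
  predictions <- read_prediction_tsv(prediction_file)
  peptides <- enumerate_candidates(variants, contexts,
                                   epitope_ic50_map(predictions), config)
  drop_pep <- attr(peptides, "dropped")
  if (nrow(peptides) == 0)
    stop("no candidate peptides survive construction")

  # per-peptide binding: every mutant-containing epitope, all alleles
  queries <- do.call(rbind, lapply(seq_len(nrow(peptides)), function(i) {
    eps <- mutant_epitopes(peptides$sequence[i],
                           peptides$mutated_positions[i],
                           config$epitope_length)
    data.frame(peptide_id = peptides$peptide_id[i], epitope_seq = eps,
               stringsAsFactors = FALSE)
  }))
  pred_rows <- merge(queries,
                     predictions[, c("epitope_seq", "allele", "ic50_nm")],
                     by = "epitope_seq")
  covered <- unique(pred_rows$epitope_seq)
  missing <- setdiff(unique(queries$epitope_seq), covered)
  if (length(missing))
    stop("prediction table lacks epitope(s): ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10))
  pred_rows$contains_mutation <- TRUE
  binding <- summarize_binding(pred_rows, config$binding_aggregate)

  expression <- read_expression_tsv(expression_file, config$tpm_floor)
  cand <- merge(peptides, variants[, c("variant_id", "tumor_mf")],
                by = "variant_id")
  cand <- merge(cand, expression[, c("variant_id", "tpm",
                                         "rna_mut_reads", "rna_wt_reads",
                                         "corr_tpm", "wf")],
                by = "variant_id")
  orphan <- setdiff(peptides$variant_id, expression$variant_id)
  if (length(orphan))
    stop("no expression record for variant(s): ",
         paste(orphan, collapse = ", "))
  cand <- merge(cand, binding, by = "peptide_id")

  ranking <- venus_score(cand, config)
  if (!is.null(output_file)) write_ranked_tsv(ranking, output_file)

  dropped <- rbind(
    if (nrow(drop_ingest)) cbind(drop_ingest[, c("variant_id", "reason")],
                                 stage = "ingestion"),
    if (nrow(drop_filter)) cbind(drop_filter, stage = "filter"),
    if (nrow(drop_pep)) cbind(drop_pep, stage = "peptide"))
  if (is.null(dropped))
    dropped <- data.frame(variant_id = character(), reason = character(),
                          stage = character(), stringsAsFactors = FALSE)
  structure(list(ranking = ranking, dropped = dropped, n_in = n_in,
                 n_candidates = nrow(ranking)),
            class = "venus_run")
}

#' @export
print.venus_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d variants in, %d dropped (%s), %d ranked candidates from %d variants\n",
              x$n_in, nrow(x$dropped),
              if (nrow(x$dropped))
                paste(names(table(x$dropped$stage)),
                      as.integer(table(x$dropped$stage)),
                      sep = ": ", collapse = ", ") else "none",
              x$n_candidates, length(unique(x$ranking$variant_id))))
  print(x$ranking)
  invisible(x)
}

#' Write a ranked candidate list as TSV
#'
#' Fixed column order: `final_position, peptide_id, variant_id, sequence,
#' tumor_mf, corr_tpm, tpm, rna_mut_reads, rna_wt_reads, best_ic50_nm,
#' best_allele, r_freq, r_expr, r_ic50, k, wf, rsum` (columns absent from
#' the input are omitted).
#'
#' @param ranking A `venus_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_tsv <- function(ranking, path) {
  tab <- as.data.frame(ranking)
  utils::write.table(tab[, intersect(RANKED_COLUMNS, names(tab))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
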