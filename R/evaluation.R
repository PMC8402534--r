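#' Percentage of candidates ranked better
#'
#' Expresses a validated neoantigen's position in a ranked candidate list as
#' an integer percentage of the list, rounded half away from zero. Published
#' per-row percentages are not all reproducible by a single rounding rule
#' (a position-1-of-180 row prints 0\% while 9-of-180 prints 5\%), so this
#' function should be trusted only where the `position` vs `position - 1`
#' and floor vs round choices agree.
#'
#' @param position 1-based position in the ranked list. Vectorized.
#' @param total List size.
#' @return Integer percentage in 0..100.
#' @examples
#' pct_ranked_better(110, 494)  # 22
#' pct_ranked_better(1, 268)    # 0
#' @export
pct_ranked_better <- function(position, total) {
  stopifnot(all(total >= 1))
  if (any(position < 1 | position > total))
    stop("position must lie in 1..total")
  as.integer(floor(100 * position / total + 0.5))
}

#' Count neoantigens captured within a cutoff
#'
#' How many validated (or implanted) neoantigens fall within the top
#' `cutoff` of their ranked lists — the payload-size question for a vaccine
#' platform that can encode only the best N candidates.
#'
#' @param positions Positions of the neoantigens in their ranked lists
#'   (`Inf` allowed for candidates absent from a reduced list).
#' @param cutoff Selection size (e.g. 20 or 60).
#' @return Count of positions at or below the cutoff.
#' @export
capture_at <- function(positions, cutoff) {
  stopifnot(length(positions) >= 1, cutoff >= 0)
  sum(positions <= cutoff)
}

#' Summarize a cohort of validated-neoantigen records
#'
#' Cohort-level validation metrics for a set of per-neoantigen records:
#' median and maximum of the percentage-ranked-better column (median of the
#' middle two for even n) and capture counts at the top-20 and top-60
#' cutoffs.
#'
#' @param records Data frame with columns `position` and `pct_better` (as
#'   from [validated_neoantigens()]).
#' @param cutoffs Two selection sizes (default 20 and 60).
#' @return A list of class `cohort_summary`: `median_pct`, `max_pct`,
#'   `capture20`, `capture60`, `n`.
#' @examples
#' cohort_summary(validated_neoantigens())
#' @export
cohort_summary <- function(records, cutoffs = c(20L, 60L)) {
  stopifnot(nrow(records) >= 1,
            all(c("position", "pct_better") %in% names(records)))
  out <- list(median_pct = stats::median(records$pct_better),
              max_pct = max(records$pct_better),
              capture20 = capture_at(records$position, cutoffs[1]),
              capture60 = capture_at(records$position, cutoffs[2]),
              n = nrow(records))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Validated neoantigens: %d\n", x$n))
  cat(sprintf("  captured in top 20: %d (%.0f%%)\n", x$capture20,
              100 * x$capture20 / x$n))
  cat(sprintf("  captured in top 60: %d (%.0f%%)\n", x$capture60,
              100 * x$capture60 / x$n))
  cat(sprintf("  %% of list ranked better: median %g, max %g\n",
              x$median_pct, x$max_pct))
  invisible(x)
}

#' Packaged validation records
#'
#' The packaged table of 20 experimentally validated, T-cell-reactive
#' neoantigens across nine solid-tumor patients: for each, the size of the
#' patient's candidate neo-peptide list, the neoantigen's position in the
#' ranked list, and the printed percentage of candidates ranked better.
#' Labels are `gene_substitution` strings (e.g. `MAGEA6_E168K`).
#'
#' @param path Override the packaged TSV (same columns).
#' @return Data frame `tumor_type, patient_id, total_candidates,
#'   neoantigen_label, position, pct_better`.
#' @export
validated_neoantigens <- function(path = system.file(
  "extdata", "validated_neoantigens.tsv", package = "venus")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(patient_id = "character"))
  stopifnot(all(tab$position >= 1),
            all(tab$position <= tab$total_candidates),
            all(tab$pct_better >= 0), all(tab$pct_better <= 100))
  tab
}

#' Positions of known-true variants in a ranked list
#'
#' For each truth id, the best (smallest) `final_position` over the ranked
#' peptides derived from that variant; a frameshift's best-ranked 25-mer
#' represents the mutation. Ids absent from the list (e.g. removed by a
#' funnel filter) get `Inf`.
#'
#' @param ranked A `venus_ranking` or any ranked data frame with
#'   `final_position` and an id column.
#' @param truth_ids Character vector of true ids.
#' @param id_col Column to match on (default `"variant_id"`).
#' @return Named numeric vector of positions, one per truth id.
#' @export
truth_positions <- function(ranked, truth_ids, id_col = "variant_id") {
  ranked <- as.data.frame(ranked)
  if (!id_col %in% names(ranked))
    stop("ranked list lacks column '", id_col, "'")
  vapply(truth_ids, function(id) {
    p <- ranked$final_position[ranked[[id_col]] == id]
    if (length(p)) min(p) else Inf
  }, numeric(1))
}
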