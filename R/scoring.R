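#' Competition ranking of one scoring parameter
#'
#' Ranks candidates by a single parameter using competition ("minimum")
#' ranks: tied values share the smallest rank of their block and the next
#' distinct value gets 1 + the count of strictly better candidates. Rank 1
#' is best; `direction` says whether larger or smaller values are better.
#'
#' @param values Numeric vector (finite; `NaN` is an error).
#' @param direction `"higher_better"` or `"lower_better"`.
#' @param ids Optional names used in error messages.
#' @return Integer ranks, same length and order as `values`.
#' @examples
#' rank_parameter(c(0.5, 0.5, 0.2), "higher_better")  # 1 1 3
#' @export
rank_parameter <- function(values, direction = c("higher_better",
                                                 "lower_better"),
                           ids = NULL) {
  direction <- match.arg(direction)
  if (length(values) < 1) stop("rank_parameter: empty input")
  bad <- !is.finite(values)
  if (any(bad))
    stop("rank_parameter: non-finite value for ",
         paste(if (is.null(ids)) which(bad) else ids[bad], collapse = ", "))
  x <- if (direction == "higher_better") -values else values
  as.integer(rank(x, ties.method = "min"))
}

#' Non-binder rank penalty (k)
#'
#' A constant added to the IC50 rank of candidates whose best predicted
#' IC50 exceeds the threshold (strictly greater than 1000 nM by default):
#' the penalty equals the number of candidate neo-peptides in the patient's
#' list, which pushes any predicted non-binder behind every unpenalized
#' candidate on that axis while preserving order among the penalized.
#'
#' @param best_ic50_nm Best predicted IC50 per candidate, nM. Vectorized.
#' @param n_candidates Size of the patient's candidate list.
#' @param threshold_nm Penalty threshold, nM.
#' @return Integer vector: `n_candidates` where IC50 > threshold, else 0.
#' @examples
#' penalty_k(c(1500, 1000, 50), n_candidates = 300)  # 300 0 0
#' @export
penalty_k <- function(best_ic50_nm, n_candidates, threshold_nm = 1000) {
  stopifnot(n_candidates >= 1)
  ifelse(best_ic50_nm > threshold_nm, as.integer(n_candidates), 0L)
}

#' Score and rank a patient's candidate neo-peptides
#'
#' The core weighted rank-sum. Each candidate is ranked independently on
#' three axes — tumor mutation allele frequency (higher better), corrected
#' expression corrTPM (higher better), and best predicted MHC-I IC50 (lower
#' better) — by competition ranks, and the final score is
#' \deqn{RSUM = (R_{FREQ} + R_{EXPR} + (k + R_{IC50})) \times WF}
#' where `k` is the non-binder penalty of [penalty_k()] and `WF` the
#' RNA-coverage weighting factor of [weighting_factor()]. Lower RSUM is
#' better. Candidates are ordered by ascending RSUM, ties broken by lower
#' IC50 then by `peptide_id`, giving a total order (`final_position`,
#' 1 = best).
#'
#' @param candidates Data frame with columns `peptide_id`, `tumor_mf`,
#'   `corr_tpm`, `wf`, `best_ic50_nm` (one row per candidate; extra columns
#'   such as `tpm` or `variant_id` are carried through).
#' @param config A [venus_config()] (supplies the penalty threshold).
#' @return An object of class `venus_ranking`: the candidate table ordered
#'   by `final_position` with columns `r_freq`, `r_expr`, `r_ic50`, `k`,
#'   `wf`, `rsum`, `final_position` appended.
#' @examples
#' cand <- data.frame(peptide_id = c("a", "b"),
#'                    tumor_mf = c(0.5, 0.2), corr_tpm = c(8, 1),
#'                    wf = c(1, 1), best_ic50_nm = c(40, 2000))
#' venus_score(cand)
#' @export
venus_score <- function(candidates, config = venus_config()) {
  need <- c("peptide_id", "tumor_mf", "corr_tpm", "wf", "best_ic50_nm")
  missing_cols <- setdiff(need, names(candidates))
  if (length(missing_cols))
    stop("candidate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  na_rows <- !stats::complete.cases(candidates[, need])
  if (any(na_rows))
    stop("candidate(s) with missing scoring inputs: ",
         paste(candidates$peptide_id[na_rows], collapse = ", "))
  if (!all(candidates$wf %in% 1:5))
    stop("wf must be an integer in 1..5")
  n <- nrow(candidates)
  out <- candidates
  out$r_freq <- rank_parameter(out$tumor_mf, "higher_better", out$peptide_id)
  out$r_expr <- rank_parameter(out$corr_tpm, "higher_better", out$peptide_id)
  out$r_ic50 <- rank_parameter(out$best_ic50_nm, "lower_better",
                               out$peptide_id)
  out$k <- penalty_k(out$best_ic50_nm, n, config$penalty_ic50_nm)
  out$rsum <- as.numeric((out$r_freq + out$r_expr + (out$k + out$r_ic50)) *
                           out$wf)
  ord <- order(out$rsum, out$best_ic50_nm, out$peptide_id)
  out <- out[ord, , drop = FALSE]
  out$final_position <- seq_len(n)
  rownames(out) <- NULL
  structure(out, class = c("venus_ranking", "data.frame"),
            config = config)
}

#' Comparator ranking strategies
#'
#' Ranks the same candidate table by one of the alternative selection
#' strategies used to benchmark the combined score:
#' \describe{
#'   \item{`venus`}{delegates to [venus_score()];}
#'   \item{`mf_only`}{descending tumor mutation allele frequency;}
#'   \item{`expr_only`}{descending corrTPM;}
#'   \item{`ic50_only`}{ascending best IC50;}
#'   \item{`funnel_then_ic50`}{fixed-threshold funnel — drop every
#'     candidate not satisfying both best IC50 <= 500 nM and gene
#'     TPM >= 0.50, then sort survivors by ascending IC50. Dropped
#'     candidates are absent from the output (they cannot be captured at
#'     any cutoff).}
#' }
#' Ties in the single-parameter strategies are broken by lower IC50 then by
#' `peptide_id`, as in the combined score.
#'
#' @inheritParams venus_score
#' @param strategy One of the strategy names above.
#' @return For `venus`, a `venus_ranking`; otherwise the (possibly reduced)
#'   candidate table ordered best-first with a `final_position` column.
#' @export
rank_alternative <- function(candidates,
                             strategy = c("venus", "mf_only", "expr_only",
                                          "ic50_only", "funnel_then_ic50"),
                             config = venus_config()) {
  strategy <- match.arg(strategy)
  if (strategy == "venus") return(venus_score(candidates, config))
  out <- candidates
  if (strategy == "funnel_then_ic50") {
    if (!"tpm" %in% names(out))
      stop("funnel_then_ic50 requires a tpm column")
    out <- out[out$best_ic50_nm <= config$funnel_ic50_nm &
                 out$tpm >= config$funnel_tpm, , drop = FALSE]
  }
  ord <- switch(strategy,
    mf_only   = order(-out$tumor_mf, out$best_ic50_nm, out$peptide_id),
    expr_only = order(-out$corr_tpm, out$best_ic50_nm, out$peptide_id),
    ic50_only = ,
    funnel_then_ic50 = order(out$best_ic50_nm, out$peptide_id))
  out <- out[ord, , drop = FALSE]
  out$final_position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' @export
print.venus_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked candidate neo-peptides: %d candidates\n", nrow(x)))
  cat(sprintf("  penalized non-binders (k > 0): %d; without RNA mutant support (WF > 1): %d\n",
              sum(x$k > 0), sum(x$wf > 1)))
  cols <- intersect(c("final_position", "peptide_id", "variant_id",
                      "tumor_mf", "corr_tpm", "best_ic50_nm", "k", "wf",
                      "rsum"), names(x))
  cat(sprintf("  top %d of %d:\n", min(n, nrow(x)), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)[, cols], n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}

#' @export
summary.venus_ranking <- function(object, cutoffs = c(20L, 60L), ...) {
  s <- list(n = nrow(object),
            n_penalized = sum(object$k > 0),
            wf_table = table(factor(object$wf, levels = 1:5)),
            rsum_range = range(object$rsum),
            cutoffs = cutoffs)
  class(s) <- "summary.venus_ranking"
  s
}

#' @export
print.summary.venus_ranking <- function(x, ...) {
  cat(sprintf("Candidates: %d (RSUM %s-%s)\n", x$n,
              format(x$rsum_range[1]), format(x$rsum_range[2])))
  cat(sprintf("IC50-penalized (k > 0): %d (%.1f%%)\n", x$n_penalized,
              100 * x$n_penalized / x$n))
  cat("Weighting factors: ",
      paste(sprintf("WF=%s: %d", names(x$wf_table), as.integer(x$wf_table)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.venus_ranking <- function(x, ...) {
  class(x) <- "data.frame"
  attr(x, "config") <- NULL
  x
}

#' Plot a ranked candidate list
#'
#' RSUM against final position, highlighting penalized non-binders and, if
#' a `truth` vector of peptide ids is given, the implanted/validated
#' candidates; vertical lines mark the top-20 and top-60 cutoffs used for
#' vaccine payload selection.
#'
#' @param x A `venus_ranking`.
#' @param truth Optional character vector of peptide ids to highlight.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.venus_ranking <- function(x, truth = NULL, ...) {
  col <- ifelse(x$k > 0, "grey60", "grey25")
  pch <- rep(4L, nrow(x))
  if (!is.null(truth)) {
    hit <- x$peptide_id %in% truth
    col[hit] <- "red3"
    pch[hit] <- 19L
  }
  plot(x$final_position, x$rsum, log = "y", col = col, pch = pch,
       xlab = "final position (1 = best)", ylab = "RSUM (log scale)", ...)
  graphics::abline(v = c(20, 60), lty = 2,
                   col = c("black", "darkgreen"))
  invisible(x)
}
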