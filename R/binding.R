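#' Summarize MHC class-I predictions per peptide
#'
#' Collapses an epitope-level prediction table to one binding summary per
#' peptide: the best (by default minimum) IC50 over all mutant-containing
#' epitopes across the patient's alleles. Wild-type-only epitopes are
#' ignored — only epitopes comprising a non-wild-type residue count towards
#' a peptide's binding evidence. Ties on IC50 are broken by the
#' lexicographically smallest (epitope, allele) pair so the summary is
#' deterministic under input permutation.
#'
#' @param predictions Data frame `peptide_id, epitope_seq, allele, ic50_nm,
#'   contains_mutation` (IC50 in nM, strictly positive; epitopes 8--11
#'   residues).
#' @param aggregate `"min"` (best predicted binder, default) or `"median"`.
#' @return Data frame `peptide_id, best_ic50_nm, best_epitope, best_allele`,
#'   one row per peptide, ordered by `peptide_id`. With `"median"`
#'   aggregation `best_ic50_nm` is the median and the reported
#'   epitope/allele is the mutant-containing prediction closest to it from
#'   below or at it.
#' @export
summarize_binding <- function(predictions, aggregate = c("min", "median")) {
  aggregate <- match.arg(aggregate)
  need <- c("peptide_id", "epitope_seq", "allele", "ic50_nm",
            "contains_mutation")
  missing_cols <- setdiff(need, names(predictions))
  if (length(missing_cols))
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(!is.finite(predictions$ic50_nm) | predictions$ic50_nm <= 0))
    stop("ic50_nm must be finite and > 0")
  bad_len <- nchar(predictions$epitope_seq) < 8 |
    nchar(predictions$epitope_seq) > 11
  if (any(bad_len))
    stop("epitope length outside 8-11 for peptide(s): ",
         paste(unique(predictions$peptide_id[bad_len]), collapse = ", "))
  mut <- predictions[as.logical(predictions$contains_mutation), , drop = FALSE]
  orphan <- setdiff(unique(predictions$peptide_id), unique(mut$peptide_id))
  if (length(orphan))
    stop("peptide(s) without any mutant-containing prediction: ",
         paste(orphan, collapse = ", "))
  mut <- mut[order(mut$peptide_id, mut$ic50_nm, mut$epitope_seq, mut$allele), ]
  out <- do.call(rbind, lapply(split(mut, mut$peptide_id), function(g) {
    target <- if (aggregate == "min") g$ic50_nm[1] else
      stats::median(g$ic50_nm)
    i <- max(which(g$ic50_nm <= target))
    data.frame(peptide_id = g$peptide_id[1],
               best_ic50_nm = target,
               best_epitope = g$epitope_seq[i],
               best_allele = g$allele[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Collapse a prediction table to a per-9-mer best IC50 map
#'
#' Minimum IC50 per distinct epitope sequence over all alleles and rows —
#' the lookup used by frameshift-peptide tailoring.
#'
#' @param predictions Data frame with columns `epitope_seq` and `ic50_nm`.
#' @return Named numeric vector (names are epitope sequences).
#' @export
epitope_ic50_map <- function(predictions) {
  stopifnot(all(c("epitope_seq", "ic50_nm") %in% names(predictions)))
  tapply(predictions$ic50_nm, predictions$epitope_seq, min)
}

#' Deterministic surrogate IC50 predictor
#'
#' A stand-in for an external MHC class-I predictor, used to exercise the
#' pipeline without network access. It hashes the (peptide, allele, seed)
#' triple with a polynomial rolling hash and maps the result log-uniformly
#' onto \code{[1, 50000]} nM. Identical inputs give identical outputs on any
#' platform; the value has no biological meaning.
#'
#' @param peptide Amino-acid string, length 8--11. Vectorized (recycled with
#'   `allele`).
#' @param allele Allele name string.
#' @param seed Integer mixed into the hash (recycled).
#' @return Pseudo-IC50 in nM, in \code{[1, 50000]}.
#' @export
surrogate_predict <- function(peptide, allele, seed = 0L) {
  n <- max(length(peptide), length(allele), length(seed))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  seed <- rep_len(seed, n)
  bad <- nchar(peptide) < 8 | nchar(peptide) > 11
  if (any(bad))
    stop("surrogate_predict: peptide length must be 8-11 (",
         paste(unique(peptide[bad]), collapse = ", "), ")")
  m <- 2147483647  # 2^31 - 1; doubles hold intermediates exactly
  vapply(seq_len(n), function(i) {
    h <- (as.numeric(seed[i]) %% m + m) %% m
    for (code in utf8ToInt(paste0(peptide[i], "|", allele[i])))
      h <- (h * 131 + code) %% m
    # one extra scramble round to decorrelate near-identical inputs
    h <- (h * 48271) %% m
    10^((h / m) * log10(50000))
  }, numeric(1))
}

#' Read and write the prediction TSV dialect
#'
#' IEDB-export-like table: `peptide_id, epitope_seq, allele, ic50_nm,
#' contains_mutation`. For frameshift peptides the table may carry rows for
#' every novel-residue 9-mer of the modified FSP under the FSP id, so that
#' tailoring can run before final peptides exist.
#'
#' @param path File path.
#' @param predictions Prediction data frame.
#' @return `read_prediction_tsv` returns the prediction data frame.
#' @export
read_prediction_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide_id", "epitope_seq", "allele", "ic50_nm",
            "contains_mutation")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("prediction table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$contains_mutation <- as.logical(tab$contains_mutation)
  tab
}

#' @rdname read_prediction_tsv
#' @export
write_prediction_tsv <- function(predictions, path) {
  cols <- c("peptide_id", "epitope_seq", "allele", "ic50_nm",
            "contains_mutation")
  utils::write.table(predictions[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
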