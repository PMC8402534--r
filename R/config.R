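#' Somatic filter thresholds
#'
#' Thresholds for the four-criterion somatic variant filter. Defaults are the
#' published operating point: tumor mutation allele frequency (MF) at least
#' 10\%, tumor/normal MF ratio at least 5, more than 2 mutant reads in the
#' tumor DNA, and fewer than 2 mutant reads in the normal DNA.
#'
#' MF values are stored as fractions in \code{[0, 1]}; the 10\% threshold is
#' therefore \code{0.10}. A normal MF of zero makes the ratio criterion pass
#' unconditionally (absence from the normal sample is the strongest somatic
#' evidence).
#'
#' @param min_tumor_mf Minimum tumor MF (fraction), inclusive.
#' @param min_mf_ratio Minimum tumor/normal MF ratio, inclusive.
#' @param min_tumor_alt_reads Tumor mutant read count must exceed this
#'   (strict).
#' @param max_normal_alt_reads Normal mutant read count must be below this
#'   (strict).
#' @return A list of class \code{filter_config}.
#' @examples
#' filter_config()
#' filter_config(min_tumor_mf = 0.05)
#' @export
filter_config <- function(min_tumor_mf = 0.10, min_mf_ratio = 5,
                          min_tumor_alt_reads = 2, max_normal_alt_reads = 2) {
  stopifnot(min_tumor_mf >= 0, min_tumor_mf <= 1, min_mf_ratio >= 0,
            min_tumor_alt_reads >= 0, max_normal_alt_reads >= 0)
  structure(list(min_tumor_mf = min_tumor_mf,
                 min_mf_ratio = min_mf_ratio,
                 min_tumor_alt_reads = min_tumor_alt_reads,
                 max_normal_alt_reads = max_normal_alt_reads),
            class = "filter_config")
}

#' Pipeline configuration
#'
#' Bundles every tunable constant of the prioritization pipeline. The
#' defaults reproduce the published operating point: the somatic filter of
#' [filter_config()], a 1000 nM IC50 threshold both for frameshift-peptide
#' tailoring and for the rank penalty, the comparator "funnel" thresholds
#' (IC50 <= 500 nM, TPM >= 0.50), the TPM floor of 0.50 used by the RNA
#' coverage weighting factor, and 9-mer epitopes.
#'
#' @param filter A [filter_config()].
#' @param tailoring_ic50_nm IC50 ceiling (nM) for retaining mutant-containing
#'   9-mer anchors during frameshift-peptide tailoring.
#' @param penalty_ic50_nm IC50 (nM) above which the rank penalty `k` fires
#'   (strictly greater triggers).
#' @param funnel_ic50_nm,funnel_tpm Fixed thresholds of the comparator funnel
#'   strategy.
#' @param tpm_floor TPM boundary of the weighting-factor scheme.
#' @param epitope_length Epitope length used when enumerating anchors
#'   (only 9 is used by the tailoring procedure; 8--11 accepted in input
#'   prediction tables).
#' @param binding_aggregate How per-peptide IC50 is summarized over epitopes
#'   and alleles: `"min"` (best predicted binder, default) or `"median"`.
#' @return A list of class \code{venus_config}.
#' @seealso [read_config()], [write_config()]
#' @export
venus_config <- function(filter = filter_config(),
                         tailoring_ic50_nm = 1000,
                         penalty_ic50_nm = 1000,
                         funnel_ic50_nm = 500,
                         funnel_tpm = 0.50,
                         tpm_floor = 0.50,
                         epitope_length = 9L,
                         binding_aggregate = c("min", "median")) {
  stopifnot(inherits(filter, "filter_config"),
            tailoring_ic50_nm > 0, penalty_ic50_nm > 0,
            funnel_ic50_nm > 0, funnel_tpm >= 0, tpm_floor >= 0,
            epitope_length >= 8, epitope_length <= 11)
  binding_aggregate <- match.arg(binding_aggregate)
  structure(list(filter = filter,
                 tailoring_ic50_nm = tailoring_ic50_nm,
                 penalty_ic50_nm = penalty_ic50_nm,
                 funnel_ic50_nm = funnel_ic50_nm,
                 funnel_tpm = funnel_tpm,
                 tpm_floor = tpm_floor,
                 epitope_length = as.integer(epitope_length),
                 binding_aggregate = binding_aggregate),
            class = "venus_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' The on-disk form is a plain YAML mapping; unknown keys are rejected so a
#' typo cannot silently fall back to a default. The round trip
#' \code{read_config(write_config(cfg, f))} is lossless.
#'
#' @param path File path.
#' @param config A [venus_config()].
#' @return `read_config` returns a \code{venus_config}; `write_config`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("filter", "tailoring_ic50_nm", "penalty_ic50_nm",
             "funnel_ic50_nm", "funnel_tpm", "tpm_floor", "epitope_length",
             "binding_aggregate")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  filt <- if (is.null(raw$filter)) filter_config() else
    do.call(filter_config, raw$filter)
  raw$filter <- NULL
  do.call(venus_config, c(list(filter = filt), raw))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "venus_config"))
  out <- unclass(config)
  out$filter <- unclass(out$filter)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.venus_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  somatic filter: tumor MF >= %.3g, MF ratio >= %.3g, tumor alt reads > %d, normal alt reads < %d\n",
              x$filter$min_tumor_mf, x$filter$min_mf_ratio,
              as.integer(x$filter$min_tumor_alt_reads),
              as.integer(x$filter$max_normal_alt_reads)))
  cat(sprintf("  tailoring IC50 ceiling: %g nM; penalty threshold: %g nM\n",
              x$tailoring_ic50_nm, x$penalty_ic50_nm))
  cat(sprintf("  funnel comparator: IC50 <= %g nM and TPM >= %g\n",
              x$funnel_ic50_nm, x$funnel_tpm))
  cat(sprintf("  WF TPM floor: %g; epitope length: %d; binding aggregate: %s\n",
              x$tpm_floor, x$epitope_length, x$binding_aggregate))
  invisible(x)
}
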