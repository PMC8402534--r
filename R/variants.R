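AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

VARIANT_COLUMNS <- c("variant_id", "chrom", "pos", "ref", "alt",
                     "variant_class", "gene_id", "transcript_id",
                     "protein_pos", "aa_ref", "aa_alt", "tumor_mf",
                     "normal_mf", "tumor_alt_reads", "normal_alt_reads",
                     "callers")

#' Validate a somatic variant table
#'
#' Checks the schema and invariants of a variant table: allele fractions in
#' \code{[0, 1]}, non-negative read counts, unique variant ids, 1-based
#' protein positions, and — for missense records — standard, differing
#' reference and alternate amino acids. Records whose class is neither
#' `missense_snv` nor `frameshift_indel` (synonymous changes, stop gains,
#' in-frame indels, ...) are dropped with a per-record reason, because only
#' missense substitutions and reading-frame-shifting indels generate the
#' candidate peptides this method ranks.
#'
#' @param variants Data frame with the columns listed in the package TSV
#'   dialect (see [read_variant_tsv()]).
#' @return The accepted rows, with attribute `"dropped"`: a data frame of
#'   `variant_id` and `reason` for every rejected record.
#' @export
validate_variants <- function(variants) {
  missing_cols <- setdiff(setdiff(VARIANT_COLUMNS, "callers"),
                          names(variants))
  if (length(missing_cols))
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!"callers" %in% names(variants)) variants$callers <- ""
  if (anyDuplicated(variants$variant_id))
    stop("duplicated variant_id: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  bad_mf <- !is.finite(variants$tumor_mf) | variants$tumor_mf < 0 |
    variants$tumor_mf > 1 | !is.finite(variants$normal_mf) |
    variants$normal_mf < 0 | variants$normal_mf > 1
  if (any(bad_mf))
    stop("allele fraction outside [0, 1] for variant(s): ",
         paste(variants$variant_id[bad_mf], collapse = ", "))
  bad_reads <- variants$tumor_alt_reads < 0 | variants$normal_alt_reads < 0
  if (any(bad_reads))
    stop("negative read count for variant(s): ",
         paste(variants$variant_id[bad_reads], collapse = ", "))

  keep <- rep(TRUE, nrow(variants))
  reason <- character(nrow(variants))
  known <- variants$variant_class %in% c("missense_snv", "frameshift_indel")
  keep[!known] <- FALSE
  reason[!known] <- paste0("unsupported variant class '",
                           variants$variant_class[!known], "'")
  is_mis <- keep & variants$variant_class == "missense_snv"
  bad_aa <- is_mis & (!(variants$aa_ref %in% AA_STANDARD) |
                        !(variants$aa_alt %in% AA_STANDARD) |
                        variants$aa_ref == variants$aa_alt)
  keep[bad_aa] <- FALSE
  reason[bad_aa] <- "missense record without a standard amino-acid change"
  bad_pos <- keep & (!is.finite(variants$protein_pos) | variants$protein_pos < 1)
  keep[bad_pos] <- FALSE
  reason[bad_pos] <- "protein_pos must be a 1-based position"

  out <- variants[keep, , drop = FALSE]
  attr(out, "dropped") <- data.frame(
    variant_id = variants$variant_id[!keep],
    reason = reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Apply the four-criterion somatic filter
#'
#' Evaluates each variant against the somatic selection criteria: tumor MF at
#' least the threshold (default 10\%), tumor/normal MF ratio at least 5
#' (treated as passing when the normal MF is zero), strictly more than 2
#' mutant tumor reads, and strictly fewer than 2 mutant normal reads. All
#' four are evaluated for every variant so the decision lists every failed
#' criterion, not just the first.
#'
#' @param variants Validated variant table (see [validate_variants()]).
#' @param thresholds A [filter_config()].
#' @return Data frame with one row per input variant, in input order:
#'   `variant_id`, `passed`, and `failed_criteria` (comma-joined subset of
#'   `mf_tumor`, `mf_ratio`, `tumor_reads`, `normal_reads`; empty string when
#'   passed).
#' @examples
#' v <- data.frame(variant_id = "v1", tumor_mf = 0.4, normal_mf = 0.1,
#'                 tumor_alt_reads = 3, normal_alt_reads = 1)
#' apply_somatic_filters(v)   # fails mf_ratio only (0.4/0.1 = 4 < 5)
#' @export
apply_somatic_filters <- function(variants, thresholds = filter_config()) {
  stopifnot(inherits(thresholds, "filter_config"))
  need <- c("variant_id", "tumor_mf", "normal_mf", "tumor_alt_reads",
            "normal_alt_reads")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    stop("variant table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !is.finite(variants$tumor_mf) | variants$tumor_mf < 0 |
    variants$tumor_mf > 1 | !is.finite(variants$normal_mf) |
    variants$normal_mf < 0 | variants$normal_mf > 1
  if (any(bad))
    stop("allele fraction outside [0, 1] for variant(s): ",
         paste(variants$variant_id[bad], collapse = ", "))

  ratio <- ifelse(variants$normal_mf == 0, Inf,
                  variants$tumor_mf / variants$normal_mf)
  fails <- cbind(
    mf_tumor     = variants$tumor_mf < thresholds$min_tumor_mf,
    mf_ratio     = ratio < thresholds$min_mf_ratio,
    tumor_reads  = variants$tumor_alt_reads <= thresholds$min_tumor_alt_reads,
    normal_reads = variants$normal_alt_reads >= thresholds$max_normal_alt_reads)
  failed <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  data.frame(variant_id = variants$variant_id,
             passed = !apply(fails, 1L, any),
             failed_criteria = failed,
             stringsAsFactors = FALSE)
}

#' Read and write the variant TSV dialect
#'
#' Tab-separated, header row, UTF-8, 1-based coordinates. Columns:
#' `variant_id, chrom, pos, ref, alt, variant_class, gene_id, transcript_id,
#' protein_pos, aa_ref, aa_alt, tumor_mf, normal_mf, tumor_alt_reads,
#' normal_alt_reads, callers` (comma-joined caller names, provenance only).
#' MF columns are fractions. The reader validates the schema via
#' [validate_variants()] and reports dropped records in the `"dropped"`
#' attribute.
#'
#' @param path File path.
#' @param variants Variant data frame.
#' @return `read_variant_tsv` returns the validated variant data frame.
#' @export
read_variant_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  validate_variants(tab)
}

#' @rdname read_variant_tsv
#' @export
write_variant_tsv <- function(variants, path) {
  utils::write.table(variants[, intersect(c(VARIANT_COLUMNS, "cds_pos"),
                                          names(variants))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read somatic variants from a VCF
#'
#' Maps a somatic VCF onto the variant TSV schema. The accepted dialect is
#' strict and validated rather than guessed: per-sample FORMAT fields `AF`
#' (alternate allele fraction) and `AD` (ref,alt depths) must be present for
#' two samples named by `tumor_sample` and `normal_sample`, and the protein
#' annotation must be carried in INFO keys `GENE`, `TRANSCRIPT`, `PCLASS`
#' (missense_snv | frameshift_indel), `PPOS`, and for missense records
#' `AAREF`/`AAALT`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param tumor_sample,normal_sample Sample column names.
#' @return Validated variant data frame, as from [read_variant_tsv()].
#' @export
read_variant_vcf <- function(path, tumor_sample = "TUMOR",
                             normal_sample = "NORMAL") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(tumor_sample, normal_sample))
    if (!s %in% samples)
      stop("sample '", s, "' not present in VCF (found: ",
           paste(samples, collapse = ", "), ")")
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (all(is.na(x)))
      stop("VCF INFO field '", key, "' is required by the accepted dialect")
    x
  }
  af <- vcfR::extract.gt(v, element = "AF", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(af) || is.null(ad))
    stop("VCF FORMAT fields AF and AD are required by the accepted dialect")
  alt_depth <- function(x) as.integer(vapply(strsplit(x, ","), function(p)
    if (length(p) >= 2) p[2] else NA_character_, character(1)))
  fix <- vcfR::getFIX(v)
  if (!is.matrix(fix))
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pclass <- info_get("PCLASS")
  out <- data.frame(
    variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                        paste0(fix[, "CHROM"], ":", fix[, "POS"], "_",
                               fix[, "REF"], ">", fix[, "ALT"]),
                        fix[, "ID"]),
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    variant_class = pclass,
    gene_id = info_get("GENE"),
    transcript_id = info_get("TRANSCRIPT"),
    protein_pos = as.integer(info_get("PPOS")),
    aa_ref = vcfR::extract.info(v, element = "AAREF"),
    aa_alt = vcfR::extract.info(v, element = "AAALT"),
    tumor_mf = af[, tumor_sample],
    normal_mf = af[, normal_sample],
    tumor_alt_reads = alt_depth(ad[, tumor_sample]),
    normal_alt_reads = alt_depth(ad[, normal_sample]),
    callers = "",
    stringsAsFactors = FALSE)
  out$aa_ref[is.na(out$aa_ref)] <- ""
  out$aa_alt[is.na(out$aa_alt)] <- ""
  validate_variants(out)
}
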