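#' Wild-type protein and CDS context for a transcript
#'
#' Pairs the wild-type protein sequence with its coding nucleotide sequence
#' and checks their consistency: the CDS must be ACGT-only (ambiguity codes
#' reject the transcript), a multiple of three long including the stop
#' codon, and translate (standard genetic code) to the protein followed by a
#' terminal stop.
#'
#' @param transcript_id Transcript identifier.
#' @param protein_seq Wild-type amino-acid sequence (no stop symbol).
#' @param cds_seq Wild-type coding sequence including the stop codon.
#' @return A list of class \code{protein_context}.
#' @export
protein_context <- function(transcript_id, protein_seq, cds_seq) {
  protein_seq <- toupper(protein_seq)
  cds_seq <- toupper(cds_seq)
  if (grepl("[^ACGT]", cds_seq))
    stop("transcript ", transcript_id,
         ": CDS contains non-ACGT (ambiguous) nucleotides")
  if (nchar(cds_seq) %% 3 != 0)
    stop("transcript ", transcript_id, ": CDS length not divisible by 3")
  if (grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), protein_seq))
    stop("transcript ", transcript_id,
         ": protein contains non-standard residues")
  aa <- translate_codons(cds_seq)
  if (aa != paste0(protein_seq, "*"))
    stop("transcript ", transcript_id,
         ": CDS does not translate to the protein plus terminal stop")
  structure(list(transcript_id = transcript_id,
                 protein_seq = protein_seq,
                 cds_seq = cds_seq),
            class = "protein_context")
}

# Standard-code translation of an ACGT string; trailing partial codon is
# dropped (relevant when walking a shifted frame to the transcript end).
translate_codons <- function(nt) {
  n <- nchar(nt) %/% 3
  if (n == 0) return("")
  codons <- substring(nt, 3 * seq_len(n) - 2, 3 * seq_len(n))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

#' Read protein/CDS FASTA files into contexts
#'
#' Record IDs (first whitespace-delimited token of the header) must match
#' between the two files and are used as transcript ids.
#'
#' @param protein_fasta,cds_fasta FASTA paths.
#' @return Named list of [protein_context()] objects keyed by transcript id.
#' @export
read_contexts <- function(protein_fasta, cds_fasta) {
  prot <- Biostrings::readAAStringSet(protein_fasta)
  cds <- Biostrings::readDNAStringSet(cds_fasta)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))
  if (!setequal(names(prot), names(cds)))
    stop("protein and CDS FASTA record ids do not match")
  out <- lapply(names(prot), function(id)
    protein_context(id, as.character(prot[[id]]), as.character(cds[[id]])))
  names(out) <- names(prot)
  out
}

#' Write contexts back to a FASTA pair
#' @param contexts Named list of [protein_context()].
#' @param protein_fasta,cds_fasta Output paths.
#' @return Invisibly, the two paths.
#' @export
write_contexts <- function(contexts, protein_fasta, cds_fasta) {
  prot <- Biostrings::AAStringSet(vapply(contexts, `[[`, "", "protein_seq"))
  cds <- Biostrings::DNAStringSet(vapply(contexts, `[[`, "", "cds_seq"))
  names(prot) <- names(cds) <- vapply(contexts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(prot, protein_fasta)
  Biostrings::writeXStringSet(cds, cds_fasta)
  invisible(c(protein_fasta, cds_fasta))
}

# Sentinel for a peptide discarded by a retention rule, carrying the reason.
discarded <- function(reason) {
  structure(list(reason = reason), class = "discarded")
}

#' Test for a discarded-peptide marker
#'
#' Builders return this marker (rather than a peptide) when a retention
#' rule discards their product; the reason is in `x$reason`.
#'
#' @param x Any object.
#' @return `TRUE` for a marker produced by a retention rule.
#' @export
is_discarded <- function(x) inherits(x, "discarded")

empty_peptides <- function() {
  data.frame(peptide_id = character(), variant_id = character(),
             source = character(), sequence = character(),
             mutated_positions = character(), fsp_parent_id = character(),
             anchor_9mer = character(), stringsAsFactors = FALSE)
}

#' Build the centered 25-mer for a missense variant
#'
#' The mutated residue is flanked by up to 12 wild-type residues on each
#' side, so an untruncated peptide is 25 residues long with the mutation at
#' position 13. Near a protein terminus the flank is truncated; peptides
#' shorter than 9 residues are discarded (a marker testable with
#' [is_discarded()] is returned, carrying the reason).
#'
#' @param variant One-row variant data frame (class `missense_snv`).
#' @param ctx The matching [protein_context()].
#' @return One-row peptide data frame (`peptide_id, variant_id, source,
#'   sequence, mutated_positions, fsp_parent_id, anchor_9mer`) or a
#'   discarded marker.
#' @examples
#' ctx <- protein_context("tx", "MKT", "ATGAAAACTTAA")
#' v <- data.frame(variant_id = "v1", variant_class = "missense_snv",
#'                 transcript_id = "tx", protein_pos = 2,
#'                 aa_ref = "K", aa_alt = "E")
#' # 3-residue protein: truncated peptide "MET" is < 9 aa, so discarded
#' is_discarded(build_snv_25mer(v, ctx))
#' @export
build_snv_25mer <- function(variant, ctx) {
  stopifnot(variant$variant_class == "missense_snv",
            inherits(ctx, "protein_context"))
  wt <- ctx$protein_seq
  pos <- as.integer(variant$protein_pos)
  if (pos > nchar(wt))
    stop("variant ", variant$variant_id, ": protein_pos ", pos,
         " beyond protein length ", nchar(wt))
  if (substr(wt, pos, pos) != variant$aa_ref)
    stop("variant ", variant$variant_id, ": reference residue mismatch (",
         substr(wt, pos, pos), " in protein, aa_ref ", variant$aa_ref, ")")
  from <- max(1L, pos - 12L)
  to <- min(nchar(wt), pos + 12L)
  seq <- paste0(substr(wt, from, pos - 1L), variant$aa_alt,
                substr(wt, pos + 1L, to))
  if (nchar(seq) < 9)
    return(discarded(sprintf("peptide length %d < 9", nchar(seq))))
  data.frame(peptide_id = paste0(variant$variant_id, "_snv"),
             variant_id = variant$variant_id,
             source = "snv_25mer",
             sequence = seq,
             mutated_positions = as.character(pos - from + 1L),
             fsp_parent_id = NA_character_,
             anchor_9mer = NA_character_,
             stringsAsFactors = FALSE)
}

# Locate the VCF-style ref allele of a frameshift record within the codon of
# its first affected residue. An explicit cds_pos field overrides the search.
locate_indel <- function(variant, ctx) {
  if (!is.null(variant$cds_pos) && length(variant$cds_pos) &&
      !is.na(variant$cds_pos))
    return(as.integer(variant$cds_pos))
  codon_start <- (as.integer(variant$protein_pos) - 1L) * 3L + 1L
  ref <- as.character(variant$ref)
  for (p in codon_start:(codon_start + 2L)) {
    if (p + nchar(ref) - 1L <= nchar(ctx$cds_seq) &&
        substr(ctx$cds_seq, p, p + nchar(ref) - 1L) == ref)
      return(p)
  }
  stop("variant ", variant$variant_id,
       ": ref allele not found in the codon of protein_pos ",
       variant$protein_pos, " (CDS/protein inconsistency)")
}

#' Construct the frameshift peptide (FSP) for an indel
#'
#' Applies the indel to the coding sequence, then translates the shifted
#' frame from the first altered codon until the first stop codon (or, when
#' no stop is met, to the transcript end — flagged in attribute
#' `"no_stop"`). The FSP proper (`novel_seq`) starts at the first amino acid
#' that differs from the wild-type protein and excludes the stop. The
#' modified FSP (`modified_seq`) prepends up to 12 wild-type residues.
#' Retention rules: an FSP must have at least 1 novel residue, and the
#' modified FSP at least 9 residues in total; otherwise a discarded marker
#' is returned (see [is_discarded()]), carrying the reason.
#'
#' @param variant One-row variant data frame (class `frameshift_indel`,
#'   VCF-style `ref`/`alt` whose length difference is not a multiple of 3).
#' @param ctx The matching [protein_context()].
#' @return A list of class `frameshift_peptide` with fields `fsp_id`,
#'   `variant_id`, `novel_seq`, `modified_seq`, `wt_prefix_len`, `no_stop`;
#'   or a discarded marker when the retention rules discard it.
#' @export
build_fsp <- function(variant, ctx) {
  stopifnot(variant$variant_class == "frameshift_indel",
            inherits(ctx, "protein_context"))
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  shift <- abs(nchar(ref) - nchar(alt))
  if (shift %% 3 == 0)
    stop("variant ", variant$variant_id,
         ": indel length divisible by 3 does not shift the frame")
  p <- locate_indel(variant, ctx)
  cds <- ctx$cds_seq
  new_cds <- paste0(substr(cds, 1L, p - 1L), alt,
                    substr(cds, p + nchar(ref), nchar(cds)))
  # first nucleotide that differs from the wild-type CDS
  d <- p
  while (d <= min(nchar(cds), nchar(new_cds)) &&
         substr(cds, d, d) == substr(new_cds, d, d)) d <- d + 1L
  c0 <- (d - 1L) %/% 3L + 1L
  tail_nt <- substr(new_cds, (c0 - 1L) * 3L + 1L, nchar(new_cds))
  tail_aa <- translate_codons(tail_nt)
  stop_at <- regexpr("*", tail_aa, fixed = TRUE)
  no_stop <- stop_at < 0
  if (!no_stop) tail_aa <- substr(tail_aa, 1L, stop_at - 1L)
  # trim leading residues identical to the wild type at aligned positions
  wt <- ctx$protein_seq
  skip <- 0L
  while (skip < nchar(tail_aa) && c0 + skip <= nchar(wt) &&
         substr(tail_aa, skip + 1L, skip + 1L) ==
           substr(wt, c0 + skip, c0 + skip)) skip <- skip + 1L
  novel <- substr(tail_aa, skip + 1L, nchar(tail_aa))
  if (nchar(novel) < 1) return(discarded("FSP length 0"))
  first_novel <- c0 + skip            # wild-type coordinate of first novel aa
  prefix <- substr(wt, max(1L, first_novel - 12L), first_novel - 1L)
  modified <- paste0(prefix, novel)
  if (nchar(modified) < 9)
    return(discarded(sprintf("modified FSP length %d < 9", nchar(modified))))
  structure(list(fsp_id = paste0(variant$variant_id, "_fsp"),
                 variant_id = variant$variant_id,
                 novel_seq = novel,
                 modified_seq = modified,
                 wt_prefix_len = nchar(prefix),
                 no_stop = no_stop),
            class = "frameshift_peptide")
}

#' Tailor a modified FSP into 9-mer-anchored 25-mers
#'
#' Enumerates every 9-mer of the modified FSP, keeps those that contain at
#' least one novel (non-wild-type) residue and whose best predicted IC50
#' over the patient's alleles is at or below `threshold_nm`; when no 9-mer
#' qualifies, the single 9-mer with the minimum IC50 is kept so a retained
#' FSP is never silently dropped. Each kept 9-mer is extended by up to 8
#' residues on both sides within the FSP (9 + 8 + 8 = 25), and peptides
#' with identical extended sequences are deduplicated (lowest anchor offset
#' wins).
#'
#' @param fsp A [build_fsp()] result.
#' @param epitope_ic50 Named numeric vector: best IC50 (nM) per 9-mer
#'   sequence. Must cover every novel-residue-containing 9-mer of the FSP.
#' @param threshold_nm IC50 retention ceiling in nM.
#' @return Peptide data frame (possibly 1 row; same columns as
#'   [build_snv_25mer()]), with `anchor_9mer` and `fsp_parent_id` filled.
#' @export
tailor_fsp <- function(fsp, epitope_ic50, threshold_nm = 1000) {
  stopifnot(inherits(fsp, "frameshift_peptide"))
  seq <- fsp$modified_seq
  L <- nchar(seq)
  offsets <- seq_len(L - 8L)
  nine <- substring(seq, offsets, offsets + 8L)
  # a window contains a novel residue iff it reaches past the wt prefix
  has_novel <- offsets + 8L > fsp$wt_prefix_len
  offsets <- offsets[has_novel]
  nine <- nine[has_novel]
  missing <- setdiff(unique(nine), names(epitope_ic50))
  if (length(missing))
    stop("missing IC50 for 9-mer(s) of ", fsp$fsp_id, ": ",
         paste(missing, collapse = ", "))
  ic50 <- unname(epitope_ic50[nine])
  keep <- ic50 <= threshold_nm
  if (!any(keep)) keep <- seq_along(ic50) == which.min(ic50)
  offsets <- offsets[keep]
  nine <- nine[keep]
  rows <- lapply(seq_along(offsets), function(i) {
    o <- offsets[i]
    s <- max(1L, o - 8L)
    e <- min(L, o + 16L)
    novel_local <- seq(s, e)[seq(s, e) > fsp$wt_prefix_len] - s + 1L
    data.frame(peptide_id = paste0(fsp$variant_id, "_a", o),
               variant_id = fsp$variant_id,
               source = "fsp_25mer",
               sequence = substr(seq, s, e),
               mutated_positions = paste(novel_local, collapse = ","),
               fsp_parent_id = fsp$fsp_id,
               anchor_9mer = nine[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out$sequence), , drop = FALSE]
}

#' Enumerate all candidate neo-peptides for a patient
#'
#' Runs [build_snv_25mer()] on missense variants and [build_fsp()] +
#' [tailor_fsp()] on frameshift variants, concatenates the results in a
#' canonical order (by `variant_id`, then `peptide_id`), and removes
#' duplicates by (`variant_id`, `sequence`). Identical sequences arising
#' from different variants are kept separate because their DNA/RNA evidence
#' differs. Peptides from the same FSP are distinct candidates and are
#' ranked independently downstream.
#'
#' @param variants Validated, filtered variant data frame.
#' @param contexts Named list of [protein_context()] keyed by transcript id.
#' @param epitope_ic50 Named numeric vector of best IC50 per 9-mer (needed
#'   only when frameshift variants are present).
#' @param config A [venus_config()].
#' @return Peptide data frame; attribute `"dropped"` records variants that
#'   produced no peptide and why.
#' @export
enumerate_candidates <- function(variants, contexts, epitope_ic50 = NULL,
                                 config = venus_config()) {
  rows <- list()
  dropped <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    ctx <- contexts[[v$transcript_id]]
    if (is.null(ctx))
      stop("variant ", v$variant_id, ": no context for transcript ",
           v$transcript_id)
    if (v$variant_class == "missense_snv") {
      pep <- build_snv_25mer(v, ctx)
      if (is_discarded(pep)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(variant_id = v$variant_id, reason = pep$reason,
                     stringsAsFactors = FALSE)
      } else rows[[length(rows) + 1L]] <- pep
    } else {
      fsp <- build_fsp(v, ctx)
      if (is_discarded(fsp)) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(variant_id = v$variant_id, reason = fsp$reason,
                     stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <-
          tailor_fsp(fsp, epitope_ic50, config$tailoring_ic50_nm)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_peptides()
  out <- out[order(out$variant_id, out$peptide_id), , drop = FALSE]
  out <- out[!duplicated(out[, c("variant_id", "sequence")]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  out
}

# 1-based integer vector from a comma-joined mutated_positions field
parse_positions <- function(x) as.integer(strsplit(x, ",")[[1]])

# All epitopes of a peptide that contain at least one mutated residue
mutant_epitopes <- function(sequence, mutated_positions, epitope_length = 9L) {
  L <- nchar(sequence)
  if (L < epitope_length) return(character())
  offsets <- seq_len(L - epitope_length + 1L)
  mut <- parse_positions(mutated_positions)
  keep <- vapply(offsets, function(o)
    any(mut >= o & mut <= o + epitope_length - 1L), logical(1))
  unique(substring(sequence, offsets[keep],
                   offsets[keep] + epitope_length - 1L))
}

#' Enumerate the epitope/allele queries for an external predictor
#'
#' Lists every mutant-containing epitope of every candidate peptide crossed
#' with the patient's alleles — the query table to submit to an MHC class-I
#' binding predictor. Only epitopes comprising a non-wild-type residue are
#' queried.
#'
#' @param peptides Peptide data frame from [enumerate_candidates()].
#' @param alleles Character vector of HLA class-I alleles.
#' @param epitope_length Epitope length (default 9).
#' @return Data frame `peptide_id, epitope_seq, allele`.
#' @export
enumerate_epitope_queries <- function(peptides, alleles,
                                      epitope_length = 9L) {
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    eps <- mutant_epitopes(peptides$sequence[i],
                           peptides$mutated_positions[i], epitope_length)
    if (!length(eps)) return(NULL)
    expand.grid(peptide_id = peptides$peptide_id[i], epitope_seq = eps,
                allele = alleles, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide_id = character(), epitope_seq = character(),
                      allele = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
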