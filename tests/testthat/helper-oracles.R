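# Independent brute-force oracles and small fixture builders.

# Evaluate the four somatic-filter predicates one variant at a time,
# straight from their definitions.
filter_oracle <- function(v, cfg = filter_config()) {
  vapply(seq_len(nrow(v)), function(i) {
    ok_mf <- v$tumor_mf[i] >= cfg$min_tumor_mf
    ok_ratio <- if (v$normal_mf[i] == 0) TRUE else
      v$tumor_mf[i] / v$normal_mf[i] >= cfg$min_mf_ratio
    ok_t <- v$tumor_alt_reads[i] > cfg$min_tumor_alt_reads
    ok_n <- v$normal_alt_reads[i] < cfg$max_normal_alt_reads
    ok_mf && ok_ratio && ok_t && ok_n
  }, logical(1))
}

# Exhaustive-comparison rank-and-sum oracle: competition ranks by counting
# strictly better candidates, then the weighted rank sum and the total
# order, all by explicit loops.
rsum_oracle <- function(tab, penalty_threshold = 1000) {
  n <- nrow(tab)
  cnt_rank <- function(values, better) vapply(seq_len(n), function(i)
    1L + sum(vapply(seq_len(n), function(j) better(values[j], values[i]),
                    logical(1))), integer(1))
  r_freq <- cnt_rank(tab$tumor_mf, function(a, b) a > b)
  r_expr <- cnt_rank(tab$corr_tpm, function(a, b) a > b)
  r_ic50 <- cnt_rank(tab$best_ic50_nm, function(a, b) a < b)
  k <- ifelse(tab$best_ic50_nm > penalty_threshold, n, 0L)
  rsum <- (r_freq + r_expr + (k + r_ic50)) * tab$wf
  ord <- order(rsum, tab$best_ic50_nm, tab$peptide_id)
  data.frame(peptide_id = tab$peptide_id[ord],
             r_freq = r_freq[ord], r_expr = r_expr[ord],
             r_ic50 = r_ic50[ord], k = k[ord], rsum = rsum[ord],
             final_position = seq_len(n), stringsAsFactors = FALSE)
}

random_variant_table <- function(n) {
  data.frame(variant_id = sprintf("rv%05d", seq_len(n)),
             tumor_mf = round(runif(n), 3),
             normal_mf = round(runif(n) * rbinom(n, 1, 0.5), 3),
             tumor_alt_reads = rpois(n, 4),
             normal_alt_reads = rpois(n, 0.8),
             stringsAsFactors = FALSE)
}

random_candidate_table <- function(n) {
  data.frame(peptide_id = sprintf("pep%02d", sample(n)),
             tumor_mf = round(runif(n), 2),
             corr_tpm = round(rlnorm(n), 2),
             tpm = round(rlnorm(n), 2),
             wf = sample(1:5, n, replace = TRUE),
             best_ic50_nm = round(10^runif(n, 0, 4.5), 1),
             stringsAsFactors = FALSE)
}

# A deterministic 30-residue protein with a consistent CDS, for index
# arithmetic checks (no repeated residues in any local window).
fixed_context_30 <- function() {
  protein <- "MARNDCEQGHILKFPSTWYVARNDCEQGHI"
  code <- Biostrings::GENETIC_CODE
  codons <- vapply(strsplit(protein, "")[[1]],
                   function(a) names(code)[code == a][1], character(1))
  protein_context("tx30", protein, paste(c(codons, "TAA"), collapse = ""))
}

missense_row <- function(id, pos, aa_ref, aa_alt, tx = "tx30") {
  data.frame(variant_id = id, variant_class = "missense_snv",
             transcript_id = tx, protein_pos = pos, aa_ref = aa_ref,
             aa_alt = aa_alt, stringsAsFactors = FALSE)
}
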