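test_that("missense 25-mer is centered with truncation at the termini", {
  ctx <- fixed_context_30()
  wt <- ctx$protein_seq

  # interior mutation: full 25-mer covering wild-type positions 3..27,
  # mutant residue at peptide position 13
  p <- build_snv_25mer(missense_row("v1", 15, substr(wt, 15, 15), "T"), ctx)
  expect_equal(nchar(p$sequence), 25)
  expect_equal(p$sequence,
               paste0(substr(wt, 3, 14), "T", substr(wt, 16, 27)))
  expect_equal(p$mutated_positions, "13")

  # mutation at the first residue: no upstream flank, 13-mer
  p1 <- build_snv_25mer(missense_row("v2", 1, "M", "L"), ctx)
  expect_equal(p1$sequence, paste0("L", substr(wt, 2, 13)))
  expect_equal(p1$mutated_positions, "1")

  # position 5: 4 upstream + 1 + 12 downstream = 17-mer
  p5 <- build_snv_25mer(missense_row("v3", 5, substr(wt, 5, 5), "W"), ctx)
  expect_equal(nchar(p5$sequence), 17)
  expect_equal(p5$mutated_positions, "5")

  # non-mutated positions recover the wild type exactly
  mut_at <- as.integer(p$mutated_positions)
  for (i in setdiff(seq_len(25), mut_at))
    expect_equal(substr(p$sequence, i, i), substr(wt, i + 2, i + 2))
})

test_that("reference mismatch and short products are handled", {
  ctx <- fixed_context_30()
  expect_error(build_snv_25mer(missense_row("v1", 15, "Q", "T"), ctx),
               "reference residue mismatch")
  tiny <- protein_context("tx", "MKT", "ATGAAAACTTAA")
  short <- build_snv_25mer(missense_row("v2", 2, "K", "E", "tx"), tiny)
  expect_true(is_discarded(short))
  expect_match(short$reason, "< 9")
})

test_that("frameshift translation matches an independent re-translation", {
  # oracle: apply the indel by string surgery, translate the whole mutant
  # CDS with Biostrings from codon 1, and read the tail off the full
  # protein string
  for (seed in 1:20) {
    ctx <- generate_toy_cds(60, seed = seed)
    set.seed(seed + 1000)
    ppos <- sample(5:40, 1)
    cpos <- (ppos - 1) * 3 + 1
    ref <- substr(ctx$cds_seq, cpos, cpos + 1)
    alt <- substr(ctx$cds_seq, cpos, cpos)          # 1-nt deletion
    v <- data.frame(variant_id = paste0("fs", seed),
                    variant_class = "frameshift_indel", ref = ref,
                    alt = alt, protein_pos = ppos, cds_pos = cpos,
                    stringsAsFactors = FALSE)
    fsp <- build_fsp(v, ctx)

    mut_cds <- paste0(substr(ctx$cds_seq, 1, cpos - 1), alt,
                      substr(ctx$cds_seq, cpos + nchar(ref),
                             nchar(ctx$cds_seq)))
    usable <- 3 * (nchar(mut_cds) %/% 3)
    full <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(mut_cds, 1, usable))))
    stop_at <- regexpr("*", full, fixed = TRUE)
    if (stop_at > 0) full <- substr(full, 1, stop_at - 1)
    # expected novel tail: longest suffix of `full` differing from wt
    wt <- ctx$protein_seq
    first_diff <- 1
    while (first_diff <= min(nchar(full), nchar(wt)) &&
           substr(full, first_diff, first_diff) ==
             substr(wt, first_diff, first_diff)) first_diff <- first_diff + 1
    expected_novel <- substr(full, first_diff, nchar(full))

    if (nchar(expected_novel) == 0) {
      expect_true(is_discarded(fsp))
    } else if (!is_discarded(fsp)) {
      expect_equal(fsp$novel_seq, expected_novel)
      expect_equal(fsp$modified_seq,
                   paste0(substr(wt, max(1, first_diff - 12),
                                 first_diff - 1), expected_novel))
      expect_true(endsWith(fsp$modified_seq, fsp$novel_seq))
    } else {
      expect_match(fsp$reason, "< 9")   # only short products may be dropped
      expect_lt(min(12, first_diff - 1) + nchar(expected_novel), 9)
    }
  }
})

test_that("frameshift retention rules discard empty and short products", {
  # deletion turns codon 2 into an immediate stop: no novel residue
  ctx <- protein_context("t1", "MMN", "ATGATGAACTAA")
  fsp0 <- build_fsp(data.frame(variant_id = "f0",
                               variant_class = "frameshift_indel",
                               ref = "GA", alt = "G", protein_pos = 2,
                               cds_pos = 3, stringsAsFactors = FALSE), ctx)
  expect_true(is_discarded(fsp0))
  expect_equal(fsp0$reason, "FSP length 0")

  # insertion at codon 3 of a 3-residue protein: 2 wt + 2 novel = 4 < 9
  ctx2 <- protein_context("t2", "MKP", "ATGAAACCCTAA")
  fsp4 <- build_fsp(data.frame(variant_id = "f4",
                               variant_class = "frameshift_indel",
                               ref = "C", alt = "CA", protein_pos = 3,
                               cds_pos = 7, stringsAsFactors = FALSE), ctx2)
  expect_true(is_discarded(fsp4))
  expect_match(fsp4$reason, "length 4 < 9")

  # in-frame indel is a usage error
  expect_error(build_fsp(data.frame(variant_id = "f3",
                                    variant_class = "frameshift_indel",
                                    ref = "AAAA", alt = "A", protein_pos = 2,
                                    cds_pos = 4, stringsAsFactors = FALSE),
                         ctx), "divisible by 3")
})

test_that("tailoring keeps binding mutant 9-mers and extends to 25-mers", {
  # modified FSP of length 19 = 12 wild-type + 7 novel residues
  fsp <- structure(list(fsp_id = "fx_fsp", variant_id = "fx",
                        novel_seq = "KNDCEQG",
                        modified_seq = "MARNDCEQGHILKNDCEQG",
                        wt_prefix_len = 12L, no_stop = FALSE),
                   class = "frameshift_peptide")
  seqs <- substring(fsp$modified_seq, 1:11, 9:19)
  # 11 total 9-mers; those starting at offsets 5..11 reach the novel tail
  expect_length(seqs, 11)

  ic50 <- setNames(rep(2000, 11), seqs)
  ic50[seqs[5]] <- 100     # only one anchor below the ceiling
  out <- tailor_fsp(fsp, ic50, threshold_nm = 1000)
  expect_equal(nrow(out), 1)
  expect_equal(out$anchor_9mer, seqs[5])
  # offset 5 extended by 8 on both sides, clipped to the 19-mer
  expect_equal(out$sequence, fsp$modified_seq)
  expect_equal(out$peptide_id, "fx_a5")
  # novel residues are positions 13..19 of the full 19-mer
  expect_equal(out$mutated_positions, paste(13:19, collapse = ","))

  # all anchors above the threshold: best-anchor fallback keeps exactly one
  ic50_all_high <- setNames(seq(1500, 2500, length.out = 11), seqs)
  fb <- tailor_fsp(fsp, ic50_all_high, threshold_nm = 1000)
  expect_equal(nrow(fb), 1)
  expect_equal(fb$anchor_9mer, seqs[5])   # the minimum-IC50 anchor

  # with an infinite ceiling every mutant-containing 9-mer is kept
  # (deduplicated by extended sequence)
  all_kept <- tailor_fsp(fsp, ic50_all_high, threshold_nm = Inf)
  n_mut <- sum(1:11 + 8 > 12)
  expect_equal(n_mut, 7)
  expect_lte(nrow(all_kept), n_mut)
  expect_true(all(nchar(all_kept$sequence) >= 9 &
                    nchar(all_kept$sequence) <= 25))

  # a missing 9-mer is an explicit error naming it
  expect_error(tailor_fsp(fsp, ic50[-5], threshold_nm = 1000), seqs[5])
})

test_that("candidate enumeration is additive, deterministic and mutant-only", {
  ctx <- fixed_context_30()
  wt <- ctx$protein_seq
  fs_ctx <- generate_toy_cds(80, seed = 3, transcript_id = "txfs")
  vars <- data.frame(
    variant_id = c("s1", "s2", "f1"),
    variant_class = c("missense_snv", "missense_snv", "frameshift_indel"),
    transcript_id = c("tx30", "tx30", "txfs"),
    protein_pos = c(15, 20, 20),
    aa_ref = c(substr(wt, 15, 15), substr(wt, 20, 20), ""),
    aa_alt = c("T", "M", ""),
    ref = c("A", "A", substr(fs_ctx$cds_seq, 58, 59)),
    alt = c("T", "T", substr(fs_ctx$cds_seq, 58, 58)),
    cds_pos = c(NA, NA, 58),
    stringsAsFactors = FALSE)
  contexts <- list(tx30 = ctx, txfs = fs_ctx)
  fsp <- build_fsp(vars[3, ], fs_ctx)
  offs <- seq_len(nchar(fsp$modified_seq) - 8)
  nine <- substring(fsp$modified_seq, offs, offs + 8)
  ic50 <- setNames(rep(100, length(nine)), nine)

  peps <- enumerate_candidates(vars, contexts, ic50)
  expect_equal(sum(peps$source == "snv_25mer"), 2)
  expect_gte(sum(peps$source == "fsp_25mer"), 1)

  # reordering the input leaves the canonical output unchanged
  peps2 <- enumerate_candidates(vars[c(3, 1, 2), ], contexts, ic50)
  attr(peps, "dropped") <- attr(peps2, "dropped") <- NULL
  expect_equal(peps, peps2)

  # every peptide carries at least one non-wild-type residue
  expect_true(all(nchar(peps$mutated_positions) > 0))
  expect_true(all(nchar(peps$sequence) >= 9 & nchar(peps$sequence) <= 25))

  # epitope queries cover only mutant-containing 9-mers
  q <- enumerate_epitope_queries(peps[peps$peptide_id == "s1_snv", ],
                                 alleles = c("HLA-A*02:01", "HLA-B*07:02"))
  expect_equal(nrow(q), 9 * 2)   # interior mutation: 9 windows x 2 alleles
  expect_true(all(vapply(q$epitope_seq, function(e)
    grepl("T", e, fixed = TRUE), logical(1))))
})

test_that("FASTA context pairs round-trip and are validated", {
  ctxs <- list(a = generate_toy_cds(30, 1, "a"),
               b = generate_toy_cds(40, 2, "b"))
  pf <- tempfile(fileext = ".fasta"); cf <- tempfile(fileext = ".fasta")
  write_contexts(ctxs, pf, cf)
  back <- read_contexts(pf, cf)
  expect_equal(back, ctxs)
  expect_error(protein_context("x", "MK", "ATGAANTAA"), "ambiguous")
  expect_error(protein_context("x", "MK", "ATGTTTTAA"),
               "does not translate")
})
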