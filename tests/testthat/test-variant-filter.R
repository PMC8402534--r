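test_that("each filter criterion fires on its own evidence", {
  v <- data.frame(
    variant_id = c("low_mf", "clean", "ratio4", "few_reads", "normal_contam"),
    tumor_mf = c(0.09, 0.50, 0.40, 0.30, 0.45),
    normal_mf = c(0, 0.0, 0.10, 0.0, 0.0),
    tumor_alt_reads = c(10, 20, 3, 2, 15),
    normal_alt_reads = c(0, 0, 1, 0, 2),
    stringsAsFactors = FALSE)
  d <- apply_somatic_filters(v)
  expect_equal(d$variant_id, v$variant_id)  # order-preserving
  expect_equal(d$passed, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(d$failed_criteria,
               c("mf_tumor", "", "mf_ratio", "tumor_reads", "normal_reads"))
})

test_that("boundary values behave exactly as configured", {
  at <- function(mf, nmf, tr, nr) apply_somatic_filters(data.frame(
    variant_id = "b", tumor_mf = mf, normal_mf = nmf,
    tumor_alt_reads = tr, normal_alt_reads = nr))$passed
  expect_true(at(0.10, 0, 3, 0))    # MF exactly at threshold passes
  expect_false(at(0.0999, 0, 3, 0))
  expect_true(at(0.5, 0.1, 3, 0))   # ratio exactly 5 passes
  expect_true(at(0.3, 0, 3, 1))     # 1 normal read tolerated
  expect_false(at(0.3, 0, 3, 2))    # 2 normal reads rejected
  expect_false(at(0.3, 0, 2, 0))    # tumor reads strictly > 2
})

test_that("zero normal MF makes the ratio criterion pass", {
  d <- apply_somatic_filters(data.frame(
    variant_id = "z", tumor_mf = 0.5, normal_mf = 0,
    tumor_alt_reads = 20, normal_alt_reads = 0))
  expect_true(d$passed)
})

test_that("filter matches independent predicate evaluation on random variants", {
  set.seed(11)
  v <- random_variant_table(2000)
  d <- apply_somatic_filters(v)
  expect_equal(d$passed, filter_oracle(v))
  # survivors as a set
  expect_setequal(d$variant_id[d$passed], v$variant_id[filter_oracle(v)])
})

test_that("raising tumor MF never flips a variant from passed to failed", {
  set.seed(12)
  v <- random_variant_table(300)
  base <- apply_somatic_filters(v)$passed
  v2 <- v
  v2$tumor_mf <- pmin(1, v$tumor_mf + runif(300, 0, 0.5))
  # keep the ratio criterion monotone too: raising tumor MF only raises it
  raised <- apply_somatic_filters(v2)$passed
  expect_true(all(raised[base]))
})

test_that("malformed fractions are rejected naming the variant", {
  v <- data.frame(variant_id = c("ok", "bad"), tumor_mf = c(0.5, 1.2),
                  normal_mf = c(0, 0), tumor_alt_reads = c(5, 5),
                  normal_alt_reads = c(0, 0))
  expect_error(apply_somatic_filters(v), "bad")
})

test_that("unsupported variant classes are dropped at ingestion with a reason", {
  v <- data.frame(
    variant_id = c("m1", "syn1", "fs1"),
    chrom = "1", pos = 1:3, ref = "A", alt = "T",
    variant_class = c("missense_snv", "synonymous", "frameshift_indel"),
    gene_id = "g", transcript_id = "tx", protein_pos = 5,
    aa_ref = c("A", "", ""), aa_alt = c("T", "", ""),
    tumor_mf = 0.4, normal_mf = 0, tumor_alt_reads = 9,
    normal_alt_reads = 0, callers = "c1", stringsAsFactors = FALSE)
  out <- validate_variants(v)
  expect_setequal(out$variant_id, c("m1", "fs1"))
  dropped <- attr(out, "dropped")
  expect_equal(dropped$variant_id, "syn1")
  expect_match(dropped$reason, "unsupported variant class")
})

test_that("variant TSV round-trips through the dialect", {
  v <- data.frame(
    variant_id = c("a", "b"), chrom = c("1", "X"), pos = c(100L, 200L),
    ref = c("A", "CT"), alt = c("G", "C"),
    variant_class = c("missense_snv", "frameshift_indel"),
    gene_id = "g1", transcript_id = "t1", protein_pos = c(7L, 9L),
    aa_ref = c("K", ""), aa_alt = c("E", ""),
    tumor_mf = c(0.25, 0.5), normal_mf = c(0, 0.01),
    tumor_alt_reads = c(12L, 30L), normal_alt_reads = c(0L, 1L),
    callers = c("mutect2,varscan2", "scalpel"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_variant_tsv(v, f)
  back <- read_variant_tsv(f)
  attr(back, "dropped") <- NULL
  expect_equal(back, v)
})

test_that("the VCF dialect maps onto the variant schema", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description=\"Transcript\">",
    "##INFO=<ID=PCLASS,Number=1,Type=String,Description=\"Class\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"Protein pos\">",
    "##INFO=<ID=AAREF,Number=1,Type=String,Description=\"Ref aa\">",
    "##INFO=<ID=AAALT,Number=1,Type=String,Description=\"Alt aa\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    paste0("chr7\t140753336\tvar1\tA\tT\t.\tPASS\t",
           "GENE=BRAF;TRANSCRIPT=tx_braf;PCLASS=missense_snv;PPOS=600;",
           "AAREF=V;AAALT=E\tAF:AD\t0.42:29,21\t0:40,0")), f)
  v <- read_variant_vcf(f)
  expect_equal(v$variant_id, "var1")
  expect_equal(v$variant_class, "missense_snv")
  expect_equal(v$tumor_mf, 0.42)
  expect_equal(v$normal_mf, 0)
  expect_equal(v$tumor_alt_reads, 21L)
  expect_equal(v$normal_alt_reads, 0L)
  expect_equal(v$protein_pos, 600L)
  expect_true(apply_somatic_filters(v)$passed)
  expect_error(read_variant_vcf(f, tumor_sample = "nope"), "nope")
})
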