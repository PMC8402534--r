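# Run expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

HLA_POOL <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-B*08:01",
              "HLA-C*07:01", "HLA-C*07:02")

#' Specification of a synthetic patient cohort
#'
#' Parameters of the seeded cohort generator. The defaults emulate the
#' statistical structure the score assumes in a typical solid-tumor
#' patient: per-patient candidate lists of a few hundred neo-peptides
#' (around the published per-patient median after filtering and frameshift
#' expansion), tumor MF spread over subclonal-to-clonal values
#' (Beta(2, 5)), gene TPM log-normal over four orders of magnitude, RNA
#' locus coverage Poisson in the TPM, and predicted IC50 drawn from a
#' binder / weak-binder / non-binder mixture in which most candidates are
#' non-binders. A small minority of implanted "true" neoantigens receive
#' jointly favorable draws: upper-quartile-and-above MF and TPM quantiles,
#' guaranteed mutant RNA support, and favorable IC50 (log-uniform 50--900
#' nM — mostly strong binders, occasionally weak ones above the fixed
#' 500 nM funnel threshold). The distribution families are generator
#' conventions, not estimates from any real cohort.
#'
#' @param seed Integer master seed; patient p uses `seed + p`.
#' @param n_patients Number of patients.
#' @param n_variants_per_patient Somatic variants drawn per patient (before
#'   the somatic filter).
#' @param frac_frameshift Fraction of variants that are frameshift indels.
#' @param n_implanted_true Implanted true neoantigens per patient (always
#'   missense, always passing the somatic filter).
#' @param mf_shape1,mf_shape2 Beta parameters of the background tumor MF.
#' @param implant_mf_q Quantile window of the MF distribution from which
#'   implanted MF is drawn.
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of gene TPM.
#' @param implant_tpm_q Quantile window for implanted TPM.
#' @param ic50_weights Mixture weights, in order: binder (< 500 nM,
#'   log-uniform 1--500), weak (uniform 500--1000), non-binder (log-uniform
#'   1000--50000).
#' @param implant_ic50_range IC50 range (nM) for implanted neoantigens,
#'   drawn log-uniformly.
#' @param n_alleles HLA class-I alleles sampled per patient from a fixed
#'   pool.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L,
                        n_patients = 9L,
                        n_variants_per_patient = 267L,
                        frac_frameshift = 0.05,
                        n_implanted_true = 5L,
                        mf_shape1 = 2, mf_shape2 = 5,
                        implant_mf_q = c(0.75, 0.95),
                        tpm_meanlog = 0.5, tpm_sdlog = 1.8,
                        implant_tpm_q = c(0.70, 0.95),
                        ic50_weights = c(binder = 0.15, weak = 0.10,
                                         nonbinder = 0.75),
                        implant_ic50_range = c(50, 900),
                        n_alleles = 3L) {
  stopifnot(n_patients >= 1, n_variants_per_patient >= 1,
            frac_frameshift >= 0, frac_frameshift <= 1,
            n_implanted_true >= 0,
            n_implanted_true <= n_variants_per_patient,
            length(ic50_weights) == 3, all(ic50_weights >= 0),
            sum(ic50_weights) > 0,
            all(implant_mf_q >= 0 & implant_mf_q <= 1),
            all(implant_tpm_q >= 0 & implant_tpm_q <= 1),
            all(implant_ic50_range > 0), n_alleles >= 1,
            n_alleles <= length(HLA_POOL))
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 n_variants_per_patient = as.integer(n_variants_per_patient),
                 frac_frameshift = frac_frameshift,
                 n_implanted_true = as.integer(n_implanted_true),
                 mf_shape1 = mf_shape1, mf_shape2 = mf_shape2,
                 implant_mf_q = implant_mf_q,
                 tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
                 implant_tpm_q = implant_tpm_q,
                 ic50_weights = ic50_weights / sum(ic50_weights),
                 implant_ic50_range = implant_ic50_range,
                 n_alleles = as.integer(n_alleles)),
            class = "cohort_spec")
}

# One draw per variant of the statistical quantities the score consumes.
# Row order: implanted truths first, then background. Callers seed the RNG.
draw_variant_stats <- function(n, n_true, spec) {
  stopifnot(n_true <= n)
  mf <- stats::rbeta(n, spec$mf_shape1, spec$mf_shape2)
  normal_mf <- ifelse(stats::runif(n) < 0.9, 0, stats::runif(n, 0, 0.08))
  tumor_alt <- stats::rpois(n, 100 * mf)
  normal_alt <- ifelse(stats::runif(n) < 0.92, 0L,
                       sample(1:3, n, replace = TRUE))
  tpm <- stats::rlnorm(n, spec$tpm_meanlog, spec$tpm_sdlog)
  tot <- stats::rpois(n, pmin(tpm, 200))
  rna_mut <- stats::rbinom(n, tot, mf)
  rna_wt <- tot - rna_mut
  regime <- sample(1:3, n, replace = TRUE, prob = spec$ic50_weights)
  ic50 <- ifelse(regime == 1, 10^stats::runif(n, 0, log10(500)),
          ifelse(regime == 2, stats::runif(n, 500, 1000),
                 10^stats::runif(n, 3, log10(50000))))
  if (n_true > 0) {
    idx <- seq_len(n_true)
    mf[idx] <- stats::qbeta(stats::runif(n_true, spec$implant_mf_q[1],
                                         spec$implant_mf_q[2]),
                            spec$mf_shape1, spec$mf_shape2)
    normal_mf[idx] <- 0
    tumor_alt[idx] <- pmax(3L, stats::rpois(n_true, 100 * mf[idx]))
    normal_alt[idx] <- 0L
    tpm[idx] <- stats::qlnorm(stats::runif(n_true, spec$implant_tpm_q[1],
                                           spec$implant_tpm_q[2]),
                              spec$tpm_meanlog, spec$tpm_sdlog)
    rna_mut[idx] <- 1L + stats::rpois(n_true, pmax(1, tpm[idx] / 4))
    rna_wt[idx] <- stats::rpois(n_true,
                                rna_mut[idx] / mf[idx] * (1 - mf[idx]))
    ic50[idx] <- 10^stats::runif(n_true, log10(spec$implant_ic50_range[1]),
                                 log10(spec$implant_ic50_range[2]))
  }
  data.frame(tumor_mf = mf, normal_mf = normal_mf,
             tumor_alt_reads = tumor_alt, normal_alt_reads = normal_alt,
             tpm = tpm, rna_mut_reads = rna_mut, rna_wt_reads = rna_wt,
             best_ic50_nm = ic50,
             is_true = seq_len(n) <= n_true)
}

#' Simulate one patient's candidate table directly
#'
#' The fast, sequence-free route to a scored input: draws the per-variant
#' statistics of [cohort_spec()] (one candidate peptide per variant),
#' applies the somatic filter, and returns the surviving candidates with
#' `corr_tpm` and `wf` computed — ready for [venus_score()] or
#' [rank_alternative()]. Implanted truths are constructed to pass the
#' filter; the `is_true` column marks them.
#'
#' @param spec A [cohort_spec()]; `n_variants_per_patient` and
#'   `n_implanted_true` set the table size.
#' @param seed Seed for this patient (defaults to `spec$seed`).
#' @return Candidate data frame with columns `peptide_id, variant_id,
#'   tumor_mf, tpm, rna_mut_reads, rna_wt_reads, corr_tpm, wf,
#'   best_ic50_nm, is_true`.
#' @export
simulate_candidates <- function(spec = cohort_spec(), seed = spec$seed) {
  with_seed(seed, {
    n <- spec$n_variants_per_patient
    stats_tab <- draw_variant_stats(n, spec$n_implanted_true, spec)
    stats_tab$variant_id <- sprintf("v%03d", seq_len(n))
    stats_tab$peptide_id <- paste0(stats_tab$variant_id, "_snv")
    decisions <- apply_somatic_filters(stats_tab)
    out <- stats_tab[decisions$passed, , drop = FALSE]
    out$corr_tpm <- corr_tpm(out$tpm, out$rna_mut_reads, out$rna_wt_reads)
    out$wf <- weighting_factor(out$tpm, out$rna_mut_reads, out$rna_wt_reads)
    rownames(out) <- NULL
    out[, c("peptide_id", "variant_id", "tumor_mf", "tpm", "rna_mut_reads",
            "rna_wt_reads", "corr_tpm", "wf", "best_ic50_nm", "is_true")]
  })
}

#' Generate a random toy coding sequence
#'
#' An ATG start, `n_codons - 2` random sense codons, and a random stop
#' codon; the matching protein has `n_codons - 1` residues. Used as the
#' substrate for peptide-construction tests and by the cohort generator.
#'
#' @param n_codons Total codons including start and stop (>= 10).
#' @param seed Integer seed; the result is a pure function of it.
#' @param transcript_id Id for the returned context.
#' @return A [protein_context()].
#' @export
generate_toy_cds <- function(n_codons, seed = 1L,
                             transcript_id = paste0("tx", seed)) {
  stopifnot(n_codons >= 10)
  with_seed(seed, {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    stops <- names(code)[code == "*"]
    body <- sample(sense, n_codons - 2L, replace = TRUE)
    cds <- paste(c("ATG", body, sample(stops, 1L)), collapse = "")
    protein_context(transcript_id, translate_codons(
      substr(cds, 1L, nchar(cds) - 3L)), cds)
  })
}

# Assign per-epitope IC50s so that the peptide-level best equals `best`:
# one anchor epitope carries `best` on the patient's first allele; every
# other (epitope, allele) pair is scaled upward from it.
assign_epitope_ic50 <- function(epitopes, alleles, best) {
  anchor <- sample(seq_along(epitopes), 1L)
  rows <- expand.grid(epitope_seq = epitopes, allele = alleles,
                      stringsAsFactors = FALSE)
  up <- 10^stats::runif(nrow(rows), 0.3, 1.5)
  ic50 <- pmin(50000, best * up)
  ic50[rows$epitope_seq == epitopes[anchor] & rows$allele == alleles[1]] <-
    best
  rows$ic50_nm <- ic50
  rows
}

#' Generate a complete on-disk synthetic cohort
#'
#' Writes, per patient, the full input bundle the pipeline consumes —
#' variant TSV, protein/CDS FASTA pair, expression TSV, prediction TSV —
#' plus a truth TSV naming the implanted true neoantigens, and a cohort
#' manifest (YAML) recording the generator settings and per-patient seeds.
#' Every variant sits on its own toy transcript; predicted IC50s are assigned so each
#' candidate's best mutant-containing epitope equals its drawn peptide-level
#' IC50. The same spec (including seed) reproduces the bundle byte for
#' byte.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a data frame of per-patient file paths.
#' @export
generate_cohort <- function(spec = cohort_spec(), dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(spec = lapply(unclass(spec), unname), patients = list())
  paths <- list()
  for (p in seq_len(spec$n_patients)) {
    pid <- sprintf("P%02d", p)
    pseed <- spec$seed + p
    files <- with_seed(pseed, write_patient_bundle(spec, pid, dir))
    manifest$patients[[pid]] <- list(seed = pseed)
    paths[[pid]] <- files
  }
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  out <- do.call(rbind, lapply(names(paths), function(pid)
    data.frame(patient_id = pid, t(paths[[pid]]),
               stringsAsFactors = FALSE)))
  invisible(out)
}

# Everything for one patient; RNG already seeded by the caller.
write_patient_bundle <- function(spec, pid, dir) {
  n <- spec$n_variants_per_patient
  n_true <- spec$n_implanted_true
  stats_tab <- draw_variant_stats(n, n_true, spec)
  alleles <- sample(HLA_POOL, spec$n_alleles)

  is_fs <- stats_tab$is_true == FALSE &
    stats::runif(n) < spec$frac_frameshift
  contexts <- list()
  vrows <- list()
  erows <- list()
  prows <- list()
  trows <- list()
  for (i in seq_len(n)) {
    vid <- sprintf("%s_v%03d", pid, i)
    txid <- paste0(vid, "_tx")
    gid <- paste0(vid, "_g")
    ctx <- generate_toy_cds(sample(60:200, 1L),
                            seed = sample.int(2^30, 1L),
                            transcript_id = txid)
    contexts[[txid]] <- ctx
    plen <- nchar(ctx$protein_seq)
    if (!is_fs[i]) {
      ppos <- sample(2:plen, 1L)
      aa_ref <- substr(ctx$protein_seq, ppos, ppos)
      aa_alt <- sample(setdiff(AA_STANDARD, aa_ref), 1L)
      cpos <- (ppos - 1L) * 3L + 1L
      code <- Biostrings::GENETIC_CODE
      ref_nt <- substr(ctx$cds_seq, cpos, cpos + 2L)
      alt_nt <- sample(names(code)[code == aa_alt], 1L)
      vclass <- "missense_snv"
      cds_pos <- NA_integer_
    } else {
      # frameshift: 1-2 nt indel anchored at a codon start, away from the
      # termini so some novel sequence can be translated
      ppos <- sample(5:max(5L, plen - 10L), 1L)
      cpos <- (ppos - 1L) * 3L + 1L
      shift <- sample(1:2, 1L)
      if (stats::runif(1) < 0.5) {   # deletion
        ref_nt <- substr(ctx$cds_seq, cpos, cpos + shift)
        alt_nt <- substr(ctx$cds_seq, cpos, cpos)
      } else {                        # insertion
        ref_nt <- substr(ctx$cds_seq, cpos, cpos)
        alt_nt <- paste0(ref_nt, paste(sample(c("A", "C", "G", "T"), shift,
                                              replace = TRUE),
                                       collapse = ""))
      }
      aa_ref <- ""
      aa_alt <- ""
      vclass <- "frameshift_indel"
      cds_pos <- cpos
    }
    vrows[[i]] <- data.frame(
      variant_id = vid, chrom = "chrS", pos = cpos, ref = ref_nt,
      alt = alt_nt, variant_class = vclass, gene_id = gid,
      transcript_id = txid, protein_pos = ppos, aa_ref = aa_ref,
      aa_alt = aa_alt, tumor_mf = round(stats_tab$tumor_mf[i], 4),
      normal_mf = round(stats_tab$normal_mf[i], 4),
      tumor_alt_reads = stats_tab$tumor_alt_reads[i],
      normal_alt_reads = stats_tab$normal_alt_reads[i],
      callers = "synthetic", cds_pos = cds_pos, stringsAsFactors = FALSE)
    erows[[i]] <- data.frame(
      variant_id = vid, gene_id = gid,
      tpm = round(stats_tab$tpm[i], 4),
      rna_mut_reads = stats_tab$rna_mut_reads[i],
      rna_wt_reads = stats_tab$rna_wt_reads[i], stringsAsFactors = FALSE)

    # epitopes needing predictions, and their assignment around the drawn
    # peptide-level best IC50
    best <- round(stats_tab$best_ic50_nm[i], 2)
    v <- vrows[[i]]
    if (vclass == "missense_snv") {
      pep <- build_snv_25mer(v, ctx)
      if (is_discarded(pep)) next
      eps <- mutant_epitopes(pep$sequence, pep$mutated_positions)
      owner <- pep$peptide_id
    } else {
      fsp <- build_fsp(v, ctx)
      if (is_discarded(fsp)) next
      L <- nchar(fsp$modified_seq)
      offs <- seq_len(L - 8L)
      offs <- offs[offs + 8L > fsp$wt_prefix_len]
      eps <- unique(substring(fsp$modified_seq, offs, offs + 8L))
      owner <- fsp$fsp_id
    }
    as <- assign_epitope_ic50(eps, alleles, best)
    as$ic50_nm <- round(as$ic50_nm, 2)
    prows[[i]] <- data.frame(peptide_id = owner, as,
                             contains_mutation = TRUE,
                             stringsAsFactors = FALSE)
    if (stats_tab$is_true[i]) {
      trows[[i]] <- data.frame(
        variant_id = vid, gene_id = gid,
        label = paste0(gid, "_", aa_ref, ppos, aa_alt),
        tumor_mf = v$tumor_mf, tpm = erows[[i]]$tpm,
        best_ic50_nm = best, stringsAsFactors = FALSE)
    }
  }

  f <- function(name) file.path(dir, paste0(pid, "_", name))
  write_variant_tsv(do.call(rbind, vrows), f("variants.tsv"))
  write_contexts(contexts, f("protein.fasta"), f("cds.fasta"))
  write_expression_tsv(do.call(rbind, erows), f("expression.tsv"))
  write_prediction_tsv(do.call(rbind, prows), f("predictions.tsv"))
  utils::write.table(do.call(rbind, trows), f("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  c(variants = f("variants.tsv"), protein = f("protein.fasta"),
    cds = f("cds.fasta"), expression = f("expression.tsv"),
    predictions = f("predictions.tsv"), truth = f("truth.tsv"))
}
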