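---
title: "Prioritizing tumor neoantigens with a weighted rank-sum score"
author: "venus package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing tumor neoantigens with a weighted rank-sum score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venus)
```

## The problem

A patient's tumor typically carries hundreds of somatic protein-coding
mutations, but only a handful of the mutated peptides (neoantigens) are
presented by the patient's MHC class-I molecules and recognized by T cells.
Personalized cancer vaccines can encode only a limited payload — on the
order of 20 to 60 peptides — so the practical question is one of
*ranking*: which candidate mutated peptides should fill those slots?

Many selection schemes apply fixed thresholds (for instance, keep only
predicted MHC-I binders with IC50 ≤ 500 nM from expressed genes). Validated
immunogenic neoantigens, however, span a broad range of predicted binding
affinities and expression levels, and hard thresholds discard true
positives that are merely mediocre on one axis. This package implements the
opposite philosophy: *no candidate is ever removed by a threshold*. Every
candidate is ranked independently on three axes, and the combined rank
decides.

## The score

For each candidate 25-mer neo-peptide the package computes three
competition ranks over the patient's full candidate list:

* `R_FREQ` — rank by tumor mutation allele frequency (MF), higher MF
  better. Clonal, high-frequency mutations are present in more tumor cells.
* `R_EXPR` — rank by corrected expression `corrTPM`, higher better (below).
* `R_IC50` — rank by best predicted MHC-I IC50 in nM over the candidate's
  mutant-containing epitopes and the patient's alleles, lower better.

These combine into the weighted rank sum

$$\mathrm{RSUM} = (R_{FREQ} + R_{EXPR} + (k + R_{IC50})) \times WF,$$

lower being better, with two correction factors:

* **Non-binder penalty `k`.** If a candidate's best IC50 exceeds 1000 nM,
  `k` equals `N`, the size of the candidate list; otherwise 0. Adding `N`
  to the IC50 rank pushes every predicted non-binder behind all unpenalized
  candidates *on that axis* while preserving their relative order — they
  are demoted, not deleted, and can still recover through the other axes.
  The boundary is strict: IC50 = 1000 nM is not penalized.
* **RNA-coverage weighting factor `WF`** (integer 1–5): 1 when mutant RNA
  reads are seen at the locus (whatever the TPM); otherwise 2–5 depending
  on whether wild-type reads are present and whether the gene clears a
  TPM ≥ 0.50 expression floor (the boundary is inclusive). Multiplying by
  `WF` penalizes candidates whose mutation has no direct RNA support.

### Corrected expression

Gene-level TPM measures the whole gene, not the mutated allele. The
corrected value rescales TPM by the mutant read fraction observed at the
variant locus in the tumor RNA-seq:

$$\mathrm{corrTPM} = \mathrm{TPM} \times
  \frac{\mathrm{mut} + 0.1}{\mathrm{mut} + \mathrm{wt} + 0.1}.$$

The pseudocount of 0.1 keeps the value defined with zero coverage (where
corrTPM = TPM: no evidence either way) and is deliberately placed
asymmetrically — once on the mutant count and once on the denominator sum —
so that corrTPM equals TPM exactly whenever no wild-type reads are seen.
We implement this literally and offer no symmetrized variant. corrTPM never
exceeds TPM, is non-decreasing in mutant reads and non-increasing in
wild-type reads.

## From variants to candidate peptides

**Somatic filter.** Candidates enter the ranking only after a
four-criterion somatic filter: tumor MF ≥ 10%; tumor/normal MF ratio ≥ 5;
more than 2 mutant reads in the tumor DNA; fewer than 2 mutant reads in the
normal DNA. All four criteria are evaluated for every variant so the
decision records every failure, and all thresholds live in
`filter_config()`. A normal MF of exactly 0 makes the ratio undefined; we
treat it as passing, since absence from the normal sample is the strongest
somatic evidence. Boundary semantics are exactly as stated: MF = 0.10
passes, 3 tumor reads pass, 1 normal read passes and 2 fail. Only missense
SNVs and frame-shifting indels are accepted; other classes (synonymous,
stop-gain, in-frame indels) are rejected at ingestion with a logged reason.

**Missense 25-mers.** Each missense variant yields one peptide: the mutant
residue flanked by up to 12 wild-type residues on each side (25 residues
when untruncated, mutation at position 13). Near a protein terminus the
flank truncates; products shorter than 9 residues are discarded. The
9-residue floor is the only length floor the method states (for frameshift
products), and we reuse it here rather than invent a second constant.

**Frameshift peptides (FSPs).** A frame-shifting indel is applied to the
coding sequence; the shifted frame is translated from the first altered
codon to the first stop codon (or the transcript end, flagged, when no stop
is met — the stop residue itself is never included). The FSP starts at the
first amino acid differing from the wild-type protein; any FSP of at least
1 novel residue is retained. A *modified FSP* prepends up to 12 wild-type
residues; modified FSPs shorter than 9 residues are discarded. Translation
uses the standard genetic code; ambiguity codes in a CDS reject the
transcript outright rather than guess.

**Tailoring.** Long FSPs contain stretches with no chance of MHC-I
presentation. The modified FSP is therefore reduced to 9-mer-anchored
25-mers: every 9-mer containing at least one novel residue is scored
against the patient's alleles; those with best IC50 at or below 1000 nM
(the same constant the `k` penalty uses — the method defines no separate
tailoring constant, so we reuse it, configurably) are kept and extended by
up to 8 residues on both sides within the FSP. When no 9-mer qualifies,
the single best-IC50 anchor is kept so that a retained FSP is never
silently dropped. Identical extended sequences are deduplicated (lowest
anchor offset wins). Each surviving 25-mer is ranked *independently* — a
long FSP legitimately contributes several candidates. Only 9-mer anchors
are enumerated; input prediction tables may carry epitopes of length 8–11,
but the tailoring grid is 9.

**Binding summary.** Per candidate, predictions are summarized as the
minimum IC50 over mutant-containing epitopes across all patient alleles —
the standard "best predicted binder" convention. The aggregation is
configurable (`min` or `median`) because the choice is not dictated by the
score itself; `min` is the default and the one used everywhere in this
package. Wild-type-only epitopes never contribute. The package consumes
prediction tables (one IC50 per epitope/allele row) produced by an external
predictor; `surrogate_predict()` provides a deterministic hash-based
stand-in for exercising the pipeline in tests, with no biological meaning.

## Deterministic ordering

Several choices make the output a reproducible total order:

* Per-axis ties use competition ("minimum") ranks: tied values share the
  best rank of their block. This is order-independent and handles the
  common case of several 25-mers from one FSP sharing identical MF and
  expression values.
* Final RSUM ties break by lower best IC50, then lexicographically by
  peptide id.
* Peptide ids are derived deterministically from the variant id and the
  anchor offset, so re-running on permuted input reproduces positions
  exactly.
* `k` uses `N` = the patient's full candidate 25-mer list size (the
  universe being ranked), configurable in principle but fixed here.

Degenerate inputs: a single-candidate list is legal (its RSUM is the
minimum attainable value 3 when unpenalized); `NaN` parameter values,
fractions outside [0, 1], missing joins, and epitopes absent from the
prediction table are hard errors naming the offending records — never
silent coercions.

## Comparator strategies

`rank_alternative()` implements the selection schemes the combined score is
benchmarked against: ranking by each single parameter alone, and
"funnel" filtering, which first removes every candidate failing fixed
thresholds (best IC50 ≤ 500 nM *and* gene TPM ≥ 0.50) and then sorts
survivors by IC50. Funnel-dropped candidates are truly gone — at any
cutoff they count as not captured, which is the point of the comparison.

## Validation metrics

For a validated neoantigen at position *p* of an *N*-candidate list,
`pct_ranked_better()` reports `round(100 p / N)` (half away from zero).
The packaged table of 20 experimentally T-cell-validated neoantigens
across nine solid-tumor patients (`validated_neoantigens()`) ships with
the *printed* per-row percentages, because no single rounding rule
reproduces every printed row (one position-1-of-180 row prints 0% while
9-of-180 prints 5%); cohort summaries therefore use the printed column,
and the rounding function is trusted only on rows where the
`p` vs `p − 1` and floor-vs-round choices agree. `capture_at()` and
`cohort_summary()` reduce a cohort to the payload-relevant metrics:
captures within the top 20 and top 60, and the median/maximum percentile.

```{r table1}
cohort_summary(validated_neoantigens())
```

## The synthetic cohort generator

Real per-patient inputs require controlled-access sequencing data and
external predictors, so the package ships a seeded generator
(`cohort_spec()`, `generate_cohort()`, `simulate_candidates()`) producing
complete input bundles with known ground truth. Its defaults emulate the
statistical structure the score assumes:

* ~267 somatic variants per patient drawn before filtering (candidate
  lists of roughly 200–240 after the somatic filter and frameshift
  expansion, matching the few-hundred scale of real patients), 5% of them
  frameshift indels;
* tumor MF ~ Beta(2, 5) — mostly subclonal, some clonal; normal MF zero
  for 90% of variants; read counts Poisson/binomial at 100× DNA depth and
  TPM-proportional RNA depth;
* gene TPM log-normal (meanlog 0.5, sdlog 1.8), spanning silent to highly
  expressed;
* best IC50 from a mixture: 15% binders (log-uniform 1–500 nM), 10% weak
  (500–1000 nM), 75% non-binders (log-uniform 1–50 μM);
* per patient, 5 implanted "true" neoantigens with jointly favorable
  draws: MF at the 75th–95th background quantile, TPM at the 70th–95th,
  guaranteed mutant RNA reads, and IC50 log-uniform on 50–900 nM —
  favorable but *not* extreme on any single axis, and occasionally above
  the 500 nM funnel threshold, which is exactly the regime in which real
  validated neoantigens were observed.

The distribution families are generator conventions chosen once at design
time, not estimates from any dataset. What passing recovery tests on this
generator shows is that the score finds jointly-favorable candidates more
reliably than single-axis or fixed-threshold selection *under the score's
own statistical assumptions*; it does not show predictor accuracy,
HLA-typing correctness, or anything about proteasomal processing —
features of real data the generator deliberately does not model (nor does
it model read-level noise, multi-gene overlaps, isoform structure, or
linkage between nearby variants). Implanted truths are always missense:
the experimentally validated set this package's metrics mirror is
substitution-only, and implanting in FSP space would entangle recovery
with the tailoring expansion.

Generation is a pure function of the seed: the same `cohort_spec` yields a
byte-identical bundle, and each patient derives its own sub-seed.

## Problem sizes

The shipped tests run the scoring oracle on 1,000 random tables of up to 6
candidates (exhaustive-comparison cross-check), the filter oracle on
10,000 random variants, and parameter recovery on 100 seeded replicates of
one patient (~210–230 candidates, 5 implants each), comparing mean top-60
capture across the five strategies. These sizes were chosen to make the
statistical assertions stable across seeds while keeping the default suite
quick to run.

## Known limitations

* MHC class-II binding is not considered; selection of CD4 epitopes rides
  on the frequency and expression axes only.
* The package consumes upstream tabular outputs (variant calls,
  expression, binding predictions); alignment, variant calling, HLA typing
  and expression quantification are out of scope, as is the external
  predictor itself.
* Self-similarity / foreignness features are deliberately absent — they
  belong to comparator tools, not to this score.
* One `gene_id` per variant is required; multi-gene overlaps must be
  resolved upstream and are surfaced as errors.
* The VCF reader accepts one documented dialect (FORMAT `AF`/`AD`, INFO
  `GENE`/`TRANSCRIPT`/`PCLASS`/`PPOS`/`AAREF`/`AAALT`) rather than
  guessing annotation conventions; anything else should be converted to
  the variant TSV.
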