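# venus — neoantigen prioritization by weighted rank-sum scoring

Personalized cancer vaccines can encode only a few dozen peptides, while a
patient's tumor typically carries hundreds of somatic protein-coding
mutations. `venus` ranks a patient's candidate mutated peptides
(neoantigens) for vaccine payload selection, for bioinformaticians working
from standard tumor/normal exome + tumor RNA-seq derived tables.

Instead of removing candidates with fixed thresholds, every candidate
25-mer neo-peptide is ranked independently on three axes — tumor mutation
allele frequency (MF), allele-corrected expression (corrTPM), and best
predicted MHC class-I IC50 — and the ranks combine into the VENUS RSUM
score (lower is better):

```
RSUM = (R_FREQ + R_EXPR + (k + R_IC50)) * WF

corrTPM = TPM * (mut_reads + 0.1) / (mut_reads + wt_reads + 0.1)

k  = N (candidate list size)  if best IC50 > 1000 nM, else 0
WF = 1 if mutant RNA reads > 0; 2-5 by RNA coverage and TPM >= 0.50
```

The package implements the full path from somatic variant tables to the
ranked list: the four-criterion somatic filter (tumor MF ≥ 10%,
tumor/normal MF ratio ≥ 5, > 2 mutant tumor reads, < 2 mutant normal
reads); construction of mutation-centered 25-mers for missense SNVs;
frameshift-peptide (FSP) translation to the first stop codon and its
"tailoring" into 9-mer-anchored 25-mers; binding-prediction and expression
joins; the score itself; comparator strategies (single-parameter and
fixed-threshold funnel selection); validation metrics; and a seeded
synthetic-cohort generator with implanted true neoantigens so everything
is testable without external data.

## Worked example

Simulate one patient's candidate table (≈220 candidates surviving the
somatic filter, 5 implanted true neoantigens), score it, and locate the
implants:

```r
library(venus)
cand <- simulate_candidates(cohort_spec(seed = 7))
r <- venus_score(cand)
print(r, n = 5)
#> Ranked candidate neo-peptides: 222 candidates
#>   penalized non-binders (k > 0): 172; without RNA mutant support (WF > 1): 112
#>   top 5 of 222:
#>  final_position peptide_id variant_id tumor_mf corr_tpm best_ic50_nm k wf rsum
#>               1   v079_snv       v079   0.7105    6.088        229.7 0  1   53
#>               2   v003_snv       v003   0.5517    3.620        136.9 0  1   78
#>               3   v002_snv       v002   0.5127    5.879        113.5 0  1   79
#>               4   v004_snv       v004   0.5216    7.091        269.4 0  1   80
#>               5   v001_snv       v001   0.5546    4.191        399.3 0  1   80

truth_positions(r, cand$peptide_id[cand$is_true], "peptide_id")
#> v001_snv v002_snv v003_snv v004_snv v005_snv
#>        5        3        2        4       11
```

All five implanted true neoantigens rank within the top 11 of 222: each is
only upper-quartile on any single axis, but jointly favorable, which is
exactly what the combined rank sum rewards. 172 of the 222 candidates are
predicted non-binders (IC50 > 1000 nM) and carry the `k` penalty; 112 lack
mutant RNA reads and are down-weighted by `WF` — demoted, not deleted.

The packaged cohort of 20 experimentally T-cell-validated neoantigens
across nine solid-tumor patients summarizes as:

```r
cohort_summary(validated_neoantigens())
#> Validated neoantigens: 20
#>   captured in top 20: 14 (70%)
#>   captured in top 60: 19 (95%)
#>   % of list ranked better: median 5, max 22
```

So a vaccine encoding each patient's top 60 ranked peptides would have
included 19 of the 20 validated neoantigens; the median validated
neoantigen sits in the top 5% of its patient's list.

The file-based pipeline (`run_pipeline()`) and a CLI with `filter`,
`build-peptides`, `score`, `rank`, `evaluate`, and `simulate` subcommands
(`inst/scripts/venus-cli.R`) wrap the same functions; see the
`venus-methods` vignette for the model, its assumptions, and every
numerical choice.

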