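# hrdforest

Pan-cancer detection of **homologous recombination deficiency (HRD)** from
whole-genome somatic mutation catalogs, for cancer genomicists who want to
call HRD — and its *BRCA1*-type vs *BRCA2*-type sub-phenotype — from
standard variant-calling output (VCF + copy-number segments) rather than
from gene panels.

Tumors that have lost homologous recombination repair against double-strand
breaks (most often through biallelic inactivation of *BRCA1*, *BRCA2*,
*RAD51C* or *PALB2*) fall back on error-prone pathways such as
microhomology-mediated end joining. This leaves a characteristic,
permanent *mutational scar* across the genome: an excess of small deletions
with flanking microhomology and — specifically in *BRCA1*-type HRD — of
1–100 kb tandem duplications. Because the scar reflects past deficiency
regardless of its cause, it detects HRD that germline testing misses
(somatic events, deep deletions, epigenetic silencing).

## The model

Every sample is reduced to counts over 142 mutation contexts:

* **96 SNV contexts** — the six base substitutions (C>A, C>G, C>T, T>A,
  T>C, T>G) in their 5′/3′ trinucleotide context (pyrimidine strand);
* **30 indel contexts** — deletions/insertions with flanking
  **microhomology** (`del.mh`, `ins.mh`, binned by homology length
  *bimh* = 1, 2, 3, 4, ≥5 bp), within **tandem repeats** (`del.rep`,
  `ins.rep`), or **neither** (`del.none`, `ins.none`), the latter four
  binned by indel length;
* **16 SV contexts** — DEL / DUP / INV by length decade (1–10 kb … >10 Mb)
  plus translocations (TRA).

These collapse to **29 relative-contribution features** (6 substitution +
7 indel + 16 SV fractions, each block normalized by its own total, with
microhomology deletions split at 1 bp vs ≥2 bp homology:
`del.mh.bimh.1` / `del.mh.bimh.2.5`). A **three-class random forest**
(*BRCA1*-deficient / *BRCA2*-deficient / proficient) is trained with:

1. one-tailed Wilcoxon feature selection (deficient > proficient,
   p < 0.01);
2. class resampling chosen by 10-fold-CV grid search (down-sample the
   proficient class 1×/2×/4× × up-sample the *BRCA1* class 1×/1.5×/2×,
   scored by AUPRC of the pooled HRD class);
3. repeated (default 100×) nested-CV **blacklisting** of samples whose
   out-of-fold predictions contradict their genetic label
   (deficient-labeled predicted HRD <60% of rounds; proficient-labeled
   predicted HRD >40%), followed by retraining on the filtered set.

The HRD probability is `P(HRD) = P(BRCA1) + P(BRCA2)`, called HRD at
≥ 0.5, with the subtype taken as the larger of the two class
probabilities. QC requires MSI absence (≤14,000 repeat-region indels),
≥50 indels, and ≥30 SVs for HRD-predicted samples.

The package also scores **biallelic gene inactivation** from copy-number
segments and annotated variants — deep deletion (total CN < 0.3, BP-score
10), LOH (minor-allele CN < 0.2, P-score 5), variant P-scores 1–5 from
clinical annotation or predicted effect, summed into a BP-score per best
event pair — derives training labels from it, and explains cohort-level
HRD genetically (per-gene one-tailed Fisher enrichment with Hochberg
correction, copy-number co-occurrence confound testing, and the clustered
causal-gene sample layout).

## Worked example

Everything below runs offline on the package's synthetic cohort generator,
whose class structure mirrors the HRD scar (both deficient classes enriched
in `del.mh.bimh.2.5`; the *BRCA1* class additionally in 1–100 kb DUPs):

```r
library(hrdforest)

sim <- simulate_cohort(n_brca1 = 35, n_brca2 = 89, n_none = 300, seed = 7)
fit <- hrd_train(sim$features, sim$labels, seed = 7, repeats = 10, ntree = 100)
fit
#> HRD random-forest classifier
#>   classes: BRCA1 / BRCA2 / none
#>   trees: 100  selected features: 8
#>   resampling: none class down 1x, BRCA1 class up 1x
#>   HRD cutoff: 0.5  seed: 7
#>   blacklisted during training: 0 sample(s) over 10 repeats

new <- simulate_cohort(n_brca1 = 2, n_brca2 = 2, n_none = 2, seed = 8)
predict(fit, new$features)
#>        sample p_brca1 p_brca2 p_none p_hrd hr_status   hrd_type
#> 1 S0001_BRCA1    0.94    0.06   0.00  1.00       HRD BRCA1-type
#> 2 S0002_BRCA1    0.98    0.01   0.01  0.99       HRD BRCA1-type
#> 3 S0003_BRCA2    0.00    0.96   0.04  0.96       HRD BRCA2-type
#> 4 S0004_BRCA2    0.00    0.98   0.02  0.98       HRD BRCA2-type
#> 5  S0005_none    0.00    0.04   0.96  0.04       HRP       none
#> 6  S0006_none    0.00    0.02   0.98  0.02       HRP       none

head(hrd_importance(fit), 4)
#>  del.mh.bimh.2.5 DUP_1e03_1e04_bp DUP_1e04_1e05_bp DEL_1e03_1e04_bp
#>            28.61            10.85             8.39             8.24
```

Each prediction row gives the forest's three class probabilities; `p_hrd`
is the summed deficiency probability that drives the HRD/HRP call, and
`hrd_type` the sub-phenotype. The importance ranking shows the model
leaning on ≥2 bp-homology microhomology deletions for HRD as a whole and
on short duplications to tell the subtypes apart.

Starting from files instead of matrices: `extract_profile()` +
`build_hrd_features()` consume VCFs read by `read_small_variant_vcf()` /
`read_sv_vcf()` against an indexed FASTA (`ref_genome()`), and
`run_pipeline()` (or `inst/scripts/run_pipeline.R` from a shell) wires the
whole cohort flow — extraction, features, prediction, QC, biallelic gene
status, enrichment — writing TSVs plus a JSON run manifest.

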