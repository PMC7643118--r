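---
title: "Mutational-scar classification of homologous recombination deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational-scar classification of homologous recombination deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdforest)
```

# The problem and the model

Loss of homologous recombination (HR) forces a tumor to repair
double-strand breaks through error-prone pathways, chiefly
microhomology-mediated end joining. The resulting genome-wide scar —
an excess of small deletions flanked by microhomology and, in
*BRCA1*-type deficiency, of 1–100 kb tandem duplications — persists in
the somatic mutation catalog regardless of whether the deficiency arose
from germline variants, somatic events, or epigenetic silencing. This
package classifies that scar. The predictor is a three-class random
forest over relative mutation-context contributions; its output is
`P(BRCA1)`, `P(BRCA2)` and `P(none)`, with the HRD probability defined
as `P(BRCA1) + P(BRCA2)` and thresholded at 0.5. The subtype of an
HRD call is the larger of the two deficiency probabilities (an exact tie
resolves to BRCA2-type, the larger class; the choice is deterministic
and, in practice, unreachable with an odd-sized forest).

## Context definitions

SNVs map to the standard 96 trinucleotide contexts (pyrimidine
reference; purine sites are reverse-complemented together with both
flanks). Indels are normalized first — shared VCF padding stripped,
then left-aligned against the reference — and classified by three rules,
with a search window equal to the indel length on each side:

* **repeat** (`del.rep`, `ins.rep`): at least one full copy of the indel
  sequence immediately downstream and indel length < 50 bp;
* **microhomology** (`del.mh`, `ins.mh`): a full copy in a flank when the
  indel is ≥ 50 bp; otherwise ≥ 2 bp of sequence identity to a flank, or
  ≥ 1 bp when the indel is ≥ 3 bp long. The number of bases in
  microhomology (*bimh*) is the larger of the downstream prefix match and
  the upstream suffix match;
* **neither** (`del.none`, `ins.none`).

Repeat is tested first: a full downstream copy of a sub-50 bp indel is a
repeat even though it would also satisfy the homology rules, which the
homology definition subsumes. Two boundary cases are deliberate: a
1–2 bp indel with exactly 1 bp of identity is *none* (the 1 bp rule
requires length ≥ 3; a 1 bp indel whose single base matches downstream
is a full copy and therefore a repeat); and insertions search their
inserted sequence against the reference flanks, symmetrically to
deletions. Each of the six types is binned (homology length for mh,
indel length otherwise) into 1, 2, 3, 4, ≥5 bp, giving 30 indel
contexts. SVs map to DEL/DUP/INV × five length decades from 1 kb plus
TRA (16 contexts); events shorter than 1 kb fall outside the printed
binning and are skipped with a counted warning rather than forced into
the lowest bin, and they likewise do not count toward the ≥ 30-SV QC
requirement.

## Features

The 96 SNV contexts collapse to the six substitution types; the 30 indel
contexts collapse to seven features, with microhomology deletions split
into `del.mh.bimh.1` and `del.mh.bimh.2.5` (1 bp vs ≥ 2 bp homology —
the ≥ 2 bp bin is the strongest single HRD marker, while 1 bp-homology
deletions are also produced by radiotherapy); the 16 SV contexts are
kept. Each block is divided by its own total, which removes overall
mutational-load differences between samples. An empty block is encoded
as all zeros, never `NaN`: samples with too few mutations are the QC
gate's responsibility (≥ 50 indels; ≥ 30 SVs when predicted HRD; no
MSI, i.e. at most 14,000 repeat-region indels — MSI hypermutation
swamps the repeat features and masks the microhomology signal).
`build_merged_mh_features()` provides the 28-feature variant with
`del.mh` unsplit, and `build_signature_features()` the variant that
replaces the SNV and SV blocks with non-negative least-squares
signature contributions (`fit_signatures_nnls()`); both exist to
quantify how little the headline model depends on those choices.

# Training procedure

`hrd_train_core()` performs the core procedure: one-tailed Wilcoxon
selection (deficient > proficient, p < 0.01; `stats::wilcox.test`, which
is exact for small untied groups and uses the tie-corrected normal
approximation otherwise), then a grid search over class resampling —
down-sampling of the proficient class by 1×/2×/4× crossed with
up-sampling of the minority *BRCA1* class by 1×/1.5×/2× — scored by the
cross-validated AUPRC of the pooled HRD class, and finally a
three-class forest fit on the resampled training set. Down-sampling is
without replacement, up-sampling with replacement, and both are applied
to training folds only, so evaluation folds never contain duplicated
samples. Ties in the grid resolve to the first cell in row-major order
(down-sampling outer), making the search deterministic.

`hrd_train()` wraps this in the two-stage procedure: stage 1 runs the
core CV repeatedly (default 100 rounds of stratified 10-fold CV) and
counts, per sample, how often its out-of-fold HRD probability crosses
the cutoff. Deficient-labeled samples called HRD in fewer than 60% of
rounds (e.g. reverted biallelic hits) and proficient-labeled samples
called HRD in more than 40% (e.g. deficiency of another HR gene) are
blacklisted; stage 2 reapplies the core procedure to the filtered set.
Feature selection and resampling parameters are computed once on the
full labeled set and reused across the repeated CVs rather than
re-estimated inside every round: both are near-deterministic given the
cohort, and fixing them keeps the per-sample call counts comparable
across rounds (and the procedure tractable).

Forest hyperparameters not fixed by the method's definition use the
randomForest defaults — 500 trees, √p candidate features per split —
and are exposed as arguments. A single integer seed governs folding,
resampling and forest fitting; retraining with the same seed reproduces
predictions exactly, and persisted models (`write_hrdforest()`, a
versioned archive) reload to identical predictions.

# Biallelic gene status and cohort analysis

Copy-number rules use strict inequalities on the minimum over segments
overlapping the transcript span (partial overlap counts): total copy
number < 0.3 is a deep deletion (BP-score 10 outright), minor-allele
copy number < 0.2 is LOH (P-score 5, copy-neutral LOH included). We
take the caller's `minor_cn` at face value and tolerate small caller
noise (e.g. minor slightly above total/2) rather than re-deriving it.
Variant P-scores are 1–5 from clinical annotation when present
(pathogenic = 5 … benign = 1), otherwise from the predicted effect
(out-of-frame frameshift 5; nonsense/splice 4; missense, essential
splice, inframe 3; other low-impact types 2 — the definition allows
"benign or likely benign" and either value sits strictly below every
decision threshold). Germline variants exceeding a cohort-frequency
cutoff (default > 1% of germlines) should be pre-marked via the
`common_germline` flag and score 0. The best event pair's P-scores sum
to the BP-score (max 10); score ties are broken greedily in the order
deep deletion > LOH + frameshift > LOH + other variant > variant pairs.
Two germline variants never form a pair (they describe one inherited
allele). Training labels require BP = 10 without MSI for the deficient
classes, and — for "none" — no deep deletion, no LOH, and no variant
above P = 3; everything else is excluded as ambiguous, including the
(unstated in the method definition) case of both genes at BP = 10.

Cause calling (`call_hrd_cause()`) deliberately uses looser thresholds
than training: deep deletion; LOH + germline P ≥ 4; LOH + somatic
P ≥ 3; or two P = 5 variants not both germline. The per-gene enrichment
of deficiency in HRD vs HRP samples is a one-tailed Fisher exact test
with Hochberg step-up correction; `cna_cooccurrence_test()` exposes the
positional confound where a gene's copy-number alterations merely ride
along with a neighboring driver (the chromosome-17/13 situation).
`cluster_hrd_samples()` reproduces the causal-gene sample layout:
samples split by subtype × impactful biallelic event (a best pair of 5
and ≥ 3), greedy max-BP gene assignment with priority
BRCA2 > BRCA1 > RAD51C > PALB2, run-length clusters after sorting, and
a cosmetic within-cluster ordering (deep deletion, LOH + frameshift,
LOH + other).

# The synthetic-fixture module

Real HRD cohorts are controlled-access, so the package ships a
first-class generator instead of data. `make_fixture_genome()` draws a
deterministic random sequence at a chosen GC fraction.
`plant_variants()` inverts the context classifier: SNV sites are found
by scanning for the required trinucleotide on either strand, deletion
sites by scanning for positions whose downstream homology structure
matches the target category, and insertions are constructed from the
downstream flank; every placement is verified by classifying the
resulting VCF-style record and rejected if flanking sequence creates an
unintended context, so the planting log is exact by construction (the
round-trip tests assert this over 100 seeds). `plant_gene_events()`
does the same for copy-number/variant combinations.

`simulate_cohort()` draws per-sample context counts from
class-conditional multinomials with Dirichlet-distributed proportions
(concentration 60) and negative-binomial loads. Its defaults are the
study conditions: class sizes 35/89/1902; proficient samples at ~8,000
SNVs, ~400 indels (5% `del.mh`), ~120 SVs; deficient samples at ~1,500
indels with 45% microhomology deletions shifted toward ≥ 2 bp homology
and ~250 SVs, with the *BRCA1* class moving about half its SV mass into
1–100 kb duplications. These magnitudes are ordinary whole-genome
somatic loads for a metastatic solid tumor and produce the qualitative
feature ranking the method is built on (microhomology deletions first,
short duplications separating the subtypes). `effect_scale = 0`
collapses all classes onto the baseline for null controls. What the
generator does *not* emulate — replication timing, strand bias,
signature-specific SNV structure, caller noise, purity — means passing
tests demonstrate correctness of the machinery and recoverability of
the planted structure, not clinical performance on real tumors; the
method's own guidance to revalidate thresholds per variant-calling
pipeline stands.

# Numerical choices and problem sizes

Feature blocks are normalized exactly (sums checked to 1e-9); AUROC is
trapezoidal over tie-collapsed operating points (validated against
exhaustive pair counting), AUPRC is average precision with tied scores
sharing their block-end precision; the F1 curve is evaluated on a 0.01
cutoff grid. NNLS goes through `pracma::lsqnonneg`. Degenerate inputs
fail loudly where the result would be meaningless (single-class truth,
a gene without copy-number coverage, no annotation on a variant,
fewer than two selected features) and degrade gracefully where the
batch should survive (individual malformed VCF records are counted and
skipped; empty mutation classes yield zero blocks).

The test suite and acceptance checks run at desk scale: cohorts of
~150–300 samples, forests of 30–100 trees, 25 blacklisting repeats, a
1,000-indel oracle comparison on a 10 kb genome, and 100-seed
round-trip loops — sizes chosen so the full suite completes in well
under a minute per file while still exercising every contract at the
boundaries stated above.

# Known limitations

The classifier is only as good as its labels and its variant calls: the
blacklisting stage absorbs label noise but not systematic caller
differences, and the probability cutoff of 0.5 is calibrated to the
training distribution, not universal. Indel classification assumes a
correct reference and simple alleles (complex substitutions are
rejected per record). The biallelic caller consumes pre-computed effect
classes and does not predict variant effects from sequence, nor does it
model promoter methylation — an acknowledged blind spot for a fraction
of samples whose scar says HRD but whose genetics appear intact.
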