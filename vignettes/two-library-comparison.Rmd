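---
title: "Two-library transcriptome comparison: model, assumptions, and limits"
author: "duoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-library transcriptome comparison: model, assumptions, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoseq)
library(dplyr)
```

## The problem

Organ-scale transcriptome studies in non-model insects often sequence one
deep library per physiological condition rather than replicated designs —
for example, the transcript catalog of the mosquito spermatheca (the female
sperm-storage organ) profiled once before and once after insemination, next
to whole-body male and female baseline libraries. With a single library per
condition there is nothing to estimate biological variance from, so the
classical replicate-aware tools (negative-binomial GLMs, exact tests) do
not apply. What can be done — and what this package implements as a tested,
reusable pipeline — is:

1. a per-CDS test of whether a coding sequence occupies different
   *fractions* of the two libraries (a 2×2 Pearson chi-squared on mapped
   reads vs all other mapped reads), with Bonferroni and Benjamini–Hochberg
   control over the catalog;
2. a pseudocounted, depth-normalized fold statistic
   $n_1 = r_1 R_2 / (R_1 (r_2 + 1))$ used to require a minimum effect size
   (eight-fold by default) on top of significance;
3. tissue-enrichment filtering against the whole-body baselines via
   relative RPKM, with "RPKM = 1" taken as the constitutive whole-body
   reference;
4. keyword-vocabulary functional classification of annotations;
5. z-scored TPM matrices with hierarchical clustering for heatmaps; and
6. $2^{-\Delta\Delta Ct}$ relative quantification of follow-up qPCR data.

A negative-binomial simulator with planted ground truth stands in for raw
sequencing data, so every stage is testable offline and the operating
characteristics of the whole cascade can be measured.

## The differential-expression model

For CDS $i$ with $r_1, r_2$ mapped reads in libraries of $R_1, R_2$ total
mapped reads, the test contrasts

$$\begin{pmatrix} r_1 & R_1 - r_1 \\ r_2 & R_2 - r_2 \end{pmatrix}$$

with the 1-df Pearson chi-squared statistic, no continuity correction. The
null hypothesis is that the CDS occupies the same proportion of both
libraries; the sampling model is binomial, i.e. *sequencing* noise only.
A CDS with $r_1 = r_2 = 0$ is reported as $(\chi^2 = 0,\ p = 1)$ rather
than dropped, so the table shape is stable. Raw p-values are corrected over
the whole catalog; the default call requires Bonferroni-corrected
$p \le 0.05$ **and** a normalized read rate of at least 8 in one direction.
The one unit added to the opposing count avoids division by zero and
shrinks the ratio at low counts, where a fold estimate from a handful of
reads would otherwise explode.

### What the fold statistic does near its threshold

The pseudocount has a consequence worth understanding before choosing
thresholds: for a CDS whose true expression ratio is exactly $F$ at equal
depths, $n_1 \approx F \mu/(\mu + 1) < F$, where $\mu$ is the expected
count in the lower library. The statistic is therefore centered *just
below* the true fold, and a transcript whose real effect equals the
threshold passes the fold gate only when sampling noise pushes it over —
roughly half the time at best. Measured on simulated data (2000 CDS,
2×10⁶ reads/library, dispersion 0.1, planted 8-fold effects, 5 seeds),
87% of planted CDS pass the significance gate but only 43% pass the
fold-8 gate, for a joint sensitivity of about 0.4; planting 16-fold
effects (twice the threshold) raises sensitivity to 0.90 with empirical
FDR 0. The practical reading: the fold threshold should be interpreted as
"comfortably above", and recovery of effects *at* the threshold is
structurally limited, not an implementation artifact.

### Error control under overdispersion

The chi-squared test models binomial sampling. Real libraries are
overdispersed — biological and technical variation adds variance the test
cannot see with one library per condition. In the Poisson limit of the
simulator (dispersion 0) the Bonferroni family-wise error rate is
controlled as nominal (measured 0.015 at $\alpha = 0.05$ over 200 null
replicates). With negative-binomial dispersion as low as 0.02, virtually
every null replicate contains Bonferroni-significant CDS (p-only FWER
$\approx 1$), because abundant transcripts fluctuate between libraries by
far more than binomial noise allows. The fold gate absorbs most of this —
a 20–30% fluctuation is nowhere near eight-fold — but not at the nominal
level: at dispersion 0.1, 22% of null replicates still produce at least
one DEG call. This anti-conservativeness is the well-known cost of
replicate-free designs and is the reason replicate-aware NB models exist;
users should read the DEG list as a ranked shortlist for validation (the
study design here validates by qPCR and RNAi), not as an FWER-guaranteed
discovery set.

## Normalization

- **RPKM** $= r \cdot 10^9/(R \cdot L)$ — absolute, length- and
  depth-scaled; used for the enrichment comparison against whole-body
  baselines.
- **TPM** — length-normalized rates rescaled to sum to $10^6$ per library;
  a composition, comparable across libraries, and the input to the
  heatmap.
- **Expression index** — counts scaled to 100 at the most-read CDS of the
  library; a within-library measure of relative prominence.
- **z-scores** — each CDS row of the TPM matrix standardized with the
  *sample* standard deviation ($n-1$), matching the default of the common
  R heatmap tools. Zero-variance rows become all zeros (with a warning)
  rather than NaN so clustering stays total.

Clustering of heatmap rows and columns uses Euclidean distance with
complete linkage — again the defaults of the cited plotting stack — via
`stats::dist()`/`stats::hclust()`, with ties broken by input order.

## Tissue-enrichment filtering

Relative RPKM divides tissue expression by
$\max(\text{RPKM}_{\text{body female}}, \text{RPKM}_{\text{body male}},
1)$. Taking the *larger* of the two body libraries is the conservative
combination rule (enrichment must beat both bodies); the floor of 1
encodes the convention that RPKM 1 is constitutive whole-body expression
and doubles as division-by-zero protection. A CDS is *enriched* when its
maximum relative RPKM (over the virgin and inseminated libraries) exceeds
1 and its larger tissue RPKM is at least double the female-body RPKM.
*Candidates* for follow-up additionally require a DEG call at the
eight-fold level and at least 30-fold expression over the whole body —
the cascade used to pick transcripts for in situ hybridization, qPCR and
RNAi in this kind of study. A consequence of the floor: a transcript
expressed below RPKM ≈ 2 everywhere can never be flagged enriched, no
matter how depleted the body libraries are; enrichment is only observable
above the constitutive reference level.

## Functional classification

Annotations are classified by lowercase substring matching against a
keyword vocabulary `(keyword, class_label, priority)`. Highest priority
wins; ties go to the earliest vocabulary entry; the shipped default
vocabulary (~55 entries over the classes recurrent in insect organ
transcriptomes) uses keyword length as priority so more specific phrases
win. A CDS with no match is `"secreted"` if it carries a signal-peptide
flag — an unannotated protein with a secretion signal is presumed released
into the organ lumen — and `"unknown/conserved"` otherwise. The mechanism,
not any particular word list, is the reproducible content: studies of this
kind use curated vocabularies of a few hundred terms that are rarely
published, so users supply their own TSV for serious annotation work.

## qPCR relative quantification

The Livak $2^{-\Delta\Delta Ct}$ procedure: technical-replicate Ct values
are arithmetically averaged first, then differenced against the reference
gene within each group ($\Delta Ct$), then against the calibrator group
($\Delta\Delta Ct$). The double difference makes the result invariant to
any global Ct shift and anchors the calibrator group at fold 1 exactly.
Dispersion bounds propagate the replicate Ct spread as
$s = \sqrt{s^2_{\text{gene}} + s^2_{\text{ref}}}$ within the sample group,
reported as $2^{-(\Delta\Delta Ct \pm s)}$. Amplification-efficiency
correction and melt-curve analysis are out of scope.

## The synthetic data generator

`simulate_dataset()` emulates the study design: four libraries (virgin,
inseminated, body female, body male) over a shared catalog.

| parameter | default | meaning |
|---|---|---|
| `n_cds` | 2000 | catalog size |
| `depth_per_library` | 2×10⁶ | expected mapped reads per library |
| `nb_dispersion` | 0.1 | NB dispersion; 0 = Poisson |
| `frac_de` | 0.05 | fraction planted DE between conditions |
| `de_fold` | 8 | planted condition fold |
| `de_skew` | 0.5 | share of DE planted virgin-up |
| `frac_enriched` | 0.05 | fraction planted tissue-enriched |
| `enriched_fold_vs_body` | 30 | body depletion of enriched CDS |
| `length_range` | 300–3000 bp | CDS lengths (uniform) |

Baseline expression is log-uniform over four orders of magnitude, which
exercises the pseudocount at low counts and mirrors transcriptome dynamic
range. Planted DE scales the up-condition mean by `de_fold`; planted
enrichment divides both body means by `enriched_fold_vs_body`. Enriched
CDS are planted among the upper half of baseline expression, because
enrichment is defined relative to the constitutive RPKM floor — a
transcript below that floor everywhere cannot carry the label. Everything
is reproducible from the single integer seed.

What the generator does **not** emulate: mapping ambiguity and multi-hit
read assignment, positional/GC bias, isoform structure, library-prep batch
effects, and between-library dispersion differences. Passing tests on this
generator therefore validate the arithmetic and the operating
characteristics under idealized counts, not robustness to real-data
artifacts upstream of the count table.

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator at the study
scale (2000 CDS, 2×10⁶ reads/library) for the error-rate and recovery
simulations — 10–200 replicates depending on the quantity — and at a few
hundred CDS for functional and determinism checks; these sizes give
stable estimates in seconds on one CPU. Other conventions: lexicographic
CDS ordering everywhere for deterministic output; DE tables sorted by BH
q-value then id; `alpha = 0` disables DEG calling outright (p-values can
underflow to exactly 0, which would otherwise still satisfy
$p \le \alpha$); counts are coerced to double before forming products so
read totals near $10^9$ cannot overflow integer arithmetic.

## A worked run

```{r example}
sim <- simulate_dataset(synthetic_config(n_cds = 500, depth_per_library = 5e5, seed = 11))
de <- call_degs(sim$dataset, "virgin", "inseminated")
glance(de)

enr <- sim$dataset |> enrichment_table() |> flag_enriched()
select_candidates(de, enr)

classified <- classify_annotations(sim$dataset$catalog)
summarize_classes(de$cds_id[de$deg_call != "none"], classified)
```

## Known limitations

- No replicate-aware inference; FWER is nominal only under pure
  sequencing noise (see above).
- Fold thresholds act on a pseudocount-shrunk statistic; effects at the
  threshold are recovered at well under full sensitivity.
- Enrichment cannot be observed for transcripts below the constitutive
  RPKM floor.
- The default keyword vocabulary is a starting point, not a curated
  annotation resource.
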