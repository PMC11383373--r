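---
title: "Bulk TCR-beta repertoire analysis: models, conventions and validation"
author: "tcrcohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulk TCR-beta repertoire analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrcohort)
```

## Scope

`tcrcohort` analyses bulk T cell receptor beta-chain (TCRB) sequencing of
clinical cohorts — here, diffuse large B cell lymphoma (DLBCL) tumors and
whole blood from HIV-negative, HIV-positive/ART-naive and
HIV-positive/ART-experienced patients. The package covers the complete chain
from rearrangement tables to reportable statistics: ingest and QC,
downsampling-averaged clonality metrics, clonal-expansion profiles,
repertoire sharing (overlap, Venn partitions, publicity, exclusive sharing,
paired tumor–blood overlap), epitope annotation against a VDJdb-style
lookup, and group/survival statistics. A synthetic-cohort generator with
recorded ground truth makes every stage testable without patient data.

## Data model and identity conventions

A `TCRRepertoire` holds one sample's clone table: CDR3 nucleotide sequence,
CDR3 amino-acid sequence, template count and frame status. A *template* is
one input DNA molecule counted by the assay, a proxy for one T cell. A
rearrangement is *productive* when it is in-frame with no stop codon; only
productive templates enter any analysis.

Two identity conventions coexist deliberately:

* **Clonality metrics are nucleotide-level.** "Unique productive
  rearrangements" counts distinct CDR3 nucleotide sequences, matching how
  the sequencing platform reports diversity. Duplicate nucleotide rows are
  merged on ingest by summing templates, which makes this count well
  defined.
* **Sharing analyses are amino-acid-level.** Overlap, Venn partitions,
  publicity, exclusive sharing, tumor–blood overlap and epitope annotation
  all collapse nucleotide variants to the CDR3 amino-acid sequence, since
  specificity is carried by the protein.

The AIRR dialect reader maps `productive = F` rows to `out_of_frame`: the
AIRR flag does not distinguish out-of-frame junctions from stop codons, and
no analysis in this package depends on that distinction among
non-productive clones.

## Quality control and downsampling

Samples enter clonality analysis only with **strictly more than 100
productive templates** (`qcFilter`, threshold exposed). All other analyses
use every sequenced sample, because presence/absence questions do not
require comparable sampling depth the way abundance-based metrics do.

Template depth differs by orders of magnitude between tissues (medians of a
few hundred productive templates in FFPE tumor versus ~20,000 in blood), so
clonality metrics are rarefied: each QC-passing sample is downsampled to a
common depth — by default recomputed as the *minimum productive count among
passing samples* (`depth = "auto"`), the largest depth at which no passing
sample must be discarded — and the three metrics are averaged over 100
random draws. Three numerical conventions matter:

* Draws are **without replacement at the template level** (classical
  rarefaction). This makes `depth = productive count` reproduce the plain
  metrics exactly, which the tests assert, and keeps the iteration mean an
  unbiased finite-population estimate.
* Averaged unique-rearrangement counts are reported as reals, not rounded,
  preserving ordering information for fold-changes.
* Per-sample RNG streams are derived from `(master seed, sample id)`
  (`deriveSeed`), so adding a sample to a cohort never perturbs any other
  sample's draws and the whole procedure is reproducible from one integer.

The three metrics are: **productive Simpson clonality**
$\sqrt{\sum_i p_i^2}$ over productive clone frequencies (1 = monoclonal,
$1/\sqrt{R}$ for $R$ equal clones); **maximum productive frequency**
$\max_i p_i$; and **unique productive rearrangements**. Simpson clonality
uses the plug-in $\sum p_i^2$ rather than the unbiased small-sample
variant; at a common rarefaction depth the plug-in bias is identical across
samples and cancels from comparisons.

**Expansion profiles** classify each clone by the proportion of repertoire
it occupies — small $(0, 10^{-4}]$, medium $(10^{-4}, 10^{-3}]$, large
$(10^{-3}, 10^{-2}]$, hyperexpanded $(10^{-2}, 1]$ — and report the summed
proportion per bin, without downsampling. The printed bin edges of such
schemes overlap at the boundaries; we fix a left-open/right-closed
convention (a clone at exactly 0.01 is "large") and expose the edges as an
argument. Profiles are computed per sample and compared between groups,
rather than pooled across samples.

## Sharing statistics

Pairwise overlap is $|A \cap B| / \min(|A|, |B|)$ on amino-acid clone sets
— presence/absence, not abundance-weighted (Morisita–Horn-style indices are
out of scope). Within-reference-group distributions exclude self-pairs and
count each unordered pair once. Tumor–blood overlap is directional:
$|T \cap B| / |T|$, the fraction of a patient's tumor clones detectable in
circulation. Publicity records clones found in at least `minSamples`
(default 5) distinct samples of a tissue; exclusive sharing restricts to
clones whose carriers all lie in a given group set (e.g. the two
HIV-positive groups) and partitions them by occupancy pattern.

## Epitope annotation

Annotation is exact string matching of CDR3 amino-acid sequences against a
VDJdb-style table; no fuzzy matching and no HLA restriction, since neither
can be justified without per-patient HLA data. The matched fraction divides
matched distinct clones by all distinct clones of the sample. For
per-species proportions the denominator is configurable: `all_tcrs`
(default; the species proportion is bounded by the matched fraction) or
`matched_tcrs` (proportions among identifiable clones). Both are offered
because published "epitope proportion" figures are ambiguous between the
two readings; neither mode changes the matching itself. A clone with
entries for several species counts once per species but once toward the
matched fraction.

## Statistics

Group location contrasts use the Wilcoxon rank-sum test (exact enumeration
when both groups have at most 10 untied observations, otherwise the
tie-corrected normal approximation with continuity correction) and the
Kruskal–Wallis test; fold-changes are ratios of group medians with the
orientation stated, flagged rather than computed when the denominator
median is zero. Multiple-comparison correction is Benjamini–Hochberg,
applied across a declared family (e.g. the per-tissue Kruskal–Wallis scans)
and reported as adjusted p-values alongside the raw ones. Correlations are
Spearman with average-rank ties.

Survival biomarkers are dichotomized at the **median of the analysed
subset** (recomputed per analysis; values tied with the median go to
"low"), and hazard ratios come from Cox partial likelihood with **Efron
tie handling** — the standard modern default. Non-convergence and monotone
likelihoods (complete separation) are flagged in the output rather than
silently reported. The per-clone survival screen over public clones uses
unadjusted p < 0.05 as a discovery filter, reflecting screening practice
for candidate clonotypes; downstream confirmation should adjust for the
clinical covariates, as `coxFit(..., adjustFor = )` supports.

## The synthetic cohort

`generateCohort` emulates the statistical structure the pipeline assumes,
with every planted parameter recorded as ground truth:

* **Clone sizes**: symmetric Dirichlet over a per-sample pool of 3,000
  clones, concentration per group and tissue. The Dirichlet-multinomial was
  chosen over a power law for its closed-form limits (uniform as
  $\alpha \to \infty$, monoclonal as $\alpha \to 0$) and clean
  concentration ordering; ordinal clonality contrasts between groups are
  all the analyses require. Defaults: tumor concentration 3 for HIV-negative
  and ART-experienced, 0.3 for ART-naive (more clonal); blood 0.15
  everywhere, giving blood its higher rarefied clonality alongside much
  higher raw diversity.
* **Depth**: log-normal total templates with medians 385 (tumor) and
  27,000 (blood); log-sd 2.0 for tumor so that a substantial minority of
  FFPE tumors fall below the QC threshold (matching observed attrition
  patterns), 0.8 for blood. Each template is productive independently with
  probability 0.77 (tumor) / 0.80 (blood); non-productive templates are
  absorbed by a separate pool of out-of-frame/stop rearrangements.
* **Keys**: clone identities are synthetic CDR3-like strings ("C" + nine
  random residues + "F") — biologically naive, but no operation inspects
  sequence content beyond equality. Keys come from a cohort-wide public
  pool with a per-group sharing probability (lowest for ART-naive, whose
  repertoires should be most private), otherwise they are private. Each
  clonotype occasionally (15%) carries a second, minor (~2% of templates)
  nucleotide variant, so the two identity conventions differ measurably.
* **Paired blood**: a fraction $\omega$ of the tumor's realized clones
  recirculates in the paired blood pool, with a concentration boost
  (`sharedCloneAlpha = 5`) so that recirculating clones are reliably
  sampled at blood depth and $\omega$ is identifiable from the measured
  overlap: without the boost, a symmetric-Dirichlet blood pool leaves
  ~15% of shared clones unsampled even at 20,000 templates, biasing
  recovery. $\omega$ defaults to 0.45 / 0.20 / 0.05 for ART-naive /
  ART-experienced / HIV-negative and declines mildly with age (0.004 per
  year), echoing the direction of the reported age association; the
  between-group spread dominates the pooled age correlation, so the strong
  printed correlation coefficient is not a generator target.
* **Survival**: exponential baseline (median 20 months at the reference),
  log-linear group and age effects, independent exponential censoring plus
  administrative censoring at 60 months; progression is an extra
  exponential risk so PFS never exceeds OS. ART durations respect the
  6-month naive/experienced boundary.
* **Epitope database**: 5% of cohort clone keys receive a species label
  (influenza A, CMV, EBV, HIV, other), 5% of those a second species.

What passing tests on this generator do *not* show: real repertoires have
power-law-like tails, V(D)J generation-probability structure, sequencing
error, and HLA-driven sharing, none of which are modelled. The generator
validates the *statistical machinery* — that planted concentrations,
overlaps, annotation fractions and hazard ratios are recovered — not the
biology.

## Validation strategy and problem sizes

The test suite checks every operation against an independent oracle: hand
computation and closed forms (uniform-repertoire clonality, the
hypergeometric law of two-clone downsampling, the Benjamini–Hochberg
step-up rule, the Kruskal–Wallis rank formula), naive set-enumeration
re-implementations for all sharing statistics on random small cohorts, null
simulations for type-I error calibration (2,000 replicates per test), and
planted-parameter recovery (concentration ordering at 12 samples per group
over 200 replicates; $\omega = 0.3$ over 50 pairs; a hazard ratio of 0.3
with confidence-interval coverage over 200 cohorts of n = 200). The
end-to-end check runs the full default cohort — 57 tumors, 21 bloods, 16
paired — twice and asserts byte-identical outputs. These sizes were chosen
as the smallest at which each property is sharply testable; all are pure
functions of their seeds.

## Worked example

```{r example, eval = FALSE}
sc <- generateCohort(cohortConfig(masterSeed = 77))
res <- runRepertoireAnalysis(sc$cohort, sc$epitopeDB, masterSeed = 13)
res$meta$depth                  # recomputed rarefaction depth
head(res$clonality)             # per-sample downsampled metrics + bins
res$clonalityContrasts          # tissue and group comparisons
res$venn$tumor                  # Venn partition of tumor clonotypes
res$tumorBlood                  # per-patient tumor-blood overlap
res$survival$biomarkers         # median-cutoff Cox fits
writeAnalysisBundle(res, "analysis_out")
```

## Known limitations

* Simpson clonality is the plug-in estimator; absolute values at low depth
  are upward-biased (by roughly $\sqrt{1/\text{depth}}$ for diverse
  samples) even though comparisons at a common depth are fair.
* The generator's Dirichlet clone-size model understates the heavy tails of
  real repertoires; absolute fold-changes between groups are therefore
  smaller than published ones even when orderings and significance
  reproduce.
* Epitope annotation is exact-match and HLA-agnostic, inheriting the
  database's ascertainment biases.
* The per-clone survival screen is a discovery filter, not an inference
  procedure; its unadjusted threshold is deliberate and documented above.
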