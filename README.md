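# tcrcohort

Bulk T cell receptor beta-chain (TCRB) repertoire analysis for clinical
cohorts, built for the setting where tumor and blood repertoires are
compared across patient groups — here, diffuse large B cell lymphoma
(DLBCL) in HIV-negative, HIV-positive/ART-naive and
HIV-positive/ART-experienced patients — and related to survival.

Deep sequencing of the CDR3 region yields, per sample, a table of
rearrangements with template counts. The scientific questions this package
answers from such tables:

* **How clonal is a repertoire?** Productive Simpson clonality
  (√Σpᵢ², 1 = monoclonal), maximum productive frequency (max pᵢ) and the
  number of unique productive rearrangements, computed after rarefying all
  samples to a common productive-template depth (draws without
  replacement, averaged over 100 iterations) so that wildly different
  T cell inputs — hundreds of templates in FFPE tumor versus tens of
  thousands in blood — are comparable. Clonal-expansion profiles bin each
  clone by the proportion of repertoire it occupies (small ≤ 10⁻⁴, medium
  ≤ 10⁻³, large ≤ 10⁻², hyperexpanded > 10⁻²).
* **Who shares clones with whom?** Pairwise overlap |A∩B| / min(|A|,|B|)
  on amino-acid clone sets, Venn partitions of clonotypes by patient
  group, public clones (present in ≥ 5 samples), clones shared exclusively
  within the HIV-positive groups, and the directional tumor–blood overlap
  |T∩B| / |T| for paired samples.
* **What do the clones recognise?** Exact CDR3 matching against a
  VDJdb-style epitope table: per-sample matched fractions and per-species
  epitope proportions.
* **Does any of it matter clinically?** Kruskal–Wallis / pairwise Wilcoxon
  with median fold-changes, Spearman correlations, Benjamini–Hochberg
  correction, Kaplan–Meier curves, and Cox regression of median-cutoff
  biomarkers and per-clone carrier status.

A fully parameterised synthetic-cohort generator (Dirichlet-multinomial
clone sizes, log-normal depths, public-clone pool, paired tumor–blood
recirculation, planted epitope annotations, proportional-hazards survival)
provides ground truth for every stage; the test suite recovers each
planted parameter through the pipeline itself.

## Worked example

```r
library(tcrcohort)

sc  <- generateCohort(cohortConfig(masterSeed = 77))   # 57 tumor + 21 blood
res <- runRepertoireAnalysis(sc$cohort, sc$epitopeDB, masterSeed = 13)
```

`sc$cohort` prints the cohort composition:

```
TCRCohort: 78 repertoires (57 tumor, 21 blood), 62 patients
                   tissue
group               blood tumor
  HIV_neg               7    19
  HIV_pos_ART_exp       7    27
  HIV_pos_ART_naive     7    11
```

QC keeps samples with more than 100 productive templates; the rarefaction
depth is recomputed as the minimum passing count (`res$meta$depth` = 139
here, 66 of 78 samples passing). Group contrasts of downsampled tumor
Simpson clonality (`res$clonalityContrasts`):

```
   group_a           group_b            p_value  fold_change
   HIV_neg           HIV_pos_ART_exp    3.95e-01 1.000
   HIV_neg           HIV_pos_ART_naive  3.59e-05 0.944
   HIV_pos_ART_exp   HIV_pos_ART_naive  1.20e-05 0.944
```

ART-naive tumors are significantly more clonal than either other group
(the fold-change orientation is group_a/group_b, so naive is higher),
while HIV-negative and ART-experienced tumors are indistinguishable —
the generator's planted structure, recovered by the pipeline. The Venn
partition of tumor clonotypes (`res$venn$tumor`) shows mostly private
group regions with a thin shared core (55 clonotypes in all three groups
here), and `res$tumorBlood` lists per-patient tumor–blood overlap with age
and group for the 16 paired patients. `writeAnalysisBundle(res, dir)`
writes every table as TSV plus a markdown report.

## Package layout

* `R/repertoire-io.R` — immunoSEQ-export and AIRR readers/writers, QC.
* `R/clonality.R` — metrics, downsampling, expansion profiles.
* `R/overlap.R` — all sharing analyses.
* `R/annotation.R` — epitope database and annotation.
* `R/cohort-stats.R` — group comparisons and survival.
* `R/synthetic-cohort.R` — the generator and its ground truth.
* `R/pipeline.R` — end-to-end orchestration and report bundles.
* `vignettes/tcr-repertoire-analysis.Rmd` — models, conventions,
  validation strategy and limitations.
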