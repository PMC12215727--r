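---
title: "Models and design decisions behind rnadx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions behind rnadx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnadx)
```

`rnadx` screens a cohort of unrelated patients' blood RNA-seq profiles for
three kinds of transcriptional aberration — expression outliers, aberrant
splice-junction usage, and mono-allelic expression — summarizes the dosage
effect of reported CNVs, and ranks candidate genes by phenotype relevance.
This vignette records the statistical models, the tunable parameters and why
their defaults are what they are, what the synthetic-cohort generator does
and does not emulate, and the numerical corner cases.

## The cohort-as-control principle

None of the screens has a matched control sample. Each patient is compared
against the remaining cohort members, on the assumption that a rare-disease
cohort is heterogeneous enough that no aberration recurs: the cohort median
behaviour is the healthy reference for any single gene, junction or site.
All thresholds below (z cut-offs, FDR levels) are screens for manual
curation, not calibrated posteriors of pathogenicity.

## Expression outlier model

For counts $k_{gs}$ (gene $g$, sample $s$):

1. **Gene filters.** The nine hemoglobin genes (HBB, HBD, HBG1, HBG2, HBZ,
   HBM, HBA2, HBA1, HBQ1) are removed first — in whole blood they carry a
   large and highly variable fraction of the library, and their variation
   would otherwise leak into every normalized value. Genes whose
   95th-percentile RPKM across samples is $\le 1$ are removed as
   undetectable ($\mathrm{RPKM} = k \cdot 10^9 / (\text{library size}
   \times \text{exonic length})$).
2. **Size factors.** Median-of-ratios: $s_s = \mathrm{median}_g\,
   k_{gs}/(\prod_t k_{gt})^{1/n}$ over genes positive in every sample,
   rescaled to geometric mean 1. When no gene is positive everywhere the
   function stops and suggests a pseudocount rather than silently changing
   the estimator.
3. **Sample QC.** Principal components of the centered
   $\log_2(k/s + 1)$ matrix; a sample is excluded when its distance from
   the cohort centroid in the top-5 component space is an extreme outlier
   under leave-one-out standardization, $(d_i - \bar d_{-i})/\mathrm{sd}(d_{-i})
   > 7$. Three properties drove this exact form, all verified in
   simulation:
   * the PCA runs on the *winsorized* matrix (below), otherwise
     heavy-tailed single-gene noise dominates the distances;
   * leave-one-out scaling keeps the criterion comparable across cohort
     sizes — with the all-sample SD a gross outlier caps its own z at
     roughly $\sqrt{n}$, so no fixed threshold works at both $n = 30$ and
     $n = 60$;
   * the threshold 7 sits between the largest value healthy cohorts reach
     in simulation (about 5.7, *including* cohorts carrying large planted
     CNVs, which must not be QC-excluded) and the signature of a globally
     degraded library (8 and above for a profile-permuted sample). A CNV
     carrier deviates on a few dozen genes; a degraded library on
     thousands — the distance statistic separates the two, robust
     per-component alternatives we tried did not.
4. **Confounder removal.** The expectation is the per-gene mean plus the
   rank-$K$ SVD reconstruction of the centered log matrix ($K$ = 5 by
   default, configurable). The SVD and the reconstruction are computed on
   a gene-wise winsorized copy (values capped at 3 robust SDs): without
   this, a strong single-sample outlier donates its own principal
   component and partially explains itself away — planted 2-fold changes
   lost roughly half their z-score before the fit was made robust.
   $K = 0$ degenerates to the per-gene mean, which is the correct limit
   for confounder-free data.
5. **Per-gene NB test.** Dispersion $\phi_g$ is the MLE of
   $k_{gs} \sim \mathrm{NB}(\mu_{gs}, \phi_g)$ over the *uncapped* cells
   (so the outlier being tested does not inflate its own null), bounded to
   $[10^{-8}, 10^3]$, with a method-of-moments fallback (and warning) if
   the optimization fails. The p-value is the doubled smaller tail, capped
   at 1; z-scores standardize the log-residual using the winsorized
   residual scale; fold change is $2^{l - \hat l}$, exactly 1 when
   observed equals expected. BH correction is applied across genes within
   each sample — matching how per-case results are reported and read —
   not across the whole matrix.
6. **Outlier rule.** `padj < 0.05` **or** `|z| >= 3`, deliberately
   disjunctive; both sub-criteria are stored separately so a reviewer can
   see which fired.

Zero-variance genes are skipped with a warning rather than producing NaN
z-scores. The inversion of the log transform uses
$\mu = s \cdot \max(2^{\hat l} - 1, 10^{-8})$ — consistent with the +1
pseudocount in the forward transform — so expectations of barely expressed
genes cannot go negative or to zero.

**Sex stratification.** `stratify_by_sex = TRUE` reruns the entire pipeline
(filters, size factors, QC, fit, test) inside each sex stratum. This is the
correct control for X-chromosome dosage in cohorts with sex-imbalanced
expression (e.g. X-aneuploidy cases); a stratum below 10 samples is refused
because cohort z-scores below that size are too unstable to screen with.

## Splicing screen

The unit is the *junction coverage score*: reads on a junction divided by
total reads on junctions sharing its donor **or** acceptor site, pooled
over both ends without double counting. Two decisions deserve record:

* **The denominator includes the junction itself.** The worked arithmetic
  of the published case this statistic screens for counts the junction of
  interest inside its own denominator (65 of 74 reads = 88% usage), and
  inclusion bounds the score in $[0, 1]$, making it a usage proportion.
  A literal "other junctions only" mode exists behind
  `include_self = FALSE` for comparison.
* **One score per junction, not per end.** Donor-side and acceptor-side
  competition are pooled; scoring the two ends separately is possible but
  doubles the test count for no observed gain in the planted-event
  benchmarks.

Junctions enter the cohort universe when they pass the strict read filter
(`> 5` uniquely mapped reads, per the stated screening rule; multimapping
reads are parsed and discarded) in at least one sample; other samples
contribute whatever counts they have (including 0) so that genuinely
sample-specific junctions can be scored against the cohort. Junctions with
fewer than 10 defined scores, or zero variance, are skipped. Strand-unknown
junctions (STAR code 0) are grouped by both ends under an "unknown" role,
keeping them inside the screen without asserting a donor/acceptor
orientation.

Event classification is purely geometric against a reduced exon model;
intron retention is only *flagged* (a canonical junction plus an elevated
intronic-coverage indicator) because quantifying retention needs exonic /
intronic coverage, which junction tables do not carry.

## Allele-specific expression

Sites observed in exactly one cohort sample ("rare in the internal batch")
with total coverage $\ge 10$ are tested against
$\mathrm{alt} \sim \mathrm{BetaBin}(n, 0.5, \rho)$. The coverage floor is a
package choice: below ~10 reads the test has no power at any plausible
effect size and the ratio estimate is meaningless. $\rho$ is estimated by
maximum likelihood from sites with allele ratio in $[0.2, 0.8]$ (presumed
null), with mean fixed at 0.5; fewer than 50 eligible sites triggers a
binomial fallback with a warning. Both tails are computed by direct mass
summation — read depths are small, and $1 - \mathrm{CDF}$ loses all
precision exactly where the interesting p-values live.

The reporting rule is deliberately two-tiered. The hard flag requires
major-allele ratio > 0.8 (in **either** direction) *and* `padj < 0.05`.
Real diagnostic findings, however, include reference-biased events at
unimpressive adjusted p-values (nonsense-mediated decay of the variant
allele reduces *total* coverage, which caps power), so sites with ratio
> 0.7 are additionally marked `review = TRUE` regardless of significance.
The ratio criterion, the significance criterion, the direction and the
review tier are all separate columns.

## CNV dosage

Covered genes are the expressed (post-filter) genes overlapping the
interval by $\ge 1$ bp, strand-agnostic (overlap via `IRanges`). The
summary is complete-case: a gene missing a z-score in any sample is dropped
from the mean for *all* samples, so every sample's mean is over the same
gene set. Carrier rank is ascending for deletions and descending for
duplications — duplications are handled symmetrically by design even though
loss events dominate the motivating material. A CNV covering no expressed
gene, or whose carrier was removed by sample QC, is marked non-assessable
rather than erroring: both situations occur in real cohorts and should not
abort a batch analysis. Per-gene (z, fold change) lists are always kept —
observed dosage response is non-uniform (the generator's default penetrance,
24/34, encodes the observed fraction of responsive genes in a well-known
22q11.2 deletion), and the per-gene profile is diagnostic information.

## Candidate ranking

Tier 1: the gene's HPO terms intersect the patient's; tier 2: disjoint but
the gene has any disease association; tier 3: neither. Matching is **exact
term identity** — no ancestor closure — because any propagation scheme
would be an uncontrolled sensitivity dial; ontology-aware matching is a
clean extension point. Within tier, records sort by minimum adjusted p
(missing treated as $+\infty$; splicing and CNV evidence carry z but no
adjusted p), then maximum |z| descending, then gene id: a total,
deterministic order, so the report is a pure function of its inputs.
Multi-modality evidence for one gene concatenates under a single record —
convergent evidence (e.g. a splice defect plus an expression change in the
same gene) is exactly what reviewers want surfaced first.

## The synthetic cohort generator

`simulate_cohort()` draws every input of the pipeline from one seeded
model; every planted aberration lands in a truth ledger. Defaults describe
a realistic mid-size whole-blood diagnostic cohort at desk scale:

| parameter | default | rationale |
|---|---|---|
| samples × genes | 60 × 5000 | enough samples for stable cohort z-scores; desk-scale runtime |
| gene means | lognormal(log 50, 1.6) | spans silent to highly expressed |
| NB dispersion | lognormal(log 0.01, 1) | anchored to the z-vs-fold-change arithmetic of published blood-cohort outlier calls, which implies residual log2 SD ≈ 0.09–0.19 (φ ≈ 0.008–0.03) for well-expressed genes after confounder removal |
| size factors | lognormal, sd 0.25, geomean 1 | typical library-depth spread |
| hemoglobin fraction | 0.40 over 9 genes | typical whole-blood hemoglobin load; the genes carry the real hemoglobin symbols so the filter is exercised |
| X-linked male:female ratio | 0.8 | incomplete dosage compensation, makes sex stratification consequential |
| junction groups | 200 groups × 2–3 junctions, depth ~Pois(100) | multinomial usage within donor/acceptor-sharing groups |
| ASE sites | 200/sample, depth ~NB(mean 30), ρ = 0.02 | beta-binomial null so overdispersion estimation is testable; 5% of sites duplicated into a second sample to exercise the rare-het filter |
| CNV penetrance | 24/34 | observed fraction of dosage-responsive genes in a 22q11.2 deletion carrier |

Planting operators either shift the expected mean before the NB draw
(expression, CNV — effects hold in expectation and touch only the targeted
cells) or redistribute reads (splicing — `plant_splice_event()` uses
deterministic largest-remainder rounding, so group totals are preserved
exactly and a 0.88 target over 74 reads yields exactly 65).

**What the generator does not emulate** — and therefore what passing
benchmarks do *not* demonstrate about real data: batch effects beyond
scalar size factors (the confounder-removal stage is validated on a
separately constructed one-factor simulation, not on the default cohort);
mean–dispersion coupling (dispersions are drawn independently of means);
alignment and mapping artifacts; reference bias at ASE sites;
gene–gene correlation beyond the hemoglobin block and the X-linked sex
effect; annotation errors. Sensitivity numbers from these cohorts are
upper bounds for real cohorts of the same size.

## Problem sizes and reproducibility

The test suite and the acceptance script run null calibrations at the
default 60 × 5000 scale (5 and 3 seeds respectively) and recovery
benchmarks at 60 × 2000 with ≥ 50 planted events per modality — sizes
chosen so the full suite completes in a few minutes on a laptop while
keeping ≥ 50 replicates behind every rate. All randomness flows from
explicit integer seeds; `simulate_cohort()` is byte-reproducible for a
fixed parameter set, and `run_cohort_analysis()` is deterministic given its
inputs (fixed tiebreaks everywhere, no hidden RNG).

## Known limitations

* The expression model removes a *fixed* number of principal components;
  it does not select the dimension per cohort. Misspecifying $K$ trades
  sensitivity against confounder leakage, and on confounder-free synthetic
  data any $K > 0$ costs a little power.
* The NB test conditions on the reconstructed expectation as if known;
  uncertainty in $\hat\mu$ and $\hat\phi$ is not propagated. BH within
  sample therefore controls FDR only approximately near the boundary.
* The splicing screen scores junction usage, not splicing efficiency:
  a uniform up- or down-regulation of all junctions in a group is
  invisible by construction.
* The ASE test assumes a symmetric 0.5 null; systematic reference bias
  would shift every site and inflate $\hat\rho$ rather than create calls,
  but a *site-specific* bias is indistinguishable from signal.
* Tier ranking treats HPO terms as flat identifiers; phenotypically close
  but non-identical terms land in tier 2.
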