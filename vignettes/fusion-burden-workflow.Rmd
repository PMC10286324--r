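---
title: "Multi-cohort gene-fusion characterization and fusion-burden prognosis"
author: "FusionBurden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort gene-fusion characterization and fusion-burden prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FusionBurden)
```

## The problem this package addresses

Prostate cancer is driven to an unusual degree by gene fusions — chimeric
transcripts joining a 5' partner gene to a 3' partner — with *TMPRSS2::ERG*
alone present in roughly half of tumors of European descent. Individual
fusions are mostly rare, so two complementary questions arise when several
RNA-seq cohorts are available:

1. **Characterization.** Which fusions recur across cohorts, which are
   already described in a fusion catalog (e.g. a Mitelman-DB-like list), and
   which are credible novel candidates? What do the partners do (ETS-family
   transcription factors, tumor suppressors, snoRNAs and their host genes,
   read-through transcription between neighboring genes)?
2. **Prognosis.** Does the per-sample *fusion burden* — the number of
   distinct deduplicated fusions, used as a surrogate for genomic
   instability — associate with time-to-event outcomes (biochemical
   recurrence or death of disease), beyond the Gleason Grading Group (GGG)?

The package consumes fusion-call tables in the Arriba TSV dialect (the
caller's per-sample `*.fusions.tsv` files or a merged per-cohort file),
per-cohort clinical tables, a known-fusion catalog, and a simplified gene
annotation table. It does not run the aligner or the fusion caller.

## Fusion identity and per-sample deduplication

All cross-cohort logic operates on a canonical key `"G1::G2"` built by
`canonicalKey()`. Only parenthesized groups of digits and commas — the
caller's distance annotations on alternative partner names, as in
`MBTPS2(33,120),LL0XNC01-39B3.1(20,917)` — are stripped; all other
parentheses are preserved, and comma-separated alternative names are kept in
order as one composite partner. Identity is the ordered gene pair:
`A::B` and `B::A` are different fusions, and breakpoints are retained for
reporting only. Composite partners are *expanded* to their member genes for
partner-level analyses (classification, promiscuity, enrichment) but kept
composite for fusion identity, because cross-cohort tables count fusions
while partner-frequency figures count genes.

When a sample reports the same key several times, `dedupSampleFusions()`
keeps the call with the highest confidence, then the most supporting reads,
then the first occurrence. Supporting reads are defined as
`split_reads1 + split_reads2 + discordant_mates`, the three support columns
of the Arriba dialect. Per-cohort summaries (`summarizeCohort()`) count
distinct (sample, key) pairs *per confidence level before deduplication*, so
a fusion observed at two levels in one sample contributes to both level rows
— this is why level percentages need not sum to 100% — while burden and all
downstream analyses use the deduplicated set. Means divide by the full
cohort sample size, including samples without calls.

## The discovery/confirmation workflow

Fresh-frozen cohorts act as *discovery* cohorts: only their high-confidence
fusions are trusted as nominations. FFPE biopsy cohorts act as
*confirmation* cohorts: RNA degradation in stored FFPE material shifts call
confidence downward, so a fusion nominated at high confidence in any
discovery cohort is accepted from the confirmation cohort at *any*
confidence, and the confirmation cohort additionally contributes its own
remaining high-confidence calls (`buildCandidateSets()`). *Evaluation*
cohorts extend the overlap with their high-confidence sets without changing
existing rows.

`overlapAndRank()` restricts to fusions seen in at least `minCohorts`
cohorts (default 2), flags exact catalog membership, and sorts by known
status (unknown first by default), then descending cohort count, then
rediscovery in a confirmation cohort, then key. Whether the rediscovery flag
precedes or follows the cohort-count sort is genuinely ambiguous for this
kind of ranking; both orders are supported (`cohortCountFirst`), with
cohort-count first as the default. Catalog matching is exact on canonical
keys; no fuzzy gene-pair fallback is applied by default because the
appropriate granularity depends on how the catalog was compiled.

`geneStatusConcordance()` compares per-sample fusion-status vectors
one-to-one against an external reference (e.g. consortium-published ERG
status) and reports the 2x2 table, agreement, and per-source positive
percentages.

## Partner annotation

`classifyPartner()` prefers the annotation table (gene class, snoRNA-host
links via `host_of`, gene-set labels such as `ETS_family`,
`tumor_suppressor`, `androgen_response`); symbols absent from the annotation
fall back to configurable prefix rules (`RNU` for snRNAs, `SNOR` for
snoRNAs, `RP11`/`CTC-`/`AC0`/`LL0` for BAC-clone-derived identifiers without
approved symbols). `findSnoFusions()` returns fusions touching snoRNAs or
their hosts and flags snRNA::snoRNA pairs. `readthroughCandidates()` flags a
fusion when both partners lie on one chromosome with an inter-span gap of at
most `maxGapBp`; the default of 200 kb is a deliberate, editable convention
— "adjacent genes" has no universal threshold, and 200 kb comfortably covers
documented read-through neighborhoods while excluding most same-chromosome
rearrangements. The gap boundary is inclusive and overlapping spans count as
gap 0. `promiscuity()` counts, per cohort, deduplicated fusion events per
gene and side, and pools cohorts as (sum of occurrences) / (sum of sample
sizes). `geneSetEnrichment()` is a hypergeometric upper-tail test with
Benjamini–Hochberg adjustment across the sets tested in one call; the
universe defaults to whatever gene list the caller supplies — typically all
genes in the annotation — since enrichment universes are analysis choices,
not facts.

The packaged `ETS_family`, `tumor_suppressor` and `androgen_response`
labels in `genes_synthetic.tsv` are an editable starting point, not a
curated truth; users should supply their own gene-set memberships.

## Survival analysis

Samples are dichotomized either by a target fusion's status or by fusion
burden at the cohort median, with *burden >= median* forming group 1 — the
boundary sample joins the high-burden group. The confidence scope is
`high_only` for fresh-frozen cohorts and `combined` (the confirmation
cohort's combined key set, any confidence) for FFPE, mirroring the
degradation logic above.

Kaplan–Meier estimation, the log-rank test and Cox proportional-hazards
regression are surfaced as `kmFit()`, `logRankTest()` and `coxFit()`, backed
by the `survival` package — the standard implementation of these estimators
— with Breslow tie handling by default (Efron optional) and 95% Wald
intervals (beta ± 1.96 SE). GGG enters as an integer 1–5 on a continuous
scale. Five-year survival readouts use the KM curve at t = 60 with time in
months (the package is unit-agnostic; months are the documented default).
Degenerate situations are handled explicitly: zero events yield p = 1 with a
warning from the log-rank test; constant covariates or fewer than two events
are errors for the Cox fit; monotone likelihood (complete separation) yields
a flagged, estimate-free result rather than a divergent one. Note that the
log-rank p is asymptotic: at very small n it can differ from the exact
permutation p by more than Monte-Carlo error, which is a property of the
chi-square approximation, not of the implementation — the test suite
therefore checks the statistic and its full permutation distribution against
independent oracles.

## What the synthetic cohorts emulate

`simConfig()`/`simulateCohort()` generate cohorts with the statistical
structure the analysis assumes, so every stage is testable without access to
raw cohorts:

* **Known fusions** drawn per sample by prevalence (default *TMPRSS2::ERG*
  0.5, the approximate European-descent prevalence, and *SLC45A3::ELK4*
  0.1).
* **Background fusions** as random ordered gene pairs with a
  negative-binomial count (mean lambda, dispersion `size`); negative
  binomial rather than Poisson because observed per-sample fusion counts are
  heavily right-skewed (single samples reaching 50–80 fusions).
* **Duplicates**: each true fusion is emitted twice with probability
  `duplicateRate` (default 0.15), with independent confidence and
  read-support draws, exercising the dedup rule.
* **FFPE degradation** acts on *observation*, not biology: specimen age is
  uniform over 4.5–11.1 years; each extra year moves `degradationSlope`
  (default 0.008) of confidence probability mass from high to low, and
  spurious calls arrive at rate `spuriousRate * age * lambda` (default rho =
  1.6), almost all at low confidence. True fusion presence is unaffected —
  degradation makes real fusions harder to call confidently and adds false
  positives.
* **Survival** from a Weibull baseline (shape 1.2, scale 1500 months) with
  hazard multiplier `exp(beta1 * [true burden >= cohort median] + beta2 *
  GGG)`, beta1 = 0.7 and beta2 = 0.65 by default, independent uniform
  censoring over 0–120 months, and GGG drawn from (0.25, 0.30, 0.20, 0.15,
  0.10). Under the default design this yields roughly 20% events, within
  the 13–43% range typical of the targeted cohorts; the recovery
  simulations in the test suite use scale 800, which yields ~30% events.
* **Library protocol**: poly(A) cohorts draw no snoRNA/snRNA partners,
  since those RNAs carry no poly(A) tail.

`studyDesign()` freezes a four-cohort design of this kind: a deeply
sequenced fresh-frozen total-RNA discovery cohort (n = 40, lambda = 59,
21/32/47% high/medium/low confidence, death-of-disease endpoint), a large
fresh-frozen poly(A) discovery cohort (n = 332, lambda = 39, 25/17/58%), an
FFPE total-RNA confirmation cohort (n = 176, lambda = 45, baseline
6.2/20/73.8% degrading with age — calibrated so young samples average ~2.4
and old samples ~0.8 high-confidence calls), and a fresh-frozen poly(A)
evaluation cohort (n = 82, lambda = 26, 33/20/47%). One global seed drives
everything; per-cohort streams are derived from it deterministically, so
identical configurations are byte-identical.

What the generator does **not** emulate: breakpoint sequence context,
expression levels, correlated fusion co-occurrence, batch effects, or any
dependence of fusion presence on clinical covariates other than the two
survival coefficients. Passing tests therefore demonstrate that the
*pipeline arithmetic and statistics* behave as specified under the assumed
data-generating process, not that the biological findings would replicate
on real cohorts.

## Numerical choices and degenerate inputs

* Rank-sum test (`rankSumTest()`, used by the specimen-age comparison):
  exact enumeration of all group assignments when both groups have <= 10
  observations (valid under ties, which integer burdens make common),
  otherwise the normal approximation with tie and continuity correction.
  Two-sided extremity is distance of the rank sum from its permutation
  mean. Age tertiles are empirical quantiles with ties assigned to the
  lower (younger) group.
* Burden median: the usual sample median (midpoint of the central order
  statistics for even n); samples present in the clinical table but absent
  from the calls count as burden 0.
* Cox convergence and separation are delegated to `survival::coxph`; a fit
  whose information matrix is singular or whose coefficients run away is
  reported as `converged = FALSE` with no estimates.
* Patient-level reduction (`readClinical(onePerPatient = TRUE)`) keeps the
  first row per patient in file order — "first available sample" is a file
  -order convention, stated rather than guessed.
* Multi-candidate partner names from the caller are kept as single
  composite partners rather than split into separate fusions; splitting
  would multiply counts without evidence that the alternatives are distinct
  events.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the simulations at sizes
chosen as a sensible compromise for routine execution: recovery of the
burden-group log hazard ratio at n = 2000 (single fit) and n = 300 x 200
replicates (CI coverage), the log-rank null level at n = 60 x 400
replicates, and the FFPE age effect at half the default design size. These
sizes are the package's own choices for routine verification; the
configuration objects accept larger values unchanged.

## Known limitations

* Catalog matching is exact-string on canonical keys; renamed or aliased
  gene symbols will not match without prior symbol harmonization.
* The combined-scope burden counts any-confidence occurrences of keys in
  the combined set; a stricter variant (any confidence only for
  discovery-matched keys) would require per-key provenance and is not
  implemented.
* The log-rank and Cox p-values are asymptotic; for very small cohorts the
  permutation machinery in the test helpers is the better reference.
* The gene annotation is a simplified TSV, not a full GTF; overlapping
  transcripts, strand-aware read-through logic and exon structure are out
  of scope.
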