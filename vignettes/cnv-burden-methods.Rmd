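---
title: "Consensus CNV calling, CNVR clustering and burden analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus CNV calling, CNVR clustering and burden analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvburden)
```

## The analysis

SNP-array CNV calling is noisy enough that single-caller calls are not
trusted: the accepted practice is to run several detection algorithms in
parallel and keep only events seen by more than one of them. `cnvburden`
implements that post-processing pipeline and the downstream cohort
statistics for a study design with placental and parental (blood) genomes
in case and control groups — the setting of recurrent pregnancy loss (RPL)
cohorts, where the placental genome's capacity to accumulate somatic
duplications is itself the phenotype of interest.

The stages are:

1. **Confidence filter.** One caller reports a log Bayes Factor per call;
   its calls below a floor (default 5) are discarded. Other callers are
   not filtered — the statistic is caller-specific.
2. **Consensus calling.** Within a sample, two same-type calls are the
   same event when their *reciprocal overlap* — `min(o/|a|, o/|b|)` for
   overlap `o` — is at least 0.4. Calls are merged by single linkage over
   these pairs; components supported by at least two distinct callers
   become consensus CNVs spanning the union of their members.
3. **CNVR clustering.** Across samples, same-type consensus CNVs join one
   CNV region (CNVR) when they overlap by at least 40% of *at least one*
   of the two intervals (`max` instead of `min`), so a short polymorphic
   CNV nested in a longer one clusters with it. Connected components,
   including singletons, are the CNVRs; sharing between groups is
   co-membership in one CNVR.
4. **Burden and group statistics.** Per-sample counts and cumulative Mb
   spans, overall and by type. Group location comparisons pass through a
   normality gate: Shapiro–Wilk in each group, Welch's t-test when both
   pass, otherwise the Wilcoxon rank-sum test. Sharing contrasts use
   Fisher's exact test; no multiple-testing adjustment is applied (the
   report exposes unadjusted p-values, stated as such).
5. **Genomic context.** Pericentromeric and subtelomeric windows are
   derived from a chromosome table (length, centromere centre):
   subtelomeric = 5% of the chromosome length at each end,
   pericentromeric = the centromere centre ± 5% of the chromosome length.
   Membership is any-overlap (≥ 1 bp); a CNV touching both windows is
   counted once with pericentromeric precedence. CNVs longer than 300 kb
   are "large" in the parental enrichment profile.
6. **Expression linkage.** Genes overlapping any CNVR (≥ 1 bp,
   strand-ignored) are "CNV genes", subdivided into deletion-only,
   duplication-only and both (the last excluded from subgroup contrasts).
   Per-gene median FPKM distributions are compared between classes with
   rank-sum tests. For individual-level dosage, raw counts are normalized
   with median-of-ratios size factors (the standard definition: per-sample
   median of count/geometric-mean over genes with no zero count, not
   rescaled to unit product), z-transformed per gene, and carriers are
   compared to non-carriers.

## Coordinate and window conventions

Internally every interval is 0-based half-open, which makes overlap
arithmetic exact and unambiguous. CNV-style TSVs use 1-based inclusive
coordinates on disk (the dialect of array-CNV reports) and gene
annotations are read as BED (0-based); conversion happens only at I/O and
is covered by round-trip tests.

Two readings of "5% windows" are defensible: 5% per side of the
centromere (total 10% pericentromeric) and 5% at each chromosome end, or
half of each. The package defaults to the former, literal reading;
`window_frac` makes the alternative a one-argument change. Similarly, the
reciprocal-overlap threshold is inclusive (`>= 0.4`), the CNVR rule is the
coverage-of-at-least-one criterion, and singleton components count as
CNVRs — the published per-group CNVR pools (for example 86 regions from
10 samples) are only arithmetically possible when unshared CNVs count as
regions, so the "at least two CNVs" phrasing of the classical CNVR
definition is treated as the merge condition, not an existence filter. A
`count_singletons` switch restores the stricter behaviour.

Single-linkage merging is a deliberate, reproducibility-relevant choice: a
component may contain pairs below the threshold (chained through a middle
call). The union span is reported (as merge tools in this space do), with
the intersection core kept as a diagnostic. Note one consequence checked
in the tests: *raising* the threshold cannot rescue more calls into
consensus, but it can split one component into two valid events, so the
event count itself is not monotone.

Inheritance annotation (maternal / paternal / somatic, with disjunctive
labels when one parent is missing) reuses the consensus reciprocal
threshold rather than introducing a second knob.

## The synthetic cohort generator

No genotype or expression data are distributed with the package; the
generator produces cohorts with the statistical structure the analysis
assumes, so every stage can be validated against a known truth.

* **Design.** Defaults mirror an RPL study: placental groups of 10 / 3 /
  9 / 8 samples (RPL miscarriage, RPL live birth, normal first trimester,
  normal term) with mean CNV counts 9 / 7 / 15 / 31 and duplication
  fractions 0.28 / 0.4 / 0.53 / 0.82; mothers for every family, fathers
  for a configurable fraction (term controls are trios, first-trimester
  controls duos); parental genomes at mean 9 CNVs, 25% duplications.
  These values reproduce the defining features of such cohorts: the
  placental duplication excess in normal term pregnancy and its collapse
  in RPL.
* **CNVs.** Lengths are log-normal (median 50 kb, σ = 1 on the log scale,
  so a few percent exceed 300 kb — an SNP-array-like spectrum); positions
  are uniform, chromosomes sampled proportional to length; same-type CNVs
  never overlap within a sample (one CNV state per locus). A pool of 50
  shared polymorphic loci is drawn once; each sample carries each locus
  with its group's frequency (defaults 0.05–0.2, giving the asymmetric
  cross-group sharing the analysis is meant to expose), and the remaining
  (private) count is Poisson so the per-sample total has the configured
  group mean. Family-linked placentas first inherit each parental CNV
  with probability 0.3, then add somatic CNVs with the mean reduced by
  the expected inherited load — the generator cannot make the total
  exactly Poisson *and* inherit per-CNV, so the Poisson mean is preserved
  in expectation and exactly for groups without parents.
* **Callers.** Three callers detect each true CNV independently
  (default probability 0.9), jitter each breakpoint with rounded Gaussian
  noise (sd 2 kb, about half a typical array's mean probe spacing), and
  add Poisson false positives (2 per genome). One caller draws log-normal
  confidences: median 20 for true calls, median 3 for false positives, so
  the conventional floor of 5 removes mostly false calls — the structure
  a log Bayes Factor filter exploits.
* **Expression.** Per-gene baselines are log-normal; genes overlapping
  any true deletion get the baseline multiplied by a configurable fold
  (default 3), emulating the elevated expression observed for
  deletion-prone loci. Carried deletions/duplications multiply a
  sample's expectation by 0.5/1.5 when dosage effects are on. Counts are
  negative-binomial (dispersion 0.1) with log-normal library factors; the
  FPKM layer is derived from counts and gene lengths.
* **Determinism.** One global seed derives three substream seeds in the
  documented order cohort → callers → expression, so a stage can be
  regenerated without rerunning the others. The default genome is four
  toy autosomes (50–150 Mb) including an acrocentric chromosome, so the
  pericentromeric window-clipping path is exercised.

What the generator does **not** emulate: probe-level intensity noise
(B-allele frequency, log R ratio), wave artefacts, GC bias, aneuploidy,
X/Y chromosomes, linkage between loci, or realistic gene clustering.
Passing recovery tests therefore validates the *post-calling* pipeline
logic and statistics, not the behaviour of CNV callers on real array
data.

## Numerical choices and degenerate inputs

* Zero-length intervals are rejected everywhere; overlap fractions of
  disjoint intervals are 0, not NA.
* Shapiro–Wilk requires 3 ≤ n ≤ 5000 and non-constant data; groups
  failing those preconditions are routed to the rank-sum test, as are
  constant groups (where Welch's statistic is undefined). The gate alpha
  (0.05) and the n ≥ 3 guard are package decisions, configurable.
* The rank-sum test follows the standard `wilcox.test` rule: exact when
  both n < 50 with no ties, otherwise normal approximation with tie and
  continuity corrections.
* Fisher's two-sided p is the sum of hypergeometric point probabilities
  not exceeding the observed one (with the conventional 1 + 1e-7 relative
  tolerance); the tests verify it against full enumeration for all tables
  with total ≤ 30.
* Size factors error when no gene has nonzero counts in every sample.
  Multiplying one sample by c scales its factor by c only *relative to
  the others* (the geometric means absorb c^(1/n)); the tests assert the
  ratio form.
* Genes with zero variance, or with an empty carrier or non-carrier set,
  are excluded from the z-score analysis and counted with a reason.
* Density plots use biased cross-validation bandwidth with a fall-back to
  the normal-reference rule when it fails to converge; plots are
  diagnostics only.
* CNVR identifiers are assigned deterministically by (chromosome, start,
  end, type) of each cluster, so reruns on identical input are
  byte-identical.

## Problem sizes used in validation

The test-suite simulations are sized to run on a laptop-scale machine:
oracle-equivalence sweeps use 1,000 random instances of up to 200 calls
against an all-pairs union-find oracle; the noiseless-recovery check uses
a 50-sample cohort (~1,000 CNVs); the detection-probability closed form
(3 × 0.8² × 0.2 + 0.8³ = 0.896) is checked on >2,000 simulated CNVs; the
burden-contrast recovery runs 200 replicate cohorts at the study's group
sizes (10/9/8) and means (9/15/31); fold-recovery uses 2,000-gene
expression matrices over three replicate cohorts. These sizes are the
package's validation choices; all are configurable upward.

## Known limitations

* The per-gene z-score analysis is underpowered when most CNVRs are
  singletons (few carriers per gene) — the pooled mode exists for exactly
  that reason, and neither mode is claimed to be the original study's
  unpublished variant.
* Single-linkage CNVRs can chain distinct polymorphisms into one region
  in CNV-dense loci; the members table retains per-sample events so finer
  post-hoc splitting is possible.
* The pipeline takes per-caller calls as given: it cannot correct caller
  biases that are correlated across callers, and the confidence filter
  applies to one caller only.
* Only autosomes are analysed; sex-chromosome records are dropped at I/O
  with a logged count.

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
cohort <- generate_cohort(cfg)
calls <- emulate_callers(cohort)
expr <- generate_expression(cohort)
paths <- write_cohort_inputs(cohort, calls, tempfile("cohort"), expr)

pc <- pipeline_config(
  calls = paths[["calls"]], chroms = paths[["chrom_info"]],
  meta = paths[["meta"]], genes = paths[["genes"]],
  counts = paths[["counts"]], fpkm = paths[["fpkm"]])
report <- run_cnv_pipeline(pc)
print(report)
summary(report)
```
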