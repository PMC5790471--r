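---
title: "Methods: paired copy-number discordance between primary tumors and liver metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired copy-number discordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pairedcna)
```

## Scope and input model

`pairedcna` compares allele-specific somatic copy-number profiles of
patient-matched primary colorectal tumors and liver metastases. Its input
boundary is deliberately downstream of array processing: each sample enters
as a *segmented profile* — intervals of constant total copy number *t* and
minor-allele copy number *m*, as produced by segmentation of SNP-array
B-allele frequency and logR signals. Computing BAF/logR, the segmentation
itself, and purity estimation are out of scope; purity travels as metadata
only, and profiles below the 50% cellularity inclusion threshold load with
a warning rather than an error, so that the caller decides about exclusion.

Coordinates are 0-based half-open everywhere (files and memory), which
keeps interval arithmetic free of off-by-one corrections; a 1-based export
flag exists for reports. Sex chromosomes are dropped by default when
reading a chromosome-sizes file: the diploid-heterozygous baseline that
anchors the category table below does not hold on male X/Y, and treating
them correctly would need a per-sample baseline ploidy the input format
does not carry. A flag retains them for users who supply such profiles
knowingly.

## State classification

Each (t, m) pair maps to one of five somatic categories or the
diploid-heterozygous baseline:

| category | definition |
|---|---|
| `HOMDEL` | t = 0 |
| `LOSS` | t = 1 |
| `CN_LOH` | t = 2, m = 0 |
| `NEUTRAL_HET` | t = 2, m = 1 |
| `GAIN` | 3 ≤ t ≤ 5 |
| `AMP` | t ≥ 6 |

LOH is minor-allele absence with DNA still present (m = 0, t ≥ 1); a
homozygous deletion is not LOH. The amplification bin is open-ended: its
historical upper edge of 8 reflects the largest value observed in the data
the table was derived from, not a biological ceiling, so higher totals are
classified `AMP` with a warning (they arise routinely here when a gained
region is genome-doubled). The invalid region m > t − m is rejected — the
minor allele is by definition the lesser allele.

## Whole-genome duplication

A sample is called genome-doubled when **more than 70%** of **at least
half** of its chromosomes lies at t ∈ {3, 4} with both parental alleles
present (m ≥ 1). Three readings fixed here:

* "at least half" is inclusive — `qualifying >= ceiling(n/2)`; ">70%" is
  strict.
* "between 3 and 4" is the closed integer set {3, 4}: copy numbers are
  integers after segmentation.
* per-chromosome denominators are **full chromosome lengths** from the
  layout. Bases with no segment count toward the denominator and never the
  numerator, so missing data can only suppress a WGD call, never create
  one.

The genome-wide fraction of (3,4)-biallelic sequence is reported as a
diagnostic (in doubled genomes it typically lands well above 45%) but is
not a gate: the decision is the per-chromosome rule alone.

## Windowed paired discordance

The genome is tiled into 10 kb windows; the last window of each chromosome
may be short (`length %% window_size`) and is kept, weighted equally —
fractions count regions, not bases. Each window takes the state of the
segment with the **largest overlap** within it; ties go to the segment with
the smaller start, then the earlier row, making assignment deterministic
and input-order independent. Windows with no overlapping segment are
missing, and a window enters the comparison denominator only when **both**
samples have a state there — a comparison needs two operands, and imputing
either would manufacture signal.

Per compared window, d = t(met) − t(primary). The window is copy-number
**concordant** iff

* d = 0, or
* the WGD correction is on, d ∈ {+1, +2}, and the LOH status is equal.

Everything else is discordant. The correction exists because a doubled
metastasis gains one to two copies essentially everywhere without selecting
an allele; such a shift is unlikely to change driver-gene expression
relative to background and would otherwise swamp the comparison. Three
consequences of the exact formulation matter:

* it is **one-directional**: d = −1/−2 (a doubled *primary*) is never
  forgiven. The cohorts this mirrors contained no primary-only WGD pairs,
  so the rule is implemented as stated rather than symmetrized.
* a +1/+2 shift that *also* changes LOH status is not forgiven — allele
  selection is exactly what the correction assumes absent.
* it is applied to **all pairs** when enabled (the default), not only to
  WGD-discordant pairs; a per-pair override is available through the
  `wgd_correction` argument.

A window with d = 0 but unequal LOH (e.g. (2,1) vs (2,0)) is copy-number
concordant: the CN metric is a pure total-copy subtraction. LOH
discordance is a separate, independently computed classification of every
compared window — `unchanged`, `loh_in_met` (acquired in the metastasis),
or `het_retained_in_met` (LOH in the primary only) — whose three fractions
always sum to 1. Keeping the two metrics independent mirrors how such
cohorts report copy-number and LOH divergence in separate panels.

Genome-altered and LOH fractions per sample use segment-covered bases as
denominator; "altered" means t ≠ 2, so copy-neutral LOH counts toward the
LOH fraction only.

## Gene-level status

A gene's state comes from the largest segment within or spanning its
footprint (TSS to the last base of the longest transcript), through the
same largest-overlap engine as the windows. Cohort bookkeeping offers two
category cuts for "amplification"/"loss": the default broad cut
({GAIN, AMP} / {LOSS, HOMDEL}) and a strict cut (AMP / HOMDEL only),
because the source material is ambiguous about whether 3-5-copy gains count
— both modes are provided and none is asserted as canonical. An event is
*private to the metastasis* when present there and absent (as a class) from
the paired primary; a gene has *shared status* when its category matches in
every pair where both samples have a status.

Raw category comparison is the default. An optional `wgd_correction`
extends the windowed +1/+2 forgiveness to genes: without it, in a cohort
where a third of metastases are genome-doubled, nearly every gene in those
pairs would register as a private amplification, which is incompatible with
reporting meaningfully small private-event counts. The cohort analysis and
the acceptance script use the corrected mode; the uncorrected contract
remains available and is what the low-level functions default to.

## Cohort statistics

Group comparisons (treatment-naive vs post-therapy metastases; synchronous
vs metachronous) use the two-tailed **pooled-variance** Student's t-test —
the literal reading of the named method — with Welch available behind
`var_equal = FALSE`. Raw p-values are reported with no multiple-testing
correction, matching the descriptive framing of such cohort reports, and
significance is flagged at p < 0.05. Tests run on raw fractions, not
arcsine- or logit-transformed values: nothing in the source material
suggests a transform, and the calibration tests show nominal type-I error
at the cohort's group sizes (10 vs 6) for the effect sizes involved.

## The synthetic-data generator

Both branches of a pair start from a diploid-heterozygous genome, receive
shared trunk events, then private branch events, then optionally a
whole-genome doubling (late doubling by default; `wgd_order = "early"`
doubles before branch events). Internally states are (major, minor) allele
counts; events are loss (one copy, minor-allele-biased via `loh_bias`),
gain (+1), amplification (+4), homozygous deletion, and copy-neutral LOH
(minor zeroed, total preserved), with copy numbers clipped at zero and the
minor-allele invariant re-normalized after every application.

**Free mode** (`target_discordance = "free"`) draws Poisson event counts
(defaults: trunk 60, branch 25 per side) with log-uniform lengths
(50-500 kb) and weighted types. The default rates give modestly unstable
genomes (~15% trunk-altered fraction) — deliberately, so that a doubled
branch keeps >70% of most chromosomes at (3,4)-biallelic states and the
WGD-recovery invariant (≥99% detection of doubled branches) holds; heavier
instability is a parameter away.

**Targeted mode** (numeric `target_discordance`, plus
`loh_met_fraction` / `loh_primary_fraction`) plants exact window-level
budgets. The genome is partitioned into blocks (log-uniform lengths,
snapped to window boundaries by default); disjoint block sets are allocated
to trunk events, CN-discordant regions, metastasis-only LOH and
primary-only LOH, so planted classes never overwrite each other and the
realized fractions equal the budgets exactly at window resolution. With
`snap_to_windows = FALSE` boundaries are arbitrary base pairs and the
planted budget is met within one window's weight per breakpoint
(boundary-quantization bound, asserted in tests). How a CN-discordant
block is realized depends on the pair's WGD configuration, because the
+1/+2 correction semantics must not forgive it and the doubled branch must
stay detectable:

* no WGD: +3-copy gains on the metastasis (d = +3);
* metastasis-only WGD: +3-copy gains on the **primary** (negative d, never
  forgiven, and the doubled metastasis keeps its (4,2) carpet);
* WGD in both: single-copy losses on the metastasis applied **after** the
  doubling (d = −1; the resulting (3,1) state still qualifies for the WGD
  rule on both branches).

In WGD-asymmetric pairs, planted LOH blocks are themselves CN-discordant
(the doubling turns them into +2-with-LOH-change windows), so the CN budget
is debited by the LOH budgets; targets too small to absorb that debit, and
any targeted configuration with primary-only WGD (where every window
carries an unforgivable negative diff), error out as infeasible rather
than silently missing the target. Trunk events in such pairs are
restricted to losses and copy-neutral LOH, whose post-doubling diffs (+1/+2
with unchanged LOH) the correction forgives — so trunk sharing does not
leak into the discordance budget.

**Ground truth** is recomputed from the *emitted* segment tables by an
independent measurement path (`pair_ground_truth()`): plain
interval-arithmetic scans with `findInterval`, sharing no code with the
GenomicRanges-based pipeline route. At the default genome size a literal
per-base implementation is impractical in R; per-base oracles are used in
the test suite on ≤100 kb toy genomes, where window assignment, genome
fractions, WGD fractions and pair discordance are checked against base
counting exactly.

**Cohort simulation** draws one block partition per cohort and marks half
the genome (by default) as recurrent "hotspot" territory from which every
pair's private events are drawn first, so discordant loci recur across
pairs the way driver regions do in real cohorts. The default 16-pair
design mirrors the study conditions this package models: 10
treatment-naive and 6 post-therapy metastases, 9 synchronous and 7
metachronous presentations, WGD in both samples in 4 pairs and in the
metastasis alone in 5 (never the primary alone), per-pair discordance
budgets averaging 0.28 (naive) vs 0.12 (post-therapy) — 0.22 overall —
and LOH budgets placing primary-only LOH mostly in naive pairs (0.09 vs
0.02) and metastasis-only LOH mostly post-therapy (0.11 vs 0.03), a mean
paired LOH difference of 0.124. Four patients carry a planted
metastasis-private amplification of one actionable gene each. Budgets are
jittered multiplicatively (log-sd 0.15, mean-corrected) to emulate
biological spread; purities are drawn uniformly on [0.5, 0.95]. The gene
panel places 188 candidate and 24 actionable footprints (10 shared)
uniformly and non-overlapping, 60 kb each on the default layout.

### What the generator does and does not emulate

It reproduces the *structure* the analysis assumes — shared trunk, private
branches, WGD, recurrent loci, planted effect sizes — with integer clonal
copy numbers. It does **not** model subclonality (non-integer states),
purity dilution of the signal, probe-level noise, or array coverage gaps;
real profiles carry all four. Passing tests therefore demonstrate that the
measurement machinery is exact on its input contract, not that upstream
segmentation errors are survivable. Two further divergences from real
cohorts are worth naming. First, window counts are layout-dependent: the
scaled default genome has 11,000 windows; `hg_autosome_layout()` (hg19-like
autosomes, ~2.88 Gb) tiles into ~288,000 — close to, but not exactly, the
~288k-window genomes of full-size human analyses, whose exact region sets
depend on the array manifest and are not reconstructable here. Second,
gene-level concordance in the default synthetic cohort (~30-40% of
candidate genes shared) is lower than the ~65% real paired cohorts report:
planted events fill the recurrent territory fairly uniformly, whereas real
discordance concentrates in gene-poor and pair-specific regions. The gene
bookkeeping is validated against the generator's independent ground truth
exactly; the absolute concordance level is a property of the synthetic
conditions, not a target.

## Numerical and design choices

* **Tie-breaks**: largest-overlap ties go to the smaller segment start,
  then the earlier segment row — deterministic, order-independent.
* **Determinism**: a single seed fixes a cohort; identical config and seed
  reproduce byte-identical pipeline outputs (checksummed in
  `manifest.tsv`, with version, seed and config hash in every table
  header).
* **Degenerate inputs**: empty profiles error in WGD and fraction calls;
  an empty layout tiles to an empty grid; zero-budget planting classes are
  skipped; genes or windows without coverage are missing, never imputed.
* **Problem sizes**: tests run the scaled 22 × 5 Mb genome (11,000
  windows) for cohort-scale checks and 22 × 10 Mb (22,000 windows) for
  parameter recovery, sizes at which planted budgets are recovered within
  ±0.02 while the full suite stays in minutes; per-base oracles use
  ≤100 kb toys where brute force is exact and fast.
* **Statistical calibration sizes**: type-I calibration uses 1,000
  metric-level replicate cohorts at the 10-vs-6 group split; power and
  direction checks use 150-200 replicates per effect size.

## Known limitations

* The category table presumes a near-diploid reference; sex chromosomes
  need user-supplied handling.
* The +1/+2 correction is a blunt instrument: it forgives genuine
  single-copy gains without LOH change in non-doubled pairs too. This is
  the stated behavior of the method being implemented (correction applied
  to all pairs), not an oversight; the uncorrected fractions are always
  computed alongside.
* Windowed fractions weight the short terminal window of each chromosome
  like any other; at 10 kb resolution on real chromosomes this is a
  ≤0.01% effect.
* `run_pipeline()` holds all profiles in memory; full-size genomes with
  hundreds of samples would want chunked processing.
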