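---
title: "Stage-resolved methylome analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved methylome analysis: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methstage)
```

# Overview

`methstage` implements the methylome computations needed to follow DNA
methylation through the formation and differentiation of mouse
spermatogonial stem cells: neonatal (P0.5) prospermatogonia resume
mitosis and give rise, by postnatal day 7, to undifferentiated (Kit−)
and differentiating (Kit+) spermatogonia. Whole-genome bisulfite
sequencing (WGBS) of these stages raises a specific set of
computational problems — partially methylated domains (PMDs), transient
non-CG (CH) methylation, 5-hydroxymethylcytosine (5hmC), and sparse
stage-specific differential methylation — and this package provides a
tested implementation of each step, together with a synthetic-data
generator that plants every signal it is supposed to recover.

This vignette explains the statistical models, the tunable parameters
and their defaults, what the simulation does and does not emulate, and
the design decisions taken where more than one reading was defensible.

# The data model

Every methylation quantity derives from the *cytosine call table*: one
row per cytosine with methylated and total read counts, strand, and
context class (CG, CHG, CHH). All internal coordinates are 0-based
half-open; 1-based conventions exist only at I/O boundaries
(`read_cytosine_report()`, `write_bed()`). Two rules are applied once,
in order, before any analysis:

1. **Symmetric-CpG merging** (`merge_symmetric_cg()`): the two
   cytosines of a CpG dyad (plus strand at p, minus strand at p+1)
   report the same methylation state, so their counts are combined
   into one strand-free record at p.
2. **Coverage filtering** (`filter_by_coverage()`): CG records need at
   least 6 reads, CH records at least 4, and any record with more than
   100 reads is discarded as a likely collapsed repeat. Filtering is
   idempotent.

Region and window levels are *pooled-read* fractions, `sum(n_meth) /
sum(n_total)`, not means of per-site fractions. The pooled definition
is the one conventionally reported for WGBS global levels and remains
well defined at low coverage; per-site fraction vectors appear only
where the DMR test needs them (below).

# Bisulfite conversion

Unconverted (but unmethylated) cytosines read as methylated. The
unmethylated lambda spike-in estimates the failure rate r as its
pooled methylation level (`estimate_nonconversion()`); the package
assumes one global rate per sample because the spike-in provides a
single genome-wide estimate. Assuming failures strike uniformly at
random among truly unmethylated cytosines, an observed level o mixes
the true level t as o = t + (1 − t)r, and
`correct_nonconversion()` inverts this exactly: t = (o − r)/(1 − r),
clamped at 0. Naive subtraction o − r is biased upward at high t; at
r ≈ 0.003 the difference is small but the mixing model is the stated
assumption, so it is inverted exactly. Whether global CG levels should
be corrected or raw is exposed as a choice (pass `rate = 0` to skip
correction); per-context breakdowns are always corrected.

# PMD segmentation

PMDs are megabase-scale blocks of intermediate methylation. The
segmenter (`segment_pmds()`) is a two-state hidden Markov model over
the levels of nonoverlapping 10-kb windows with at least 5 informative
CGs: a PMD state with lower-mean Gaussian emissions and a background
state with higher-mean emissions. Emission parameters are initialized
by a two-component EM fit of the pooled level histogram and refined by
Baum–Welch together with the transition matrix, which carries a sticky
Dirichlet prior (prior mass on staying, initialized at 0.99) because
true domains span tens to hundreds of windows. Viterbi decoding gives
the state path; consecutive PMD windows merge into segments.

Numerical choices:

* **Degenerate (unimodal) inputs.** When the two fitted emission means
  are closer than `min_separation` (default 0.1), the level histogram
  is effectively unimodal and no PMDs are called, rather than letting
  the HMM split noise.
* **Detection vs display.** Segments shorter than `min_length`
  (default 100 kb) are dropped at detection; a separate
  `report_min_length` (default 500 kb) reproduces the convention of
  displaying only large domains. Keeping the two apart means the
  display rule never silently changes what was detected.
* **Missing windows** (below the site minimum) are skipped in the
  observation sequence; a segment may therefore bridge small gaps.
* At least 50 informative windows are required to fit emissions.

The segmenter replaces an external black-box tool by design: its
validation target is planted truth (Jaccard overlap of at least 0.9 on
domains of 1 Mb and larger at 15× depth), not coordinates from any
particular external run.

Downstream classification takes PMD calls from the P0.5 methylome:
windows overlapping any PMD by 1 bp or more are PMD windows
(`classify_windows_pmd()`), and genes whose promoter — 2000 bp
upstream to 500 bp downstream of the TSS, strand-aware — overlaps a
PMD are PMD genes (`assign_pmd_genes()`). PMD genes are expected to be
transcriptionally silenced; `pmd_expression_summary()` reports the two
groups on the log2(FPKM + 1) scale.

# DMR calling

Stage-specific differentially methylated regions are found by a
sliding-window screen between two stages (`find_dmrs()`):

1. **Enumeration.** 500-bp windows slide at 100-bp steps. A window
   qualifies when it contains at least 5 CG sites covered at least 10
   times in *both* stages; the same site set enters both stages'
   vectors. Replicates are pooled at the count level before the
   screen: with two biological replicates per stage, a replicate-level
   t-test would have no usable degrees of freedom, so the unit of
   observation is the per-CG-site methylation fraction within the
   window, and the 5-site minimum guarantees at least 5 observations
   per group.
2. **Testing.** Welch's unequal-variance t-test compares the two
   stages' per-site fraction vectors (two-sided). When both groups
   have zero variance the statistic is undefined: p is set to 0 when
   the means differ (every site differs in the same direction) and 1
   when they are equal — explicit and conservative.
3. **Correction.** Benjamini–Hochberg is applied once across all
   eligible windows of the comparison (not per chromosome), because
   the screen is genome-wide.
4. **Thresholding.** A window is significant when all three hold: the
   pooled-level difference exceeds 30 percentage points in absolute
   value, p < 0.02, and q < 0.05. The 30% criterion is read as 30
   absolute points — the standard reading in WGBS work; a relative
   criterion would make any hypomethylated region trivially
   significant.
5. **Merging.** Overlapping significant windows of the same direction
   merge into maximal runs; gain and loss runs are merged separately,
   since a mixed-sign merge would produce a self-contradictory DMR.
   Intervals are half-open, so abutting windows do not merge. Every
   DMR length is therefore 500 + 100k bp. DMR stage levels are
   recomputed as pooled levels over the merged interval.

The screen's operating characteristics are validated on simulation:
planted 40-point DMRs (8 CG sites, 15× per strand, 2 replicates) are
recovered with sensitivity above 0.8, the empirical false-discovery
proportion over 20 simulation replicates stays within the nominal
0.05, and a null comparison of identical methylomes yields no calls.

# Trajectory clustering

Each DMR becomes a trajectory row (L0, Δ1, Δ2): its level in P0.5
prospermatogonia (percentage points) and the changes across the two
transitions (`build_trajectories()`). Rows are clustered by
agglomerative hierarchical clustering with Euclidean distance and
complete linkage — the default behavior of `hclust`/`dist` — with the
dendrogram cut at k = 6 (`cluster_trajectories()`). No scaling is
applied: all three coordinates share the percentage-point scale.

Raw dendrogram labels are arbitrary, so clusters are renumbered by
sorting their mean trajectories lexicographically in descending
(L0, Δ1, Δ2) order. High-start archetypes come first and
low-start/late-gain archetypes last, which makes labels reproducible
and invariant to row permutation.

k = 6 is a parameter defaulting to the observed number of trajectory
groups; `select_k_silhouette()` exists to validate that choice against
planted data, not to second-guess it. It cuts the same dendrogram at
each candidate k and returns the k with maximal mean silhouette width.
A best silhouette below 0.4 sets `structure = FALSE`: a single
trivariate Gaussian blob already scores about 0.3 under this linkage,
while genuinely separated archetypes score 0.5 and above, so 0.4
separates "no structure" from "real structure".

# 5hmC estimation

Bisulfite sequencing reads 5mC and 5hmC both as methylated; oxidative
bisulfite reads only 5mC. `estimate_5hmc()` therefore subtracts the
oxBS level from the BS level at sites covered at least `min_coverage`
(default 6, reusing the CG filter) in *both* assays — subtraction is
meaningless at sites measured in one assay only. Per-site negative
differences are sampling noise and are clamped to 0, with the raw
difference retained for diagnostics. The pooled estimate subtracts
pooled levels (unclamped sums) by default because pooling clamped
values biases the estimate upward; `clamp_pooled = TRUE` restores
strict per-site clamping for comparison. Genome-wide 5hmC is reported
at CG sites (`pooled_hmc_cg`), where nearly all hydroxymethylation
resides; `hmc_context_split()` quantifies that dominance using
unclamped per-context sums floored at zero, so symmetric noise at
unhydroxylated CH sites cancels instead of accumulating.
`modified_base_density()` converts levels into modified bases per 100
bp, which can rank compartments differently from levels: a dense,
moderately modified satellite compartment can out-dense a sparse,
highly methylated genome-wide background.

# Gene association

`build_regulatory_domains()` re-implements basal-plus-extension
regulatory domains: a strand-aware basal window from 5 kb upstream to
1 kb downstream of the TSS, extended in both directions up to 1 Mb
from the TSS but truncated at the nearest neighboring gene's basal
domain (never below the gene's own basal window). Construction is
deterministic and order-independent. DMRs link to every gene whose
extended domain they overlap by 1 bp or more.

Expression changes between stages are called when the fold change
(larger FPKM over smaller) exceeds 2.0 *and* the absolute difference
exceeds 5.0 FPKM, jointly. With a zero FPKM in one stage the fold
change is undefined; the fold criterion is treated as satisfied and
the call reduces to the delta criterion — a gene appearing from 0 to
more than 5 FPKM is unambiguously changed. Swapping stages flips up
and down and preserves "none". Enrichment of expression change among
DMR-linked genes is tested with Pearson's chi-squared on the 2×2
linked-by-changed table, df = 1, without continuity correction.

# The synthetic-data generator

`simulate_methylome()` emits per-stage, per-replicate call tables plus
an exact truth record. Its defaults are the desk-scale study
conditions used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| genome | 2 chromosomes × 5 Mb | ~1/500 of a mammalian genome; full pipeline in seconds |
| CpG dyad spacing | ~100 bp (exponential gaps) | mammalian-like CpG density |
| CH spacing | ~40 bp | desk-scale stand-in for full CH density (see below) |
| depth | Poisson, mean 15 per strand | matches the ~15.5×-per-strand design |
| replicates | 2 per stage | matches the two-biological-replicate design |
| background CG level | 0.85 | non-PMD neonatal prospermatogonia |
| PMDs | 1 per chromosome, 1.5–2.5 Mb at 0.45 | large intermediate-level domains |
| DMR archetypes | 6 trajectories (`dmr_archetypes()`) | the six observed cluster patterns |
| CH level | 0.10 in P0.5, 0.01 after | CH methylation lost on resumption of mitosis |
| 5hmC at CG | 0.014 | genome-wide neonatal level |
| conversion failure | 0.003 | sub-0.5% failure, conversion > 99.5% |

Reads are binomial per site on the failure-mixed probability
t + (1 − t)r, with an optional beta-binomial layer
(`overdispersion`) so the DMR caller's calibration can be examined
under overdispersed noise as well. CpG dyads are emitted on both
strands; the spike-in is emitted with true level 0. Everything is
bit-reproducible from (config, seed).

Two approximations are deliberate. First, cytosine composition: in a
real mammalian genome only ~4–5% of cytosines sit in CG context, which
would require a CH site every ~2.5 bp — unaffordable at default scale.
The default keeps CH sites at 40-bp spacing; analyses that depend on
the composition itself (the per-context breakdown of all cytosines)
are validated with a config whose CG:CH cytosine ratio matches the
mouse genome over a smaller region. Second, the two sparsely populated
trajectory archetypes are only verbally characterized in the source
material; `dmr_archetypes()` parameterizes them as mid-level patterns
(one gaining methylation on the Kit−→Kit+ transition) and marks them
as approximations. Archetype stage levels were chosen to span the
dynamic range of the observed heat-map patterns with distinct mean
trajectories; rows are pre-sorted into the canonical cluster order so
planted archetype i is recovered as cluster i.

The generator does *not* emulate: sequence composition (GC isochores,
CpG islands), repeat structure, chromatin-state correlates of PMDs,
read-level error profiles, or mapping bias. Passing recovery tests
therefore demonstrates the correctness and calibration of the
*computations* under the stated noise model, not robustness to every
artifact of real libraries.

`simulate_expression()` plants the two expression signals the
association analyses look for: PMD genes draw FPKM from a low
log-normal, and genes whose regulatory domains overlap planted DMRs
change expression between stages with elevated probability, with
planted changes constructed to clear the fold/delta thresholds (a
planted "down" change from a baseline too low to clear the delta
criterion is planted upward instead).

# Problem sizes and determinism

The test suite runs its simulations at 0.3–5 Mb genome scale, chosen
so the full suite completes in about a minute while every recovery
bound retains comfortable statistical margin. The acceptance script
uses one 5-Mb chromosome with 100 planted DMRs per seed, 20 seeds for
the false-discovery proportion and 10 for the conversion-rate bound.
All randomness flows from explicit integer seeds; identical inputs
give bit-identical outputs.

# Known limitations

* The Welch screen models site-level fractions, not biological
  replicate variance; with overdispersion well beyond the binomial the
  realized FDR can exceed the nominal level (the `overdispersion`
  knob exists to study this).
* The HMM segmenter assumes two emission components; methylomes with
  three distinct level regimes (e.g., widespread intermediate
  compartments) would need a third state.
* Nonconversion is corrected with a single global rate; context- or
  region-specific failure is not modeled.
* 5hmC estimation by subtraction ignores the joint sampling
  distribution of BS and oxBS counts; a maximum-likelihood joint
  estimator is out of scope.
* Repeat-consensus compartments (satellites) are accepted as
  pre-tagged call tables; the package does not align reads.
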