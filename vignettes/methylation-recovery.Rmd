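---
title: "Quantifying de novo DNA methylation recovery from MeDIP-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying de novo DNA methylation recovery from MeDIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methrecover)
library(dplyr)
```

## The experimental design this package analyzes

A chromatin-remodeling factor required for DNA methylation (such as the
SNF2-family ATPase LSH/HELLS) is knocked out, leaving fibroblasts with a
genome-wide methylation deficit concentrated at particular region classes:
satellite repeats, IAP and LINE retrotransposons, many gene bodies,
intergenic blocks and a subset of promoters. The factor — or a
catalytically dead point mutant — is then re-expressed, and the question is
how much of the lost methylation each rescue line regains, and where.

Four methylomes are profiled by MeDIP-seq (immunoprecipitation of
methylated DNA followed by sequencing, where read density over a region is
a proxy for its methylation):

* a wild-type **reference** (`WT`),
* the knockout carrying an empty vector, the **baseline** (`MSCV`),
* one or more **test** rescue lines (active factor, or the ATP-binding
  mutant `K237Q`).

The same design recurs at single-locus resolution with clone bisulfite
sequencing, and globally with HPLC quantification of 5-methylcytosine and
qPCR of re-silenced transcripts; the package covers those calculators too.

## Normalization

Region-level read counts are not comparable across samples or regions as
they stand. Two steps make them so.

**RPK scaling.** Each count is divided by its region length in kilobases
(`rpk()`), then log2-transformed with a pseudocount:
`value = log2(count / (length/1000) + pseudocount)`. The pseudocount
(default 0.5, a conventional half-count) keeps zero-count regions finite;
the method text this pipeline follows is silent on zeros, so this choice is
ours and is configurable.

**Invariant-region affine transform.** A set of *invariant* ("non-changing")
control regions — regions known not to differ in methylation between the
compared cell states — anchors between-sample comparability. For each
non-reference sample an ordinary least-squares line of the sample's log2
values on the reference's, restricted to the invariant set, is fitted
(`fit_invariant_model()`), and the whole sample is transformed with
`value' = (value - intercept) / slope` (`apply_model()`) so that the
invariant regression has intercept 0 and gradient 1. This holds exactly by
the linearity of least squares, up to floating point — the package asserts
it to 1e-9 — and the transform is affine, hence rank-preserving within a
sample.

Design choices the method text leaves open, decided here: the regression
direction is sample-on-reference (everything is anchored to the wild-type
profile; the direction is configurable); a negative fitted slope is an
error, not a silent transform, because an anti-correlated invariant set
indicates corrupt input; the invariant fit uses the same log2-RPK values as
the rest of the pipeline.

One statistical caveat worth knowing: with noisy counts on both axes, OLS
slopes are attenuated below 1 (errors in variables). The transform still
exactly renormalizes the invariant regression, but an invariant set whose
true signal spread is small relative to counting noise is a weak anchor.
This is why useful invariant sets span the full dynamic range — from
constitutively unmethylated CpG islands to fully methylated repeats — and
why the synthetic generator builds its anchor set that way (below).

## The methylation-recovery statistic

For each region, on the normalized log2 scale, with `w` the reference
value, `m0` the baseline value and `s` a test sample's value:

* deficit: `D = w - m0` — how much log2 signal the knockout lost;
* residual deficit: `S = w - s` — how much is still missing in the rescue;
* **methylation recovery**: `MR = 100 (D - S) / D`, equivalently
  `100 (s - m0) / D` — the percent of the lost log2 signal regained.

`MR = 100` when the rescue matches the reference and `MR = 0` when it
matches the baseline; these two identities pin the statistic down. (The
source formula as printed garbles this expression typographically — it
applies a second log2 to quantities that are already log2 differences,
which breaks both identities — so the package implements the canonical
form above.)

MR is only meaningful where there was a deficit to recover. Regions with
`D < d_min` are flagged `low_deficit` and excluded from summaries, never
silently dropped. The default `d_min = 1` log2 unit (a two-fold loss)
operationalizes "methylated in wild type but not in the knockout"; no
numeric cutoff is stated in the source, so the value is ours and is
reported in every output. MR is *not* clamped to [0, 100] by default:
sampling noise legitimately produces overshoots, and clamping would bias
class summaries; it is available as an opt-in flag.

Summaries follow the conventions of the recovery boxplots:
`summarize_recovery()` computes quartiles by linear interpolation of order
statistics (R quantile type 7; other conventions shift whiskers slightly)
and whiskers at the most extreme observations within 1.5 IQR of the
quartiles. `fraction_recovered()` reports the percent of scored regions
with `MR >= mr_threshold` (default 50%, the package's reading of
"substantially recovered"; again configurable and recorded in the output).
`spearman_matrix()` compares whole methylome profiles by Spearman rank
correlation with average ranks for ties; a constant column yields `NA`
("undefined"), never a silent 0.

```{r recovery-demo}
params <- sim_params(n_regions = 120, n_invariant = 100)
ann    <- simulate_annotation(params, seed = 1)
truth  <- simulate_methylomes(ann, params, seed = 2)
counts <- simulate_medip_counts(truth, ann, params, seed = 3)
norm   <- normalize_dataset(counts, ann, params$samples)
tidy(norm)
records <- recovery_table(norm, params$samples, ann, d_min = 1)
summarize_recovery(records)
```

## What the synthetic generator emulates

The deposited sequencing data behind the original analysis is not needed:
`sim_params()` + the `simulate_*()` functions generate every input the
pipeline consumes, from a seed, with the statistical structure the analysis
assumes. All generators are pure functions of `(params, seed)`.

**Methylomes.** Wild-type methylation is Beta(8, 2) per region (mostly
methylated, as MeDIP-visible regions are). A configurable fraction of each
class is factor-dependent; at those regions the baseline loses
`loss_fraction = 0.9` of wild-type methylation — dependent regions are
defined by being essentially unmethylated in the knockout, which is also
what makes the `d_min` filter meaningful. Invariant anchor regions keep a
common level in all samples, drawn uniformly on [0, 1]: a control set is
only useful if it spans the scale it anchors.

**The recovery parameter.** Each test sample has a true recovery fraction
`rho` (paper-like preset: 0.6 for the active rescue, echoing the reported
40–80% range; 0.1 for the dead mutant's weak but consistent recovery),
optionally biased per class (`class_bias`) to emulate the active factor
favoring gene bodies and the mutant favoring intergenic regions. `rho` is
defined on the scale the MR statistic measures: the test sample's expected
MeDIP signal interpolates *geometrically* between baseline and wild type,
`q_test = q_m0^(1-rho) * q_wt^rho` with
`q = background + (1 - background) * methylation`, so the fraction of the
log2 deficit regained is exactly `rho` and MR estimates `100 rho`. (Linear
interpolation of methylation itself would make MR a biased estimate of the
interpolation weight — by 10–15 points mid-range at a 3-log2 deficit —
because the statistic lives on the log scale; defining the truth parameter
on the measurement scale keeps the simulation's "truth" and the
estimator's estimand the same quantity.)

**Counts.** Region counts are negative binomial with mean
`library_factor * enrichment * (length/1000) * depth * q` and variance
`mu + dispersion * mu^2` (defaults: depth 200 reads/kb at full
methylation, dispersion 0.2). The per-sample `library_factor` (log-uniform
on [0.5, 2]) is the distortion the normalization must remove. The
per-region `enrichment` (log2-uniform on [-3, 8], shared by all samples)
emulates the orders-of-magnitude spread of real region-level MeDIP
coverage driven by CpG density, mappability and repeat copy number; being
shared, it cancels out of `D`, `S` and MR, but it gives the invariant
regression and the rank correlations the dynamic range real count tables
have. Region lengths are class-typical (promoters 0.5–2 kb, gene bodies
2–10 kb, intergenic 1–5 kb, repeats 1–6 kb — full-length IAP/LINE elements
are 6–7 kb and satellite arrays kb-scale), floored at 200 bp, the
sonication-fragment scale. CpG-density *confounding* of MeDIP enrichment
(differential pulldown efficiency per methylated cytosine) is deliberately
not simulated, matching the pipeline's explicit non-goal of
CpG-coupling correction.

**What passing tests do and do not show.** Under these conditions the
package verifies that class-median MR recovers `rho` within ±8 points in
at least 18 of 20 seeds at 500 regions/class, and that an active-like
rescue (`rho = 0.6`) outranks a mutant-like one (`rho = 0.1`) in every
class in 20 of 20 seeds. That demonstrates the estimator and pipeline are
correct for data with this structure; it does not validate the biological
model on real data, where CpG-density effects, copy-number change between
lines, and batch structure would add distortions the generator does not
produce.

## Clone bisulfite analysis

The single-locus counterpart: PCR amplicons from bisulfite-converted DNA
are cloned and Sanger-sequenced, one clone per DNA strand. The package
re-implements the essentials of this analysis style:

* `align_global()` — Needleman–Wunsch global alignment of each clone to the
  *unconverted* reference (match +1, mismatch −1, gap −2), with a fixed
  traceback tie-break order (diagonal, then up, then left) so calls are
  byte-reproducible. Comparing against the unconverted reference makes
  calling a direct read-off; the conversion chemistry lives in the
  simulator.
* `call_methylation()` — at each CpG cytosine: clone `C` = methylated,
  `T` = unmethylated, anything else missing. Per-clone QC: the
  **conversion rate** (fraction of non-CpG reference cytosines read as
  `T`; incomplete chemistry leaves stray `C`s) and the **identity** over
  aligned non-cytosine positions (so expected C-to-T changes never count
  as mismatches).
* `build_pattern()` — excludes clones under `min_conversion = 0.95` or
  `min_identity = 0.80` (common practice for this analysis style; the
  source states no thresholds), then tabulates per-CpG and overall percent
  methylation over non-missing calls. Only the top strand is analyzed, as
  in one-strand-per-row lollipop figures.
* `compare_patterns()` — difference in overall percent with a seeded
  clone-resampling bootstrap interval; `render_lollipop_text()` and
  `autoplot()` draw the familiar filled/open circle grids.

```{r bisulfite-demo}
amp <- simulate_amplicon(length_bp = 200, n_cpg = 10, seed = 11)
clones <- simulate_bisulfite_clones(amp, p_meth = 0.7, n_clones = 8,
                                    seed = 12)
pat <- analyze_clones(amp, clones$clones)
glance(pat)
cat(render_lollipop_text(pat), sep = "\n")
```

## Assay calculators

**Pfaffl qPCR fold change.** `pfaffl_fold_change()` computes
`E_t^dCt_t / E_ref^dCt_ref` with efficiencies as per-cycle amplification
factors (2 = perfect doubling; percent-style inputs like 95 are rejected
rather than guessed at) and `dCt = control − sample` (the sign convention
is ours and documented; at `E = 2` the expression reduces exactly to the
classic `2^(-ddCt)`). Technical-replicate Cts are averaged before the
ratio, the usual practice where the source does not specify.

**HPLC percent 5mC.** `hplc_5mc_percent()` converts dCMP and 5-methyl-dCMP
peak areas (detected at 276 and 282 nm) to molar amounts via their
extinction coefficients (8.86e3 and 9.0e3) and reports
`100 * n_5mC / (n_C + n_5mC)` — 5mC as a percentage of the cytosine pool,
which is the scale on which statements like "3.3% of total cytosine" are
made. The result is invariant to rescaling both areas.

## Numerical and interface conventions

* Coordinates are BED: 0-based, half-open, everywhere; 1-based inputs must
  be converted by the caller. Strand is read but ignored by counting
  (MeDIP enrichment is strand-agnostic). A read overlapping k regions
  counts in all k; duplicate reads are counted as given.
* The BED dialect puts the region class in column 5 and an optional 0/1
  invariant flag in column 7; canonical 5-column files round-trip
  byte-identically.
* All text outputs are UTF-8 with LF endings; every pipeline artifact is a
  pure function of `(params, seed)` and the package asserts byte-identical
  reruns.
* Degenerate inputs fail loudly: fewer than 3 invariant regions, a
  constant reference over the invariant set, `D = 0` with `d_min = 0`,
  all clones failing QC, both HPLC areas zero.

## Problem sizes

The shipped checks run the full pipeline at 500 regions per class over 20
seeds for the parameter-recovery and ordering properties (a few seconds
per run), 100-instance oracle comparisons for counting, correlation,
alignment and quantiles, and 50-clone bisulfite recovery — sizes chosen so
the whole suite exercises every claim in minutes on a laptop while keeping
the Monte-Carlo margins (±8 points on a class median at n = 500) well
resolved.

## Known limitations

* MeDIP CpG-density coupling is not corrected or simulated; recoveries are
  relative to the assay's own enrichment scale.
* MR is a per-region ratio of noisy differences; at deficits near `d_min`
  the selection on the *measured* deficit slightly biases MR downward.
  Class medians over hundreds of regions absorb this (it is inside the
  ±8-point envelope the tests assert), but per-region MR values near the
  threshold should be read with care.
* The bootstrap interval in `compare_patterns()` resamples clones, not
  CpGs; it reflects clone-to-clone variation within one amplicon.
* Statistical testing of MR differences between samples is out of scope,
  as is genome-browser track export.
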