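---
title: "Hierarchical antibody-binding calls from tiled peptide arrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical antibody-binding calls from tiled peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcope)
```

## The problem

Whole-proteome peptide microarrays tile every protein with overlapping
16-mer peptides and read out serum antibody binding as fluorescence, so
a single chip reports millions of probe-level measurements per serum.
The analytical task is to decide, for each immune serum, which probes
are antibody-bound, to assemble bound probes into epitope regions with
a consensus binding sequence, to roll regions up to proteins, and to
quantify co-recognition across animals and reproducibility across
replicate chips. `episcope` implements this chain end to end together
with the orthogonal-validation statistics used to check array calls
against an independent assay.

## Probe library design

Reviewed proteins are tiled every 2 aa, unreviewed ones every 4 aa
(`tile_protein()`, `build_probe_library()`). Two choices are worth
spelling out:

* **C-terminal anchor.** When `(L - 16) mod step != 0` the regular grid
  leaves up to `step - 1` terminal residues unprobed; one extra probe
  anchored at `L - 15` is appended so the tiling covers the entire
  linear sequence. `cterm_anchor = FALSE` restores strict arithmetic
  tiling.
* **Nonstandard residues.** Proteins may contain X/U/B/Z. Probes
  containing them are kept (so protein coordinates stay intact) but
  flagged `nonstandard`; the simulator never spikes them. Proteins
  shorter than 16 aa are skipped with a warning. Both policies are
  package decisions - the standard handling is not dictated by the
  assay itself.

Identical peptides arising at several positions are synthesised once;
`restore_redundant()`/`restore_matrix()` broadcast each unique
peptide's value back to every (protein, start) occurrence before any
positional operation, so a shared peptide is smoothed in each protein
context separately.

## Preprocessing

The order is fixed: log2, quantile normalisation across samples,
then a sliding-mean smooth along each protein (`+/-8` aa around the
probe start, truncated at protein ends, never crossing protein
boundaries). Window membership anchors on the probe **start**
coordinate (option `anchor = "mid"` uses the probe midpoint instead);
with a 2-aa grid the default window averages up to 9 probes. Quantile
normalisation uses the standard rank-mean construction with ties
receiving the mean of the rank means they span; all samples are
normalised jointly by default (`norm_groups` overrides, e.g. per
batch). Raw values must be positive; an explicit `pseudocount` is the
only escape hatch.

## Probe-level inference

All tests are one-sided (upper tail): antibody binding only elevates
signal.

* Global z-test: pooled mean and SD are computed over the **entire**
  processed matrix (all probes x all samples, naive included), and
  `p_g = 1 - pnorm(x, mu, sigma)`.
* Differential test: a one-observation prediction-style t against the
  naive group of the same probe,
  `t = (x - mean_naive) / (sd_naive * sqrt(1 + 1/n))`, `df = n - 1`.
  A variance floor (`var_floor = 0.01` log2 units) guards probes whose
  naive signal is (near-)constant; with the floor active and `x` equal
  to the naive mean the p-value is exactly 0.5.
* Combination: Wilkinson's max with k = 2, `p = max(p_g, p_d)^2`, the
  exact null of the maximum of two independent uniforms.
* FDR: Benjamini-Hochberg per immune sample across all occurrences
  (per-sample adjustment matches the per-sample construction of the
  differential test); called iff `q <= 0.05`.
* Singleton removal: a called occurrence with no called occurrence
  within one tiling step on either side (same protein, same sample) is
  suppressed unless the same occurrence is called on a replicate chip
  of the same serum.

Signal tiers use strict inequalities - inclusive `> 3` SD, moderate
`> 6` SD, restrictive `> 10` SD above the pooled mean - and the FDR
cutoff uses `<=`, so a probe exactly at a tier boundary falls in the
weaker tier while a q-value exactly at the cutoff is still a call.

## Epitope segmentation and rollup

Called probes adjacent on the tiling grid (start-to-start gap at most
`max_gap_aa`, default the protein's tiling step) form chains. A chain
is a path in the probe contiguity graph, so its minimum spanning tree
is the path itself and SKATER-style partitioning reduces to recursive
edge cuts: the feature matrix is the per-sample `-log10` combined p of
the members (no rescaling), each candidate cut is scored by the
decrease in total within-cluster sum of squared deviations, and a cut
is accepted while the decrease is at least `min_gain_frac` (default
0.1) of the chain's total SSD and both sides have at least `min_size`
(default 1) members. Homogeneous chains therefore stay whole, and a
chain bound by different mice in different halves is cut at the
feature boundary.

Per sample, an epitope's p-value is Wilkinson's method on the
2nd-highest member p: `pbeta(p_(n-1), n-1, 2)` for `n >= 2` members,
the member p itself for a singleton region (such regions only arise
through replicate rescue or an extreme SKATER cut and are retained).
Protein p-values are Tippett's `1 - (1 - min p)^m` over the protein's
epitopes, computed as `-expm1(m * log1p(-p))` for numerical stability
at small p. Both levels are BH-adjusted per sample and called at
`q <= 0.05`.

Tier at the epitope/protein level is a conjunction: an item is in tier
T for a sample iff it is FDR-called **and** its maximum member smoothed
signal exceeds the tier-T SD cutoff. Tier membership is cumulative
(restrictive implies moderate implies inclusive). K-of-N counts the
immune mice calling an item, with replicate chips of one serum
collapsed to a single mouse; because co-recognition in a strength
category is what the per-tier landscape reports, the epitope and
protein tables carry both the plain FDR-called `K` and per-tier
`K_inclusive`/`K_moderate`/`K_restrictive`.

The consensus of a region with member starts `s_1 < ... < s_k` is the
protein slice `[s_k, s_1 + 15]`; on a regular step-s grid its length is
`16 - s(k-1)`. When that is non-positive the members share no common
core and the full spanned interval is returned flagged
`no_common_core` - downstream counts should treat such regions as
composite binding areas rather than single epitopes.

## Replicate concordance

`concordance_report()` compares the two chips of a replicated serum at
every level and tier. The tier conditions which items enter the
denominator (items the chip places in tier T); co-recognition in the
other chip means, by default, that the item is FDR-called there at any
tier (`match = "called"`). The alternative `match = "same_tier"`
requires the other chip to reach the same tier; it mostly measures
noise at the tier boundaries (an item sitting near the 10 SD line
flips category without flipping its call), which is why the default is
the call-based definition. Epitopes match by interval overlap (Jaccard
>= 0.5 on protein coordinates) rather than identical bounds. Both
directions are reported.

## The synthetic-data generator

`simulate_intensities()` emulates the data structure the analysis
assumes: lognormal background (log2-normal, mean 7, SD 1) split evenly
between a per-probe affinity shared across chips and per-cell noise; a
1.5x global elevation of immune chips (hyper-immune sera); sparse
naive autoantibody probes (rate 0.001 per mouse, 4 SD, present in both
conditions of their mouse); per-mouse private epitopes (6) and a
minority of shared epitopes (4, each spiked into 2-6 mice); epitope
lengths 8-12 aa; spike amplitude 8 background-SD on the log2 scale
(multiplicative on the raw scale); per-cell replicate noise (SD 0.25)
and an additive batch shift (0.3) that joint quantile normalisation
removes. The study design is mirrored: 5 naive + 6 immune mice, one
immune serum on two chips. Each stage draws from its own seed
substream, so enlarging the proteome does not perturb the intensity
draws and a fixed config is byte-reproducible.

A spiked region elevates every probe whose window overlaps the epitope
by at least half the epitope length; the truth manifest records both
the core epitope interval and the aa span of those spiked probes (the
*footprint*). `evaluate_recovery()` scores recovery by Jaccard overlap
between the footprint and a recovered region, because both are
probe-level footprints on the same scale - the core interval is
structurally ~4x narrower than any region assembled from 16-mers, so a
core-vs-region Jaccard would be bounded near 0.25 even for a perfect
recovery. A region counts as recovered when a spiked mouse's chip
places it at the moderate tier and the overlap reaches 0.5, and
shared-region co-recognition is scored against `K_moderate`.

What the generator does **not** model: probe synthesis quality and
scanner gain, spatial chip artifacts (vendor-corrected upstream),
sequence-dependent binding chemistry, partial binding of probes that
contain only part of an epitope, and affinity/titer relationships
(array signal is not an affinity measure). Passing recovery tests
therefore shows the inference chain is correct on data with the
assumed structure, not that the thresholds are optimal for any
particular real assay. One geometric consequence is worth noting: with
binary half-overlap spiking, an 8-aa epitope elevates ~9 probes on a
2-aa grid, more than the 4-5 probes that physically contain a full
8-aa epitope, so recovered regions are wider than real binding
patterns and their consensus cores shorter or absent; the consensus
machinery is therefore validated on constructed call patterns with the
realistic containment geometry as well.

## Validation statistics

* Enrichment: `prob_at_least_hypergeom()`/`prob_at_least_binomial()`
  compute upper tails; `fraction_sweep()` tabulates both models over
  assumed reactive fractions with `K = round(fraction * N)`. The
  minimum success count `x` is always explicit - the two models only
  agree when applied to the same tail, and at pool sizes in the
  millions they differ by well under 5%.
* Two-proportion test: pooled-variance score z (equivalent to the
  chi-square test of `prop.test(correct = FALSE)`); continuity
  correction available but off by default.
* ICC: `icc_from_variance_components()` fits random intercepts
  (lme4) for the listed grouping factors plus optional fixed effects
  on log-transformed readings and reports
  `sigma^2_target / (sum of all random-intercept variances +
  residual)`, banded poor/moderate/good/excellent at 0.5/0.75/0.9.
  The denominator deliberately includes every component - the "share
  of variance" reading.
* ELISA: replicates are averaged per serum **before** thresholding
  (a 1.9/2.1 pair averages to 2.0 and is positive); positivity is
  OD >= 2 inclusive; a peptide is validated in a group when >= 25% of
  the group's sera are positive, applied per declared sample group.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: a zero pooled SD is an
error; zero naive variance goes through the variance floor; empty
p-value sets are errors rather than silent 1s; BH on an empty vector
returns an empty vector; negative ICC variance estimates are truncated
at zero by the fitter. Ties in quantile normalisation take the mean of
the spanned rank means; ties in SKATER cut scores resolve to the
left-most best cut.

The test suite runs the default simulation (200 proteins x mean 120
aa, ~10-12k probes, 13 chips) in a few seconds per seed; recovery and
concordance properties are asserted over three seeds, and the
distributional oracles use 1e5 Monte-Carlo draws. These sizes were
chosen so the full chain - library, preprocessing, three-level calling,
segmentation - is exercised at a realistic probe-to-sample ratio while
keeping a complete run interactive.

## Known limitations

Wilkinson's max with k = 2 treats the global and differential p-values
as independent; they share the same observed signal and are positively
dependent, so combined probe p-values are mildly anti-conservative
under the null. In practice BH plus singleton removal keeps the null
probe call rate far below the nominal FDR (measured ~1e-3 at q <=
0.05 on fully null simulations), but the per-test calibration should
not be over-interpreted. Epitope boundaries inherit the smoothing
window: regions extend ~8 aa beyond the outermost bound probe.
`K`-style counts depend on the tier conjunction rule; the package
exposes both the plain FDR-called and per-tier variants rather than
declaring one canonical. The pipeline deliberately does not estimate
antibody titer or affinity from fluorescence.
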