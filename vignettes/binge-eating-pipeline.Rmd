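---
title: "Methods: lick microstructure, binge phenotyping, fear conditioning and ROI densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lick microstructure, binge phenotyping, fear conditioning and ROI densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bingetools)
library(dplyr)
library(tibble)
```

`bingetools` implements the computational core of a stress-induced
binge-like eating experiment in rats: scoring lickometer records, sorting a
cohort into binge-eating-prone (BEP) and binge-eating-resistant (BER)
phenotypes, quantifying conditioned fear and its normalizations, and
measuring relative *c-fos* expression as background-corrected optical
density in image regions of interest. This vignette documents the models,
the parameters that matter, the numerical conventions, and what the
package's synthetic-data validation does and does not establish.

## Licking microstructure

Rats lick in stereotyped high-frequency bursts (6–8 Hz) separated by
pauses. The analysis unit is the *licking cluster*: a burst of **three or
more licks** whose internal inter-lick intervals are all **shorter than
500 ms**; an interval of 500 ms *or longer* closes the burst. The boundary
belongs to the separator: an interval of exactly 0.500 s splits. Both the
0.5 s threshold and the 3-lick minimum are arguments
(`threshold`, `min_licks`) with those conventional defaults.

Six session metrics follow from the segmentation: total number of licks,
number of clusters, cluster size (mean licks per cluster), cluster duration
(mean seconds per cluster, last lick minus first lick), meal duration
(summed cluster durations), and first-lick latency (seconds from session
start to the first lick).

Two decisions the definition leaves open:

* **Stray licks.** Bursts of one or two licks are not clusters. Their licks
  still count toward the *total number of licks* (the literal reading of
  that metric); `count_stray_licks = FALSE` restricts the total to
  in-cluster licks for sensitivity analyses.
* **Missing, not zero.** When a train has no clusters, cluster size and
  duration are `NA`, and with no licks the latency is `NA`. Encoding these
  as zeros would bias group means toward zero precisely in the sparse
  sessions (e.g. groups without sucrose access) that produce them.

```{r microstructure}
licks <- tibble(timestamp_s = c(1.0, 1.2, 1.4, 2.0, 2.1, 5.0, 5.1, 5.2, 5.3))
lick_summary(licks)
```

## Session timeline and epochs

A test session is 900 s; six 20-s tones (2 kHz, 75 dB — metadata only, they
affect no computation) start 20 s into the session and are separated by
125-s silent gaps, putting tone onsets at 20, 165, 310, 455, 600 and 745 s.
In conditioning sessions a 1-s foot shock occupies the last second of each
tone; shock placement is carried as metadata for simulation and never
modeled physiologically.

All intervals are half-open `[start, end)` in 0-based session time: a lick
at a tone's exact onset belongs to the tone. `epoch_partition()` tiles the
session into `pre_tone`, alternating `tone_k` / `between_k`, and
`post_tone`; the tiles are disjoint and cover the session exactly, so
per-epoch lick counts always sum to the session total.

For tone-aligned analyses, segmentation is **epoch-local**: each epoch's
sub-train is segmented independently, so a burst straddling a tone offset
splits into two epoch-local bursts. This keeps during-tone and between-tone
metrics independently computable at the cost of slightly undercounting
clusters that genuinely bridge a boundary. The 135 s after the last tone
(and the 20 s before the first) form a `tail` phase that joins the
between-tone aggregate only on request (`include_tail = TRUE`), since
nothing in the session structure makes the tail equivalent to an
inter-tone gap.

## Binge phenotyping: the tertile rule

Within each stress session the cohort's raw intakes (grams — deliberately
*not* body-weight-normalized, for continuity with how such phenotypes are
defined) are ranked and split into high / intermediate / low tertiles. Over
three stress sessions, a rat high **at least twice and never low** is BEP;
low **at least twice and never high** is BER; everyone else is labeled
`unclassified` rather than dropped, so cohort accounting stays explicit.

Rank-based thirds are the default; `method = "range"` offers a value-based
alternative (equal thirds of the intake range) since the split type is
rarely stated in practice. Two details the rule leaves open:

* **Remainders.** With `n` not divisible by 3, `floor(n/3)` rats go to each
  extreme and the remainder to the intermediate tertile (7 rats split
  2/3/2). Keeping the extremes strict is conservative: it can only make the
  BEP/BER labels harder to earn.
* **Ties.** Ties at a tertile boundary are broken deterministically by
  `rat_id` with a warning; silent nondeterminism in a classification step
  is worse than an arbitrary-but-stated rule.

The appetitive baseline detector (`detect_stable_baseline()`) finds the
earliest window of three consecutive sessions with no significant intake
change — a repeated-measures one-way ANOVA across sessions with rats as
the blocking factor, stable when `p > 0.05`. A session effect of exactly
zero (identical intakes, residual also zero) is treated as stable rather
than undefined. A coefficient-of-variation criterion (`method = "cv"`,
default limit 15%) is provided as a model-free alternative.

## Intake and freezing normalizations

Intake energy is `grams / solution_density * energy_density /
(body_weight / 1000)` — kcal per kg body weight, with defaults for a 10%
sucrose solution: 0.4 kcal/ml and density 1.0 g/ml (grams read as ml; the
true density of a 10% solution is ≈ 1.04 g/ml, so the density is an
argument). 15 g consumed by a 300 g rat is 20 kcal/kg.

Test sessions are normalized per rat to baseline means: test intake over
the mean of the appetitive sessions, and test freezing (mean seconds over
the six tones) over the mean of the last three conditioning sessions. The
baseline mean maps to exactly 1.0; a zero baseline yields `NA` with a
warning rather than an infinity. Whether the intake ratio uses kcal/kg or
g/kg is immaterial — the constant cancels — so it is computed from kcal/kg.

Freezing is consumed as experimenter-annotated per-tone seconds in
`[0, 20]`; the package does not detect freezing from video or activity
traces (that scoring is manual in this paradigm), it only simulates such
annotations in the generator.

## Densitometry

Relative expression in a dark-field in situ hybridization image is the
**mean gray value** of the pixels whose centers fall inside the ROI
polygon, minus the background estimate: the mean over the background
contours of their own per-contour mean intensities (three small contours on
unlabeled tissue is the established practice; at least one is required and
fewer than three draws a warning). Signal is bright-on-dark, the
measurement is relative, and no logarithmic transform is applied.
`statistic = "integrated"` substitutes summed intensity for the mean; note
integrated and mean OD rank groups identically only when ROI areas match.

Numerical conventions: pixel `(row r, col c)` covers `[c-1, c] x [r-1, r]`
with center `(c - 0.5, r - 0.5)`; membership is polygon-contains-center by
an even-odd crossing test with no partial-pixel weighting — simple and
directly checkable against a per-pixel oracle. Negative corrected OD is
retained and flagged, never clipped, so group means stay unbiased.
Corrected OD is invariant under an additive image offset and scales with
multiplicative gain.

Because hybridization and exposure settings are constant only within a
region's batch, `batch_compare_guard()` refuses contrasts that pool
different brain regions, or different exposure batches within a region
unless explicitly allowed. Per-section measurements are averaged per animal
(`per_animal_od()`) before group statistics, the animal being the
experimental unit; the averaging step is separate so a per-section analysis
remains possible.

## Statistics

One- and two-way ANOVA with interaction, Bonferroni post hoc pairwise
comparisons, and two-tailed unpaired pooled-variance t-tests, at
α = 0.05. Unbalanced two-way designs use **Type-III** sums of squares with
sum-to-zero contrasts — the convention of the mainstream GUI packages this
layer mirrors — implemented by single-term deletion on the sum-to-zero
parameterization; on balanced designs the decomposition is exact
(`ΣSS + SS_resid = SS_total` to 1e-9). Post hoc t statistics use the
ANOVA's pooled residual mean square and residual degrees of freedom, and
the Bonferroni multiplier is the number of comparisons actually requested,
not all possible pairs. Zero residual variance (constant response) is
reported as an explicit flag with `NA` F statistics rather than a
fabricated value. Repeated measures are handled only as subject blocking
(in the baseline detector); mixed models are out of scope.

## The synthetic-data generators

Each generator is seed-deterministic and returns its ground truth beside
the data, so recovery tests compare estimates to known planted values.

**Lick trains** come from a two-timescale renewal process: cluster onsets
separated by pauses `pause_min + Exp(pause_mean_excess)`, lick counts
`3 + Poisson(mean_cluster_licks - 3)`, within-cluster intervals
truncated-normal on `(0, 0.5)` s. The feasibility constraints
(`within_ili_mean + 3·within_ili_sd < 0.5`, `pause_min ≥ 0.5`) are not
cosmetic: they make the generated clusters *identifiable*, i.e. exactly
what the segmenter must find, so the recovery tests are exact rather than
approximate. A `tone_suppression` multiplier thins cluster onsets inside
tone epochs (0 silences them), emulating conditioned suppression. The
process has no circadian structure, no within-session satiety, and no
lick-rate rhythm beyond the two timescales — so passing recovery tests
validates the segmentation arithmetic, not any physiological claim.

**Cohorts** draw per-rat, per-session intakes from phenotype-specific
normals truncated at 0 g, with additive stress effects (positive for prone
rats, zero for resistant by default). The cohort is composed of
deterministic fractions `p_bep` prone, `p_intermediate` intermediate (at
the midpoint mean) and the remainder resistant. The intermediate
population matters: the tertile rule is rank-based, so the high and low
tertiles each hold only a third of the cohort, and planted extremes can
only be recovered reliably when their fractions do not exceed a third.
Recovery runs use 30-rat cohorts split 1/3–1/3–1/3 with adjacent means
2 SD apart (8, 12, 16 g at SD 2 g), which yields ≳ 98% planted-label
recovery over 200 cohorts; a two-population cohort with half the rats
prone caps near 75% for structural, not statistical, reasons.

**Freezing** trajectories follow a per-session acquisition curve (default
shape: low first conditioning session, then a stable plateau), a
multiplicative sucrose effect in the test session for sucrose-access rats,
and truncated Gaussian per-tone noise clipped to `[0, 20]` s.

**Grain images** emulate dark-field emulsion statistics as independent
per-pixel Poisson grain counts (background density outside the ROI, signal
density inside) scaled by a grain gain and clipped to bit depth; the
expected corrected OD is `(signal − background) × gain`. Real
autoradiographs have spatially correlated grain clumps, uneven
illumination and tissue texture; the generator validates the measurement
arithmetic, not robustness to those artifacts.

## Validation problem sizes

The shipped checks run at these sizes, chosen to keep Monte-Carlo error
well inside each tolerance: 1,000 random trains for the segmentation
oracle and for epoch conservation; 500 sessions (300 s each) for cluster
parameter convergence within 5%; 200 cohorts of 30 rats for ≥ 95%
phenotype recovery; 50 images (120×120 px) for densitometry recovery
within 5%; 1,000 null replicates for type-I calibration of all four tests
within [0.03, 0.07]; and 100 replicate experiments (12 rats/group, 1.5 SD
planted effects) for ≥ 90% directional reproduction of the three headline
contrasts (prone > resistant appetitive intake; conditioned-stimulus
suppression of test intake in resistant-paired rats; sucrose-blunted
freezing in prone-paired rats).

## Known limitations

* Lick logs are consumed as CSV seconds; native lickometer formats
  (Med-PC, TDT multichannel) need prior conversion.
* Only grayscale single-channel TIFFs are read; no registration, atlas
  alignment or automatic ROI placement.
* No estrous-cycle covariates, no mixed-effects models, no within-cluster
  rhythm analysis.
* The end-to-end synthetic experiment shares its generative family with
  the generators used for unit recovery; it demonstrates internal
  consistency of the pipeline under planted effects, not performance on
  any real cohort.
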