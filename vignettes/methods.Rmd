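---
title: "Models and methods: synthetic dorsal-horn densitometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synthetic dorsal-horn densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its generative model, its
measurement pipeline, and the design decisions behind both. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Why a synthetic pipeline

The quantities of interest — densities of IB4⁺ and GAD65⁺ boutons in
laminae I/II, von Frey thresholds, Hargreaves latencies, all as percent of
sham — come from measurement chains whose raw inputs (confocal micrographs,
staircase response sequences) are essentially never deposited. The package
therefore couples a *generator* whose ground truth is known to the same
*quantification* code a study would run on real images, and treats the
study's reported percentages as parameter-recovery targets: the generator's
packaged time-course encodes the reported values, and the pipeline must get
them back out of rendered pixels and simulated trials.

Passing recovery tests therefore shows the measurement chain is unbiased
*under the generator's assumptions*; it cannot validate assumptions the
generator does not model (see "What the generator does not emulate").

## The generative model

**Geometry.** A section is a 600 × 200 µm two-sided frame at 0.1 µm/pixel:
a white-matter (WM) boundary at 20 µm depth (optionally bowed
sinusoidally), a 20 µm lamina I band and an 80 µm lamina II band beneath
it, a midline at half-width used as the mirror axis, and a lesion zone —
a 60 µm-wide medio-lateral interval of lamina II centred on the middle
third of the ipsilateral side. The 0.1 µm pixel resolves the 0.05 µm²
(5-pixel) size filter; it is the scale a 63× confocal quantification image
would provide. The lesion zone is deliberately wider than the 50 µm
lamina-II ROI because the protocol places the rectangle *within* the region
of decreased staining. The frame height and width are the package's choice:
large enough that both ROIs and the lesion search fit with margins, small
enough that a full cohort renders in minutes.

**Puncta.** Each channel is a homogeneous spatial Poisson process over the
laminar bands, with density in the study's unit (puncta per 100 µm²).
Single-punctum areas are log-normal with the channel's mean apparent area
(0.3 µm² IB4, 0.2 µm² GAD65) and CV 0.5; areas are *apparent* (post-optics)
areas, which is why the renderer's default PSF sigma is zero — discs are
drawn at exactly their apparent area, and blurring them again would
double-count the optics. Peak amplitudes are uniform in a 400–1200 DN band
over a 100 DN background: far above any detection threshold, and low enough
that even a few stacked puncta stay below the 4095 DN ceiling, matching a
protocol that avoids saturation. Sham baselines (IB4: 4 and 20 /100 µm² in
LI and LII; GAD65: 12 and 15) are invented — the study reports only
percentages — and chosen at the scale typical for confocal bouton counts;
all recovery targets are ratios, which cancel the baseline.

**Injury and variance components.** For cuff animals the lamina-II density
inside the (mirrored) lesion interval is the sham baseline times the
configured percent-of-sham; lamina II outside the interval stays at
baseline, which is what makes lesion *detection* meaningful. Lamina-I
scaling applies across the band. The packaged time-course fixes the
reported values at the days the study states them (IB4 LII: 1.5% at day 21,
52.1% at day 56; GAD65 LII: 34.1% and 72%; GAD65 LI: 63.1% at day 21; von
Frey 16.3% at day 21; Hargreaves 70.1% at day 28) and smooth interpolations
elsewhere. Because the study never states section- vs animal-level variance
components, both are exposed and the defaults are invented: a multiplicative
log-normal animal effect (CV 0.15) and section effect (CV 0.10). The animal
effect has a shared latent factor across the two markers with coupling 0.6,
so the cross-marker density correlation is tunable (coupling 0 gives the
null used in the Spearman tests). All stochastic steps take explicit seeds;
cohort sub-seeds derive deterministically from (seed, day, animal, section).

**Behaviour.** Withdrawal is Bernoulli with a logistic psychometric
function of log₁₀ force, P = 0.5 at the true threshold, slope 5 per log₁₀
gram. Staircases start at the weakest filament — the protocol presents
hairs serially in ascending order of strength until the first withdrawal —
then follow the up-down rule, stopping four presentations after the first
reversal; a "no response" at 26 g or a response at 0.6 g stops immediately
(those thresholds are censored at the bounds). The ascending start matters:
starting mid-range compresses estimated thresholds toward the centre of the
filament set and biases the cuff/sham threshold ratio upward by roughly a
tenth, while the ascending start leaves the ratio essentially unbiased. Sham truths are 15 g and 10 s; cuff truths are the configured
percentages of these. Hargreaves trials are Gaussian around the true
latency (SD 1.5 s), truncated at the 20.48 s cut-off; no inter-animal
variance is added to behavioural truths beyond the trial/staircase noise,
which is the literal reading of one true endpoint per condition.

## The measurement pipeline

**Accentuation.** The proprietary "target accentuate" step is described
only behaviourally — it reduces the contrast of large structures much more
than bouton-scale ones — so it is implemented as a grayscale white top-hat
with a flat disc whose diameter is three bouton diameters (1.65 µm). A flat
field maps to zero, a 20 µm band is removed entirely, and sub-disc puncta
pass through with their background-subtracted amplitude. The disc
erosion/dilation is compiled code (`src/morphology.cpp`), decomposed into
vertical running-extrema so scans are cache-friendly; the only installed
morphology package binarises grayscale input and could not be used for
this step (it still provides connected-component labelling).

**Segmentation.** Supra-threshold pixels are grouped into 4-connected
components (conservative splitting of touching puncta); components below
0.05 µm² are discarded. The default threshold follows the
background + 3 SD rule, with background level and spread estimated robustly
from the accentuated image itself (median + 3 MAD), because the top-hat
shifts the background distribution; a fixed DN threshold can be supplied.
Blob centroids are intensity-weighted and kept in continuous micron
coordinates.

**Overlap correction.** Counts are corrected by the channel's mean
single-varicosity area. Two rules are implemented. The default is the
total-area rule, `max(raw_count, round(total_blob_area / mean_area))`: it
is unbiased when single-punctum areas vary around the mean, because only
the *sum* of areas enters. The per-blob rule
`Σ max(1, round(area_i / mean_area))` is also available; it preserves raw
counts exactly while no blob exceeds 1.5× the mean area, but under a CV-0.5
area distribution its expected value is ≈1.15 per isolated punctum
(`E[max(1, round(X))]` for X log-normal with mean 1), an inflation the
total-area rule avoids — which is why the pipeline default is total-area.
Rounding is round-half-to-even throughout.

**ROI placement.** The lesion is located by sliding a 30 µm window (5 µm
stride) across the middle third of the side's medio-lateral extent,
counting lamina-II IB4 blob centroids; the contiguous run of windows below
half the side-wide median density, containing the minimum, is the lesion
interval. If no window clears that criterion (sham, uniform staining, empty
channel) the default middle-third rectangle is used — the sham homotopic
placement. ROIs are then axis-aligned rectangles: lamina I 40 × 15 µm with
the long side flush against the WM boundary, lamina II 50 × 30 µm with its
near edge 50 µm below the boundary, both centred on the lesion's
medio-lateral centre and mirrored across the midline for the contralateral
side. For curved boundaries the 50 µm offset is evaluated at the ROI
centre's medio-lateral position. A blob belongs to an ROI when its centroid
falls inside the continuous rectangle — unbiased under translation, and it
makes realised ROI areas exactly 600 and 1500 µm² rather than
pixel-quantised.

**Densities and statistics.** Density is 100 × corrected count / ROI area.
Sections are averaged to one value per animal before any statistic (the
study's n is animals; whether averaging preceded statistics is not stated,
so the animal-level reading was chosen). Normalisation divides cuff values
by the same-day, same-side sham mean; statistics run on absolute values
only — the interface does not accept normalised values. "One-way ANOVA
t-tests" are implemented as two-sided t-tests (unpaired sham-vs-cuff,
paired ipsi-vs-contra), which are identical to one-way ANOVAs with two
groups; behaviour uses a two-way group × day ANOVA with per-day
Bonferroni-corrected contrasts. The phase-wise Spearman correlation pools
one (IB4, GAD65) pair per animal per day; p-values use the exact null for
n ≤ 12 without ties and the t approximation otherwise. The correlation's
sign is reported as computed and never forced: the narrative direction of
the original association is ambiguous, and the synthetic coupling model
produces positive coupling by construction.

**Up-down scoring.** The 50% threshold is `(10^[X_f + k·δ])/10000` grams
with X_f the final filament in log₁₀(10⁴ × grams) units and δ = 0.224. The
published k tables are not reproduced anywhere in the source material, so k
is computed for every pattern by the construction that generated those
tables: the maximum-likelihood location of a cumulative-normal psychometric
function with spread δ, expressed as `(μ_ML − X_f)/δ`. The formula identity
`threshold = 10^(X_f + k·δ)/10⁴` then holds to machine precision, and the
estimator is checked in the suite against a per-sequence ML logistic oracle
and against hand-derivable symmetric patterns (equal responses at two
levels give the geometric midpoint). One-sided sequences are censored at
0.6/26 g. The protocol text mentions both "ascending order" application and
the up-down switching rule; the up-down rule is implemented, since the
formula requires it.

## Numerical choices and degenerate inputs

- Pixel bins are half-open; pixel (i, j) has centre ((j−½)px, (i−½)px). A
  punctum's disc owns the pixels whose centres it covers; sub-pixel puncta
  light their nearest pixel so no punctum vanishes.
- Rendering clips to [0, 4095] after rounding; fully saturated channels
  quantify to an empty result with a warning.
- Morphology treats out-of-frame pixels as neutral, so flat fields stay
  flat at borders; ROI crops carry an 8 µm context margin.
- Degenerate statistics (constant paired differences, single-animal
  strata) are skipped with warnings or reported as NA rather than failing
  the whole analysis.
- Ties in the lesion search are broken by the default middle-third
  placement.

## Problem sizes

The packaged cohort (5 sham + 6 cuff × 6 sections; 10 + 10 behavioural
animals) is the size the acceptance script runs per day, on a 450 × 160 µm
frame, averaging 3 replicate histology cohorts per day and 24 behavioural
cohorts so the reported values estimate the recovered mean rather than a
single stochastic draw. The test suite uses smaller frames (420 × 150 µm)
and cohorts (3–5 animals × 3–4 sections) with correspondingly widened
stochastic tolerances. These sizes are stated here as the package's own
choices for routine runs.

## What the generator does not emulate

Single optical sections only (no 3-D stacks); no cell bodies, dendrites,
blood vessels or staining-chemistry artefacts; no spatial inhomogeneity of
background; no correlation between punctum area and injury (the study
reports bouton size unchanged); behavioural truths carry no inter-animal
variance. Recovery results should be read with those limits in mind.
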