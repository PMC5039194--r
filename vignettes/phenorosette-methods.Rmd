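---
title: "Models and methods behind phenorosette"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenorosette}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorosette)
```

`phenorosette` turns top-view tray RGB images, PAM
chlorophyll-fluorescence traces and rosette-area time series into the
trait tables a salinity screen needs: morphometrics, greenness-hue
abundances, photosystem II quantum-yield and quenching parameters,
two-interval growth rates and the shoot ion-independent tolerance
(SIIT) index, with ANOVA/Tukey, Mann–Whitney, PCA and Ward clustering
on top.  This vignette is the package's own account of the models,
numerical choices and limitations.

## Experimental structure

`generate_design()` enumerates accessions × treatments × replicates
into plants and assigns them, in a seeded random order, to trays of
4 × 5 pots — the tray format of compact conveyor phenotyping systems.
Treatments carry nominal NaCl doses (0/50/100/150 mM), the effective
soil concentrations realised by watering regimes on such platforms.
Days are integers with day 0 the start of salt exposure.

## RGB pipeline

Tray images are cut into equal half-open pot cells (row-major,
origin top-left).  An optional margin accommodates tray borders; the
cells must tile the remaining region exactly, and a mismatch is an
error that reports both sizes.  Tray detection and lens-distortion
correction on real platforms are hardware-calibrated; here the grid is
config-declared, and the pipeline's stage order leaves a natural
pass-through point where a distortion correction could be inserted.

**Segmentation.** Vegetation is classified by a colour-index rule: a
pixel is plant if its excess-green index 2G − R − B exceeds a
threshold (default 25 on the 0–255 scale) and its green channel
exceeds a floor (default 50).  Soil, pot rims and shadows are
grey-brown with excess green near zero, so the rule is robust to
illumination level (a luminance shift adds equally to all channels and
cancels in 2G − R − B).  The defaults were fixed against the bundled
soil and leaf palettes and are ordinary config values.

**Mask clean-up.** `clean_mask()` removes components smaller than
`min_object_px` (default 20 px), then decides connectivity on a
morphologically closed, hole-filled copy of the mask (disc brush,
default radius 2 px) so that the separate leaves of one rosette count
as a single object; the largest object wins (ties broken by lowest
centroid row, then column), and the output keeps the *originally
segmented* pixels of that object plus its enclosed holes.  The closing
dilation itself is deliberately not counted: adding it would inflate
small-rosette areas by several percent, a measurable bias with no
measurement meaning.  The operation is idempotent and maps the empty
mask to itself.

## Morphometrics

From a cleaned mask, `compute_morphometrics()` reports seven standard
silhouette descriptors.  Area is the pixel count.  The perimeter is
estimated from the traced outer chain code with the
Vossepoel–Smeulders calibrated weights (0.980 per isothetic step,
1.406 per diagonal, −0.091 per direction change); naive 1/√2 step
counting overestimates a digital circle's perimeter by ~5%, which
would push the roundness 4πA/P² of a perfect disk down to ~0.91,
whereas the calibrated estimator is accurate to a few tenths of a
percent.  Roundness is clipped at 1 to guard rasterisation artifacts
on small masks.  Compactness is solidity, with the convex hull taken
over the four corners of every foreground pixel rather than pixel
centres: corner hulls make the solidity of a plus-pentomino exactly
5/7 and keep a disk at ≥ 0.98, whereas centre hulls can exceed 1.
Eccentricity √(1 − λ₂/λ₁) and slenderness √(λ₁/λ₂) come from the
eigenvalues of the pixel covariance; slenderness is thus a
whole-rosette aspect ratio (a per-leaf definition would need
individual-leaf segmentation, which is out of scope — the trait is
named accordingly).  Rotational mass symmetry is 1 minus the
coefficient of variation of pixel mass over 36 equal angular sectors
about the centroid, clipped to [0, 1]; the sector count is
configurable.  Sector binning uses a half-sector offset plus a 1e-9
snap so that axis-aligned and diagonal pixel lines fall consistently
into bins, making all traits exactly invariant under translation and
90° rotation; the centroid pixel, which has no angle, is excluded from
the tally.  These definitions are the standard image-analysis ones,
adopted because the platform's own formal trait definitions are not
public; each is a documented substitution, not a claim about the
proprietary implementation.

## Colour segmentation

A single hue palette per experiment keeps hue indices comparable
across plants and days.  Calibration pixels are pooled from images at
the start, middle and end of the phenotyping period and from both
treatments, restricted to mask-true pixels; pooling is global across
accessions.  For colour work the mask is additionally intersected with
the raw colour-index mask (`veg_mask`), because hole filling adds
soil-coloured pixels that would otherwise capture a k-means centroid
and contaminate abundances — the cleaned mask remains the basis for
area and shape.

k-means runs on raw RGB coordinates with Euclidean distance, k = 9 by
default.  Initial centres are drawn by k-means++ sampling over the
*distinct* colours (random-row seeding fails when a few exact colours
dominate the dataset), with 10 seeded restarts keeping the best
within-cluster sum of squares; a fixed seed gives a bit-identical
palette.  Centroids are ordered dark → light by luminance
(0.299R + 0.587G + 0.114B), which pins down "hue 1 … hue 9" for an
experiment.  Every rosette pixel is assigned its nearest centroid
(ties to the lowest index), and per-plant hue abundance divides each
hue's pixel count by the rosette area.  The floating-point residual of
that division (≤ 1 ulp) is folded into the largest fraction so
abundance vectors sum to 1 exactly; zero-area plants yield flagged
missing records rather than division errors.  `hue_salt_ratio()`
reports per-accession salt/control abundance ratios, flagging
zero-control cases as missing instead of returning infinities.

## Chlorophyll fluorescence

Two `chlf_protocol()` timetables describe the measurements: a
*quenching-kinetics* run (5 s Fo measuring-flash window, 800 ms
saturation pulse at 1200 µmol m⁻² s⁻¹ for Fm, 17 s dark relaxation,
70 s actinic light at 210 µmol m⁻² s⁻¹ with pulses at 8, 18, 28, 48,
68 s — states L1–L4, Lss — then 100 s darkness with pulses at 30, 60,
90 s — D1–D3) and a *light-curve* run (four 60 s actinic steps at 95,
210, 320, 440 µmol m⁻² s⁻¹, one pulse at each step's end, L1–L4).

`extract_levels()` reads the levels off an annotated trace: Fo is the
mean of the measuring-flash window; Fm and each Fm′ the maximum inside
the corresponding pulse window; Ft(s) the mean of the 200 ms window
ending at the pulse start; Fp the maximum during the actinic rise
before the first pulse.  The protocol fixes the pulse timing but not
averaging windows, so the 5 s Fo mean and 200 ms Ft window are package
choices.  Missing annotations raise errors naming the event; Fm ≤ Fo
is a degenerate-trace error.  `integrate_image_stack()` reduces
fluorescence image stacks to traces as the mean over mask pixels minus
the frame's background mean, making the signal exactly invariant to a
constant offset.

Fo′ uses the Oxborough–Baker relation Fo′ = Fo / (Fv/Fm + Fo/Fm′),
the standard estimate when far-red Fo′ is not measured.
`derive_parameters()` then applies the lake-model energy partition:
ΦP = (Fm′ − Ft)/Fm′, ΦNO = Ft/Fm, ΦNPQ = Ft/Fm′ − Ft/Fm (closing to
1 algebraically), plus qP, qL = qP·Fo′/Ft, qN = (Fm − Fm′)/(Fm − Fo′)
(the Fo′-corrected variant), NPQ = Fm/Fm′ − 1, Fv′/Fm′, and
Rfd = (Fp − Ft_ss)/Ft_ss against the steady state (Lss for quenching,
L4 for the light curve).  The platform's trait list also names a "PQ"
coefficient without a public definition; the package implements qL,
the lake-model photochemical quenching, under its own name — a
documented choice.  Division guards return flagged `NA`s so one
degenerate plant cannot abort a tray.  `relative_trait_table()`
normalises any long trait table by the grand mean per trait (and
state), giving unit-mean columns for development-plus-treatment
fluctuation plots.

## Growth and SIIT

Growth is modelled piecewise linearly: `fit_growth_rate()` is the OLS
slope of area against day within a closed interval, per plant, with
R² as a diagnostic.  Default intervals are days [0, 4] and [7, 11]
for an 11-day run and [0, 3] / [4, 7] for a 7-day screen,
config-selectable.  SIIT divides each salt plant's growth rate by the
mean control rate of its accession; per-plant values (rather than an
accession-mean fit) keep error bars available.  Negative fitted
slopes are clipped to zero with a flag — shrinking rosettes mean
tissue loss, not negative tolerance — and a non-positive control mean
flags the ratio missing.  GR is invariant to adding a constant to all
areas and scales linearly with area units, so SIIT is scale-free.

## Statistics and clustering

`anova_tukey()` wraps `aov()` + `TukeyHSD()` and renders the pairwise
results as a compact letter display via the insert-and-absorb
algorithm.  `mann_whitney()` computes U from ranks; its default
normal approximation uses the tie-corrected variance and a 0.5
continuity correction, and an exact mode enumerates all group
labelings (valid under ties), chosen automatically when both groups
have ≤ 8 observations.  The approximation is known to be coarse for
tiny groups: against exhaustive enumeration its two-sided p can
deviate by up to 0.088 at 2 + 2 observations and ~0.02–0.03 around
3–4 per group, entering the ±0.02 band only from roughly 4 + 5
upward — the reason the exact mode is the small-sample default.

The "z-Fisher" style per-trait normalisation used for heatmaps is
implemented as plain per-column z-scoring with the sample (n − 1)
standard deviation (Fisher's z transform applies to correlations, not
trait values, so the name is interpreted rather than transliterated);
it is isolated in `standardize_traits()` so it can be swapped.  PCA
runs on the column-standardised matrix with mean imputation (flagged)
for missing values and zero-variance columns dropped with a warning.
Ward clustering uses `hclust(method = "ward.D2")` on Euclidean
distances, over accessions and independently over traits;
`early_late_cluster_report()` assembles the canonical
accession × 10-trait matrix (eight ChlF traits at the final day's
highest-irradiance state as salt/control ratios, plus SIIT₁ and
SIIT₂), standardises per trait, and cuts at 3 row / 2 column clusters
by default.  Multiple testing across traits and days is deliberately
not corrected, matching the per-trait testing convention of such
screens; a Benjamini–Hochberg option is available through
`p.adjust()` downstream.  Replicates are averaged per accession before
clustering.

## The synthetic generator

The generator defines the study conditions everything is verified
under.

*Trays.* Rosettes are fans of 6–10 rotated ellipses (aspect 2.5,
jittered angles and lengths) centred in pot cells, each leaf painted
in one of nine reference greens; leaf size is iteratively rescaled
until the rendered pixel area is within 3% of the growth-model target.
Soil is textured by luminance-only jitter, which leaves the
excess-green index untouched, so zero-noise renders are exactly
palette-coloured.  The default render is 640 × 480 (the same scene at
platform-native 2560 × 1920 is a 4× scale-up); per-pot masks, hue
maps and exact hue fractions are returned as ground truth.

*Growth.* Areas follow the two-interval linear model with additive
Gaussian noise (default SD 15 px on a 250 px start), clipped at zero.
Defaults: control 110 px/day; salt multiplies growth by 0.6 (early)
and 0.45 (late) at 100 mM, with the reduction deepening over time;
per-accession log-normal multipliers (SD 0.08) create natural
variation in vigor, tolerance and photosynthetic response.

*Fluorescence.* NPQ builds up as NPQ_max(1 − e^(−t/τ)) under actinic
light (τ = 20 s) and relaxes exponentially in darkness (τ = 40 s); qP
declines from 1 toward a steady state and recovers in darkness.
Induction curves in the source literature are shown but not
parameterised, so this is the simplest monotone model with a closed
form.  Levels follow from Fm′ = Fm/(1 + NPQ), the Oxborough–Baker
Fo′, and Ft = Fm′ − qP·(Fm′ − Fo′); traces hold exact plateaus in the
extraction windows, so zero-noise round trips are exact to machine
precision.  Sampling is 50 Hz — the frame rate of the platform
fluorescence cameras; trace noise is additive Gaussian (default SD
0.005 on Fm = 1).  Neither camera's noise is characterised publicly,
so synthetic noise magnitudes are free parameters, not estimates.

What the generator does *not* emulate: overlapping neighbour plants,
specular soil highlights, white-balance drift, leaf curling and
movement between imaging rounds, non-exponential NPQ kinetics, or
spatial heterogeneity across a rosette.  Passing tests therefore
demonstrate correctness of the *computations* under controlled
conditions, not robustness to every artifact of real platform imagery.

## Verification problem sizes

The test suite and `scripts/acceptance.R` use: 10⁴ random level sets
for the energy-partition algebra; both full pulse schedules at zero
noise and 50 plants at 1% trace noise for parameter recovery (mean
relative error ~3–4%, dominated by ΦNPQ in dark-relaxation states
where the true value is near zero); a disk of radius 60 px and a
4:1 ellipse for morphometrics; one 12-plant painted tray for palette
recovery; a 50-plant segmentation sweep with targets of 400–3000 px;
16 + 16-plant cohorts for SIIT; the full deterministic null
distribution of U for every group-size pair ≤ 8; 20 seeded
8-accession archetype runs for Ward recovery; and 12-plant × 8-day
(scripts) to 144-plant × 8-day (test suite) pipeline runs for
end-to-end determinism, which complete in roughly ten seconds and one
minute respectively.

## Known limitations

* Tray geometry is config-declared; there is no automatic tray or pot
  detection, and no lens-distortion model.
* Slenderness and rotational symmetry are whole-rosette statistics;
  per-leaf morphology is out of scope.
* The Mann–Whitney normal approximation is unreliable below ~5
  observations per group (use the exact mode, which is the default
  there).
* The ChlF extractor assumes traces annotated with the protocol's
  event windows; it does not segment unannotated raw recordings.
* Colour work assumes a shared global palette; experiments with
  radically different illumination per session would need per-session
  calibration and a colour-constancy step the package does not
  provide.
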