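---
title: "Quantifying RNP granule remodeling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNP granule remodeling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctate)
```

## The measurement problem

Somatic RNP granules in neuronal cell bodies are near-diffraction-limited
(100–200 nm) puncta of RNA-binding proteins and mRNAs superimposed on a
diffuse cytoplasmic pool of the same molecules. At a 0.043 µm pixel size,
a granule spans only a few pixels; the cell nucleus occupies most of the
cell-body volume, so on a single confocal section the cytoplasm appears
as a bright ring around a dark nuclear void. Stimulus-induced remodeling
is quantified by three readouts: how many granules a field contains, how
strongly a protein partitions into them, and what fraction of a given RNA
sits inside them. This vignette documents how `punctate` computes each
readout, the parameters that matter, and the design decisions taken where
the procedure left room.

Coordinates are `[row, col]`, 1-based, with pixel centers at integer
coordinates, everywhere in the package — one convention end to end
prevents off-by-one drift between the raw and detection grids.

## Particle detection

Raw fields (single z-slices, one channel) are processed as:

1. Gaussian blur, `blur_sigma` (default 0.5 raw px — mild smoothing, one
   detection-grid pixel).
2. Two-fold bilinear upsampling (`resize_factor = 2`), so that few-pixel
   puncta acquire enough area for stable connected components.
3. Linear min–max rescaling to the 16-bit range. This is deterministic
   and parameter-free; a constant field has no range and maps to zeros
   (with a warning), which correctly yields zero particles.
4. A band-pass response: difference of Gaussians with inner scale
   `bandpass_sigma` (default 2 detection px) and outer scale 1.6×. Pixels
   whose response exceeds `relative_threshold ×` (response range over the
   image) are foreground.
5. 8-connected components with area ≥ `min_size` (default 4 detection px)
   become particles; channels stained with antibodies additionally drop
   particles under `size_exclusion = 13` detection px.

Two choices deserve comment. First, the published relative thresholds for
this kind of data (0.6234 for granule channels, 0.3434 for smFISH
channels) belong to a particular detector implementation whose internal
operator is not public; our band-pass detector preserves the *interface*
— a unitless threshold in (0, 1) — but is not operator-identical, so the
numerically optimal threshold for a given channel differs. That is why
the threshold is a calibrated quantity, not a constant:
`calibrate_threshold()` sweeps a grid, scores each value by mean F1
against point annotations, and returns the argmax, breaking ties toward
the larger (more conservative) threshold. If every grid value scores
zero, the largest value is returned with a warning rather than an
arbitrary interior point. On the synthetic channels shipped with the
package the calibrated optimum sits near 0.3–0.6 depending on noise and
amplitude heterogeneity.

Second, the threshold cut is measured as a fraction of the full response
range but applied as an absolute response level (`response > t·range`),
not as an offset from the response minimum. Difference-of-Gaussian
responses have negative side lobes, so an offset-from-minimum rule would
let low thresholds dip below zero and merge the entire background into
one foreground component; the absolute rule keeps the cut strictly
positive and makes the particle count monotone non-increasing in the
threshold (level sets of a unimodal blob shrink without splitting), a
property the test suite checks explicitly.

Both size parameters are counted on the resized detection grid, because
detection runs after resizing; they remain configurable for anyone who
prefers the raw-grid reading.

F1 scoring treats an annotation as a true positive when it falls inside a
particle's raw-grid footprint; each particle can absorb at most one
annotation (greedy by distance to the particle centroid), unmatched
annotations are false negatives, and unmatched particles false positives.
`F1 = 2PR/(P+R)` is defined as 0 when `P + R = 0`.

## Partition coefficients

The partition coefficient of a granule is the ratio between its maximal
intensity and the mean diffuse cytoplasmic signal. Granule maxima are
always measured on the *raw* image through the detection-grid footprint
(the rescaled detection image is for segmentation only). The cytoplasm
mask is built by:

1. blanking granule footprints to zero (literal ImageJ semantics; a
   normalized-convolution variant that ignores blanked pixels is
   available behind `normalized_blur = TRUE`),
2. blurring with `blur_sigma = 8` raw px,
3. keeping pixels whose blurred value lies in `[mean, upper_limit]`
   (default ceiling 65000), where `mean` is the blurred image's global
   mean, and
4. excluding the granule footprints from the result.

Two refinements: blanked footprints are dilated by `blank_dilate_px`
(default 2 raw px) before blanking, because the detection mask cuts a
punctum roughly at half maximum and its Gaussian skirt otherwise leaks a
percent-level bias into the diffuse-pool mean; and the lower threshold
carries a `1e-9` relative tolerance so that a perfectly uniform image —
where every blurred value equals the mean up to float rounding — yields
the full-image mask rather than an arbitrary half of it.

The σ = 8 blur is wide compared to the nuclear voids, so where the mean
threshold lands relative to the cytoplasm/background midpoint decides
whether the mask stays clean. When the cytoplasm covers more than about
half the field (the packed-tissue situation these crops come from), the
global mean exceeds the midpoint and the mask boundary falls strictly
inside the cytoplasm; sparse fields with large dark areas will pull
background pixels into the mask and bias coefficients — a limitation
inherited from the global-mean rule itself.

Field means are unweighted arithmetic means over granules; replicate
summaries belong downstream in the SuperPlot machinery, matching the
convention that each granule is one data point. For time-lapses, each
frame is cropped to the analysis regions, granules are pooled across
regions before averaging (`pool = FALSE` averages region means instead —
the procedure descriptions do not fix this choice, and pooling matches
"mean of all granules present at a time point"), and frames with zero
detected granules carry an explicit `NA` rather than zero, which would
otherwise drag time-course averages toward full decondensation.
Decondensation time courses are summarized by least-squares fitting of
`ρ(t) = ρ_∞ + (ρ_0 − ρ_∞)·e^{−kt}` (Levenberg–Marquardt, non-negative
bounds, start values taken from the data extremes).

## Colocalization

RNA spots are detected with the spot defaults (threshold 0.3434-class,
minimum size 4, no size exclusion) and reduced to intensity-weighted
centers of mass on the raw grid. A spot is "in" a granule when its
center-of-mass pixel, rounded to the nearest raw pixel, carries a granule
label — strict pixel membership, the literal object-based reading. Some
object-based tools accept centers within a small radius of the particle;
that radius is exposed as `tolerance_px` (default 0) rather than chosen
silently. Fractions are undefined (an error, not zero) when no spots
exist; zero granules with spots present give fraction 0.

## Traces

ΔF/F uses the mean of the first four values as F0 (the frames acquired
before the stimulus), so the baseline maps to exactly zero; F0 ≤ 0 is an
error rather than an infinity. Endpoint (dose–response) changes are
reported on the t0-normalized scale, `f_end/f_0 − 1`, together with the
normalized endpoint itself — the two readings are algebraically
equivalent and both are returned so the caller can plot either.
Translation-foci time courses divide each movie's counts by that movie's
own maximum (all-zero movies are excluded with a warning) and report the
across-movie mean ± SEM per frame, with SEM = sample sd / √n over movies.
Foci counting itself is manual in this workflow; the package normalizes
and summarizes the counts rather than re-detecting foci.

## Statistics

`superplot_summary()` reports, per condition, both the mean of
biological-replicate means (the unit that avoids pseudoreplication) and
the pooled mean over all points; the two coincide for balanced designs.
`run_test()` covers the four designs used for this kind of data — Welch
t (Student's behind `var_equal`), Mann–Whitney, Kruskal–Wallis with
Dunn's post-tests, one-way ANOVA with Dunnett's post-tests — on either
individual points or replicate means. Dunn's test is implemented directly
(mean-rank z comparisons with tie correction) with Bonferroni adjustment
by default, since no installed package provides it; it reduces exactly to
the tie-corrected Kruskal–Wallis statistic for two groups, which the test
suite uses as a cross-check. Dunnett's adjustment comes from `multcomp`;
its single-step multivariate-t p-values are computed by randomized
quasi-Monte-Carlo integration, so the call is wrapped in a pinned local
RNG state to keep results deterministic for a given table. The suite
calibrates all four designs on 1000 null tables and requires empirical
type-I error between 3% and 7% at α = 0.05.

The interactor filter retains a protein only if, in each of (by default)
two replicates, it has ≥ 10 bait peptides and at least 2× more bait than
control peptides; a control count of zero passes the ratio whenever the
minimum holds, and absence from a replicate fails that replicate.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not the optics that produce it:

- **Geometry.** Ring-shaped cell bodies (cytoplasmic annulus around a
  nuclear void). `demo_scene()` builds the canonical test scene: a 2 × 2
  tile of cells whose rings extend past the field borders, as in a crop
  from packed tissue; cytoplasm then covers most of the field, which is
  the regime in which the global-mean mask rule is clean (see above).
  The nuclear/background level defaults to half the cytoplasm level —
  real nuclei are dim, not black, and a moderate step keeps ring-edge
  band-pass responses well below granule responses.
- **Granules.** Isotropic 2D Gaussians, default σ = 1.5 raw px
  (point-spread-limited appearance of a 100–200 nm punctum at 0.043
  µm/px) and amplitude 300 over a cytoplasm of 200 (true partition
  coefficient 2.5, the condensed-state regime). Raw-image intensity
  scales are free parameters — the source data expose only processed
  coefficients, never raw intensity statistics — so defaults were chosen
  once for detector testability. Centers sit at integer pixels so
  noise-free peak values are exact.
- **Noise.** Additive Gaussian read noise plus optional Poisson shot
  noise via a gain (`gain · Poisson(I/gain)`), both off by default in
  unit tests; values clip (never wrap) at the declared bit depth,
  matching camera saturation.
- **Kinetics.** After the stimulus frame, all granule amplitudes follow
  `amp(t) = cytoplasm · (ρ(t) − 1)` with
  `ρ(t) = ρ_∞ + (ρ_0 − ρ_∞)·e^{−k(t−t_s)}`, so the noise-free field mean
  equals ρ(t) exactly. `conserve_total = TRUE` additionally raises the
  cytoplasm level so the total intensity integral is constant across
  frames — decondensation without a protein-level change, used to verify
  that end-over-start ROI ratios stay at 1.
- **smFISH pairs.** Exactly `round(n·fraction)` spots are placed inside
  granules (one per granule, sub-pixel jitter — an RNA inside a 100–200
  nm granule sits within a pixel of its center at this pixel size) and
  the rest in granule-free cytoplasm, more than 2σ + 1 px from every
  granule center, with a minimum spot separation so spots stay
  individually resolvable.
- **Calcium.** Flat baseline, linear rise from stimulus to peak,
  exponential decay toward a plateau, Gaussian noise.

Every stochastic operation takes an explicit seed and leaves the global
RNG untouched; identical spec + seed is bit-identical. What the generator
does *not* emulate: optical PSF structure, 3D sectioning, granule
motion/fusion/fission, photobleaching, autofluorescence texture, or
spatially correlated noise. Tests passing on these scenes demonstrate
that the measurement chain is correct and unbiased under its stated
assumptions — not that detection would be this clean on real tissue,
where threshold calibration against manual annotations carries the
burden the synthetic ground truth carries here.

## Problem sizes and numerical tolerances

The validation suite runs 20 clean fields (10–30 granules each, centers
≥ 6 px apart) through a 17-point threshold sweep for detection fidelity;
a 41-point grid on 10 annotated fields against a brute-force argmax for
calibration; 100 granules with distinct amplitudes under 5% Gaussian
noise for coefficient recovery (mean within 5%, Spearman ≥ 0.95); a
60-frame time-lapse (ρ 2.5 → 1.5, k = 0.1/frame, 5% noise) for kinetics
(k within 20%); 200-spot channel pairs at requested fractions 0, 0.25,
0.5 and 1 for colocalization (exact binomial 95% interval); and 1000
null tables per statistical design. These sizes were chosen so each
property is measured with comfortable statistical margin while the whole
suite stays quick enough to run habitually. Scale-invariance checks are
held to `1e-12` (the measurement is a ratio); rendering identities to
float tolerance; recovery checks to the tolerances above, which reflect
noise levels, not implementation slack.

## Known limitations

- The global-mean cytoplasm mask biases coefficients on fields that are
  mostly dark (see above); it is faithful to the procedure rather than
  robust to violated assumptions.
- The band-pass detector is not the original small-particle-detection
  operator; published threshold values transfer in role, not in value.
- Membership at a single center-of-mass pixel makes colocalization
  sensitive to sub-pixel registration error between channels.
- Granule tracking across frames, fusion/fission calling, 3D detection,
  and pixel-correlation colocalization (Pearson/Manders) are out of
  scope.
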