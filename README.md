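# punctate

Quantification of RNP-granule remodeling in fluorescence microscopy of
intact brain tissue.

Neuronal cell bodies contain membrane-less ribonucleoprotein (RNP)
condensates — 100–200 nm puncta of RNAs and RNA-binding proteins sitting
over a diffuse cytoplasmic pool. Neuromodulatory stimuli can *decondense*
these granules: protein shifts from the granular to the soluble pool, and
granule-associated mRNAs are released and translated. `punctate`
implements the image-quantification side of that biology for confocal
fields of cell bodies (where the nucleus fills most of the cell and the
cytoplasm appears as a bright ring):

- **Particle detection.** Fields are Gaussian-blurred, upsampled two-fold
  (bilinear), rescaled to 16-bit, and thresholded on a
  difference-of-Gaussian band-pass response at a unitless fraction of the
  in-image response range; 8-connected components of ≥ 4 detection pixels
  become particles, optionally excluding those under 13 pixels. The
  relative threshold is calibrated by maximizing the F1 score against
  point annotations.
- **Partition coefficients.** For each granule *i*,
  `ρ_i = max_i(I_raw) / mean(I_raw | cytoplasm mask)`, where the cytoplasm
  mask is built by blanking granule footprints, blurring with σ = 8 px,
  and keeping pixels whose blurred value lies in `[mean, 65000]`. ρ = 1
  means fully decondensed; time-lapse means are fit with
  `ρ(t) = ρ_∞ + (ρ_0 − ρ_∞)·exp(−k·t)`.
- **Object-based colocalization.** smFISH spots are reduced to
  intensity-weighted centers of mass; the colocalized fraction is the
  share of spot centers falling inside granule footprints.
- **Trace analysis.** Calcium traces as `ΔF/F = (F(t) − F0)/F0` with F0
  the mean of the four pre-stimulus frames; dose–response endpoints on the
  t0 = 1 scale; translation-foci time courses normalized to each movie's
  own maximum.
- **Replicate-aware statistics.** SuperPlot summaries (replicate means vs
  pooled points), Welch/Student t, Mann–Whitney, Kruskal–Wallis + Dunn,
  one-way ANOVA + Dunnett, and the peptide-count filter for
  co-immunoprecipitation interactors (≥ 10 peptides, ≥ 2× enrichment, in
  both replicates).
- **Synthetic microscopy.** A generator renders ring-shaped cell bodies,
  Gaussian puncta, smFISH channel pairs, decondensation time-lapses and
  calcium transients with Poisson–Gaussian noise and a complete ground
  truth, so every measurement above can be validated end to end without
  external data.

## Worked example

Render a noisy synthetic field (15 granules of amplitude 300 over a
cytoplasm at 200, read noise sd 10), detect the granules, and measure
their partition coefficients:

```r
library(punctate)

spec <- demo_scene(n_granules = 15, noise_gaussian_sd = 10, seed = 42)
out  <- generate_field(spec, seed = 1)
out$field
#> <image_field> 128 x 128 px, 0.043 um/px, channel 'granule', 16-bit
#>   intensity range [63.29, 523.1]

res <- field_partition(out$field, detection_params(relative_threshold = 0.35))
res
#> <partition_result> 15 granule(s), field mean 2.526, cytoplasm 198.8
head(res$per_granule, 3)
#>   id coefficient max_raw_intensity
#> 1  1    2.448174          486.6474
#> 2  2    2.624468          521.6912
#> 3  3    2.580528          512.9567
```

All 15 granules are found; the estimated cytoplasm level (198.8) and mean
partition coefficient (2.526) sit within ~1% of the generator's ground
truth (200 and 2.5): each granule peaks at cytoplasm + amplitude = 500,
so the true coefficient is 500/200 = 2.5, and the per-granule scatter
reflects the injected read noise. The relative threshold (here 0.35) is a
channel property; `calibrate_threshold()` selects it by F1 score against
point annotations.

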