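# perizone

Quantification of sub-synaptic protein organization in fluorescence
microscopy, for neuroscientists measuring where endocytic and scaffold
proteins sit relative to the active zone. The package implements two
measurement families as tested, reusable R pipelines:

* **STED images of cultured hippocampal neurons** — perpendicular line
  profiles across side-view synapses (peak-to-peak distance of a protein to
  the active-zone/PSD marker, and its peak level within the periactive-zone
  window of ±68 nm or 136 nm one-sided), cluster detection around the
  active-zone center at en-face synapses (counts, distances, integrated
  intensity = area × mean), and confocal-level protein means within an
  Otsu-derived presynaptic mask.
* ***Drosophila* NMJ volumes (Airyscan-class)** — whole-bouton 3D
  intensities inside a normalized-sum / gaussian / auto-threshold / eroded
  mask with rolling-ball background subtraction, and periactive-zone (PAZ)
  unit statistics: units are local minima of a composite image
  (e.g. Nwk + Dyn − Brp) expanded by seeded region growing, edge-excluded
  by a mean Euclidean-distance-map score < 7.5 px, split into a 175 nm
  **mesh** band and a **core**, and summarized by the polarization
  `log2(mesh mean / core mean)`, Brp objects per µm², and the percentage of
  units containing Brp or apposed to Pak.

A statistics layer reproduces the assumption-gated comparison scheme
(Shapiro/Levene gates → Student's t / ANOVA + Tukey-Kramer, or
Mann-Whitney U / Kruskal-Wallis + Holm) plus Pearson colocalization, and a
synthetic-microscopy generator (`generate_sted_field()`,
`generate_nmj_volume()`) produces scenes with exhaustive ground truth so
every stage is verifiable by parameter recovery — no raw image downloads
are needed anywhere in the test suite.

## A worked example

Recover known protein offsets from a synthetic STED field:

```r
library(perizone)
cfg <- experiment_config()
scene <- generate_sted_field(synth_sted_params(
  n_sideview = 6, n_enface = 0, delta_nm = c(-90.8, 0, 90.8), seed = 7))
rois <- sideview_rois_from_truth(scene$truth, cfg)
sapply(rois, function(roi) {
  pr <- align_profile(extract_profile(scene$field, roi, cfg))
  profile_metrics(pr, cfg)$peak_to_peak_nm
})
#> [1] -90.8   0.0  90.8 -90.8   0.0  90.8
```

Each value is the signed distance (nm, positive toward the presynaptic
side) between the protein peak and the marker peak of one synapse; the
generator placed the bands at −90.8, 0 and +90.8 nm (±4 pixels at the
22.7 nm STED pixel pitch), and the pipeline recovers them exactly on
noise-free scenes. The full NMJ pipeline runs as one call:

```r
nmj <- generate_nmj_volume(synth_nmj_params(seed = 1))
res <- analyze_nmj_paz(nmj$volume)
res$summary[, c("n_units_analyzed", "brp_density_per_um2",
                "pct_brp_positive", "polarization_nwk")]
#>   n_units_analyzed brp_density_per_um2 pct_brp_positive polarization_nwk
#> 1               15           0.5052632               60         0.980222
```

Twelve Brp puncta in the 23.75 µm² bouton give a density of ~0.5 per µm²;
60% of analyzed units contain Brp (the generator's `brp_fraction = 0.6`),
and the recovered Nwk polarization is close to `log2(2) = 1` for the
default two-fold mesh enrichment.

## Layout

* `R/` — calibration/config/IO (`experiment_config()`, `load_field()`),
  synthetic generators, side-view, en-face, confocal, NMJ-bouton, PAZ and
  statistics modules.
* `src/` — compiled kernels: 8-connected labeling, seeded region growing,
  morphological reconstruction, regional minima, fast disc erosion/dilation.
* `vignettes/synapse-quantification.Rmd` — the measurement models, the
  synthetic-scene design, numerical choices and limitations.
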