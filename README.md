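# cochleamorph

Quantitative 3D morphometry of the cochlea from micro-CT, centred on the
osseous spiral lamina (OSL) — the thin bony shelf, made of a tympanic and
a vestibular plate, that spirals from the modiolus to the lateral wall and
carries the auditory nerve fibres. Otosclerotic remodeling changes both
the OSL's width and the porosity of its plates, and calcified lesions
("cochleoliths") form at specific tonotopic places; this package turns
those observations into reproducible measurements.

Given a grayscale volume (TIFF stack or NIfTI) and three landmark points
(cochlear centre, helicotrema, basal end), the pipeline computes:

* **Segmentation** — window thresholding plus connected-component noise
  filtering, label subtraction (the apex soft-tissue recipe) and masked
  intensity extraction.
* **OSL width profile** — the spiral is unwrapped into a continuous
  angular coordinate about the modiolar axis; in each 4° radial section
  the modiolar and lateral walls are localised to sub-voxel precision and
  the width is their distance, `w(θ)`, from base to apex.
* **Tonotopic band statistics** — positions are normalised by arc length
  and mapped to frequency with a Greenwood-form function
  `f(x) = A·(10^(a·x) − k)` (defaults A = 165.4 Hz, a = 2.1, k = 0.88,
  x from apex; spiral-ganglion variants via configuration). The spiral is
  partitioned into octave bands and the mean ± SD width is reported per
  band. Inclusions are assigned to bands by overlap fraction.
* **Plate porosity** — the OSL is split into its tympanic and vestibular
  plates along the inter-plate gap, segmented into basal / midturn / apex
  thirds, and each plate segment's porosity is `p = (Vf − Vo)/Vf · 100%`,
  where `Vo` is the porous volume and `Vf` its pore-filled counterpart
  (morphological closing with an exact Euclidean ball, or a mesh
  shrink-wrap backend with STL export).

A synthetic cochlea phantom (`generate_phantom()`, `generate_porous_slab()`)
with *exact* ground truth — analytic width profile, voxel-counted
porosity, known inclusion position — makes every stage verifiable without
specimen data. See the methods vignette
(`vignettes/cochleamorph-methods.Rmd`) for the models and numerical
choices.

## Worked example

```r
library(cochleamorph)

# a 2-turn phantom at 100 um voxels, 20% plate porosity, cochleolith at 2 kHz
spec <- phantom_spec(voxel_size_um = 100, turns = 2,
                     pore_target_fraction = 0.2, seed = 5)
ph <- generate_phantom(spec)
ph
#> <cochlea_phantom> 160 x 160 x 40 @ 100 um; 2.00 turns, OSL 80998 voxels

frame <- build_reference_frame(ph$landmarks$center, ph$landmarks$helicotrema,
                               ph$landmarks$basal)
bone <- remove_small_components(
  threshold_segment(ph$volume, threshold_rule(120, 220)), 27)

profile <- attach_position(width_profile(extract_wall_contours(bone, frame)))
bands <- band_stats(profile, octave_partitions())
bands[6:11, ]   # basal half shown
#>       band_label   f_lo_hz   f_hi_hz mean_width_mm sd_width_mm n_samples
#>    635Hz-1.27kHz   635.136  1270.272         0.664       0.035        17
#>  1.27kHz-2.54kHz  1270.272  2540.544         0.797       0.044        21
#>  2.54kHz-5.08kHz  2540.544  5081.088         0.945       0.039        26
#>  5.08kHz-10.2kHz  5081.088 10162.176         1.077       0.048        33
#>  10.2kHz-20.3kHz 10162.176 20324.352         1.261       0.055        44
#>  20.3kHz-20.7kHz 20324.352 20677.074         1.339       0.001         2
```

The mean width falls monotonically from 1.34 mm in the most basal band to
0.28 mm at the apex — the phantom's configured (and the human OSL's
reported) range — with the per-band SD reflecting the within-band slope of
the width profile.

```r
segment_porosity(bone, frame, closing_radius_vox = 3)
#>  segment      plate backend Vo_mm3 Vf_mm3 p_pct
#>    basal   tympanic   voxel 11.821 15.734  24.9
#>  midturn   tympanic   voxel 14.520 18.637  22.1
#>     apex   tympanic   voxel 14.164 16.263  12.9
#>    basal vestibular   voxel 11.765 15.733  25.2
#>  midturn vestibular   voxel 14.465 18.639  22.4
#>     apex vestibular   voxel 14.240 16.260  12.4
```

`Vo` is the segmented plate volume, `Vf` the pore-filled volume, and
`p_pct` the resulting porosity; the basal values match the phantom's
per-segment truth to a fraction of a percentage point (the apex is less
porous because its narrow ribbon admits fewer interior pores — exactly as
the truth table records).

```r
incl <- threshold_segment(ph$volume, threshold_rule(230))
localize_inclusion(incl, attr(profile, "midpoints_mm"), octave_partitions())[1, ]
#>       band_label overlap_fraction
#>  1.27kHz-2.54kHz                1
```

The dense lesion planted at the 2 kHz tonotopic position is assigned
entirely to the octave band containing 2 kHz.

`run_pipeline(pipeline_config(phantom = spec, seed = 5), "out/")`
executes the whole chain and writes `width.csv`, `bands.csv`,
`porosity.csv`, `inclusion.csv` and a machine-readable `summary.json`.
A thin command-line front-end with `phantom` / `segment` / `width` /
`porosity` / `run` subcommands is installed at `inst/cli/cochleamorph.R`.

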