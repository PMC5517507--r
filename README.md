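# poleprofile

Posterior-pole profile analysis from en-face OCT: locate the **deepest
point of the eyeball (DPE)** — the posterior-most point of the Bruch's
membrane/choroid interface — in a stack of coronal (en-face) OCT
sections, and relate its position to optic disc tilt, torsion and
ovality.

Myopic eyes elongate locally as well as globally; the resulting
posterior-pole contour appears to pull the optic nerve head toward the
deepest point, producing the tilted, torted discs typical of myopia. The
package is aimed at researchers who want to study that relationship with
a fully automated, fully testable measurement chain. Because clinical
volumes of this kind are not publicly available, the package ships a
ground-truthed **phantom generator**: every measurement, classification,
geometric prediction and statistic can be exercised end-to-end against
known truth.

## What it computes

In the canonical right-eye frame (origin at the fovea, +x temporal, +y
superior; left eyes mirrored on ingestion; coronal sections 0-based,
2.6 µm apart, 1,000 sections = 2.6 mm of depth):

* **DPE detection** — per-pixel depth map (most posterior section whose
  Bruch's-membrane mask contains the pixel, via two-stage Otsu
  thresholding, binary median filtering, closing and an area filter),
  then the smoothed-argmax section and the intensity-weighted centroid of
  the interface island.
* **Posterior-pole metrics** — disc-DPE and fovea-DPE distances (µm),
  signed disc-DPE and fovea-DPE depths (sections × 2.6 µm), and the
  signed, inferior-positive disc-DPE and disc-fovea angles.
* **Disc configuration** — ovality LD/SD from a direct least-squares
  ellipse fit of the margin, torsion as the signed deviation of the long
  axis from the fovea-referenced vertical meridian (positive =
  inferotemporal), and horizontal/vertical tilt from cross-section chords
  (ONH plane vs Bruch's-membrane reference plane).
* **Geometric model** — the four-region DPE classification (near fovea /
  superior / inferior / near disc, 3,000 µm radii), the foreshortening
  law `ovality = 1 / cos(tilt)`, and the angle-addition identity
  `torsion = disc-DPE angle − disc-fovea angle`.
* **Statistics** — two-way mixed-model ICC (consistency, single and
  average measure, F-based CIs), group comparisons (t / ANOVA +
  Kruskal-Wallis / χ²), Pearson correlation tables, and univariate-screen
  (P < 0.2) → multivariate OLS regression reports.
* **Pipeline** — `run_pipeline()` simulates (or ingests) a cohort,
  measures every eye and writes the cohort CSV plus group, subgroup,
  correlation and regression tables; `reproducibility_run()` simulates
  the 10 + 15-eye intervisit design and reports the five reliability
  ICCs. A thin CLI lives in `inst/cli/poleprofile.R`.

Volumes travel as multi-page 16-bit TIFF + JSON sidecar (bit-exact round
trip); tables as CSV with a units header row.

## Worked example

Build a myopic-looking phantom — a gently curved posterior pole with a
320 µm staphyloma-like bump inferotemporal of the disc and a 13° disc
tilt toward it — render it, and measure it:

```r
library(poleprofile)

s  <- build_surface(base_radius = 60, bump_center = c(-1.2, -2.6),
                    bump_amplitude = 320, bump_sigma = 2)
lm0 <- place_landmarks(s, disc_fovea_angle_deg = 6)
dir <- angle_inferior_positive(lm0$disc_center, s$true_dpe[1:2])
lm  <- place_landmarks(s, disc_fovea_angle_deg = 6,
                       tilt_spec = list(tilt_deg = 13, direction_deg = dir))
v   <- render_enface(s, lm, list(nx = 192, ny = 144, n_sections = 400,
                                 band_um = 31.2, speckle_sd = 0.2), seed = 7)
m   <- measure_eye(v)
m$dpe; m$metrics; m$disc; m$category$label
```

```
surface_model: base radius 60 mm, bump 320 um (sigma 2.00 mm) at (-1.20, -2.60) mm
  true DPE: (-0.990, -2.140) mm, depth 263.6 um
dpe_result: section 299 (depth 777.4 um), center (-0.978, -2.124) mm, area 0.148 mm2 [ok]
posterior_pole_metrics:
  disc-DPE   4354.2 um, depth   340.6 um, angle   36.6 deg
  fovea-DPE  2338.2 um, depth   145.6 um; disc-fovea angle 6.0 deg
disc_config: LD 1600 um / SD 1559 um (ovality 1.026), torsion 30.8 deg, tilt H 10.6 / V 6.5 deg
[1] near_fovea
```

Reading it: the detector found the DPE within one 62.5 µm pixel of the
true argmax ((-0.978, -2.124) vs (-0.990, -2.140) mm). The DPE sits 36.6°
inferior of the disc's horizontal meridian and the fovea 6.0° inferior,
so the geometric model predicts a torsion of 36.6 − 6.0 ≈ 30.6°; the
torsion actually measured from the disc's long axis is 30.8° — the
angle-addition identity in action:

```r
predict_torsion(m$metrics$disc_dpe_angle_deg, m$metrics$disc_fovea_angle_deg)
#> [1] 30.63...
```

The measured ovality 1.026 matches the foreshortening law
`1/cos(13°) = 1.026`, and the signed depths say the DPE lies 340.6 µm
posterior to the temporal disc border (131 sections × 2.6 µm).

The methods vignette (`vignettes/posterior-pole-analysis.Rmd`) documents
the model, the sign conventions, the phantom's assumptions and the
numerical choices in detail.

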