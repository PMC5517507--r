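---
title: "Locating the deepest point of the eyeball in en-face OCT: models, phantoms and measurement conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the deepest point of the eyeball in en-face OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poleprofile)
```

## The problem

Myopic eyes elongate not only globally but in a localized manner, and the
resulting posterior-pole contour appears to reorganise the optic nerve
head: discs in highly myopic eyes look tilted and torted. A way to study
this is to find the *deepest point of the eyeball* (DPE) — the
posterior-most point of the Bruch's membrane (BM)/choroid interface — from
a swept-source OCT volume viewed as a stack of en-face (coronal) sections,
and to relate the DPE's position to the disc's measured tilt, torsion and
ovality.

`poleprofile` implements that entire analysis as an automated, tested
pipeline: a phantom generator with exact ground truth, a detector that
reproduces the examiner's procedure of scrolling the coronal sections back
and forth, the in-plane and depth metrics with their sign conventions, the
four-region classification of the DPE location, the geometric model that
predicts torsion and ovality from the DPE position, and the statistics the
analysis reports (two-way mixed-model ICC, group comparisons, Pearson
correlations, screened multivariate regression). No patient data are used
anywhere; every empirical statement in the test suite is computed on
phantoms at run time.

## Coordinate frame and conventions

All analysis happens in a canonical right-eye fundus frame:

* origin at the fovea, **+x temporal**, **+y superior**, lateral units mm;
* depth positive-posterior in micrometers; coronal sections are 0-based
  and increase posteriorly; depth differences are *counted in sections*
  and converted at the section pitch (2.6 µm/section at scanner defaults,
  1,000 sections = 2.6 mm of depth);
* left eyes are mirrored about the vertical axis on ingestion, so signed
  angles are comparable across eyes;
* angles at the disc use the *inferior-positive* convention: the disc-DPE
  angle is the signed angle between the temporal horizontal meridian
  through the disc centre and the ray to the DPE, positive when the DPE is
  inferior. The disc-fovea angle is defined identically (a normal fovea
  sits 2-6° inferior to the disc, hence positive);
* torsion is the signed deviation of the disc's long axis from the
  fovea-referenced vertical meridian (the perpendicular of the disc-fovea
  line). Positive torsion is inferotemporal. In the canonical frame this
  is a *clockwise* rotation of the long axis away from the meridian. This
  choice is forced by consistency: with the disc plane tilted toward the
  DPE, the projected long axis lies perpendicular to the tilt direction,
  and the measured torsion then equals (disc-DPE angle − disc-fovea
  angle). Only the clockwise-positive reading makes that identity come out
  with the published signs (inferior-DPE eyes: positive torsion; superior:
  negative).

## The phantom generator

The synthetic posterior pole is

$$z(x, y) \;=\; z_{\text{base}}(x, y) \;+\; A\,
  \exp\!\Big({-\tfrac{(x - b_x)^2 + (y - b_y)^2}{2\sigma^2}}\Big),$$

a sphere of radius $R$ tangent at the field centre plus a single Gaussian
bump of amplitude $A$ (µm) and width $\sigma$ (mm) — the localized
elongation that carries the DPE away from the pole. The true DPE is the
dense-grid argmax of $z$ at 10 µm resolution, stored with every phantom.
Multi-bump surfaces are available for detector stress tests; the deepest
point of the summed surface remains the defined truth.

Parameters that matter, with defaults:

| parameter | default | meaning |
|---|---|---|
| `base_radius` | 60 mm | residual background curvature of the *flattened* stack |
| `bump_amplitude` | cohort-drawn, 30-380 µm | relief of the DPE above the local base |
| `bump_sigma` | 2 ± 0.3 mm | lateral extent of the localized elongation |
| `band_um` | 10.4 µm (4 sections) | rendered thickness of the BM band |
| `speckle_sd` | 0.2 | multiplicative log-normal speckle SD |
| raster | 512 × 384 px, 1,000 × 2.6 µm | 12 × 9 mm field, 23.4 µm pixels |

Two of these need justification:

* **`base_radius` = 60 mm, not a globe radius (~12-14 mm).** The clinical
  en-face stacks are generated *after automatic flattening at the RPE*,
  yet depths are read across sections — the flattening and the depth
  signal coexist in the clinical software in a way its documentation does
  not explain. A raw globe of radius 13 mm would sag ~2.6 mm across a
  12 × 9 mm field, consuming the entire axial span and swamping any
  localized bump, which is precisely why the scanner flattens. We
  therefore render a *gently curved residual* surface: deep enough that
  depth readings behave like the clinical ones (references at the fovea
  and the temporal disc border differ by tens to hundreds of µm), shallow
  enough that a staphyloma-like bump of a few hundred µm can genuinely be
  the deepest point at any of the four canonical locations. With a
  perfectly flat base the degenerate all-equal-depth case would dominate.
* **Bump amplitude is drawn as relief above the local base depth.** The
  cohort spec asks for DPE locations in given proportions (near fovea /
  superior / inferior / near disc, in the myopic vs emmetropic mixture of
  the reference cohort); drawing absolute amplitudes would let the base
  curvature recapture the argmax for eccentric bumps. Each eye is redrawn
  (up to 20 times) until the true DPE classifies into the intended
  region; the recorded truth is always the actual argmax category.

Rendering: for each lateral pixel with rendered depth $z$, sections
anterior to $z$ show retina-level reflectivity, sections within
$[z, z + \text{band}]$ show the bright BM band, deeper sections show
darker choroid; inside the disc margin the band is absent (BM opening) and
a dark cup is rendered. Speckle is multiplicative log-normal — the
simplest model that produces the granular look of OCT sections without
claiming OCT physics (no interference, attenuation, or vasculature).
Intensities are quantised to the 16-bit grid at render time so that the
TIFF round trip is bit-exact.

## The detector

The examiner's procedure — scroll the sections until the bright interface
island disappears — is operationalised as:

1. **Threshold.** A volume-global two-stage Otsu: the first split
   separates the dark choroid, a second split of the upper class isolates
   the BM band from the retina when the two are clearly distinct (mean
   ratio ≥ 1.3). The cue is relative brightness, never an absolute level.
2. **Mask clean-up.** Per section: a 3 × 3 binary median (majority vote)
   against speckle, morphological closing (radius 2 px), and a minimum
   region area of 0.05 mm².
3. **Depth map.** For every lateral pixel, the most posterior section
   whose mask contains it; pixels never segmented (the BM opening) are
   missing. More than 50% missing raises a `low_contrast` flag.
4. **DPE.** The maximum of the 3 × 3-median-smoothed depth map (the
   smoothing suppresses single-pixel speckle wins). Ties resolve to the
   more posterior section; the centre is the intensity-weighted centroid
   of the interface region in that deepest section, with the largest
   region chosen (and flagged) if several are present. Depth relief below
   2 sections flags `low_relief` (flat-surface degenerate case: the
   centre then reports the field centroid).

Numerical behaviour worth knowing: on sloped surface regions the band
ring in a single section has lateral width band/slope. At the clinical
23 µm pixel pitch that is several pixels, but at the coarse desk-scale
rasters the tests use it can fall below one pixel, where the majority
filter prunes it. Desk-scale configurations therefore thicken the band
with the pixel pitch (31.2 µm at 125 µm pixels); this preserves the
band-to-pixel geometry of the full-scale instrument rather than changing
the science.

## Metrics, disc configuration, classification

The six DPE metrics are Euclidean in-plane distances (µm) from disc
centre and fovea, the two signed angles described above, and two signed
depths: DPE section minus temporal-disc-border section, and DPE section
minus foveal-interface section, each times the pitch. Depths are kept
signed (positive = DPE posterior) because group SDs larger than the means
imply genuine sign variation that the statistics need.

Disc ovality is measured by a direct least-squares conic fit to the
margin points (LD/SD of the fitted axes). The fit coincides with the
longest/shortest hand-drawn diameters for true ellipses, which is what the
phantom margins are; an orientation below ovality 1.02 is numerically
unstable and torsion is then reported 0 with `torsion_defined = FALSE`.
Tilt is measured exactly as the cross-sectional protocol prescribes: the
chord joining the two clinical margin points on the scan line (ONH plane)
versus the chord joining the BM interface at the same positions
(reference plane), on the disc-fovea axis (horizontal; temporal-deeper
positive) and its perpendicular (vertical; inferior-deeper positive).
Chords, not plane fits, keep the angles comparable with the clinical
values.

Classification: within 3,000 µm of the fovea → `near_fovea`; else within
3,000 µm of the disc centre → `near_disc`; else superior/inferior by the
side of the extended fovea-disc line. Radii are inclusive; a point on the
line beyond both radii classifies as inferior (the rules as published
leave both unstated; the near-disc rule's text actually repeats "of the
fovea", an evident slip we resolve to the disc centre). When both radii
could contain the DPE the fovea takes precedence — only reachable when
disc and fovea are closer than 6 mm, which the generator avoids.

The geometric model is deliberately small: orthographic projection of a
tilted circular disc (long diameter 2r along the tilt axis, short diameter
2r·cos θ, hence ovality 1/cos θ), and the angle-addition identity
predicted torsion = disc-DPE angle − disc-fovea angle. Both are treated
as *predictions to test against the forward-simulated measurements*, not
as constraints imposed on them.

## Statistics

The ICC is the consistency-type two-way mixed model (Shrout-Fleiss 3,1
and 3,k) computed from the ANOVA decomposition, with the standard F-based
95% intervals; `stats::aov` serves as an independent oracle in the tests.
The published analysis says only "two-way mixed effect model" with
single/average footnotes; consistency was chosen because both observers
applied the same caliper protocol, making systematic rater offsets
uninteresting. A matrix with zero within-subject disagreement is defined
as ICC 1.

Group comparisons use the independent t-test (two groups), one-way ANOVA
*and* Kruskal-Wallis (four groups; the published tables mix both, so both
are emitted and normality is not adjudicated), and Pearson's chi-squared
without continuity correction for categorical tables. The regression
procedure regresses each candidate alone, admits survivors of the
univariate screen at P < 0.2 into a joint OLS model, and reports betas
with 95% CIs. (The published table footnote says P < 0.05 while the text
says P < 0.2; the text's rule is implemented.) Collinear survivors are
kept, with a condition-number warning, rather than silently dropped.

## Reproducibility design

`reproducibility_run()` simulates the intervisit design: independent
series on 10 emmetropic and 15 myopic eyes, each rendered twice with
fresh speckle and a fixation offset of SD 0.05 mm per axis, measured
end-to-end on both visits, and summarised as single- and average-measure
ICCs for the five reported metrics (DPE interface section, disc-DPE
distance, disc-DPE depth, fovea-DPE depth, disc-DPE angle). With zero
noise all five ICCs are exactly 1; at the default noise they exceed the
0.75 "excellent" bar with a wide margin, because the between-eye anatomy
variance dwarfs the measurement noise — which is also the regime the
clinical reliability figures describe.

## Problem sizes used by the tests

The full-scale defaults (512 × 384 × 1,000 voxels per eye) are what the
package renders if asked. The test-suite and the worked examples use
desk-scale problem sizes chosen once: 96-192 pixel rasters (62-125 µm
pixels), 150-450 sections, 5-25 eyes per cohort, 50 noiseless phantoms
for the recovery study at the full 512 × 384 lateral raster, and 100
forward-simulated eyes for the torsion identity. These sizes keep every
property being tested (sub-pixel centroid recovery, one-section depth
resolution, ICC margins) well away from its tolerance while remaining
runnable on a laptop.

## Known limitations

* The phantom emulates geometry and first-order appearance, not OCT
  physics: no A-scan interference, attenuation, shadowing, choroidal
  vasculature, or eye-motion artefacts. Passing tests demonstrate the
  *measurement chain* is correct, not that segmentation would survive
  every pathology a clinic sees.
* The depth map records the last section containing the band; on steep
  slopes at coarse rasters this is conservative (see above). Reference
  readings at the fovea or disc border on a steep slope can be a few
  sections off at desk scale.
* The cohort simulator reproduces the *structure* of the reference
  cohort (group sizes, location mixture, covariate means/SDs, thresholds,
  the ≤ 30 mm axial-length exclusion), not its clinical joint
  distributions; measured-vs-true agreement, not clinical effect sizes,
  is what its tests certify.
* Real margins are hand-drawn on photographs; the phantom's margins are
  exact ellipses, so the ellipse-fit route is exact by construction and
  the hand-vs-fit discrepancy of real data is out of scope.
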