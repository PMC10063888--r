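---
title: "Measuring retinal vessel geometry under constant and individual conversion factors"
author: "rvgc package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring retinal vessel geometry under constant and individual conversion factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvgc)
```

## The measurement problem

Fundus photography shows the retinal vasculature in pixels, but clinical
interpretation of vessel calibers needs microns.  Because the true pixel
pitch of a fundus image depends on camera, field of view, scanning
resolution and the refraction of the photographed eye, vessel-analysis
pipelines calibrate against the optic disc (OD): the mean adult disc is
taken to be 1800 um across, so dividing 1800 um by a disc diameter in
pixels yields an image conversion factor (ICF) in um/px.  Two
conventions exist:

* **constant ICF** — 1800 um divided by the *cohort-average* disc
  diameter, applied to every image of a study; and
* **individual ICF** — 1800 um divided by the disc diameter of the
  *analyzed eye itself*.

The ICF does double duty.  It converts pixel widths to microns, and it
fixes the pixel size of the standard measurement zones: annuli around
the disc center starting half a disc diameter beyond the disc margin
(radius 1.0 reference diameters), with zone B ending at radius 1.5 and
zone C at 2.5 diameters.  With an individual ICF the inner boundary
coincides with the eye's own measured disc diameter; with a constant ICF
every image gets the same fixed pixel annulus.

Twelve retinal vessel geometric characteristics (RVGC) are measured per
image: the central retinal artery and vein equivalents and their ratio
in zone B (CRAE, CRVE, AVR) and over the full zone C (CRAEoC, CRVEoC,
AVRoC); the box-counting fractal dimension of the zone C vessel skeleton
(Df, and Dfa/Dfv for each type alone); and the mean simple tortuosity of
the zone C segments (STt overall, STa/STv per type).

The package implements this measurement chain on *labeled vessel maps*
(rasters with codes 0 background / 1 artery / 2 vein / 3 disc), a
synthetic generator of ground-truthed eyes to run it on, and the
agreement statistics used to compare measurement protocols.

## The measurement chain

**Vessel identification and width.**  Vessels are connected components
of each type's label mask.  Each mask is thinned to a one-pixel skeleton
(Zhang-Suen), and the local caliber at a skeleton point is twice the
Euclidean distance to the nearest background pixel, taken as the maximum
over the point's 3x3 neighborhood inside the mask — the ridge value of
the distance transform, which compensates the half-pixel jitter of
thinned skeletons.  A vessel's width in a zone is the mean over its
skeleton points inside the annulus; components contributing fewer than
10 points to the annulus are dropped as noise.

**Central retinal equivalents.**  Per type, the six largest vessel
widths (ties broken by vessel id) enter the iterative pairing formula:
sort, combine the largest with the smallest as
`w' = c * sqrt(w_max^2 + w_min^2)` with `c = 0.88` for arteries and
`0.95` for veins, carry an odd middle value, and repeat until one
equivalent remains.  If fewer than six vessels are measurable the list
is padded by repeating the smallest width and the result is flagged —
the batch analogue of adding vessels by hand.  Equivalents convert to um
by multiplication with the ICF.  Note that identical artery and vein
calibers give AVR = 1.748/2.138 = 0.818, not 1: the ratio of the pairing
chains' coefficients.

**Simple tortuosity.**  Per segment, the ratio of traced path length to
the endpoint chord.  The trace is the shortest 8-connected path through
the skeleton between the innermost and outermost points of the annulus,
smoothed by a 9-point running mean and subsampled every 5 px before
summing segment lengths: without smoothing, rasterization jitter of
+/-0.5 px inflates the arc length of a perfectly straight vessel by a
few parts per thousand, which matters at tortuosity values of 1.00-1.10.

**Fractal dimension.**  Binary box counting on the skeleton points
inside zone C: dyadic box sizes from 2 px to a quarter of the pattern's
bounding box (at least five ladder points are required), ordinary
least-squares slope of log N(s) against log(1/s).  The estimator is
calibrated in the tests on a straight line (1.0), a filled square (2.0)
and a depth-9 Sierpinski triangle (log 3 / log 2 = 1.585).

## The synthetic cohort

The generator emulates the imaging conditions of a scanned-film
screening cohort, and its defaults are frozen as the package's study
conditions:

| parameter | default | rationale |
|---|---|---|
| disc diameter | 1800 +/- 135 um | gives individual ICFs of 2.4 +/- 0.18 at the native scale |
| native scale | 2.4 um/px | mean disc renders at 750 px, as in high-resolution film scans |
| vessels | 7 arteries + 7 veins | at least six per type must survive zone selection |
| artery caliber | 89 +/- 12 um | calibrated so measured cohort CRAE is ~163 um |
| vein caliber | 95 +/- 13 um | calibrated so measured cohort CRVE is ~219 um |
| tortuosity | amplitude 24-52 px, wavelength 330-470 px | sinusoidal; yields simple tortuosity ~1.09 |
| taper | 0 | optional linear caliber loss with radial distance |

Vessels leave the disc as radial rays at jittered, evenly spaced angles
with a sinusoidal perpendicular displacement (ramped in over the first
half wavelength so vessels exit the disc radially).  Centerlines start
0.45 disc diameters from the center and end at 3.1 diameters, beyond
every zone C boundary in use.  Rendering stamps each vessel as a band of
its true width (`width_px = width_um / true_scale * scale_factor`) into
a label raster; the disc ellipse is drawn last.  A change of resolution
is modeled as an ideal resampling — all coordinates and widths scale
linearly — and a macula-centered (MC) view places the window on the
fovea, fixed at 2.5 disc diameters temporal to the disc on the
horizontal meridian.  That choice keeps zone C complete inside a
60-degree MC frame (the disc is taken to subtend 5 degrees), while
35-45 degree MC frames clip zone C and trigger the exclusion rule, as
they should.

The default frame is the tightest window containing zone C (plus the
margin to the constant-ICF zones), capped by the field of view; rendered
metadata records the disc geometry as drawn, the ground-truth vessel
table, and the clipped fraction of the eye's zone C annulus.

**What the generator does not emulate.**  Vessels do not branch, so the
fractal dimension of a synthetic eye is ~0.97 — a union of smooth curves
has box-counting dimension near 1 — rather than the ~1.24 typical of
real vasculature; comparisons of Df *between protocols* are meaningful,
its absolute level is not.  There is no photometric model (binary labels
only), no film grain or scanner artifacts, no ocular-magnification
differences between eyes, and fellow ("left") eyes share disc size and
calibers but not real biological asymmetries.  Passing tests therefore
validate the measurement chain and the protocol comparisons, not
photographic vessel segmentation, which is out of scope (input is a
labeled map).

## The three protocol comparisons

`runICFComparison()` renders disc-centered (ODC) images of a cohort,
computes the constant ICF from all discs and an individual ICF per eye,
measures every image under both, and emits per-characteristic paired
tests (two-sided paired t for normally distributed differences,
Wilcoxon signed-rank otherwise — the branch chosen by a Shapiro-Wilk
screen at alpha = 0.05, since the choice rule must be made explicit
somewhere) and a Bland-Altman analysis of individual minus constant:
mean difference, sample SD, limits of agreement md +/- 1.96 SD, a
one-sample t-test of the differences against zero, and the slope test
of differences regressed on pairwise means for proportional bias.  The
significance threshold is Bonferroni-corrected, 0.05/12 = 0.0042.

`runCenteringComparison()` renders the same eyes in ODC and MC framing
at equal resolution, measures both with individual ICFs, and excludes
eyes whose zone C annulus is clipped beyond 5% in either view.
`runLateralityComparison()` builds fellow eyes (same disc, same calibers
plus 2 um of independent noise, freshly drawn vessel courses,
horizontally mirrored) and compares right against left under the
constant ICF — a null comparison by construction.

Two properties tie the package to its scientific point.  First, under
the individual ICF the equivalents in microns are invariant to image
resolution (the disc diameter and the vessel widths rescale together),
whereas a constant ICF carried over from differently scaled images
biases them by the full resolution ratio.  Second, the dimensionless
characteristics (AVR, ST, Df) agree between ODC and MC views whenever
zone C is complete in both, while caliber equivalents are the fragile
quantities.  Both are exercised at full study scale (20 and 30 eyes) in
the acceptance tests and recomputed by `scripts/acceptance.R`.

## Numerical choices and edge cases

* Widths use the ridge-corrected distance transform; bands render with
  stamp radius `w/2`, so a 60 px target measures 60 +/- 1 px.
* Zero-variance difference series make the Bland-Altman bias tests
  undefined; the summary is flagged degenerate instead of erroring, and
  an all-zero paired comparison reports p = 1 by convention.
* Box counting is anchored at the pattern bounding box; mirroring or
  reframing realigns the grid, which moves Df by up to ~1% — the reason
  Df tolerances are wider than tortuosity tolerances throughout.
* The measurement-zone reading of the zone definitions (margins at
  0.5-1.0 and 0.5-2.0 disc diameters from the disc *margin*, i.e. radii
  of 1.0-1.5 and 1.0-2.5 diameters from the center) follows the standard
  software convention; the reference disc size (1800 um) is configurable
  since 1850 um is also in use.
* Conversion factors carry full precision internally; two-decimal
  rounding is applied only for display.
* All randomness flows from explicit integer seeds; cohorts derive
  per-eye seeds from one master seed, and rerunning any comparison with
  the same configuration reproduces its CSV outputs byte for byte.

## A worked example

```{r example, eval = FALSE}
eye <- generateEye(seed = 1)
map <- renderView(eye, viewSpec("ODC"))
icf <- individualICF(opticDiscFromMap(map))
computeRVGC(map, icf)
```

Problem sizes used by the test suite and the acceptance script — 20
eyes for the resolution-invariance study, 30 for the centering study,
reduced 300 px discs for unit tests — were chosen as the smallest
cohorts at which the stochastic summaries are stable to well within
their tolerances.
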