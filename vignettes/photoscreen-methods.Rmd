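---
title: "Methods: smartphone photoscreening analysis"
author: "photoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone photoscreening analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoscreen)
```

## The measurement problem

Pediatric vision screening looks for three treatable risk factors:
strabismus (misaligned visual axes), significant refractive error
(typically myopia) and anisometropia (a large refractive difference
between the eyes). Two classic photographic tests expose all three with
nothing but a point flash and a camera:

* **Automated Hirschberg test.** The specular reflection of a point flash
  on the cornea (the corneal luminous reflection, CLR) sits at a position
  that depends on the eye's orientation relative to the flash-camera axis.
  Measuring the offset of the reflection from the limbus center in each eye
  gives the per-eye axial deviation; the between-eye difference is the
  binocular deviation.
* **Photorefraction (red reflex).** With an eccentric flash and a dilated
  pupil, light reflected from the fundus re-emerges through the pupil. A
  focused eye returns it along the incident path (dark pupil); a defocused
  eye spreads it into a bright, usually red, crescent whose side encodes
  the sign of the error (on the flash side: myopia; opposite: hyperopia)
  and whose width grows with its magnitude.

This package implements the full analysis chain for one exam: a flash
still for the Hirschberg measurement, a maximally exposed frame for the
red reflex, a facial-landmark record, and a scale fiducial of known
physical size displayed at the forehead. It also implements a synthetic
scene renderer so that every stage can be validated against exact ground
truth without clinical images.

## From pixel offsets to angles

Let $\Delta x_L, \Delta y_L, \Delta x_R, \Delta y_R$ be the per-eye
offsets (in pixels; x right, y down) of the CLR center relative to the
limbus center, $\alpha$ the frontal-plane scale in mm per pixel, and $d$
the eyeball diameter in mm. The per-eye axial deviations are

$$\theta_{h,L} = \tan^{-1}\!\frac{2\alpha\,\Delta x_L}{d},\qquad
  \theta_{v,L} = \tan^{-1}\!\frac{2\alpha\,\Delta y_L}{d},$$

and likewise for the right eye; the binocular deviations are the
differences $\theta_h = \theta_{h,L} - \theta_{h,R}$ and
$\theta_v = \theta_{v,L} - \theta_{v,R}$. Significantly positive and
negative $\theta_h$ indicate exotropia and esotropia; a significantly
nonzero $\theta_v$ indicates vertical strabismus. The factor 2 reflects
specular-reflection geometry: the reflection moves at half the angular
rate of the axis. The eyeball diameter cannot be measured from a single
photo, so the population average $d = 20$ mm is used; this is a per-exam
configurable constant and its uncertainty (a few percent on $\theta$) is
documented rather than propagated.

Screening-positive rules (all comparisons are "at least", i.e. `>=`):

* strabismus risk: $\max(|\theta_h|, |\theta_v|) \ge 10^\circ$;
* refractive-error risk, per eye: crescent width $\ge 1$ mm (myopic
  direction when the crescent rises on the flash side, hyperopic
  opposite, indeterminate when the pupil is fully lit, since severe
  myopia and hyperopia are then indistinguishable);
* anisometropia risk: unsigned between-eye width difference $\ge 1$ mm.

The 10° rule is applied to each axis via the max of the two binocular
deviations; the combination rule across axes is an open design point and
this choice is deliberately conservative (either axis can trigger).
Anisometropia uses unsigned widths regardless of crescent side;
opposite-side crescents are additionally noted in the result's quality
remarks. Crescent width as a severity proxy is device-specific, so no
diopter estimate is ever produced — width is used only against the
screening thresholds.

## Pipeline stages and their numerical choices

**Processing order.** The Hirschberg still is processed first: its
contracted pupil and strong sclera/iris contrast give the more reliable
limbus estimate, which then constrains the noisier red-reflex frame.

**Closed-eye gate.** From the eyelid landmark contours, openness =
(maximum gap between upper and lower lid, measured perpendicular to the
corner-to-corner axis) / (corner distance). An eye is rejected as closed
when the ratio is strictly below $\eta = 0.25$ ("below the threshold", so
exactly 0.25 passes). Measuring the gap perpendicular to the corner axis
makes the ratio invariant to head tilt and uniform scale.

**Tilt correction.** The image is rotated by minus the recorded head tilt
about the midpoint between the two eye-corner centroids (bilinear
interpolation; zero tilt is an exact crop), and per-eye patches are cut
covering the landmark bounding box padded by 25% of the corner distance
per side — enough margin for the limbus at any plausible eye geometry.
The patch-to-image mapping is recorded and invertible.

**Region of interest.** Skin hue/saturation statistics are estimated from
the outer 10% border frame of the patch (or supplied); pixels matching
both within tolerance (hue ±20°, saturation ±0.2) are background, and the
connected non-skin component containing the patch center is the
sclera-limbus-iris region. Value is deliberately ignored so that shading
does not split the region; dark irides and white sclera both separate
from skin in hue/saturation alone. Colored contact lenses, which defeat
hue-based separation, are a known failure mode and out of scope.

**IsoData threshold.** The sclera/iris boundary intensity is the fixed
point of the intermeans update
$t \leftarrow \mathrm{round}\{(\mu_{\le t} + \mu_{> t})/2\}$, initialized
at the midpoint of the occupied range, with the update clamped so both
classes stay non-empty (guaranteeing termination) and round-half-up as
the tie rule.

**Arc-restricted circle Hough.** Edge points are the boundary pixels of
the sub-threshold (dark) region. Each point votes only for candidate
centers from which the point is seen within ±45° of horizontal — the left
and right limbus arcs — so eyelid-covered top/bottom arcs contribute
nothing. Radii scan [0.15, 0.45] × corner distance in 1 px steps on an
integer center grid; ties break by most votes, then larger radius, then
smaller y, then smaller x. The integer peak is refined by an algebraic
least-squares circle fit to the inlier edge points (within ±2 px of the
peak circle, on the voting arcs), and 0.5 px is added to the radius to
compensate the half-pixel inward bias of boundary pixels. Peak support
below 20 points is a detection failure.

**Photorefraction refinement.** On the red-reflex frame the same-radius
circle (±10% band) is moved within an 8 px window to maximize contour
contrast: mean intensity over the outer annulus [r, 1.15r] minus the
inner annulus [0.85r, r), restricted to the same ±45° arcs, with a
parabolic sub-pixel peak refinement. Non-positive best contrast is a
detection failure.

**CLR spot.** Inside the limbus disk, candidate pixels have minimum
channel value within 2% of the disk maximum (a cluster of maximal
intensity across all channels) and at least 128 (so a frame with no flash
reflection fails loudly rather than promoting iris pixels). The largest
4-connected component wins (size ties: topmost then leftmost centroid)
and is summarised by its largest inscribed circle; plateau ties of the
distance transform resolve to the plateau centroid, giving sub-pixel spot
centers.

**Crescent.** Inside the limbus disk, excluding the CLR component, raw
crescent pixels satisfy (red > green + blue AND brightness >
2 × median disk brightness) OR red saturated, where brightness is
(R+G+B)/3 — the simplest channel-symmetric choice. The median excludes
the CLR pixels. Components under 5 px are discarded. The retained set is
summarised by its minimum-area enclosing ellipse (Khachiyan's algorithm
on the convex hull); the *width* is $\alpha$ × the horizontal extent of
the pixel set, horizontal being the flash-displacement axis. Because a
binary pixel filter quantizes the extent to the pixel pitch, the two
horizontal extremes are localised to sub-pixel precision by the midpoint
crossing of the brightness profile across each edge (falling back to the
integer extent for very thin sets). Whether the
oval's width means its minor axis, major axis or flash-axis extent is
genuinely open, and the flash-axis extent is the choice implemented and
tested. The side is toward-flash when the pixel centroid lies on the
flash side of the limbus center. A retained area of at least 70% of the
limbus disk marks a fully lit pupil; the width is then reported as the
limbus diameter and the refractive direction becomes indeterminate. An
empty retained set is a valid measurement: width 0, side "none".

**Scale fiducial.** A square matrix-code tag of known physical edge
length, displayed on a phone at the forehead, calibrates
$\alpha$ = encoded edge length / detected pixel side length (the mean of
the four sides of the symbol's bounding quadrilateral). The symbol is a
purpose-built synthetic stand-in for a QR code with the same role: a
1-module black border ring, a 1-module white margin and a D×D data grid
carrying a CRC-16-protected JSON payload `{"id", "edge_mm"}`. Decoding
assumes a frontal, axis-aligned tag, consistent with the
held-at-forehead protocol; the module count is recovered by scanning all
plausible counts and letting the CRC reject wrong readings. Payloads that
decode but lack `edge_mm` are rejected explicitly.

## The synthetic scene generator

`eye_scene_spec()` + `render_exam()` render the two-frame exam with exact
ground truth: flat-shaded disks (sclera, iris, pupil) with anti-aliased
edges, a white CLR spot at a controllable offset (8% of the limbus radius),
a red-reflex frame with dilated pupil, dark-red fundus glow and a crescent
drawn as an anti-aliased circular segment of controllable width and side, an
eyelid band clipping the eye to $|dy| \le r\cos\beta$ (so occlusion
half-angle $\beta$ hides exactly the limbus arcs within $\beta$ of
vertical), head tilt as a rigid rotation of the face geometry, an upright
fiducial at the top of the frame, and seeded additive Gaussian noise
clipped to [0, 255].

Palette constraints matter: the crescent color (255, 120, 105) satisfies
red > green + blue with margin, and its brightness (160) exceeds twice
the median limbus-disk brightness (the iris, (40, 52, 70), brightness 54)
by a factor comfortable against noise; partially covered boundary pixels
cross the filter threshold near 50% coverage, keeping the measured extent
within one pixel of truth. Truth condition labels are produced by running
the package's own classifier on the noise-free ground-truth measurements,
so clean end-to-end recovery must be exact by construction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: photorealistic shading and specular texture,
fundus reflectance physics (the crescent is geometric, not optical),
skin-tone variation across the face, motion blur, off-axis perspective of
the fiducial, and detector noise in facial landmarks (synthetic-truth
landmark records are exact).

Validation problem sizes are the package's test protocol: a 10,000-point
grid for the closed form; 1,000 histograms, 100 components and 100 point
sets for the operator oracles; 200 random scenes (plus 50 with 35-40°
eyelid occlusion) for parameter recovery; and 100-examinee cohorts, clean
and at noise sd 8, for end-to-end screening. Random scenes sample the
scale at 10-12 px/mm, the smartphone-at-arm's-length regime
($\alpha \le 0.1$ mm/px): the binary crescent filter quantizes measured
width to the pixel pitch, so coarser sampling cannot resolve the 0.1 mm
recovery tolerance regardless of algorithm.

The cohort generator separates affected and unaffected strata by a margin
around the screening thresholds (strabismic eyes deviate 12-20° versus at
most 1.5° per unaffected eye; refractive-error eyes show 1.3-2.5 mm
crescents versus at most 0.5 mm; anisometropia boosts one eye by 1.5 mm),
so condition labels are stable under measurement noise of a pixel or two.
Conditions interact realistically: the boosted eye of an anisometropic
examinee is usually also myopic by label. Optional blink cases render a
closed-eye first attempt followed by an open retry, mirroring a 1-shot /
2-shot acquisition protocol.

## Known limitations

* The limbus detector presumes a dark iris against white sclera; colored
  contact lenses and low-contrast irides are out of scope.
* Hidden (intermittent/latent) strabismus, which only a cover test
  reveals, is invisible to a single-flash Hirschberg measurement.
* $d = 20$ mm is an assumed constant; per-examinee deviation biases
  $\theta$ proportionally.
* Crescent width is a screening signal, not a diopter estimate.
* The fiducial decoder is frontal and axis-aligned by design; strong
  perspective or rotation of the tag defeats it.
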