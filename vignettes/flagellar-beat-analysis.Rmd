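---
title: "Quantifying the flagellar beat of tethered sperm"
author: "flagbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the flagellar beat of tethered sperm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagbeat)
```

## The measurement problem

Sperm motility responses to second-messenger signalling (cAMP raised by
bicarbonate, or manipulated optogenetically) manifest as changes in two
kinematic quantities of the flagellar beat: the **beat frequency** and the
**local beat asymmetry** along the flagellum. Both are extracted from
high-speed dark-field movies of single sperm whose head is tethered to the
chamber surface, so the flagellum beats in an approximately fixed focal
plane. `flagbeat` implements the full chain from raw movie to these
statistics, together with a synthetic movie generator that makes every
stage testable by parameter recovery.

The pipeline is:

1. **Preprocess** each frame: Gaussian blur (sigma 0.5 px) and
   rolling-ball background subtraction (radius 5 px, i.e. 3.25 um at
   0.65 um/px).
2. **Trace** the flagellar midline at sub-pixel resolution.
3. **Kinematics**: resample each trace onto a fixed arc-length grid and
   compute the signed *curvature angle* field theta(s, t).
4. **Spectral**: per-position FFT of theta(s, .), merged into a
   sperm-level beat frequency.
5. **Asymmetry**: the absolute time-averaged curvature angle per
   position, compared between conditions with a pointwise two-way ANOVA.
6. **Report**: one-beat-cycle waveform projections and CSV/JSON outputs.

`analyze_movie()` runs stages 1-5 and returns a classed fit object with
`print`, `summary`, `coef` and `plot` methods; `run_pipeline()`
orchestrates movie sets and condition comparisons.

## The curvature angle

The central kinematic variable is the curvature angle. At arc-length
position $s$ (measured from the head-side end of the trace) with reference
distance $d$ (default 10 um):

$$\theta(s,t) = \angle\big(\,\overrightarrow{p(s-d)\,p(s)},\;
  \overrightarrow{p(s)\,p(s+d)}\,\big),$$

the signed planar angle between the chord arriving at $s$ and the chord
leaving it, with the sign given by the z-component of their cross product.
Only the reference distance of this quantity is fixed by convention in the
tracing tools this package follows; the chord-to-chord construction is our
reconstruction, chosen because

* it is symmetric in $\pm s$ and robust to pixel noise at a 10 um
  separation,
* on a circular arc of radius $R$ it equals $d/R$ exactly, which provides
  a closed-form oracle (verified to machine precision in the tests), and
* a straight flagellum gives identically zero.

Near the head and the tip the chords are shortened one-sidedly rather
than masking a full reference distance at both ends (switchable via
`kinematics_config(one_sided_ends = FALSE)`); quantitative checks in the
tests therefore evaluate interior positions, $d \le s \le L - d$. Angles
are radians internally and degrees in all exported tables; the
resampling step is 1 um so that the 15-60 um frequency window contains
46 grid points.

A tangent-to-tangent definition over the same distance converges to the
same values for smooth curves; the arc oracle pins our convention.

## Local beat asymmetry

The local beat asymmetry at position $s$ is

$$a(s) = \big|\,\langle \theta(s,t) \rangle_t\,\big|,$$

the absolute time-average of the curvature angle: zero for a perfectly
symmetric beat, growing as the beat becomes biased to one side. Masked
cells are excluded, and positions with fewer than half their frames valid
are masked entirely.

One geometric subtlety matters when *injecting* asymmetry into synthetic
data. A constant offset added to the **tangent angle** merely tilts the
flagellum rigidly and leaves every curvature angle unchanged. To bias the
*curvature angle* by a constant $c$ everywhere -- the quantity $a(s)$
actually measures -- the tangent angle must grow linearly along the
flagellum at rate $c/d$ (a circular-arc bend of radius $d/c$).
`curvature_offset(c)` builds exactly that tangent-offset function, and
with it $a(s) = c$ at all interior positions in closed form: the
traveling-wave part averages out over integer numbers of beat cycles and
the arc contributes $c$ to every chord pair. A 0.2 rad injected offset is
thus recovered as $a(s) \approx 11.46^\circ$, which the acceptance tests
verify through the full image pipeline within 5%.

## The synthetic movie generator

`generate_waveform()` evaluates the tangent-angle model

$$\psi(s,t) = \mathrm{offset}(s) + A(s)\,
  \sin\!\big(2\pi f t - 2\pi s/\lambda\big)$$

on an arc-length grid (0.5 um step) and integrates the unit tangent from
a fixed head point -- the waveform is parameterised in tangent angle, not
transverse displacement, so the curvature-angle ground truth is exact
rather than a small-amplitude approximation. Defaults: length 80 um,
amplitude 0.5 rad, wavelength 60 um, 20 Hz, 200 frames/s, 0.65 um/px --
plausible mouse-sperm scales; they are free parameters, not measured
claims. The head is tethered at a fixed point with no yaw, mirroring
tethered-sperm imaging.

`render_movie()` draws each midline as a bright ridge with Gaussian
cross-section (SD 1.3 px) on a dark background, adds a brighter Gaussian
blob at the head (dark-field images show the head as the brightest
structure; the tracer uses it to orient the midline), and adds seeded
additive Gaussian noise, clamped at zero. Identical seeds give
bit-identical movies. The noise model is additive only -- dark-field
imaging of sperm has high signal-to-noise, so Poisson shot noise is not
emulated -- and the optics are reduced to a Gaussian ridge profile.
Consequently, passing recovery tests demonstrates correctness of the
*algorithms*, not robustness to out-of-focus segments, intensity
variation along the flagellum, debris, or crossing flagella in real
recordings.

## Midline tracing

The tracer reconstructs the standard skeleton-and-refine approach with
every published parameter honoured (`trace_settings()` defaults):

1. tracer-internal blur (sigma 1.0 px), applied sequentially after the
   preprocessing blur (sigma 0.5 px) -- the two blurs are taken as
   successive steps, not alternatives;
2. **triangle threshold** of the 256-bin intensity histogram: the bin
   maximising the perpendicular distance to the line from the histogram
   peak to the farthest non-empty bin, both axes normalised to unit span
   (ties in the peak go to the lowest bin, ties in the farthest bin to
   the highest; a histogram without interior candidates is flagged
   degenerate and the peak bin returned);
3. largest 8-connected component, Zhang-Suen thinning, pruning of side
   branches shorter than 5 px, longest geodesic path through the
   skeleton (a warning is raised if more than two endpoints survive
   pruning);
4. head-end orientation by the tether position if known, otherwise by
   endpoint brightness, falling back to the previous frame's head
   position across a movie;
5. 3-fold spline upscaling of the ordered point list, and extension of
   the tip along the local tangent to the ridge's half-intensity edge
   (the skeleton of a capped band systematically stops short of the true
   end; the intensity edge of a blurred ridge end sits at half height);
6. **Gaussian normal refinement**: the intensity profile along each
   local normal (+/- 5 um, 0.5 px steps, offsets symmetric about zero)
   is fitted by a closed-form log-parabola around its maximum and the
   point moved to the fitted centre; the fitted ridge width is retained.
   Points whose fit fails keep their skeleton position and are flagged;
   the first 10 points are excluded from refinement (the bright head
   blob has no ridge profile to fit) -- this also implements the
   "exclude head from correction" behaviour whose full semantics in the
   original tool are not published;
7. position and fit-width smoothing over +/- 15 neighbours restricted to
   9.6 um, with windows kept symmetric and shrinking at the ends (an
   asymmetric end window would drag the endpoints inward and bias the
   trace length).

Tangents are estimated from chords of up to 14 points, shrunk near the
ends. Coordinates follow image convention: origin at the top-left pixel
centre (1-based), x rightward, y downward; arc length starts at the
head-side first point. Optional steps published as disabled (head
centre-of-mass point, filtering points by fit, repeating the fit after
binarisation) are implemented behind flags and off by default.

On synthetic movies with up to 10% noise the traced midline deviates from
ground truth by about 0.14 px RMS (interior 5-90% of arc length), the
total trace length is stable to under 1% SD across a beating cycle, and a
quarter-circle arc's length is recovered within 0.1%.

## Beat frequency

At every grid position the curvature-angle time course is mean-subtracted
and transformed with a plain FFT over non-overlapping 400-frame windows
(rectangular window, no zero padding, spectra averaged across windows;
400 frames at 200 fps gives 0.5 Hz bins). Masked samples under 5% of a
window are imputed by the window mean, windows with more masking are
skipped. The local beat frequency merges the two dominant peaks,

$$f_{\mathrm{local}} = \tfrac{1}{2}(f_1 + f_2),$$

where $f_1$ is the highest-power bin above DC and $f_2$ the
second-highest **local maximum** of the spectrum. Two guards make $f_2$
meaningful: it must be a local maximum (not a leakage shoulder of
$f_1$), and its power must reach at least 5% of the $f_1$ peak
(`peak_floor`), because in any noisy spectrum *some* local maximum exists
at an arbitrary frequency and merging it in would destroy the estimate on
single-frequency beats. When no qualifying second peak exists, $f_2$
falls back to $f_1$. Both guards are documented, switchable
(`peak_floor = 0` restores the literal two-peak reading), and an optional
harmonic exclusion can drop $f_2 \approx k f_1$; it is off by default so
the merge follows the published formula literally. The sperm-level
frequency is the arithmetic mean of $f_{\mathrm{local}}$ over all valid
positions 15-60 um from the head.

Synthetic movies at 10, 15, 20 and 27 Hz (the physiologically observed
range) are recovered within one FFT bin (+/- 0.5 Hz) in all seeded
replicates of the acceptance suite.

## Condition comparisons

Asymmetry profiles from two conditions are compared in two complementary
ways:

* **difference curve**: per position, the mean and SD of the per-sperm
  difference $a_B(s) - a_A(s)$ (paired by sperm id -- the natural default
  since the same tethered cells are recorded before and after
  stimulation), or the difference of group means with pooled SD when
  unpaired;
* **pointwise ANOVA**: `aov(asym ~ condition * position)` with sperm as
  replicate, followed by the Tukey-adjusted contrast between conditions
  *within each position* (via `emmeans`), giving a pointwise p-value
  curve. Maximal runs of $p < 0.05$ are reported as significant regions,
  each with its minimum member p-value.

The two-way design treats position as a crossed fixed factor; whether the
original analyses treated position as a repeated measure within sperm is
not published, so the design is documented here and the building blocks
(`difference_curve`, `pointwise_anova`) are exposed separately. Adjusting
within the per-position family rather than across all
condition-by-position pairs is deliberate: a global Tukey correction over
~10^4 interaction pairs could never produce per-region p-values of the
magnitude reported for profile data, and would make the pointwise error
rate uninterpretable. Grid positions where a condition has fewer than two
sperm (ragged distal ends) are dropped with a warning; a design in which
*no* position has replication, or one with zero within-cell variance,
raises an explicit error rather than returning NaN p-values. Mixed-effects
models with a per-sperm random effect would be a principled alternative
and are intentionally out of scope.

**Calibration.** `simulate_asymmetry_profiles()` draws per-sperm
curvature-offset functions as a smooth Gaussian process along the
flagellum (white noise convolved with a Gaussian kernel; marginal SD
0.05 rad) plus measurement noise, runs them through the real waveform
and asymmetry code, and feeds the ANOVA. With both groups drawn from the
same distribution the pointwise false-positive fraction is 0.052
(measured over 60 replicates); the 20-replicate calibration check in the
acceptance suite uses a 2 um kernel bandwidth so that the ~80 grid
positions contribute many effectively independent tests and the
20-replicate estimate of that same quantity has a standard error of
about 0.015. The power scenario uses a 15 um bandwidth -- between-sperm
waveform variation in real data is smooth over tens of micrometers --
with a strong curvature offset (0.15 rad) confined to the first 30 um:
the detected significant region covers the proximal flagellum and, at
the frozen seeds, nothing beyond 45 um. Because the pointwise error rate
is 5% by construction, occasional isolated distal regions are expected
in roughly one in twenty replicates of such a scenario; region reporting
deliberately does not suppress single-position runs.

## One-beat-cycle projections

The waveform overlay uses the first $n = \mathrm{round}(\text{frame
rate}/\text{beat frequency})$ traced frames -- exactly one beat cycle --
each drawn in a distinct colour from a perceptually uniform colormap with
a 50 um scale bar. Halves round up (so 12.5 becomes 13), a minimum of 2
frames is enforced, and a beat frequency at or above Nyquist is an
error. At 200 fps: 10 frames for a 20 Hz beat, 7 for 27 Hz.

## Numerical choices and degenerate inputs

* Blur kernels are discrete Gaussians truncated at $\lceil 3\sigma
  \rceil$ and renormalised; boundaries reflect.
* Background subtraction is grayscale opening with a spherical
  structuring element (the surface a ball rolling under the intensity
  landscape traces); its intensity aspect defaults to 0.01 per px, i.e.
  effectively flat, appropriate for the flat background of dark-field
  frames. Output is clamped non-negative.
* A constant frame cannot be thresholded and raises an error, as do
  empty or flat histograms; blank frames and frames with several large
  components raise trace failures that `trace_movie()` logs and skips
  (a movie fails only when every frame fails).
* The log-parabola Gaussian fit uses the 7 samples around the profile
  maximum; fits with non-negative curvature, centres outside the window,
  or non-positive samples are rejected and the point kept unrefined.
* Resampling grids are `seq(0, floor(L/step)*step, step)`: the last grid
  point never exceeds the traced length and the remainder is masked.
* All RNG consumption is wrapped so that a seeded generation never
  disturbs the caller's RNG state.

## Problem sizes

Validation runs use movies of 400 frames (2 s at 200 fps, the standard
spectral window) at 10% noise for frequency and asymmetry recovery, one
10-frame beat cycle for tracing accuracy, 20 simulation replicates with
10 sperm per group for the statistical calibration, and the exhaustive
5-40 Hz x {100, 200} fps grid for the overlay formula; these sizes give
each check a sharp expected value while keeping the suite comfortably
reproducible on a laptop.

## Known limitations

* 2-D tracing only: out-of-plane excursions of a real beat foreshorten
  the projected flagellum and bias curvature angles; no correction is
  attempted.
* One flagellum per movie; no multi-sperm tracking or collision
  handling.
* The published tracing tool's "head rotation matrix radius" and "unify
  start points" options have no published semantics; they are
  implemented as documented approximations (head-point exclusion from
  refinement; per-movie head-end continuity).
* The (f1+f2)/2 merge biases the local frequency towards harmonics when
  a real waveform has strong overtones and harmonic exclusion is off --
  the default follows the published formula, not the statistically
  optimal choice.
* Frequency resolution is fixed by the window (0.5 Hz at 200 fps / 400
  frames); sub-bin peak interpolation is deliberately not performed.
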