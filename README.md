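# flagbeat

Quantitative analysis of the flagellar beat of single tethered sperm from
high-speed dark-field microscopy movies.

Sperm respond to signalling cues (most prominently cAMP, raised by
bicarbonate or manipulated optogenetically) by changing how their
flagellum beats. Two statistics capture these responses and are what this
package computes from raw movie stacks:

- the **beat frequency** of each cell, extracted per flagellar position
  from the curvature-angle time course by Fourier analysis, and
- the **local beat asymmetry** along the flagellum, which reveals where a
  stimulus bends the average waveform.

The package covers the whole chain — frame preprocessing, sub-pixel
midline tracing, curvature-angle kinematics, spectral analysis, asymmetry
statistics with condition comparisons, and one-beat-cycle waveform
projections — plus a synthetic traveling-wave flagellum simulator so that
every stage is validated by parameter recovery against known ground truth.

## The statistics

A traced midline is resampled on a fixed arc-length grid (1 µm). At
position *s* with reference distance *d* = 10 µm, the **curvature angle**
is the signed planar angle between successive chords,

θ(s, t) = ∠( p(s−d)→p(s), p(s)→p(s+d) ),

zero on a straight flagellum and d/R on a circular arc of radius R. From
the field θ(s, t):

- **local beat frequency** f_local(s) = (f₁ + f₂)/2, where f₁ and f₂ are
  the two dominant peaks of the power spectrum of θ(s, ·) over 400-frame
  windows; the **sperm-level frequency** is the mean of f_local over
  15–60 µm from the head;
- **local beat asymmetry** a(s) = | ⟨θ(s, t)⟩_t |, the absolute
  time-averaged curvature angle — zero for a perfectly symmetric beat;
- condition differences Δa(s) are plotted as mean ± SD across sperm with
  pointwise two-way ANOVA / Tukey p-values and contiguous significant
  regions (p < 0.05);
- the **one-beat-cycle projection** overlays the first
  round(frame rate / beat frequency) traces in distinct colours.

## Worked example

Simulate a sperm beating at 20 Hz with a 0.1 rad curvature-angle bias,
render it as a noisy dark-field movie, and analyse it:

```r
library(flagbeat)

p     <- waveform_params(beat_freq_hz = 20, n_frames = 400, noise_sd = 0.1,
                         asym_offset = curvature_offset(0.1), seed = 1)
truth <- generate_waveform(p)
movie <- render_movie(truth)
movie
#> Sperm movie: 400 frames of 101 x 145 px @ 200 fps, 0.65 um/px

fit <- analyze_movie(movie)
fit
#> Flagellar beat analysis
#>   400/400 frames traced @ 200 fps, 0.65 um/px
#>   beat frequency: 20.00 Hz (mean local f over 15-60 um)
#>   mean |asymmetry|: 5.32 deg; one beat cycle = 10 frames

coef(fit)
#>  beat_freq_hz mean_asym_deg
#>     20.000000      5.319963

trace_error_px(fit$trace, truth, movie)$rms_px
#> [1] 0.16
```

The injected 20 Hz beat is recovered exactly (it falls on an FFT bin);
the 0.1 rad ≈ 5.73° curvature offset appears as a mean asymmetry of
5.32° through the full image pipeline; and the traced midline deviates
from the known ground truth by 0.16 px RMS. `plot(fit)` shows the
curvature kymograph, the frequency and asymmetry profiles and the
one-beat-cycle overlay; `summary(fit)` prints per-window detail.

Groups of cells and before/after comparisons run through
`run_pipeline()` with a YAML config (see `?run_config`), or from a shell
via the thin CLI in `inst/cli/flagbeat` (subcommands `simulate`,
`trace`, `analyze`, `compare`, `project`, `run-all`).

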