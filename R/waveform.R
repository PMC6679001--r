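#' Parameters of a synthetic traveling-wave flagellum
#'
#' Bundles everything needed to synthesize a beating flagellum: a traveling
#' bending wave described in tangent angle,
#' \deqn{\psi(s,t) = \mathrm{offset}(s) + A(s)\,
#'   \sin(2\pi f t - 2\pi s/\lambda),}
#' sampled at `frame_rate_hz` for `n_frames` frames, plus the rendering
#' geometry (pixel size) and noise level used by [render_movie()].
#'
#' The head is tethered at a fixed point, as for tethered-sperm dark-field
#' imaging; the midline follows by integrating the unit tangent from the
#' head. Defaults are plausible mouse-sperm scales: an 80 um flagellum
#' carrying a 60 um wave of 0.5 rad tangent amplitude, beating at 20 Hz,
#' imaged at 200 frames/s and 0.65 um/px.
#'
#' @param length_um Flagellum length in micrometers.
#' @param beat_freq_hz Fundamental beat frequency (Hz); must be below the
#'   Nyquist frequency `frame_rate_hz / 2`.
#' @param amp_envelope Tangent-angle amplitude \eqn{A(s)} in radians: a
#'   function of arc length (um) or a single number for a constant envelope.
#' @param asym_offset Static tangent-angle offset (rad) as a function of arc
#'   length or a single number. Its time-average survives in \eqn{\psi} over
#'   integer numbers of beat cycles. Use [curvature_offset()] to inject a
#'   constant *curvature-angle* offset instead.
#' @param wavelength_um Spatial wavelength of the traveling wave (um).
#' @param frame_rate_hz Sampling rate (Hz).
#' @param n_frames Number of frames (at least 2).
#' @param pixel_size_um Micrometers per pixel.
#' @param noise_sd Additive Gaussian intensity noise SD, as a fraction of the
#'   ridge peak amplitude (which is 1 in rendered units).
#' @param seed RNG seed for rendering noise; identical seeds give
#'   bit-identical movies. `NULL` leaves the caller's RNG state untouched.
#' @param ds_um Arc-length discretisation step of the ground truth (um);
#'   consecutive midline points are at most this far apart.
#' @return An object of class `waveform_params`.
#' @seealso [generate_waveform()], [render_movie()], [curvature_offset()]
#' @export
waveform_params <- function(length_um = 80, beat_freq_hz = 20,
                            amp_envelope = 0.5, asym_offset = 0,
                            wavelength_um = 60, frame_rate_hz = 200,
                            n_frames = 400, pixel_size_um = 0.65,
                            noise_sd = 0.05, seed = NULL, ds_um = 0.5) {
  stopifnot_scalar_pos(length_um, "length_um")
  stopifnot_scalar_pos(beat_freq_hz, "beat_freq_hz")
  stopifnot_scalar_pos(wavelength_um, "wavelength_um")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(ds_um, "ds_um")
  if (ds_um > 1.5)
    stop("`ds_um` must be <= 1.5 so consecutive midline points stay close")
  if (beat_freq_hz >= frame_rate_hz / 2)
    stop("Nyquist violation: beat_freq_hz must be below frame_rate_hz / 2")
  if (!is.numeric(n_frames) || length(n_frames) != 1 || n_frames < 2)
    stop("`n_frames` must be at least 2")
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1))
    stop("`seed` must be a single number or NULL")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be non-negative")
  structure(list(
    length_um = length_um, beat_freq_hz = beat_freq_hz,
    amp_envelope = as_envelope(amp_envelope, "amp_envelope"),
    asym_offset = as_envelope(asym_offset, "asym_offset"),
    wavelength_um = wavelength_um, frame_rate_hz = frame_rate_hz,
    n_frames = as.integer(n_frames), pixel_size_um = pixel_size_um,
    noise_sd = noise_sd, seed = seed, ds_um = ds_um
  ), class = "waveform_params")
}

#' @export
print.waveform_params <- function(x, ...) {
  cat("Synthetic flagellar waveform parameters\n")
  cat(sprintf("  length %g um, beat %g Hz, wavelength %g um\n",
              x$length_um, x$beat_freq_hz, x$wavelength_um))
  cat(sprintf("  %d frames @ %g fps, %g um/px, noise sd %g\n",
              x$n_frames, x$frame_rate_hz, x$pixel_size_um, x$noise_sd))
  invisible(x)
}

#' Tangent-angle offset producing a constant curvature-angle bias
#'
#' The local beat asymmetry is the absolute time-averaged *curvature angle*,
#' i.e. the angle between midline chords separated by the reference distance
#' `d_ref_um`. A constant tangent-angle offset tilts the flagellum rigidly
#' and leaves every curvature angle unchanged; to bias the curvature angle
#' by a constant `theta_rad` at every position, the tangent angle must grow
#' linearly along the flagellum (a circular-arc bend of radius
#' `d_ref_um / theta_rad`). This helper returns that tangent-offset function
#' for use as `asym_offset` in [waveform_params()].
#'
#' @param theta_rad Target time-averaged curvature angle (rad) at interior
#'   positions; may also be a function of arc length, in which case the
#'   tangent offset is its integral divided by `d_ref_um`.
#' @param d_ref_um Curvature-angle reference distance (um); 10 um by default.
#' @return A function of arc length (um) returning tangent-angle offsets (rad).
#' @examples
#' p <- waveform_params(asym_offset = curvature_offset(0.2), n_frames = 40)
#' @export
curvature_offset <- function(theta_rad, d_ref_um = 10) {
  stopifnot_scalar_pos(d_ref_um, "d_ref_um")
  if (is.numeric(theta_rad) && length(theta_rad) == 1) {
    force(theta_rad)
    return(function(s) theta_rad * s / d_ref_um)
  }
  if (is.function(theta_rad)) {
    fine <- seq(0, 500, by = 0.1)
    phi <- cumtrapz_uniform(theta_rad(fine), 0.1) / d_ref_um
    f <- approxfun(fine, phi, rule = 2)
    return(f)
  }
  stop("`theta_rad` must be a single number or a function of arc length")
}

#' Generate the ground-truth kinematics of a synthetic beating flagellum
#'
#' Evaluates the traveling-wave tangent-angle model of [waveform_params()] on
#' an arc-length x time grid and integrates the unit tangent from the fixed
#' head point to obtain per-frame midlines. Alongside the tangent-angle field
#' it reports the nominal curvature-angle field (chord-to-chord angles at the
#' reference distance, computed from the analytic midline) and the nominal
#' asymmetry profile, so downstream estimates can be checked by parameter
#' recovery.
#'
#' @param params A [waveform_params()] object.
#' @param ref_distance_um Reference distance (um) for the nominal
#'   curvature-angle field; matches the tracer's default of 10 um.
#' @return An object of class `flagellar_truth`: arc grid `s_um`, time grid
#'   `t_s`, tangent angles `psi` (rad, positions x frames), midline
#'   coordinates `x_um`/`y_um` (positions x frames, head at the origin, y
#'   pointing down as in image coordinates), nominal curvature angles
#'   `theta_nom` (rad) with validity mask `theta_valid`, nominal asymmetry
#'   profile `asym_nominal_rad`, and the generating `params`.
#' @export
generate_waveform <- function(params, ref_distance_um = 10) {
  if (!inherits(params, "waveform_params"))
    stop("`params` must come from waveform_params()")
  s <- seq(0, params$length_um, by = params$ds_um)
  t <- (seq_len(params$n_frames) - 1) / params$frame_rate_hz
  off <- params$asym_offset(s)
  amp <- params$amp_envelope(s)
  if (length(off) != length(s) || length(amp) != length(s))
    stop("envelope functions must be vectorised over arc length")
  phase <- outer(-2 * pi * s / params$wavelength_um,
                 2 * pi * params$beat_freq_hz * t, `+`)
  psi <- off + amp * sin(phase)
  x <- apply(cos(psi), 2, cumtrapz_uniform, h = params$ds_um)
  y <- apply(sin(psi), 2, cumtrapz_uniform, h = params$ds_um)
  th <- chord_theta_matrix(x, y, params$ds_um, ref_distance_um)
  structure(list(
    s_um = s, t_s = t, psi = psi, x_um = x, y_um = y,
    theta_nom = th$theta, theta_valid = th$valid,
    asym_nominal_rad = abs(rowMeans(th$theta, na.rm = TRUE)),
    ref_distance_um = ref_distance_um, params = params
  ), class = "flagellar_truth")
}

#' @export
print.flagellar_truth <- function(x, ...) {
  cat(sprintf(
    "Ground-truth flagellar waveform: %d frames, %d arc points (%g um)\n",
    ncol(x$psi), nrow(x$psi), max(x$s_um)))
  cat(sprintf("  beat %g Hz @ %g fps; nominal asymmetry %.3f-%.3f deg\n",
              x$params$beat_freq_hz, x$params$frame_rate_hz,
              min(rad2deg(x$asym_nominal_rad), na.rm = TRUE),
              max(rad2deg(x$asym_nominal_rad), na.rm = TRUE)))
  invisible(x)
}

#' Ground-truth curvature field of a synthetic waveform
#'
#' Packs the nominal curvature-angle field of a [generate_waveform()] result
#' into the same container produced by [build_field()], so spectral and
#' asymmetry analyses can run directly on noise-free ground truth.
#'
#' @param truth A `flagellar_truth` object.
#' @return A `curvature_field` object (angles in radians internally).
#' @export
as_curvature_field <- function(truth) {
  if (!inherits(truth, "flagellar_truth"))
    stop("`truth` must come from generate_waveform()")
  new_curvature_field(
    theta = truth$theta_nom, valid = truth$theta_valid,
    s_um = truth$s_um, t_s = truth$t_s,
    frame_rate_hz = truth$params$frame_rate_hz,
    ref_distance_um = truth$ref_distance_um
  )
}

#' Write ground-truth midlines to CSV
#'
#' Long-format export of a `flagellar_truth` object with columns
#' `frame`, `point_index`, `x_um`, `y_um`, `arclen_um`, `tangent_angle_rad`.
#'
#' @param truth A `flagellar_truth` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (!inherits(truth, "flagellar_truth"))
    stop("`truth` must come from generate_waveform()")
  n_s <- nrow(truth$psi)
  n_t <- ncol(truth$psi)
  df <- data.frame(
    frame = rep(seq_len(n_t), each = n_s),
    point_index = rep(seq_len(n_s), times = n_t),
    x_um = as.vector(truth$x_um),
    y_um = as.vector(truth$y_um),
    arclen_um = rep(truth$s_um, times = n_t),
    tangent_angle_rad = as.vector(truth$psi)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
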