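# Shared fixture builders: everything is generated in code at test time.

# Small, fast default movie: 40 frames (= 4 cycles at 20 Hz, 200 fps).
tiny_params <- function(...) {
  args <- list(n_frames = 40, noise_sd = 0.05, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(waveform_params, args)
}

tiny_movie <- function(params = tiny_params()) {
  render_movie(generate_waveform(params))
}

# Analytic circular-arc trace frame on a uniform arc grid (no imaging).
arc_frame <- function(radius_um, length_um = 80, step_um = 1) {
  s <- seq(0, length_um, by = step_um)
  data.frame(x_um = radius_um * sin(s / radius_um),
             y_um = radius_um * (1 - cos(s / radius_um)),
             arclen_um = s)
}

# Wrap per-frame data frames into a flagellar_trace object.
as_trace <- function(frames, pixel_size_um = 0.65, frame_rate_hz = 200) {
  structure(list(frames = frames, failed = integer(0),
                 pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz,
                 origin_px = c(x = 0, y = 0), settings = NULL),
            class = "flagellar_trace")
}

# Curvature field with prescribed theta matrix (radians).
field_from_matrix <- function(theta, s_um = seq_len(nrow(theta)) - 1,
                              frame_rate_hz = 200, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(theta), ncol(theta))
  flagbeat:::new_curvature_field(
    theta = theta, valid = valid, s_um = s_um,
    t_s = (seq_len(ncol(theta)) - 1) / frame_rate_hz,
    frame_rate_hz = frame_rate_hz, ref_distance_um = 10)
}
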