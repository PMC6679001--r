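#' Number of frames spanning one beat cycle
#'
#' One beat cycle at beat frequency f recorded at frame rate r spans
#' r / f frames; the overlay uses the nearest integer (ties round up).
#'
#' @param frame_rate_hz Recording rate (Hz).
#' @param beat_freq_hz Beat frequency (Hz); must be positive and below
#'   half the frame rate.
#' @return Integer frame count, at least 2.
#' @export
beat_cycle_frames <- function(frame_rate_hz, beat_freq_hz) {
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  if (!is.numeric(beat_freq_hz) || beat_freq_hz <= 0)
    stop("`beat_freq_hz` must be positive")
  if (beat_freq_hz >= frame_rate_hz / 2)
    stop("beat frequency at or above Nyquist: no beat cycle resolvable")
  n <- floor(frame_rate_hz / beat_freq_hz + 0.5)
  as.integer(max(2, n))
}

#' One-beat-cycle waveform projection
#'
#' Selects the first n = round(frame rate / beat frequency) traced frames
#' -- exactly one beat cycle -- and assigns each a distinct colour from a
#' perceptually uniform colormap, producing the familiar colour-coded
#' waveform overlay with a 50 um scale bar.
#'
#' @param trace A `flagellar_trace` (or a `beat_analysis`, whose trace and
#'   estimated frequency are used).
#' @param sperm_freq_hz Sperm-level beat frequency (Hz).
#' @param frame_rate_hz Recording rate (Hz); defaults to the trace's.
#' @param palette Colormap name passed to [grDevices::hcl.colors()].
#' @return An object of class `beat_cycle_projection`: the selected
#'   `traces`, their `frame_idx` (each source frame used exactly once),
#'   `colors`, `n_overlay_frames` and the 50 um scale bar length.
#' @export
beat_cycle_projection <- function(trace, sperm_freq_hz,
                                  frame_rate_hz = trace$frame_rate_hz,
                                  palette = "viridis") {
  if (inherits(trace, "beat_analysis")) {
    if (missing(sperm_freq_hz)) sperm_freq_hz <- trace$sperm_freq_hz
    frame_rate_hz <- trace$frame_rate_hz
    trace <- trace$trace
  }
  if (!inherits(trace, "flagellar_trace"))
    stop("`trace` must be a flagellar_trace or beat_analysis")
  n <- beat_cycle_frames(frame_rate_hz, sperm_freq_hz)
  if (n > length(trace$frames))
    stop(sprintf("one beat cycle needs %d frames but the movie has %d",
                 n, length(trace$frames)))
  idx <- seq_len(n)
  structure(list(traces = trace$frames[idx], frame_idx = idx,
                 colors = hcl.colors(n, palette),
                 n_overlay_frames = n, scale_bar_um = 50,
                 pixel_size_um = trace$pixel_size_um),
            class = "beat_cycle_projection")
}

#' @export
print.beat_cycle_projection <- function(x, ...) {
  cat(sprintf("One-beat-cycle projection: %d frames, scale bar %g um\n",
              x$n_overlay_frames, x$scale_bar_um))
  invisible(x)
}

#' @export
plot.beat_cycle_projection <- function(x, ...) {
  xs <- unlist(lapply(x$traces, function(f) if (is.null(f)) NULL else f$x_um))
  ys <- unlist(lapply(x$traces, function(f) if (is.null(f)) NULL else f$y_um))
  plot(NA, xlim = range(xs), ylim = rev(range(ys)), asp = 1,
       xlab = "x (um)", ylab = "y (um)", axes = FALSE, ...)
  for (i in seq_along(x$traces)) {
    f <- x$traces[[i]]
    if (!is.null(f)) lines(f$x_um, f$y_um, col = x$colors[i], lwd = 2)
  }
  x0 <- min(xs)
  y0 <- max(ys)
  segments(x0, y0, x0 + x$scale_bar_um, y0, lwd = 3)
  text(x0 + x$scale_bar_um / 2, y0, labels = sprintf("%g um", x$scale_bar_um),
       pos = 3, cex = 0.8)
  invisible(x)
}
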