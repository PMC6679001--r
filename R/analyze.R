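#' Analyse the flagellar beat of one movie
#'
#' The main estimator: traces the flagellum in every frame, builds the
#' curvature-angle field on a fixed arc-length grid, extracts per-position
#' beat frequencies by Fourier analysis and merges them into the
#' sperm-level beat frequency, and computes the local beat-asymmetry
#' profile.
#'
#' @param movie A `sperm_movie` (from [read_movie()] or [render_movie()]).
#' @param settings A [trace_settings()] object.
#' @param config A [kinematics_config()] object.
#' @param fft_window FFT window length in frames.
#' @param s_range Arc-length window (um) for the sperm-level frequency.
#' @param sperm_id,condition Labels propagated to the asymmetry profile.
#' @param allow_short Allow movies shorter than `fft_window`.
#' @return An object of class `beat_analysis` with components `trace`
#'   (`flagellar_trace`), `field` (`curvature_field`), `frequency`
#'   (`frequency_profile`), `asymmetry` (`asymmetry_profile`),
#'   `sperm_freq_hz`, `n_overlay_frames` and the acquisition metadata.
#'   Supported methods: `print`, `summary`, `coef` (beat frequency and
#'   mean asymmetry), `plot`.
#' @examples
#' p <- waveform_params(beat_freq_hz = 20, n_frames = 40, noise_sd = 0.02,
#'                      seed = 1)
#' movie <- render_movie(generate_waveform(p))
#' fit <- analyze_movie(movie, fft_window = 40)
#' coef(fit)
#' @export
analyze_movie <- function(movie, settings = trace_settings(),
                          config = kinematics_config(), fft_window = 400,
                          s_range = c(15, 60), sperm_id = NA_character_,
                          condition = NA_character_, allow_short = FALSE) {
  trace <- trace_movie(movie, settings)
  field <- build_field(trace, config)
  freq <- frequency_profile(field, window = fft_window,
                            allow_short = allow_short)
  f_sperm <- sperm_frequency(freq, s_range)
  asym <- asymmetry_profile(field, sperm_id = sperm_id,
                            condition = condition)
  structure(list(trace = trace, field = field, frequency = freq,
                 asymmetry = asym, sperm_freq_hz = f_sperm,
                 n_overlay_frames = beat_cycle_frames(movie$frame_rate_hz,
                                                      f_sperm),
                 frame_rate_hz = movie$frame_rate_hz,
                 pixel_size_um = movie$pixel_size_um,
                 sperm_id = sperm_id, condition = condition,
                 settings = settings, config = config,
                 s_range = s_range),
            class = "beat_analysis")
}

#' @export
print.beat_analysis <- function(x, ...) {
  ok <- !vapply(x$trace$frames, is.null, logical(1))
  cat("Flagellar beat analysis\n")
  cat(sprintf("  %d/%d frames traced @ %g fps, %g um/px\n",
              sum(ok), length(ok), x$frame_rate_hz, x$pixel_size_um))
  cat(sprintf("  beat frequency: %.2f Hz (mean local f over %g-%g um)\n",
              x$sperm_freq_hz, x$s_range[1], x$s_range[2]))
  cat(sprintf("  mean |asymmetry|: %.2f deg; one beat cycle = %d frames\n",
              mean(x$asymmetry$asym_deg, na.rm = TRUE),
              x$n_overlay_frames))
  invisible(x)
}

#' @export
summary.beat_analysis <- function(object, ...) {
  f <- object$frequency
  sel <- f$s_um >= object$s_range[1] & f$s_um <= object$s_range[2] &
    is.finite(f$f_local_hz)
  out <- list(
    sperm_freq_hz = object$sperm_freq_hz,
    f_local_range_hz = range(f$f_local_hz[sel]),
    n_positions = sum(sel),
    asym_quartiles_deg = quantile(object$asymmetry$asym_deg,
                                  c(0.25, 0.5, 0.75), na.rm = TRUE),
    traced_frames = sum(!vapply(object$trace$frames, is.null, logical(1))),
    n_frames = length(object$trace$frames),
    n_overlay_frames = object$n_overlay_frames)
  class(out) <- "summary.beat_analysis"
  out
}

#' @export
print.summary.beat_analysis <- function(x, ...) {
  cat(sprintf("Beat frequency: %.2f Hz (local f %.2f-%.2f Hz, %d positions)\n",
              x$sperm_freq_hz, x$f_local_range_hz[1], x$f_local_range_hz[2],
              x$n_positions))
  cat(sprintf("Asymmetry quartiles: %.2f / %.2f / %.2f deg\n",
              x$asym_quartiles_deg[1], x$asym_quartiles_deg[2],
              x$asym_quartiles_deg[3]))
  cat(sprintf("Traced %d/%d frames; one beat cycle = %d frames\n",
              x$traced_frames, x$n_frames, x$n_overlay_frames))
  invisible(x)
}

#' @export
coef.beat_analysis <- function(object, ...) {
  c(beat_freq_hz = object$sperm_freq_hz,
    mean_asym_deg = mean(object$asymmetry$asym_deg, na.rm = TRUE))
}

#' @export
plot.beat_analysis <- function(x, which = c("kymograph", "frequency",
                                            "asymmetry", "projection"),
                               ...) {
  which <- match.arg(which, several.ok = TRUE)
  if (length(which) > 1) {
    old <- par(mfrow = c(ceiling(length(which) / 2), 2))
    on.exit(par(old))
  }
  conv <- 180 / pi
  if ("kymograph" %in% which) {
    th <- x$field$theta * conv
    th[!x$field$valid] <- NA
    image(x$field$t_s, x$field$s_um, t(th),
          xlab = "time (s)", ylab = "arc length (um)",
          main = "curvature angle (deg)",
          col = hcl.colors(64, "Blue-Red 2"))
  }
  if ("frequency" %in% which) {
    plot(x$frequency$s_um, x$frequency$f_local_hz, type = "l",
         xlab = "arc length (um)", ylab = "local beat frequency (Hz)",
         main = sprintf("sperm frequency %.1f Hz", x$sperm_freq_hz))
    abline(v = x$s_range, lty = 3)
    abline(h = x$sperm_freq_hz, col = "darkred")
  }
  if ("asymmetry" %in% which) {
    plot(x$asymmetry$s_um, x$asymmetry$asym_deg, type = "l",
         xlab = "arc length (um)", ylab = "|mean curvature angle| (deg)",
         main = "local beat asymmetry")
  }
  if ("projection" %in% which) {
    plot(beat_cycle_projection(x), main = "one beat cycle")
  }
  invisible(x)
}
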