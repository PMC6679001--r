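#' One-sided power spectrum of a curvature-angle time course
#'
#' Splits the series into consecutive non-overlapping windows of
#' `window` frames (the first `floor(n / window)` windows), subtracts each
#' window's mean, applies a plain FFT (rectangular window, no zero
#' padding) and averages the one-sided power spectra. Frequency resolution
#' is `frame_rate_hz / window`. Masked samples (NA) are imputed by the
#' window mean when they make up less than `max_masked` of the window;
#' windows with more masking are skipped.
#'
#' @param series Numeric vector, theta(s, .) at one position (any angle
#'   unit; peak frequencies are amplitude-scale invariant).
#' @param frame_rate_hz Sampling rate (Hz).
#' @param window Window length in frames (default 400).
#' @param max_masked Maximum tolerated masked fraction per window.
#' @param allow_short If the series is shorter than `window`, use the whole
#'   series as a single window instead of failing.
#' @return A list with `freq` (Hz, from 0 to Nyquist), `power` (mean over
#'   windows), and `n_windows` actually used; `NULL` when every window was
#'   skipped.
#' @export
power_spectrum <- function(series, frame_rate_hz, window = 400,
                           max_masked = 0.05, allow_short = FALSE) {
  n <- length(series)
  if (n < window) {
    if (!allow_short)
      stop(sprintf(paste0(
        "series of %d frames is shorter than the %d-frame window; ",
        "reduce `window` or set allow_short = TRUE"), n, window))
    window <- n
  }
  n_win <- n %/% window
  spectra <- list()
  for (w in seq_len(n_win)) {
    seg <- series[((w - 1) * window + 1):(w * window)]
    bad <- !is.finite(seg)
    if (mean(bad) > max_masked) next
    if (any(bad)) seg[bad] <- mean(seg[!bad])
    seg <- seg - mean(seg)
    p <- Mod(fft(seg))^2 / window
    spectra[[length(spectra) + 1]] <- p[seq_len(window %/% 2 + 1)]
  }
  if (length(spectra) == 0) return(NULL)
  power <- Reduce(`+`, spectra) / length(spectra)
  freq <- (seq_along(power) - 1) * frame_rate_hz / window
  list(freq = freq, power = power, n_windows = length(spectra))
}

#' Merge the two dominant spectral peaks into a local beat frequency
#'
#' f1 is the frequency of the highest-power bin above 0 Hz; f2 the
#' frequency of the second-highest *local maximum* whose power reaches at
#' least `peak_floor` times the f1 power (so shoulders of f1 and
#' noise-floor wiggles do not qualify); when no such second peak exists,
#' f2 falls back to f1. The merged local beat frequency is (f1 + f2) / 2
#' exactly. Mean subtraction upstream guarantees f1 never reports the DC
#' bin.
#'
#' @param spectrum A list with `freq` and `power`, from [power_spectrum()].
#' @param peak_floor Minimum power of a candidate f2 peak, relative to the
#'   f1 peak; 0 accepts any local maximum.
#' @param exclude_harmonics Drop candidate f2 peaks lying within half a
#'   frequency bin of an integer multiple of f1.
#' @return A list with `f1_hz`, `f2_hz`, `f_local_hz`; all `NA` for an
#'   all-zero spectrum (masked position).
#' @export
local_frequency <- function(spectrum, peak_floor = 0.05,
                            exclude_harmonics = FALSE) {
  na <- list(f1_hz = NA_real_, f2_hz = NA_real_, f_local_hz = NA_real_)
  if (is.null(spectrum)) return(na)
  pos <- spectrum$freq > 0
  f <- spectrum$freq[pos]
  p <- spectrum$power[pos]
  if (all(p <= 0)) return(na)
  i1 <- which.max(p)
  n <- length(p)
  left <- c(-Inf, p[-n])
  right <- c(p[-1], -Inf)
  is_peak <- p > left & p >= right
  cand <- which(is_peak & seq_len(n) != i1 & p >= peak_floor * p[i1])
  if (exclude_harmonics && length(cand) > 0) {
    db <- f[2] - f[1]
    harm <- abs(f[cand] / f[i1] - round(f[cand] / f[i1])) * f[i1] < db / 2
    cand <- cand[!harm]
  }
  f1 <- f[i1]
  f2 <- if (length(cand) == 0) f1 else f[cand[which.max(p[cand])]]
  list(f1_hz = f1, f2_hz = f2, f_local_hz = (f1 + f2) / 2)
}

#' Per-position beat frequencies of a curvature field
#'
#' Applies [power_spectrum()] and [local_frequency()] to the
#' curvature-angle time course at every arc-length position.
#'
#' @param field A `curvature_field`.
#' @param window FFT window length in frames.
#' @param peak_floor,exclude_harmonics Passed to [local_frequency()].
#' @param allow_short Passed to [power_spectrum()].
#' @return An object of class `frequency_profile`: a data frame with
#'   `s_um`, `f1_hz`, `f2_hz`, `f_local_hz`, `n_windows` (NA rows are
#'   masked positions), carrying the frame rate and window as attributes.
#' @export
frequency_profile <- function(field, window = 400, peak_floor = 0.05,
                              exclude_harmonics = FALSE, allow_short = FALSE) {
  if (!inherits(field, "curvature_field"))
    stop("`field` must be a curvature_field")
  rows <- lapply(seq_len(nrow(field$theta)), function(i) {
    series <- field$theta[i, ]
    series[!field$valid[i, ]] <- NA_real_
    sp <- tryCatch(
      power_spectrum(series, field$frame_rate_hz, window,
                     allow_short = allow_short),
      error = function(e) stop(e))
    lf <- local_frequency(sp, peak_floor, exclude_harmonics)
    data.frame(s_um = field$s_um[i], f1_hz = lf$f1_hz, f2_hz = lf$f2_hz,
               f_local_hz = lf$f_local_hz,
               n_windows = if (is.null(sp)) 0L else sp$n_windows)
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_rate_hz") <- field$frame_rate_hz
  attr(out, "window") <- window
  class(out) <- c("frequency_profile", "data.frame")
  out
}

#' Sperm-level beat frequency
#'
#' The beat frequency of a sperm cell is the arithmetic mean of the local
#' beat frequency over all valid flagellar positions inside a fixed
#' arc-length window, 15-60 um from the head by default (the proximal
#' principal piece, where tracing is most reliable).
#'
#' @param profile A `frequency_profile`, or a data frame with `s_um` and
#'   `f_local_hz`.
#' @param s_range Closed arc-length interval (um) to average over.
#' @return The sperm-level beat frequency (Hz).
#' @export
sperm_frequency <- function(profile, s_range = c(15, 60)) {
  sel <- profile$s_um >= s_range[1] & profile$s_um <= s_range[2] &
    is.finite(profile$f_local_hz)
  if (!any(sel))
    stop(sprintf("no valid positions in [%g, %g] um", s_range[1], s_range[2]))
  mean(profile$f_local_hz[sel])
}
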