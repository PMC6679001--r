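#' Tracing settings
#'
#' All tunable parameters of preprocessing and midline tracing, with the
#' defaults used for tethered mouse sperm at 200 fps and 0.65 um/px:
#' a pre-blur of sigma 0.5 px, rolling-ball background subtraction with a
#' 5 px radius, triangle thresholding, a tracer-internal blur of sigma
#' 1.0 px, 3-fold spline upscaling of the skeleton point list, Gaussian
#' ridge fits along local normals within +/- 5 um, tangent chords of up to
#' 14 points, and position/width smoothing over +/- 15 neighbours within
#' 9.6 um.
#'
#' @param gauss_sigma_px Pre-blur Gaussian SD in px.
#' @param bg_radius_px Rolling-ball radius in px.
#' @param threshold_method Thresholding method; only `"triangle"` is
#'   implemented.
#' @param tracer_sigma_px Tracer-internal Gaussian SD in px, applied after
#'   preprocessing and before thresholding (sequential with the pre-blur).
#' @param upscale_fold Spline upscaling factor for the skeleton point list.
#' @param normal_radius_um Half-length (um) of the intensity profile sampled
#'   along each local normal for the Gaussian centre fit.
#' @param max_vector_len_points Maximum chord length (points) used to
#'   estimate local tangents; shrunk near the ends.
#' @param smoothing_window_points Half-window (points) for position and
#'   fit-width smoothing.
#' @param smoothing_distance_um Maximum accepted arc distance (um) of
#'   neighbours entering the smoothing window.
#' @param head_ref_distance_um Distance (um) from the first point used to
#'   form the head reference vector.
#' @param exclude_head_points Number of head-side points excluded from
#'   Gaussian refinement (kept at their skeleton positions and flagged).
#' @param min_branch_px Side branches of the skeleton shorter than this are
#'   pruned (the traced midline is the longest skeleton path).
#' @param add_head_com Prepend the head centre of mass as first point
#'   (disabled by default).
#' @param filter_points_by_fit Drop points whose Gaussian fit failed instead
#'   of keeping them unrefined (disabled by default).
#' @param repeat_fit_after_binarization Run a second refinement pass
#'   (disabled by default).
#' @return An object of class `trace_settings`.
#' @export
trace_settings <- function(gauss_sigma_px = 0.5, bg_radius_px = 5,
                           threshold_method = "triangle",
                           tracer_sigma_px = 1.0, upscale_fold = 3,
                           normal_radius_um = 5.0,
                           max_vector_len_points = 14,
                           smoothing_window_points = 15,
                           smoothing_distance_um = 9.6,
                           head_ref_distance_um = 10.0,
                           exclude_head_points = 10, min_branch_px = 5,
                           add_head_com = FALSE, filter_points_by_fit = FALSE,
                           repeat_fit_after_binarization = FALSE) {
  num <- list(gauss_sigma_px = gauss_sigma_px, bg_radius_px = bg_radius_px,
              tracer_sigma_px = tracer_sigma_px, upscale_fold = upscale_fold,
              normal_radius_um = normal_radius_um,
              max_vector_len_points = max_vector_len_points,
              smoothing_window_points = smoothing_window_points,
              smoothing_distance_um = smoothing_distance_um,
              head_ref_distance_um = head_ref_distance_um,
              min_branch_px = min_branch_px)
  for (nm in names(num)) stopifnot_scalar_pos(num[[nm]], nm)
  threshold_method <- match.arg(threshold_method, "triangle")
  structure(c(num, list(threshold_method = threshold_method,
                        exclude_head_points = as.integer(exclude_head_points),
                        add_head_com = isTRUE(add_head_com),
                        filter_points_by_fit = isTRUE(filter_points_by_fit),
                        repeat_fit_after_binarization =
                          isTRUE(repeat_fit_after_binarization))),
            class = "trace_settings")
}

#' @export
print.trace_settings <- function(x, ...) {
  cat("Flagellar tracing settings\n")
  for (nm in names(x)) cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Gaussian blur of a single frame
#'
#' Separable discrete Gaussian convolution with kernel
#' \eqn{k_i \propto \exp(-i^2 / 2\sigma^2)}, \eqn{i = -r, \ldots, r},
#' \eqn{r = \max(1, \lceil 3\sigma \rceil)}, normalised to unit sum;
#' reflecting boundary.
#'
#' @param img Numeric matrix (one grayscale frame).
#' @param sigma_px Gaussian SD in pixels; 0 returns the input unchanged.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma_px) {
  if (!is.matrix(img)) stop("`img` must be a 2-D matrix")
  cpp_gauss_blur(img, sigma_px)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the frame with a
#' spherical structuring element of the given radius (the surface traced by
#' a ball rolling under the intensity landscape) and subtracts it. `aspect`
#' sets the ball height in intensity units per pixel of geometric height;
#' small values make the ball effectively flat, which is appropriate for
#' the flat dark background of dark-field recordings. Output is
#' non-negative.
#'
#' @param img Numeric matrix.
#' @param radius_px Ball radius in pixels.
#' @param aspect Intensity units per pixel of ball height.
#' @return Background-subtracted matrix, clamped at zero.
#' @export
subtract_background <- function(img, radius_px, aspect = 0.01) {
  if (!is.matrix(img)) stop("`img` must be a 2-D matrix")
  stopifnot_scalar_pos(radius_px, "radius_px")
  cpp_rolling_ball(img, radius_px, aspect)
}

#' Preprocess one movie frame
#'
#' Gaussian pre-blur followed by rolling-ball background subtraction,
#' the standard preparation of dark-field frames before tracing.
#'
#' @param frame Numeric matrix (2-D grayscale frame).
#' @param settings A [trace_settings()] object.
#' @return Preprocessed non-negative matrix.
#' @export
preprocess_frame <- function(frame, settings = trace_settings()) {
  if (!is.matrix(frame))
    stop("`frame` must be a 2-D matrix (got something else)")
  out <- gaussian_blur(frame, settings$gauss_sigma_px)
  subtract_background(out, settings$bg_radius_px)
}

#' Triangle threshold of an intensity histogram
#'
#' Draws the straight line from the histogram peak to the farthest non-empty
#' bin and returns the bin maximising the perpendicular distance between the
#' histogram curve and that line (axes normalised to unit span). Intended
#' for histograms dominated by a single background peak, as in dark-field
#' images where most pixels are background.
#'
#' @param counts Non-negative counts per intensity bin.
#' @param mids Optional bin centres (defaults to bin indices); the returned
#'   threshold is expressed on this scale.
#' @return A list with `threshold` (bin centre), `bin` (index into
#'   `counts`), and `degenerate` (`TRUE` when no interior candidate exists,
#'   e.g. a two-bin histogram, in which case the peak bin is returned).
#' @export
triangle_threshold <- function(counts, mids = NULL) {
  if (length(counts) == 0 || all(counts == 0))
    stop("empty histogram: no non-zero bins")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  if (is.null(mids)) mids <- seq_along(counts)
  nz <- which(counts > 0)
  if (length(unique(counts[nz])) == 1 && length(nz) == length(counts))
    stop("flat histogram: threshold undefined (degenerate)")
  peak <- which.max(counts)
  far_cand <- nz[abs(nz - peak) == max(abs(nz - peak))]
  far <- far_cand[length(far_cand)]
  lo <- min(peak, far)
  hi <- max(peak, far)
  if (hi - lo < 2) {
    return(list(threshold = mids[peak], bin = peak, degenerate = TRUE))
  }
  idx <- (lo + 1):(hi - 1)
  # normalised coordinates: bins and counts both scaled to [0, 1]; the
  # line runs from the peak (0, 1) to the farthest non-empty bin (1, v2)
  u <- (idx - peak) / (far - peak)
  v <- counts[idx] / counts[peak]
  v2 <- counts[far] / counts[peak]
  d <- abs(u * (v2 - 1) - (v - 1)) / sqrt(1 + (v2 - 1)^2)
  best <- idx[which.max(d)]
  list(threshold = mids[best], bin = best, degenerate = FALSE)
}

# Triangle threshold of an image via a 256-bin histogram.
frame_threshold <- function(img, n_bins = 256) {
  rng <- range(img)
  if (diff(rng) <= 0) stop("constant frame: nothing to threshold")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- hist(as.vector(img), breaks = breaks, plot = FALSE)
  tt <- triangle_threshold(h$counts, h$mids)
  tt$threshold
}
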