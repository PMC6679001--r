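#' Render a synthetic flagellum as a dark-field-like movie
#'
#' Draws each ground-truth midline as a bright ridge with Gaussian
#' cross-section on a dark background, optionally adds a brighter head blob
#' at the tether point (dark-field images show the head as the brightest
#' structure, which the tracer uses to orient the midline), and adds seeded
#' Gaussian intensity noise. Intensities are clamped at zero; the ridge peak
#' amplitude defines intensity unit 1.
#'
#' @param truth A `flagellar_truth` from [generate_waveform()].
#' @param params The [waveform_params()] used to generate `truth` (supplies
#'   pixel size, noise SD and seed). Defaults to `truth$params`.
#' @param ridge_sigma_px SD (px) of the Gaussian ridge cross-section.
#' @param ridge_amp Peak ridge intensity (arbitrary units).
#' @param render_head Draw a bright Gaussian blob at the tethered head.
#' @param head_amp,head_sigma_px Peak intensity and SD of the head blob.
#' @param margin_px Dark margin around the bounding box of all midlines.
#' @param frame_dim Optional `c(height, width)` in px; if the midlines (plus
#'   margin) do not fit, rendering fails naming the offending frame.
#' @param clamp Clamp intensities at zero (default). Disable to inspect the
#'   raw additive noise model.
#' @return An object of class `sperm_movie`: `frames` (height x width x
#'   n_frames array), `frame_rate_hz`, `pixel_size_um`, `origin_px` (um ->
#'   px offset such that `x_px = x_um / pixel_size_um + origin_px[1]`),
#'   `head_px`, and `meta` with the scalar generation parameters.
#' @export
render_movie <- function(truth, params = truth$params, ridge_sigma_px = 1.3,
                         ridge_amp = 1, render_head = TRUE, head_amp = 1.5,
                         head_sigma_px = 2, margin_px = 10, frame_dim = NULL,
                         clamp = TRUE) {
  if (!inherits(truth, "flagellar_truth"))
    stop("`truth` must come from generate_waveform()")
  psz <- params$pixel_size_um
  xp <- truth$x_um / psz
  yp <- truth$y_um / psz
  pad <- margin_px + ceiling(4 * max(ridge_sigma_px, head_sigma_px))
  x0 <- pad + 1 - min(xp)
  y0 <- pad + 1 - min(yp)
  if (is.null(frame_dim)) {
    H <- ceiling(max(yp) + y0 + pad)
    W <- ceiling(max(xp) + x0 + pad)
  } else {
    H <- frame_dim[1]
    W <- frame_dim[2]
    for (k in seq_len(ncol(xp))) {
      if (max(xp[, k]) + x0 + pad > W || max(yp[, k]) + y0 + pad > H)
        stop(sprintf("frame %d: midline does not fit a %dx%d frame", k, H, W))
    }
  }
  n_t <- ncol(xp)
  frames <- array(0, dim = c(H, W, n_t))
  with_seed(params$seed, {
    for (k in seq_len(n_t)) {
      img <- cpp_render_ridge(xp[, k] + x0, yp[, k] + y0, H, W,
                              ridge_sigma_px, ridge_amp)
      if (render_head) {
        blob <- cpp_render_ridge(rep(xp[1, k] + x0, 2), rep(yp[1, k] + y0, 2),
                                 H, W, head_sigma_px, head_amp)
        img <- pmax(img, blob)
      }
      if (params$noise_sd > 0)
        img <- img + matrix(rnorm(H * W, sd = params$noise_sd), H, W)
      frames[, , k] <- if (clamp) pmax(img, 0) else img
    }
  })
  structure(list(
    frames = frames, frame_rate_hz = params$frame_rate_hz,
    pixel_size_um = psz, origin_px = c(x = x0, y = y0),
    head_px = c(x = xp[1, 1] + x0, y = yp[1, 1] + y0),
    meta = list(length_um = params$length_um,
                beat_freq_hz = params$beat_freq_hz,
                wavelength_um = params$wavelength_um,
                noise_sd = params$noise_sd, seed = params$seed,
                ridge_sigma_px = ridge_sigma_px, ridge_amp = ridge_amp)
  ), class = "sperm_movie")
}

#' Construct a movie object from a raw frame stack
#'
#' @param frames Numeric array (height x width x n_frames) or a list of
#'   matrices of equal size.
#' @param frame_rate_hz Acquisition rate (Hz).
#' @param pixel_size_um Micrometers per pixel.
#' @return A `sperm_movie` object.
#' @export
sperm_movie <- function(frames, frame_rate_hz, pixel_size_um) {
  if (is.list(frames))
    frames <- array(unlist(frames),
                    dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                            length(frames)))
  if (length(dim(frames)) != 3)
    stop("`frames` must be a height x width x n_frames array")
  stopifnot_scalar_pos(frame_rate_hz, "frame_rate_hz")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, origin_px = c(x = 0, y = 0),
                 head_px = NULL, meta = list()),
            class = "sperm_movie")
}

#' @export
print.sperm_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Sperm movie: %d frames of %d x %d px @ %g fps, %g um/px\n",
              d[3], d[1], d[2], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' Write a movie as multi-page 16-bit TIFF with a metadata sidecar
#'
#' Intensities are scaled to the 16-bit range by the stack maximum; the
#' scale, frame rate, pixel size and generation metadata go to a YAML
#' sidecar (`<path>.yml`) so that [read_movie()] restores physical units.
#'
#' @param movie A `sperm_movie`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  if (!inherits(movie, "sperm_movie")) stop("`movie` must be a sperm_movie")
  scale <- max(movie$frames, 1e-12)
  pages <- lapply(seq_len(dim(movie$frames)[3]),
                  function(k) movie$frames[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(frame_rate_hz = movie$frame_rate_hz,
               pixel_size_um = movie$pixel_size_um,
               intensity_scale = scale,
               origin_px = as.list(movie$origin_px),
               head_px = if (is.null(movie$head_px)) NULL
                         else as.list(movie$head_px),
               meta = movie$meta)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a movie from a multi-page TIFF
#'
#' If a `<path>.yml` sidecar written by [write_movie()] exists, frame rate,
#' pixel size and the intensity scale are restored from it; otherwise both
#' acquisition parameters must be supplied.
#'
#' @param path TIFF path.
#' @param frame_rate_hz,pixel_size_um Acquisition parameters; override or
#'   replace sidecar values.
#' @return A `sperm_movie`.
#' @export
read_movie <- function(path, frame_rate_hz = NULL, pixel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("movie file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  fr <- frame_rate_hz %||% meta$frame_rate_hz
  ps <- pixel_size_um %||% meta$pixel_size_um
  if (is.null(fr) || is.null(ps))
    stop("frame_rate_hz and pixel_size_um required (no sidecar found)")
  scale <- meta$intensity_scale %||% 1
  frames <- array(unlist(pages) * scale,
                  dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  m <- sperm_movie(frames, fr, ps)
  if (!is.null(meta$origin_px)) m$origin_px <- unlist(meta$origin_px)
  if (!is.null(meta$head_px)) m$head_px <- unlist(meta$head_px)
  m$meta <- meta$meta %||% list()
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
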