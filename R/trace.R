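#' Trace the flagellar midline in a preprocessed frame
#'
#' Binarises the frame at the triangle threshold (after the tracer-internal
#' blur), keeps the largest connected component, thins it to a one-pixel
#' skeleton, extracts the longest skeleton path (which prunes side
#' branches), orients it head-to-tip, and upscales the ordered point list by
#' spline interpolation. The head end is the endpoint nearer `head_hint_px`
#' when given, otherwise the endpoint with the brighter surroundings (the
#' head is the brightest structure in dark-field images).
#'
#' @param preprocessed Preprocessed frame from [preprocess_frame()].
#' @param settings A [trace_settings()] object.
#' @param head_hint_px Optional `c(x, y)` pixel position of the tethered
#'   head used to orient the trace.
#' @return A data frame with ordered sub-pixel columns `x_px`, `y_px`
#'   (head first).
#' @export
trace_midline <- function(preprocessed, settings = trace_settings(),
                          head_hint_px = NULL) {
  if (!is.matrix(preprocessed)) stop("`preprocessed` must be a 2-D matrix")
  img <- gaussian_blur(preprocessed, settings$tracer_sigma_px)
  thr <- tryCatch(frame_threshold(img),
                  error = function(e)
                    stop("trace failure: ", conditionMessage(e)))
  bin <- matrix(as.integer(img > thr), nrow(img), ncol(img))
  if (sum(bin) < 10)
    stop("trace failure: no flagellum-like component above threshold")
  lab <- cpp_label_components(bin)
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sum(sizes >= 0.5 * sizes[big]) > 1)
    stop("trace failure: multiple large components above threshold")
  mask <- matrix(as.integer(lab == big), nrow(lab), ncol(lab))
  skel <- cpp_prune_spurs(cpp_thin(mask), settings$min_branch_px)
  path <- cpp_longest_path(skel)
  if (nrow(path) < max(5, settings$min_branch_px))
    stop("trace failure: skeleton too short to be a flagellum")
  n_end <- cpp_count_endpoints(skel)
  if (n_end > 2)
    warning(sprintf(
      "skeleton retains %d endpoints after pruning; longest path taken",
      n_end))
  x <- as.numeric(path[, 2])
  y <- as.numeric(path[, 1])
  ends <- rbind(c(x[1], y[1]), c(x[length(x)], y[length(y)]))
  if (!is.null(head_hint_px)) {
    d <- sqrt((ends[, 1] - head_hint_px[1])^2 + (ends[, 2] - head_hint_px[2])^2)
    if (d[2] < d[1]) {
      x <- rev(x)
      y <- rev(y)
    }
  } else {
    br <- vapply(1:2, function(k)
      local_brightness(preprocessed, ends[k, 1], ends[k, 2], 4), numeric(1))
    if (br[2] > br[1]) {
      x <- rev(x)
      y <- rev(y)
    }
  }
  x <- runmean_shrink(x, 2)
  y <- runmean_shrink(y, 2)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  keep <- c(TRUE, diff(s) > 0)
  x <- x[keep]; y <- y[keep]; s <- s[keep]
  n_out <- length(x) * settings$upscale_fold
  s_out <- seq(0, s[length(s)], length.out = n_out)
  fx <- splinefun(s, x, method = "natural")
  fy <- splinefun(s, y, method = "natural")
  data.frame(x_px = fx(s_out), y_px = fy(s_out))
}

local_brightness <- function(img, x, y, r) {
  jj <- max(1, round(x - r)):min(ncol(img), round(x + r))
  ii <- max(1, round(y - r)):min(nrow(img), round(y + r))
  mean(img[ii, jj])
}

# Moving average with half-window k. Windows stay symmetric and shrink
# towards the ends (an asymmetric window would drag the endpoints inward
# and systematically shorten the trace).
runmean_shrink <- function(x, k) {
  n <- length(x)
  if (k < 1 || n < 3) return(x)
  i <- seq_len(n)
  h <- pmin(k, i - 1, n - i)
  cs <- c(0, cumsum(x))
  (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
}

# Extend the traced point list beyond the skeleton tip along the local
# tangent while the ridge intensity stays above half the local ridge level
# (the intensity edge of a blurred ridge end sits at about half height).
# Only the tip end is extended; the head end terminates in the bright head.
extend_tip <- function(x, y, img, spacing, max_px = 6) {
  n <- length(x)
  if (n < 12) return(list(x = x, y = y, added = 0L))
  tx <- x[n] - x[n - 9]
  ty <- y[n] - y[n - 9]
  tl <- sqrt(tx^2 + ty^2)
  if (tl == 0) return(list(x = x, y = y, added = 0L))
  tx <- tx / tl
  ty <- ty / tl
  i_ref <- stats::median(cpp_bilinear(img, x[(n - 9):n], y[(n - 9):n]))
  step <- 0.25
  u <- seq(step, max_px, by = step)
  px <- x[n] + u * tx
  py <- y[n] + u * ty
  inten <- cpp_bilinear(img, px, py)
  below <- which(inten < 0.5 * i_ref)
  reach <- if (length(below) == 0) max_px else u[below[1]] - step
  if (reach < spacing) return(list(x = x, y = y, added = 0L))
  u_new <- seq(spacing, reach, by = spacing)
  list(x = c(x, x[n] + u_new * tx), y = c(y, y[n] + u_new * ty),
       added = length(u_new))
}

#' Refine traced points by Gaussian ridge fits along local normals
#'
#' For every ordered point, samples the image intensity along the local
#' normal within +/- `normal_radius_um`, fits a 1-D Gaussian to the profile
#' (closed-form parabola on the log intensities around the profile maximum)
#' and moves the point to the fitted centre. Positions and fitted ridge
#' widths are then smoothed over +/- `smoothing_window_points` neighbours
#' restricted to `smoothing_distance_um`. The first `exclude_head_points`
#' points are excluded from refinement (the bright head blob has no ridge
#' profile) and flagged.
#'
#' Quality flags: 0 = refined, 1 = Gaussian fit failed (point kept at its
#' skeleton position), 2 = head-excluded.
#'
#' @param points Data frame with `x_px`, `y_px` from [trace_midline()].
#' @param image The image the ridge centre is fitted on (typically the
#'   preprocessed frame after the tracer-internal blur).
#' @param settings A [trace_settings()] object.
#' @param pixel_size_um Micrometers per pixel.
#' @return One trace frame: data frame with `x_px`, `y_px`, `x_um`, `y_um`,
#'   `arclen_um`, `fit_width_um`, `quality`.
#' @export
refine_normals <- function(points, image, settings = trace_settings(),
                           pixel_size_um) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  n <- nrow(points)
  if (n < 5) stop("too few points to refine")
  x <- points$x_px
  y <- points$y_px
  h <- max(1, floor(settings$max_vector_len_points / 2))
  i_hi <- pmin(n, seq_len(n) + h)
  i_lo <- pmax(1, seq_len(n) - h)
  tx <- x[i_hi] - x[i_lo]
  ty <- y[i_hi] - y[i_lo]
  tl <- sqrt(tx^2 + ty^2)
  tl[tl == 0] <- 1
  nx <- -ty / tl
  ny <- tx / tl
  r_px <- settings$normal_radius_um / pixel_size_um
  step <- 0.5
  # offsets must be symmetric about zero or the profile fit is biased
  offs <- (-floor(r_px / step):floor(r_px / step)) * step
  m <- length(offs)
  Xs <- outer(x, rep(1, m)) + outer(nx, offs)
  Ys <- outer(y, rep(1, m)) + outer(ny, offs)
  prof <- matrix(cpp_bilinear(image, as.vector(Xs), as.vector(Ys)), n, m)
  base <- apply(prof, 1, min)
  w <- prof - base
  jmax <- max.col(w, ties.method = "first")
  half <- 3L
  ok <- jmax > half & jmax <= m - half
  # common design matrix for the log-parabola fit around the profile peak
  xr <- (-half:half) * step
  D <- cbind(1, xr, xr^2)
  Pinv <- solve(crossprod(D), t(D))
  centre <- rep(NA_real_, n)
  width <- rep(NA_real_, n)
  for (i in which(ok)) {
    wi <- w[i, (jmax[i] - half):(jmax[i] + half)]
    if (any(wi <= 0)) next
    cf <- Pinv %*% log(wi)
    a <- cf[3]
    if (!is.finite(a) || a >= 0) next
    delta <- -cf[2] / (2 * a)
    if (abs(delta) > half * step) next
    centre[i] <- offs[jmax[i]] + delta
    width[i] <- sqrt(-1 / (2 * a))
  }
  quality <- ifelse(is.na(centre), 1L, 0L)
  head_idx <- seq_len(min(n, settings$exclude_head_points))
  quality[head_idx] <- 2L
  centre[head_idx] <- NA_real_
  use <- !is.na(centre)
  xr2 <- x
  yr2 <- y
  xr2[use] <- x[use] + centre[use] * nx[use]
  yr2[use] <- y[use] + centre[use] * ny[use]
  if (settings$filter_points_by_fit) {
    keep <- quality != 1L
    xr2 <- xr2[keep]; yr2 <- yr2[keep]
    width <- width[keep]; quality <- quality[keep]
    n <- length(xr2)
  }
  spacing_um <- mean(sqrt(diff(xr2)^2 + diff(yr2)^2)) * pixel_size_um
  k_dist <- if (spacing_um > 0)
    floor(settings$smoothing_distance_um / spacing_um) else n
  k <- max(1, min(settings$smoothing_window_points, k_dist))
  xs <- runmean_shrink(xr2, k)
  ys <- runmean_shrink(yr2, k)
  width_s <- smooth_na(width, k)
  arclen <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2))) * pixel_size_um
  data.frame(x_px = xs, y_px = ys,
             x_um = (xs - 1) * pixel_size_um, y_um = (ys - 1) * pixel_size_um,
             arclen_um = arclen, fit_width_um = width_s * pixel_size_um,
             quality = quality)
}

# Moving average ignoring NAs (used for fit widths with failed fits).
smooth_na <- function(x, k) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- max(1, i - k):min(n, i + k)
    v <- x[idx]
    if (any(!is.na(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Trace one raw frame end to end
#'
#' Convenience wrapper: [preprocess_frame()], [trace_midline()] and
#' [refine_normals()] in sequence.
#'
#' @inheritParams trace_midline
#' @param frame Raw grayscale frame (matrix).
#' @param pixel_size_um Micrometers per pixel.
#' @return A trace frame data frame (see [refine_normals()]).
#' @export
trace_frame <- function(frame, settings = trace_settings(), pixel_size_um,
                        head_hint_px = NULL) {
  pre <- preprocess_frame(frame, settings)
  pts <- trace_midline(pre, settings, head_hint_px = head_hint_px)
  fit_img <- gaussian_blur(pre, settings$tracer_sigma_px)
  spacing <- mean(sqrt(diff(pts$x_px)^2 + diff(pts$y_px)^2))
  ext <- extend_tip(pts$x_px, pts$y_px, fit_img, spacing)
  pts <- data.frame(x_px = ext$x, y_px = ext$y)
  refine_normals(pts, fit_img, settings, pixel_size_um)
}

#' Trace every frame of a movie
#'
#' Runs the per-frame tracing pipeline over a whole movie. The head end is
#' oriented by the movie's stored tether position when available, falling
#' back to the previous frame's head position (the head of a tethered sperm
#' is stationary). Frames whose trace fails are recorded and skipped.
#'
#' @param movie A `sperm_movie`.
#' @param settings A [trace_settings()] object.
#' @param head_hint_px Optional `c(x, y)` tether position in pixels;
#'   defaults to the movie's metadata when present.
#' @return An object of class `flagellar_trace`: per-frame data frames (see
#'   [refine_normals()]; `NULL` for failed frames), the indices of `failed`
#'   frames, and acquisition metadata.
#' @export
trace_movie <- function(movie, settings = trace_settings(),
                        head_hint_px = movie$head_px) {
  if (!inherits(movie, "sperm_movie")) stop("`movie` must be a sperm_movie")
  n_t <- dim(movie$frames)[3]
  frames <- vector("list", n_t)
  failed <- integer(0)
  hint <- head_hint_px
  for (k in seq_len(n_t)) {
    res <- tryCatch(
      trace_frame(movie$frames[, , k], settings, movie$pixel_size_um,
                  head_hint_px = hint),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, k)
    } else {
      frames[[k]] <- res
      if (is.null(head_hint_px)) hint <- c(res$x_px[1], res$y_px[1])
    }
  }
  if (length(failed) == n_t)
    stop("tracing failed in every frame of the movie")
  if (length(failed) > 0)
    warning(sprintf("tracing failed in %d/%d frames (e.g. frame %d)",
                    length(failed), n_t, failed[1]))
  structure(list(frames = frames, failed = failed,
                 pixel_size_um = movie$pixel_size_um,
                 frame_rate_hz = movie$frame_rate_hz,
                 origin_px = movie$origin_px, settings = settings),
            class = "flagellar_trace")
}

#' @export
print.flagellar_trace <- function(x, ...) {
  ok <- !vapply(x$frames, is.null, logical(1))
  len <- vapply(x$frames[ok], function(f) max(f$arclen_um), numeric(1))
  cat(sprintf("Flagellar trace: %d/%d frames traced, length %.1f +/- %.1f um\n",
              sum(ok), length(x$frames), mean(len), sd(len)))
  invisible(x)
}

#' Midline tracing error against a synthetic ground truth
#'
#' Distance of traced points to the true midline polyline, pooled over
#' frames, restricted to an interior arc-length band (the skeleton endpoint
#' and the head blob make the extreme ends unreliable in any tracer).
#'
#' @param trace A `flagellar_trace` from [trace_movie()].
#' @param truth The `flagellar_truth` the movie was rendered from.
#' @param movie The rendered `sperm_movie` (provides the um -> px mapping).
#' @param arc_range Fractions of the traced arc length to evaluate.
#' @return A list with `rms_px`, `max_px` and the per-frame RMS `per_frame`.
#' @export
trace_error_px <- function(trace, truth, movie, arc_range = c(0.05, 0.90)) {
  psz <- movie$pixel_size_um
  per_frame <- rep(NA_real_, length(trace$frames))
  all_d <- numeric(0)
  for (k in seq_along(trace$frames)) {
    f <- trace$frames[[k]]
    if (is.null(f)) next
    vx <- truth$x_um[, k] / psz + movie$origin_px[1]
    vy <- truth$y_um[, k] / psz + movie$origin_px[2]
    L <- max(f$arclen_um)
    sel <- f$arclen_um >= arc_range[1] * L & f$arclen_um <= arc_range[2] * L
    d <- cpp_dist_to_polyline(f$x_px[sel], f$y_px[sel], vx, vy)
    per_frame[k] <- sqrt(mean(d^2))
    all_d <- c(all_d, d)
  }
  list(rms_px = sqrt(mean(all_d^2)), max_px = max(all_d),
       per_frame = per_frame)
}

#' Write / read a flagellar trace as CSV
#'
#' Long format with columns `frame`, `point_index`, `x_um`, `y_um`,
#' `arclen_um`, `fit_width_um`, `quality_flag`. Values are written with full
#' double precision so a written trace reads back exactly.
#'
#' @param trace A `flagellar_trace`.
#' @param path CSV path.
#' @return `path` invisibly for the writer; a `flagellar_trace` for the
#'   reader.
#' @export
write_trace <- function(trace, path) {
  rows <- lapply(seq_along(trace$frames), function(k) {
    f <- trace$frames[[k]]
    if (is.null(f)) return(NULL)
    data.frame(frame = k, point_index = seq_len(nrow(f)),
               x_um = fmt17(f$x_um), y_um = fmt17(f$y_um),
               arclen_um = fmt17(f$arclen_um),
               fit_width_um = fmt17(f$fit_width_um),
               quality_flag = f$quality)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' @rdname write_trace
#' @param pixel_size_um,frame_rate_hz Acquisition metadata to attach on read.
#' @export
read_trace <- function(path, pixel_size_um = NA, frame_rate_hz = NA) {
  df <- read.csv(path)
  ids <- sort(unique(df$frame))
  frames <- vector("list", max(ids))
  for (k in ids) {
    sub <- df[df$frame == k, ]
    sub <- sub[order(sub$point_index), ]
    frames[[k]] <- data.frame(
      x_px = sub$x_um / pixel_size_um + 1, y_px = sub$y_um / pixel_size_um + 1,
      x_um = sub$x_um, y_um = sub$y_um, arclen_um = sub$arclen_um,
      fit_width_um = sub$fit_width_um, quality = sub$quality_flag)
  }
  structure(list(frames = frames, failed = setdiff(seq_len(max(ids)), ids),
                 pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz,
                 origin_px = c(x = 0, y = 0), settings = NULL),
            class = "flagellar_trace")
}
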