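#' Kinematics configuration
#'
#' Parameters converting traces into the curvature-angle field: the
#' curvature reference distance (the arc-length separation of the two
#' chords whose signed angle is the curvature angle), the head reference
#' distance, the resampling step of the fixed arc-length grid, and the
#' angle unit used on output (angles are radians internally).
#'
#' @param curvature_ref_distance_um Chord separation (um) of the curvature
#'   angle.
#' @param head_ref_distance_um Distance (um) defining the head reference
#'   vector.
#' @param arclen_step_um Arc-length resampling step (um); must be at most
#'   `curvature_ref_distance_um / 5` so chords span several grid points.
#' @param angle_unit `"degrees"` (default) or `"radians"` for exported
#'   tables.
#' @param one_sided_ends Keep positions near head and tip using shortened
#'   one-sided chords (default) instead of masking a full reference
#'   distance at both ends.
#' @return An object of class `kinematics_config`.
#' @export
kinematics_config <- function(curvature_ref_distance_um = 10.0,
                              head_ref_distance_um = 10.0,
                              arclen_step_um = 1.0,
                              angle_unit = c("degrees", "radians"),
                              one_sided_ends = TRUE) {
  stopifnot_scalar_pos(curvature_ref_distance_um, "curvature_ref_distance_um")
  stopifnot_scalar_pos(head_ref_distance_um, "head_ref_distance_um")
  stopifnot_scalar_pos(arclen_step_um, "arclen_step_um")
  if (arclen_step_um > curvature_ref_distance_um / 5)
    stop("arclen_step_um must be <= curvature_ref_distance_um / 5")
  structure(list(curvature_ref_distance_um = curvature_ref_distance_um,
                 head_ref_distance_um = head_ref_distance_um,
                 arclen_step_um = arclen_step_um,
                 angle_unit = match.arg(angle_unit),
                 one_sided_ends = isTRUE(one_sided_ends)),
            class = "kinematics_config")
}

# Signed chord-to-chord curvature angles on a uniform arc-length grid.
# theta(s) = angle between the chord s -> s+d and the chord s-d -> s,
# sign from the z-component of their cross product; chords are shortened
# one-sidedly at the ends (or masked when one_sided = FALSE).
chord_theta <- function(x, y, step, d_ref, one_sided = TRUE) {
  n <- length(x)
  theta <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  if (n < 3 || (n - 1) * step < d_ref)
    return(list(theta = theta, valid = valid))
  k <- max(1L, as.integer(round(d_ref / step)))
  i <- seq_len(n)
  j2 <- pmin(n, i + k)
  j1 <- pmax(1L, i - k)
  v1x <- x[j2] - x
  v1y <- y[j2] - y
  v2x <- x - x[j1]
  v2y <- y - y[j1]
  th <- atan2(v2x * v1y - v2y * v1x, v2x * v1x + v2y * v1y)
  ok <- j2 > i & j1 < i
  if (!one_sided) ok <- ok & (i + k <= n) & (i - k >= 1)
  theta[ok] <- th[ok]
  list(theta = theta, valid = ok)
}

chord_theta_matrix <- function(x, y, step, d_ref, one_sided = TRUE) {
  n_t <- ncol(x)
  theta <- matrix(NA_real_, nrow(x), n_t)
  valid <- matrix(FALSE, nrow(x), n_t)
  for (k in seq_len(n_t)) {
    ct <- chord_theta(x[, k], y[, k], step, d_ref, one_sided)
    theta[, k] <- ct$theta
    valid[, k] <- ct$valid
  }
  list(theta = theta, valid = valid)
}

#' Resample a trace onto a fixed arc-length grid
#'
#' Cubic-spline interpolation of x(s) and y(s) at s = 0, step, 2 step, ...;
#' the grid is identical across frames so positions are comparable over
#' time. Grid points beyond a frame's traced length are absent from that
#' frame (they are masked in the assembled field).
#'
#' @param trace A `flagellar_trace`, or a single trace frame data frame.
#' @param config A [kinematics_config()].
#' @return The same structure with frames resampled (columns `x_um`,
#'   `y_um`, `arclen_um`).
#' @export
resample_arclength <- function(trace, config = kinematics_config()) {
  if (is.data.frame(trace)) return(resample_frame(trace, config))
  trace$frames <- lapply(trace$frames, function(f) {
    if (is.null(f)) NULL else resample_frame(f, config)
  })
  trace
}

resample_frame <- function(f, config) {
  if (nrow(f) < 2) stop("trace frame has fewer than 2 points")
  s <- f$arclen_um
  if (any(diff(s) <= 0)) stop("arc length must be strictly increasing")
  L <- max(s)
  grid <- seq(0, floor(L / config$arclen_step_um) * config$arclen_step_um,
              by = config$arclen_step_um)
  fx <- splinefun(s, f$x_um, method = "natural")
  fy <- splinefun(s, f$y_um, method = "natural")
  data.frame(x_um = fx(grid), y_um = fy(grid), arclen_um = grid)
}

#' Curvature angles of one resampled trace frame
#'
#' The curvature angle at arc-length position s is the signed planar angle
#' between the chord from s to s + d and the chord from s - d to s, with
#' d the reference distance; its sign follows the z-component of the cross
#' product of the two chords. On a circular arc of radius R this equals
#' d / R; on a straight line it is zero. Chords are shortened one-sidedly
#' near head and tip (configurable).
#'
#' @param frame A resampled trace frame (from [resample_arclength()]).
#' @param config A [kinematics_config()].
#' @return A list with `s_um`, `theta_rad` and logical `valid`. Frames
#'   shorter than the reference distance give an all-masked result with a
#'   warning.
#' @export
curvature_angle <- function(frame, config = kinematics_config()) {
  s <- frame$arclen_um
  step <- config$arclen_step_um
  if (max(s) < config$curvature_ref_distance_um) {
    warning("frame shorter than the curvature reference distance; all masked")
    return(list(s_um = s, theta_rad = rep(NA_real_, length(s)),
                valid = rep(FALSE, length(s))))
  }
  ct <- chord_theta(frame$x_um, frame$y_um, step,
                    config$curvature_ref_distance_um, config$one_sided_ends)
  list(s_um = s, theta_rad = ct$theta, valid = ct$valid)
}

new_curvature_field <- function(theta, valid, s_um, t_s, frame_rate_hz,
                                ref_distance_um, angle_unit = "degrees") {
  structure(list(theta = theta, valid = valid, s_um = s_um, t_s = t_s,
                 frame_rate_hz = frame_rate_hz,
                 ref_distance_um = ref_distance_um, angle_unit = angle_unit),
            class = "curvature_field")
}

#' Assemble the curvature-angle field of a movie
#'
#' Resamples every traced frame onto the common arc-length grid, computes
#' per-frame curvature angles and stacks them into the position x time
#' matrix theta(s, t). Cells beyond a frame's length, in failed frames, or
#' where no chord fits are masked; masked cells are excluded from every
#' downstream average.
#'
#' @param trace A `flagellar_trace` with at least 2 frames.
#' @param config A [kinematics_config()].
#' @return An object of class `curvature_field`: `theta` (radians,
#'   positions x frames), logical `valid` of the same shape, `s_um`, `t_s`,
#'   `frame_rate_hz` and the reference distance.
#' @export
build_field <- function(trace, config = kinematics_config()) {
  if (!inherits(trace, "flagellar_trace"))
    stop("`trace` must come from trace_movie() or read_trace()")
  n_t <- length(trace$frames)
  if (n_t < 2) stop("need at least 2 frames to build a field")
  res <- lapply(trace$frames, function(f)
    if (is.null(f)) NULL else resample_frame(f, config))
  lens <- vapply(res, function(f) if (is.null(f)) 0 else max(f$arclen_um),
                 numeric(1))
  grid <- seq(0, max(lens), by = config$arclen_step_um)
  n_s <- length(grid)
  theta <- matrix(NA_real_, n_s, n_t)
  valid <- matrix(FALSE, n_s, n_t)
  for (k in seq_len(n_t)) {
    f <- res[[k]]
    if (is.null(f)) next
    ca <- suppressWarnings(curvature_angle(f, config))
    idx <- seq_along(ca$s_um)
    theta[idx, k] <- ca$theta_rad
    valid[idx, k] <- ca$valid
  }
  new_curvature_field(theta, valid, grid,
                      (seq_len(n_t) - 1) / trace$frame_rate_hz,
                      trace$frame_rate_hz,
                      config$curvature_ref_distance_um,
                      config$angle_unit)
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf(
    "Curvature-angle field: %d positions (0-%g um) x %d frames @ %g fps\n",
    nrow(x$theta), max(x$s_um), ncol(x$theta), x$frame_rate_hz))
  cat(sprintf("  valid cells: %.1f%%; reference distance %g um\n",
              100 * mean(x$valid), x$ref_distance_um))
  invisible(x)
}

#' @export
as.data.frame.curvature_field <- function(x, ...) {
  n_s <- nrow(x$theta)
  n_t <- ncol(x$theta)
  conv <- if (x$angle_unit == "degrees") 180 / pi else 1
  data.frame(frame = rep(seq_len(n_t), each = n_s),
             time_s = rep(x$t_s, each = n_s),
             s_um = rep(x$s_um, times = n_t),
             theta = as.vector(x$theta) * conv,
             valid = as.vector(x$valid))
}

#' Write a curvature field to long-format CSV
#'
#' Columns `frame`, `time_s`, `s_um`, `theta` (in the configured angle
#' unit) and `valid`.
#'
#' @param field A `curvature_field`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  df <- as.data.frame(field)
  names(df)[names(df) == "theta"] <-
    if (field$angle_unit == "degrees") "theta_deg" else "theta_rad"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
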