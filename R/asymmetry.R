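#' Local beat asymmetry profile
#'
#' The local beat asymmetry at an arc-length position is the absolute value
#' of the time-averaged curvature angle at that position: zero for a
#' perfectly symmetric beat, increasing as the beat becomes biased to one
#' side. Positions with fewer than `min_valid_frac` valid frames are
#' masked.
#'
#' @param field A `curvature_field`.
#' @param min_valid_frac Minimum fraction of valid frames per position.
#' @param sperm_id,condition Labels attached to the profile for group
#'   analyses.
#' @return An object of class `asymmetry_profile`: data frame with `s_um`,
#'   `asym_deg` (absolute time-averaged curvature angle, degrees) and
#'   `n_frames` (valid frames per position).
#' @export
asymmetry_profile <- function(field, min_valid_frac = 0.5,
                              sperm_id = NA_character_,
                              condition = NA_character_) {
  if (!inherits(field, "curvature_field"))
    stop("`field` must be a curvature_field")
  if (length(field$theta) == 0 || all(!field$valid))
    stop("empty curvature field")
  th <- field$theta
  th[!field$valid] <- NA_real_
  n_ok <- rowSums(field$valid)
  a <- abs(rowMeans(th, na.rm = TRUE))
  a[n_ok < min_valid_frac * ncol(th)] <- NA_real_
  out <- data.frame(s_um = field$s_um, asym_deg = rad2deg(a),
                    n_frames = n_ok)
  attr(out, "sperm_id") <- sperm_id
  attr(out, "condition") <- condition
  class(out) <- c("asymmetry_profile", "data.frame")
  out
}

profile_attr <- function(p, what) {
  v <- attr(p, what)
  if (is.null(v)) NA_character_ else as.character(v)
}

# Stack a list of asymmetry profiles into one long data frame.
profiles_long <- function(profiles, condition) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    id <- profile_attr(p, "sperm_id")
    if (is.na(id)) id <- sprintf("%s_%02d", condition, i)
    data.frame(sperm_id = id, condition = condition, s_um = p$s_um,
               asym_deg = p$asym_deg)
  })
  do.call(rbind, rows)
}

#' Condition difference curve of local beat asymmetry
#'
#' Computes, per arc-length position, the mean difference in local beat
#' asymmetry between two groups of sperm (e.g. after minus before
#' stimulation) with its standard deviation. In paired mode (the natural
#' choice when the same tethered cells are recorded under both conditions)
#' profiles are matched by `sperm_id` and the SD is that of the per-sperm
#' differences; otherwise the difference of group means with the pooled SD
#' is reported.
#'
#' @param group_a,group_b Lists of [asymmetry_profile()] objects (condition
#'   A = reference, e.g. before stimulation).
#' @param paired Match profiles by sperm id; falls back to unpaired with a
#'   warning when the ids do not match.
#' @return A data frame with `s_um`, `delta_mean_deg` (B minus A),
#'   `delta_sd_deg`, `n_a`, `n_b`.
#' @export
difference_curve <- function(group_a, group_b, paired = TRUE) {
  if (inherits(group_a, "asymmetry_profile")) group_a <- list(group_a)
  if (inherits(group_b, "asymmetry_profile")) group_b <- list(group_b)
  grid <- Reduce(intersect, lapply(c(group_a, group_b),
                                   function(p) p$s_um))
  if (length(grid) == 0) stop("no overlapping arc-length positions")
  grid <- sort(grid)
  take <- function(p) p$asym_deg[match(grid, p$s_um)]
  A <- vapply(group_a, take, numeric(length(grid)))
  B <- vapply(group_b, take, numeric(length(grid)))
  A <- matrix(A, nrow = length(grid))
  B <- matrix(B, nrow = length(grid))
  if (paired) {
    ids_a <- vapply(group_a, profile_attr, character(1), "sperm_id")
    ids_b <- vapply(group_b, profile_attr, character(1), "sperm_id")
    matched <- !anyNA(ids_a) && !anyNA(ids_b) &&
      length(ids_a) == length(ids_b) && setequal(ids_a, ids_b) &&
      !anyDuplicated(ids_a)
    if (!matched) {
      warning("sperm ids do not match between groups; using unpaired mode")
      paired <- FALSE
    } else {
      B <- B[, match(ids_a, ids_b), drop = FALSE]
    }
  }
  if (paired) {
    D <- B - A
    delta <- rowMeans(D)
    dsd <- apply(D, 1, sd)
  } else {
    delta <- rowMeans(B) - rowMeans(A)
    va <- apply(A, 1, stats::var)
    vb <- apply(B, 1, stats::var)
    na <- ncol(A)
    nb <- ncol(B)
    dsd <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  }
  data.frame(s_um = grid, delta_mean_deg = delta, delta_sd_deg = dsd,
             n_a = ncol(A), n_b = ncol(B))
}

#' Pointwise two-way ANOVA of asymmetry profiles
#'
#' Fits `asym ~ condition * position` (both fixed factors, sperm as
#' replicate) over the common position grid and extracts, at every
#' position, the Tukey-adjusted contrast between conditions, giving a
#' pointwise p-value curve p(s). Contiguous runs of p < `alpha` are
#' reported as significant regions together with the minimum p inside each
#' region.
#'
#' @param group_a,group_b Lists of [asymmetry_profile()] objects, at least
#'   2 sperm each.
#' @param alpha Significance threshold (0.05 as in the difference-curve
#'   figures this reproduces).
#' @param labels Condition labels.
#' @return A list with `p` (data frame `s_um`, `p`, `significant`) and
#'   `regions` (data frame `start_um`, `end_um`, `min_p`).
#' @export
pointwise_anova <- function(group_a, group_b, alpha = 0.05,
                            labels = c("A", "B")) {
  if (inherits(group_a, "asymmetry_profile")) group_a <- list(group_a)
  if (inherits(group_b, "asymmetry_profile")) group_b <- list(group_b)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need at least 2 sperm per condition")
  long <- rbind(profiles_long(group_a, labels[1]),
                profiles_long(group_b, labels[2]))
  grid <- sort(intersect(unique(long$s_um[long$condition == labels[1]]),
                         unique(long$s_um[long$condition == labels[2]])))
  long <- long[long$s_um %in% grid & is.finite(long$asym_deg), ]
  cell_n <- table(long$condition, long$s_um)
  deficient <- apply(cell_n < 2, 2, any)
  if (all(deficient)) {
    bad <- which(cell_n < 2, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "singular design: condition %s at s = %s um has < 2 sperm",
      rownames(cell_n)[bad[1]], colnames(cell_n)[bad[2]]))
  }
  if (any(deficient)) {
    drop_s <- as.numeric(colnames(cell_n)[deficient])
    warning(sprintf(
      "%d position(s) with < 2 sperm in a condition dropped from the ANOVA",
      length(drop_s)))
    long <- long[!long$s_um %in% drop_s, ]
  }
  long$condition <- factor(long$condition, levels = labels)
  long$position <- factor(long$s_um)
  fit <- aov(asym_deg ~ condition * position, data = long)
  if (sd(stats::residuals(fit)) < 1e-12)
    stop("degenerate ANOVA: zero within-cell variance")
  emm <- emmeans::emmeans(fit, ~ condition | position)
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  p <- ctr$p.value
  s <- as.numeric(as.character(ctr$position))
  ord <- order(s)
  pdf <- data.frame(s_um = s[ord], p = p[ord])
  pdf$significant <- is.finite(pdf$p) & pdf$p < alpha
  list(p = pdf, regions = significant_regions(pdf$s_um, pdf$p, alpha))
}

#' Contiguous significant regions of a p-value curve
#'
#' Maximal runs of consecutive positions with p below `alpha`; each region
#' reports the minimum p among its member positions.
#'
#' @param s_um Ordered positions (um).
#' @param p Pointwise p-values (NA counts as not significant).
#' @param alpha Threshold.
#' @return Data frame with `start_um`, `end_um`, `min_p` (zero rows when
#'   nothing is significant).
#' @export
significant_regions <- function(s_um, p, alpha = 0.05) {
  sig <- is.finite(p) & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(start_um = numeric(0), end_um = numeric(0),
                      min_p = numeric(0)))
  data.frame(
    start_um = s_um[starts[keep]],
    end_um = s_um[ends[keep]],
    min_p = vapply(keep, function(k)
      min(p[starts[k]:ends[k]]), numeric(1)))
}

#' Compare local beat asymmetry between two conditions
#'
#' Combines the [difference_curve()] (mean +/- SD of the per-sperm
#' difference) with the [pointwise_anova()] significance analysis into one
#' comparison object, the quantitative content of a
#' difference-curve-with-significance-bands figure.
#'
#' @inheritParams pointwise_anova
#' @param paired Passed to [difference_curve()].
#' @return An object of class `condition_comparison`: data frame `curve`
#'   (difference curve plus `p` and `significant`), `regions`, `alpha`,
#'   `labels`.
#' @export
compare_conditions <- function(group_a, group_b, paired = TRUE, alpha = 0.05,
                               labels = c("A", "B")) {
  curve <- difference_curve(group_a, group_b, paired = paired)
  an <- pointwise_anova(group_a, group_b, alpha = alpha, labels = labels)
  m <- match(curve$s_um, an$p$s_um)
  curve$p <- an$p$p[m]
  curve$significant <- an$p$significant[m]
  structure(list(curve = curve, regions = an$regions, alpha = alpha,
                 labels = labels, paired = paired),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s): %s -> %s, n = %d vs %d\n",
              if (x$paired) "paired" else "unpaired",
              x$labels[1], x$labels[2], x$curve$n_a[1], x$curve$n_b[1]))
  if (nrow(x$regions) == 0) {
    cat(sprintf("  no significant regions at p < %g\n", x$alpha))
  } else {
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("  significant region %g-%g um (min p = %.3g)\n",
                  x$regions$start_um[i], x$regions$end_um[i],
                  x$regions$min_p[i]))
  }
  invisible(x)
}

#' @export
plot.condition_comparison <- function(x, ...) {
  cv <- x$curve
  ylim <- range(cv$delta_mean_deg + cv$delta_sd_deg,
                cv$delta_mean_deg - cv$delta_sd_deg, 0, na.rm = TRUE)
  plot(NA, xlim = range(cv$s_um), ylim = ylim,
       xlab = "arc length (um)",
       ylab = expression(Delta * " asymmetry (deg)"), ...)
  if (nrow(x$regions) > 0)
    rect(x$regions$start_um, ylim[1], x$regions$end_um, ylim[2],
         col = "grey85", border = NA)
  abline(h = 0, col = "grey50")
  lines(cv$s_um, cv$delta_mean_deg + cv$delta_sd_deg, col = "rosybrown2")
  lines(cv$s_um, cv$delta_mean_deg - cv$delta_sd_deg, col = "rosybrown2")
  lines(cv$s_um, cv$delta_mean_deg, col = "darkred", lwd = 2)
  invisible(x)
}

#' Simulate groups of asymmetry profiles
#'
#' Draws synthetic sperm whose curvature-angle bias varies smoothly along
#' the flagellum: each sperm gets a curvature offset
#' `base_offset(s) + eta(s)` where `eta` is a smooth Gaussian process
#' (white noise convolved with a Gaussian kernel of bandwidth
#' `corr_len_um`, marginal SD `sperm_sd` rad), the field is generated by
#' [generate_waveform()] with that offset, white measurement noise of SD
#' `noise_sd` rad is added to the curvature angles, and the asymmetry
#' profile is computed with [asymmetry_profile()]. Used for calibration and
#' power analyses of the group statistics.
#'
#' @param n_sperm Number of sperm in the group.
#' @param base_offset Curvature-angle offset (rad) shared by the group: a
#'   function of arc length or a single number.
#' @param sperm_sd Between-sperm SD (rad) of the smooth curvature offset.
#' @param corr_len_um Kernel bandwidth (um) of the smooth between-sperm
#'   variation.
#' @param noise_sd Per-cell measurement noise SD (rad) on curvature angles.
#' @param condition Condition label attached to the profiles.
#' @param seed RNG seed.
#' @param params Template [waveform_params()] for the underlying beat.
#' @return A list of `n_sperm` [asymmetry_profile()] objects.
#' @export
simulate_asymmetry_profiles <- function(n_sperm, base_offset = 0.08,
                                        sperm_sd = 0.05, corr_len_um = 6,
                                        noise_sd = 0.02,
                                        condition = "sim", seed = NULL,
                                        params = waveform_params(
                                          n_frames = 400, ds_um = 1)) {
  base_fun <- as_envelope(base_offset, "base_offset")
  with_seed(seed, {
    lapply(seq_len(n_sperm), function(i) {
      s_fine <- seq(0, params$length_um, by = params$ds_um)
      eta <- smooth_gp(length(s_fine), corr_len_um / params$ds_um) * sperm_sd
      eta_fun <- approxfun(s_fine, eta, rule = 2)
      curv <- function(s) base_fun(s) + eta_fun(s)
      p_i <- params
      p_i$asym_offset <- curvature_offset(curv)
      truth <- generate_waveform(p_i)
      fld <- as_curvature_field(truth)
      fld$theta <- fld$theta +
        matrix(rnorm(length(fld$theta), sd = noise_sd),
               nrow(fld$theta), ncol(fld$theta))
      asymmetry_profile(fld, sperm_id = sprintf("%s_%02d", condition, i),
                        condition = condition)
    })
  })
}

# Smooth unit-variance Gaussian process on a regular grid: white noise
# convolved with a Gaussian kernel of bandwidth `bw` grid steps.
smooth_gp <- function(n, bw) {
  r <- ceiling(3 * bw)
  k <- exp(-0.5 * ((-r:r) / bw)^2)
  k <- k / sqrt(sum(k^2))
  z <- rnorm(n + 2 * r)
  as.numeric(stats::filter(z, k, sides = 2))[(r + 1):(r + n)]
}
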