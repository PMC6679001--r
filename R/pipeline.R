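#' Pipeline run configuration
#'
#' Bundles input movies grouped by condition with all analysis settings.
#' Every referenced file must exist; this is checked at construction, so a
#' bad path fails before any computation starts. Configurations round-trip
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param inputs Named list: condition label -> character vector of TIFF
#'   paths, one per sperm. With two conditions the i-th movie of each is
#'   treated as the same sperm (before/after pairing).
#' @param output_dir Output directory (created on run).
#' @param frame_rate_hz,pixel_size_um Acquisition parameters; `NULL` reads
#'   them from each movie's sidecar.
#' @param trace A [trace_settings()] object.
#' @param kinematics A [kinematics_config()] object.
#' @param fft_window FFT window (frames).
#' @param s_range Arc-length window (um) for the sperm frequency.
#' @param paired Paired condition comparison.
#' @param alpha Significance threshold for the comparison.
#' @param seed RNG seed recorded in the manifest.
#' @param allow_short Allow movies shorter than the FFT window.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs, output_dir, frame_rate_hz = NULL,
                       pixel_size_um = NULL, trace = trace_settings(),
                       kinematics = kinematics_config(), fft_window = 400,
                       s_range = c(15, 60), paired = TRUE, alpha = 0.05,
                       seed = 1, allow_short = FALSE) {
  if (!is.list(inputs) || is.null(names(inputs)) || any(names(inputs) == ""))
    stop("`inputs` must be a named list of movie path vectors")
  for (cond in names(inputs)) {
    missing <- inputs[[cond]][!file.exists(inputs[[cond]])]
    if (length(missing) > 0)
      stop(sprintf("config error: input file not found: %s", missing[1]))
  }
  structure(list(inputs = inputs, output_dir = output_dir,
                 frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um, trace = trace,
                 kinematics = kinematics, fft_window = fft_window,
                 s_range = s_range, paired = isTRUE(paired), alpha = alpha,
                 seed = seed, allow_short = isTRUE(allow_short)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$trace <- unclass(x$trace)
  x$kinematics <- unclass(x$kinematics)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  run_config(inputs = lapply(x$inputs, unlist),
             output_dir = x$output_dir,
             frame_rate_hz = x$frame_rate_hz,
             pixel_size_um = x$pixel_size_um,
             trace = do.call(trace_settings, x$trace[setdiff(
               names(x$trace), "threshold_method")]),
             kinematics = do.call(kinematics_config, x$kinematics),
             fft_window = x$fft_window, s_range = unlist(x$s_range),
             paired = x$paired, alpha = x$alpha, seed = x$seed,
             allow_short = x$allow_short %||% FALSE)
}

pipeline_log <- function(...) {
  message(sprintf("[flagbeat %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' For every movie of every condition: preprocess, trace, build the
#' curvature field, estimate the frequency profile and sperm frequency,
#' and compute the asymmetry profile; write per-sperm CSVs (trace, field,
#' frequency, asymmetry), a per-condition frequency summary, and -- with
#' exactly two conditions -- the asymmetry difference curve, pointwise
#' p-values and significant regions. A machine-readable JSON manifest
#' records package version, settings (with a fingerprint), seed and
#' per-sperm status. Failing sperm are logged and skipped; the run fails
#' only if every sperm fails.
#'
#' @param config A [run_config()] (or a YAML path).
#' @return Invisibly, a list with `analyses` (per condition), `summary`
#'   data frame, `comparison` (or `NULL`), and the `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) stop("`config` must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  analyses <- list()
  status <- list()
  summary_rows <- list()
  for (cond in names(config$inputs)) {
    paths <- config$inputs[[cond]]
    cond_dir <- file.path(config$output_dir, cond)
    dir.create(cond_dir, showWarnings = FALSE, recursive = TRUE)
    fits <- list()
    for (i in seq_along(paths)) {
      id <- sprintf("sperm_%02d", i)
      pipeline_log("condition %s: analysing %s (%s)", cond, id, paths[i])
      fit <- tryCatch({
        movie <- read_movie(paths[i], config$frame_rate_hz,
                            config$pixel_size_um)
        analyze_movie(movie, config$trace, config$kinematics,
                      fft_window = config$fft_window,
                      s_range = config$s_range, sperm_id = id,
                      condition = cond, allow_short = config$allow_short)
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        pipeline_log("condition %s: %s FAILED: %s", cond, id,
                     conditionMessage(fit))
        status[[paste(cond, id, sep = "/")]] <- conditionMessage(fit)
        next
      }
      status[[paste(cond, id, sep = "/")]] <- "ok"
      sdir <- file.path(cond_dir, id)
      dir.create(sdir, showWarnings = FALSE)
      write_trace(fit$trace, file.path(sdir, "trace.csv"))
      write_field(fit$field, file.path(sdir, "field.csv"))
      write.csv(fit$frequency, file.path(sdir, "frequency.csv"),
                row.names = FALSE)
      write.csv(fit$asymmetry, file.path(sdir, "asymmetry.csv"),
                row.names = FALSE)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        sperm_id = id, condition = cond, sperm_freq_hz = fit$sperm_freq_hz,
        n_overlay_frames = fit$n_overlay_frames)
      fits[[id]] <- fit
    }
    analyses[[cond]] <- fits
  }
  if (all(vapply(analyses, length, integer(1)) == 0))
    stop("pipeline failed: no sperm could be analysed")
  summary_df <- do.call(rbind, summary_rows)
  write.csv(summary_df, file.path(config$output_dir, "frequency_summary.csv"),
            row.names = FALSE)
  comparison <- NULL
  if (length(analyses) == 2 &&
      all(vapply(analyses, length, integer(1)) >= 2)) {
    labs <- names(analyses)
    grp <- lapply(analyses, function(fits)
      lapply(fits, function(f) f$asymmetry))
    comparison <- tryCatch(
      compare_conditions(grp[[1]], grp[[2]], paired = config$paired,
                         alpha = config$alpha, labels = labs),
      error = function(e) {
        pipeline_log("comparison failed: %s", conditionMessage(e))
        NULL
      })
    if (!is.null(comparison)) {
      write.csv(comparison$curve,
                file.path(config$output_dir, "comparison.csv"),
                row.names = FALSE)
      write.csv(comparison$regions,
                file.path(config$output_dir, "regions.csv"),
                row.names = FALSE)
    }
  }
  manifest <- list(
    package = "flagbeat",
    version = as.character(packageVersion("flagbeat")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    settings = list(trace = unclass(config$trace),
                    kinematics = unclass(config$kinematics),
                    fft_window = config$fft_window,
                    s_range = config$s_range, paired = config$paired,
                    alpha = config$alpha),
    settings_hash = fnv1a(yaml::as.yaml(list(
      trace = unclass(config$trace),
      kinematics = unclass(config$kinematics),
      fft_window = config$fft_window))),
    conditions = names(config$inputs),
    inputs = config$inputs,
    status = status)
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(analyses = analyses, summary = summary_df,
                 comparison = comparison, manifest = manifest))
}
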