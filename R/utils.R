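# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

# Cumulative trapezoidal integral of y over a uniform grid with step h.
cumtrapz_uniform <- function(y, h) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2) * h)
}

# FNV-1a hash of a character string, as 8 hex digits (manifest fingerprints).
fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# Coerce a scalar or function to a function of arc length.
as_envelope <- function(x, name) {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1 && is.finite(x)) {
    force(x)
    return(function(s) rep(x, length(s)))
  }
  stop(sprintf("`%s` must be a function of arc length or a single number", name),
       call. = FALSE)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
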