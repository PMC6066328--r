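# Internal helpers: classed conditions, local RNG scope, small numerics.

dfs_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "dfs_error", "error"), call = call))
}

abort_domain     <- function(msg) dfs_stop(msg, "dfs_domain_error")
abort_range      <- function(msg) dfs_stop(msg, c("dfs_range_error", "dfs_domain_error"))
abort_format     <- function(msg) dfs_stop(msg, "dfs_format_error")
abort_validation <- function(msg) dfs_stop(msg, "dfs_validation_error")
abort_fit        <- function(msg) dfs_stop(msg, "dfs_fit_error")
abort_param      <- function(msg) dfs_stop(msg, "dfs_param_error")
abort_estimation <- function(msg) dfs_stop(msg, "dfs_estimation_error")
abort_simulation <- function(msg) dfs_stop(msg, "dfs_simulation_error")
abort_empty      <- function(msg) dfs_stop(msg, c("dfs_empty_error", "dfs_validation_error"))

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_domain(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    abort_domain(sprintf("'%s' must be > 0 (got %g)", name, x))
  invisible(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    abort_param("a single integer 'seed' is required (no hidden global RNG state)")
  as.integer(seed %% .Machine$integer.max)
}

# Evaluate `expr` under `seed` and restore the caller's RNG state afterwards,
# so seeded functions do not leak state into the session.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Centred moving average; edges keep the raw values. Used for event detection
# only, never for fitting.
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || length(x) < window) return(x)
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  bad <- is.na(sm)
  sm[bad] <- x[bad]
  sm
}

# Cumulative trapezoidal integral of y over x (same length as x, starts at 0).
cumtrapz0 <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum(0.5 * diff(x) * (y[-1L] + y[-n])))
}

# Cheap deterministic hash of an R object (provenance stamp for reports).
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
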