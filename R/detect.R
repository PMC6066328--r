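# Rupture-event detection and per-event loading-rate estimation on single
# retraction curves.

#' Detection parameters
#'
#' @param min_force Detection threshold (pN): the force discontinuity at a
#'   candidate rupture must exceed this. Default 15 (3x the default simulated
#'   noise SD).
#' @param min_points Minimum samples in the rising stretch segment preceding
#'   the rupture (>= 5).
#' @param smoothing_window Centred moving-average window (samples) applied to
#'   the trace for detection only, never for fitting.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(min_force = 15, min_points = 5L,
                             smoothing_window = 5L) {
  check_scalar(min_force, "min_force")
  if (!is.numeric(min_points) || min_points < 5)
    abort_domain("'min_points' must be >= 5")
  if (!is.numeric(smoothing_window) || smoothing_window < 1)
    abort_domain("'smoothing_window' must be >= 1")
  structure(list(min_force = min_force, min_points = as.integer(min_points),
                 smoothing_window = as.integer(smoothing_window)),
            class = "detection_params")
}

# Baseline = median of the final 10% of the retraction trace (the tip is far
# from the surface there, so the trace is force-free by construction).
baseline_correct <- function(force) {
  n <- length(force)
  nb <- min(n, max(5L, floor(0.1 * n)))
  force - stats::median(force[(n - nb + 1L):n])
}

#' Detect the candidate rupture event on a retraction curve
#'
#' Locates the largest force discontinuity: a drop toward baseline exceeding
#' `min_force` within at most 3 samples of the (smoothed) trace, preceded by a
#' rising segment with positive net rise over at least `min_points` samples
#' (2% of the trace length, if longer, so the rise is resolved above the
#' smoothed noise at slow pulling speeds).
#' The reported rupture force is the baseline-corrected *unsmoothed* force at
#' the detected index. Absence of an event is a value (`NULL`), not an error.
#'
#' @param curve A [force_curve()].
#' @param det A [detection_params()].
#' @return `NULL`, or a list with `curve_id`, `rupture_force` (pN),
#'   `rupture_index` (sample index), `pulling_velocity`.
#' @export
detect_rupture <- function(curve, det = detection_params()) {
  fb <- baseline_correct(curve$force)
  fs <- moving_average(fb, det$smoothing_window)
  n <- length(fs)
  if (n < det$min_points + 4L) return(NULL)

  # drop from sample i to the minimum of the next <= 3 samples
  lead1 <- c(fs[-1L], fs[n])
  lead2 <- c(fs[-(1:2)], fs[n], fs[n])
  lead3 <- c(fs[-(1:3)], fs[n], fs[n], fs[n])
  drop <- fs - pmin(lead1, lead2, lead3)

  cand <- which(drop > det$min_force & fs > det$min_force)
  if (!length(cand)) return(NULL)
  i <- cand[which.max(drop[cand])]

  # rising approach: net rise over the min_points smoothed samples ending
  # half a smoothing window before the edge (the centred average folds the
  # drop itself into later samples). Sample-to-sample monotonicity is
  # meaningless under noise at realistic sampling; the net-rise form rejects
  # isolated spikes, which is the point.
  half <- det$smoothing_window %/% 2L + 1L
  j_end <- i - half
  rise_span <- max(det$min_points, ceiling(0.02 * n))
  j_start <- j_end - rise_span + 1L
  if (j_start < 1L) return(NULL)
  if (fs[j_end] - fs[j_start] <= 0) return(NULL)
  if (fb[i] < det$min_force) return(NULL)

  list(curve_id = curve$curve_id, rupture_force = fb[i], rupture_index = i,
       pulling_velocity = curve$pulling_velocity)
}

#' Estimate the loading rate at rupture
#'
#' Ordinary least-squares slope of (baseline-corrected, unsmoothed) force
#' versus time over the samples between `window * rupture_force` and the
#' rupture index. The default window (0.8) confines the fit to the final,
#' quasi-linear part of the ramp: with a soft cantilever the series
#' compliance -- and hence dF/dt -- changes severalfold between 30% and 100%
#' of the peak force, so only the near-rupture slope approximates the
#' instantaneous loading rate that governs the rupture-force distribution;
#' 0.8 balances that against the slope noise of a too-narrow window.
#'
#' @param curve A [force_curve()].
#' @param event A candidate from [detect_rupture()].
#' @param window Fraction of the rupture force at which the fit window opens.
#' @param min_samples Minimum samples in the window (>= 3); fewer is an
#'   estimation error.
#' @return Loading rate (pN/s). The fitted line's value at the rupture time
#'   is attached as attribute `force_at_rupture`: it is a lower-noise,
#'   selection-free reading of the rupture force than the single sample at
#'   the detected index (which is biased upward by ~noise/2 because detection
#'   maximises over noisy drops). A non-positive fitted slope raises an
#'   estimation error (the caller flags/excludes the event).
#' @export
estimate_loading_rate <- function(curve, event, window = 0.8, min_samples = 3L) {
  if (window <= 0 || window >= 1) abort_domain("'window' must lie in (0, 1)")
  i <- event$rupture_index
  fb <- baseline_correct(curve$force)
  n <- length(fb)
  if (i < min_samples)
    abort_estimation("rupture too close to the start of the trace")
  # Locate the window opening on a heavily smoothed trace (1% of the trace
  # length): with light smoothing, noise dips below the threshold right next
  # to the peak and collapse the window to a handful of samples, which both
  # inflates the slope variance and -- because non-positive slopes are
  # rejected -- biases the surviving estimates upward. The crossing search
  # stops half a smoothing window before the rupture edge, where the centred
  # average starts folding in the post-rupture drop.
  w_loc <- max(5L, ceiling(0.01 * n))
  sm <- moving_average(fb, w_loc)
  i_safe <- max(1L, i - (w_loc %/% 2L + 2L))
  thr <- window * event$rupture_force
  below <- which(sm[seq_len(i_safe)] < thr)
  j0 <- if (length(below)) max(below) + 1L else 1L
  if (i - j0 + 1L < min_samples) j0 <- max(1L, i - max(min_samples, 8L) + 1L)
  idx <- j0:i
  if (length(idx) < min_samples)
    abort_estimation(sprintf(
      "loading-rate window [%g pN, rupture] contains %d samples (< %d)",
      thr, length(idx), min_samples))
  tt <- curve$time[idx]
  ff <- fb[idx]
  slope <- sum((tt - mean(tt)) * (ff - mean(ff))) / sum((tt - mean(tt))^2)
  if (!is.finite(slope) || slope <= 0)
    abort_estimation("non-positive force slope in loading-rate window; event excluded")
  structure(slope,
            force_at_rupture = mean(ff) + slope * (tt[length(tt)] - mean(tt)))
}
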