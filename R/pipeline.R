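# End-to-end orchestration: simulate (optional) -> detect -> TLS tether fit
# -> Lc filter -> loading rates -> cluster -> Bell-Evans fit with bootstrap.

#' Extract rupture events from a set of force curves
#'
#' Runs [detect_rupture()], [fit_tether_tls()] and [estimate_loading_rate()]
#' over each curve. Curves without a detected event are skipped; events whose
#' tether fit or loading-rate estimate fails are dropped and counted.
#'
#' The reported rupture force is refined by the near-rupture force-ramp fit
#' (the OLS line of [estimate_loading_rate()] evaluated at the rupture time):
#' reading the single sample at the detected index instead carries a
#' systematic +noise/2 selection offset, because detection picks the largest
#' noisy drop.
#'
#' Detection is two-stage so that the censoring of small rupture forces is
#' *sharp*: candidates are scanned with a sensitive drop bar (40% of
#' `min_force`), and an event is kept only if its precise ramp-line force
#' reaches the effective detection limit `min_force * smoothing_window / 3`.
#' Gating on the raw noisy drop instead spreads the detection boundary over
#' roughly +/- 5 pN, which shifts the slow clusters' observable mean forces
#' away from any sharply-truncated model of them.
#'
#' Loading rates are computed per `lr_method`. `"tether"` (default) applies
#' the chain rule `r = v / (1/k_c + dx/dF)` with the tether compliance
#' `dx/dF` evaluated from the event's own fitted contour length at its
#' rupture force -- the quantity the rupture-force distribution actually
#' depends on. `"slope"` uses the windowed OLS slope of force versus time
#' directly; it is unbiased on average but noisy on single events (see the
#' vignette).
#'
#' @param curves List of [force_curve()] objects.
#' @param det [detection_params()].
#' @param template [tether_model()] for the TLS fit.
#' @param lr_window Loading-rate window (fraction of peak force), default 0.8.
#' @param lr_method `"tether"` (default) or `"slope"`; see Details.
#' @param verbose Log per-stage counts with `message()`.
#' @return Data frame with one row per extracted event: `curve_id`,
#'   `rupture_force`, `rupture_index`, `contour_length`, `loading_rate`,
#'   `pulling_velocity`, `accepted` (NA until the Lc filter runs). Stage
#'   counts are attached as attribute `counts`.
#' @export
extract_events <- function(curves, det = detection_params(),
                           template = tether_model(), lr_window = 0.8,
                           lr_method = c("tether", "slope"),
                           verbose = FALSE) {
  lr_method <- match.arg(lr_method)
  det_cand <- det
  det_cand$min_force <- 0.4 * det$min_force
  censor <- det$min_force * max(1, det$smoothing_window / 3)
  rows <- vector("list", length(curves))
  n_detected <- 0L; n_tls_failed <- 0L; n_lr_failed <- 0L
  n_below_censor <- 0L
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    cand <- detect_rupture(cv, det_cand)
    if (is.null(cand)) next
    n_detected <- n_detected + 1L
    slope <- tryCatch(estimate_loading_rate(cv, cand, window = lr_window),
                      dfs_estimation_error = function(e) NULL)
    f_rup <- cand$rupture_force
    if (!is.null(slope)) {
      f_ref <- attr(slope, "force_at_rupture")
      if (is.finite(f_ref) && f_ref > 0) f_rup <- f_ref
    }
    if (f_rup < censor) { n_below_censor <- n_below_censor + 1L; next }
    tls <- tryCatch(fit_tether_tls(cv, cand, template),
                    dfs_fit_error = function(e) NULL)
    if (is.null(tls)) { n_tls_failed <- n_tls_failed + 1L; next }
    if (lr_method == "slope") {
      if (is.null(slope)) { n_lr_failed <- n_lr_failed + 1L; next }
      lr <- as.numeric(slope)
    } else {
      teth_i <- tether_with_n(template, max(tls$lc, 1) / template$l_planar)
      lr <- cv$pulling_velocity /
        (1 / cv$spring_constant + fjc_dxdf(max(f_rup, 5), teth_i))
    }
    rows[[i]] <- data.frame(curve_id = cand$curve_id,
                            rupture_force = f_rup,
                            rupture_index = cand$rupture_index,
                            contour_length = tls$lc,
                            loading_rate = lr,
                            pulling_velocity = cv$pulling_velocity,
                            accepted = NA, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(events)) events <- data.frame()
  counts <- list(curves = length(curves), detected = n_detected,
                 below_censor = n_below_censor,
                 tls_failed = n_tls_failed, lr_failed = n_lr_failed,
                 extracted = nrow(events))
  if (verbose)
    message(sprintf("extract_events: %d curves, %d candidates, %d below the %g pN detection limit, %d tether-fit failures, %d loading-rate failures, %d events",
                    counts$curves, counts$detected, censor,
                    counts$tls_failed, counts$lr_failed, counts$extracted))
  attr(events, "counts") <- counts
  events
}

#' Run the full dynamic force spectroscopy pipeline
#'
#' Either simulates an experiment from `config` or analyses supplied
#' `curves`: event detection, TLS tether fits, Gaussian contour-length
#' filter, loading-rate estimation, k-means loading-rate clustering, and a
#' robust Bell-Evans fit with bootstrap confidence intervals. Deterministic
#' given the seeds.
#'
#' @param config Optional [simulation_config()]; when given, curves are
#'   simulated and its tether doubles as the TLS template.
#' @param curves Optional list of [force_curve()] objects (exactly one of
#'   `config` / `curves` must be supplied).
#' @param det [detection_params()].
#' @param template [tether_model()] for the TLS fit; default
#'   `config$tether` or the package default.
#' @param k Cluster count; default the number of distinct velocities.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed for clustering/bootstrap (mandatory).
#' @param lr_window Loading-rate window fraction, default 0.8.
#' @param lr_method Per-event loading-rate estimator, `"tether"` (default)
#'   or `"slope"`; see [extract_events()].
#' @param cluster_scale Clustering scale for [cluster_loading_rates()]:
#'   `"velocity"` (default; k-means over the nominal loading-rate groups),
#'   `"log10"` or `"linear"` (k-means on the measured per-event rates).
#' @param response Bell-Evans response curve: `"path"` (default; cluster
#'   mean forces are fitted to the censored first-passage mean along the
#'   reconstructed constant-velocity force path, which accounts for the
#'   loading rate varying during each pull), `"mean"` (fixed-rate Bell-Evans
#'   mean force) or `"mode"` (most-probable-force line); see
#'   [fit_bell_evans()]. The `"path"` and `"mean"` responses also model the
#'   detection limit: the smoothed drop criterion censors ruptures below
#'   about `min_force * smoothing_window / 3` (~25 pN at the defaults),
#'   which otherwise inflates the slow clusters' mean forces.
#' @param verbose Log stage counts.
#' @return An object of class `dfs_report`: `fit` (a `bell_evans_fit` with
#'   CIs), `lc_filter`, `events`, per-stage `counts`, and `provenance`
#'   (config hash, seeds, package version). Zero usable events raise a
#'   classed empty-report error rather than a crash.
#' @export
run_pipeline <- function(config = NULL, curves = NULL,
                         det = detection_params(), template = NULL,
                         k = NULL, B = 1000L, seed, lr_window = 0.8,
                         lr_method = c("tether", "slope"),
                         cluster_scale = c("velocity", "log10", "linear"),
                         response = c("path", "mean", "mode"),
                         verbose = FALSE) {
  response <- match.arg(response)
  lr_method <- match.arg(lr_method)
  cluster_scale <- match.arg(cluster_scale)
  if (response == "path" && cluster_scale != "velocity")
    abort_param("response = 'path' requires cluster_scale = 'velocity'")
  seed <- check_seed(seed)
  if (is.null(config) == is.null(curves))
    abort_param("supply exactly one of 'config' or 'curves'")
  if (!is.null(config)) {
    sim <- simulate_experiment(config)
    curves <- sim$curves
    template <- template %||% config$tether
  }
  template <- template %||% tether_model()

  events <- extract_events(curves, det = det, template = template,
                           lr_window = lr_window, lr_method = lr_method,
                           verbose = verbose)
  counts <- attr(events, "counts")
  if (counts$extracted == 0L)
    abort_empty("no rupture events extracted; empty report")

  lcf <- filter_by_contour_length(events)
  events$accepted <- events$curve_id %in% lcf$accepted_ids
  accepted <- events[events$accepted & events$loading_rate > 0, , drop = FALSE]
  counts$lc_accepted <- nrow(accepted)
  if (verbose)
    message(sprintf("Lc filter: mu = %.1f nm, sigma = %.1f nm, accepted %d / %d",
                    lcf$mu, lcf$sigma, counts$lc_accepted, counts$extracted))
  if (nrow(accepted) == 0L)
    abort_empty("no events accepted by the contour-length filter; empty report")

  # The drop criterion censors small rupture forces: an instantaneous step of
  # height F produces a maximal 3-sample drop of only (3/w) * F on a w-sample
  # smoothed trace, so ruptures below min_force * w/3 are undetectable. The
  # path and mean responses model cluster means as left-truncated there.
  trunc_eff <- det$min_force * max(1, det$smoothing_window / 3)
  paths <- NULL
  if (response == "path") {
    # noiseless tether + cantilever force path per velocity, with the tether
    # contour length taken from the fitted Lc distribution centre
    teth_fit <- tether_with_n(template,
                              max(lcf$mu, 10) / template$l_planar)
    kc <- curves[[1L]]$spring_constant
    vels <- sort(unique(accepted$pulling_velocity))
    z_max <- 1.05 * (fjc_extension(400, teth_fit) + 400 / kc)
    # The contour-length filter thins events at a rate that falls with
    # rupture force (low-force stretch segments give noisier Lc estimates,
    # which stray outside the one-sigma acceptance band more often). That
    # reweights each cluster's observable force distribution, so the
    # response models it: a logistic acceptance curve a(F), estimated from
    # the events in the broad (3 sigma) specific Lc band, multiplies the
    # first-passage weights.
    a_fun <- function(f, v) rep(1, length(f))
    cand <- events[abs(events$contour_length - lcf$mu) <= 3 * lcf$sigma, ,
                   drop = FALSE]
    if (nrow(cand) > 50L && stats::var(cand$accepted) > 0) {
      sel <- tryCatch(
        stats::glm(accepted ~ rupture_force + log(pulling_velocity),
                   family = stats::binomial(), data = cand),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(sel) && all(is.finite(stats::coef(sel)))) {
        cf <- stats::coef(sel)
        a_fun <- function(f, v) stats::plogis(cf[1L] + cf[2L] * f +
                                                cf[3L] * log(v))
      }
    }
    paths <- lapply(vels, function(v) {
      tt <- seq(0, z_max / v, length.out = 1500L)
      f0 <- series_force_path(v * tt, teth_fit, kc)
      list(time = tt, force = f0, accept = a_fun(f0, v))
    })
  }
  fit <- bootstrap_bell_evans(accepted, k = k, B = B, seed = seed,
                              response = response, kBT = template$kBT,
                              scale = cluster_scale, paths = paths,
                              trunc = if (response != "mode") trunc_eff else 0)

  provenance <- list(config_hash = config_hash(list(config = config, det = det,
                                                    template = template,
                                                    lr_window = lr_window,
                                                    lr_method = lr_method,
                                                    cluster_scale = cluster_scale,
                                                    response = response)),
                     seed = seed,
                     sim_seed = if (!is.null(config)) config$seed else NA,
                     package_version = as.character(utils::packageVersion("dfspec")))
  structure(list(fit = fit, lc_filter = lcf, events = events,
                 counts = counts, provenance = provenance),
            class = "dfs_report")
}

#' @export
print.dfs_report <- function(x, ...) {
  cat("Dynamic force spectroscopy report\n")
  cat(sprintf("  curves: %d, detected: %d, events: %d, Lc-accepted: %d\n",
              x$counts$curves, x$counts$detected, x$counts$extracted,
              x$counts$lc_accepted))
  print(x$lc_filter)
  print(x$fit)
  invisible(x)
}
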