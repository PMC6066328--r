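# Physics-based generator of AFM retraction force curves and contact-trial
# outcomes, with full ground truth. The generator exists so that every
# downstream stage (detection, TLS tether fit, Lc filter, clustering,
# Bell-Evans fitting, binding statistics) can be exercised and validated
# without instrument data.

#' A single AFM retraction force curve
#'
#' Constructor with invariant checks: equal-length arrays (>= 2 samples),
#' strictly increasing time, and tip-sample distance consistent with
#' `pulling_velocity * time`.
#'
#' @param curve_id Identifier string.
#' @param time Time since start of retraction (s), strictly increasing.
#' @param tip_sample_distance Tip-sample separation (nm), 0 at contact and
#'   increasing on retraction.
#' @param force Measured force (pN); tensile forces are positive.
#' @param pulling_velocity Retraction velocity (nm/s).
#' @param spring_constant Cantilever spring constant (pN/nm).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(curve_id, time, tip_sample_distance, force,
                        pulling_velocity, spring_constant) {
  n <- length(time)
  if (n < 2L || length(tip_sample_distance) != n || length(force) != n)
    abort_validation("force_curve arrays must have equal length >= 2")
  if (any(diff(time) <= 0))
    abort_validation(sprintf("curve '%s': time must be strictly increasing", curve_id))
  check_scalar(pulling_velocity, "pulling_velocity")
  if (!is.numeric(spring_constant) || spring_constant <= 0)
    abort_validation(sprintf("curve '%s': spring_constant must be > 0", curve_id))
  tol <- 1e-6 * max(tip_sample_distance) + 1e-9
  if (max(abs(tip_sample_distance - pulling_velocity * time)) > tol)
    abort_validation(sprintf(
      "curve '%s': tip_sample_distance must equal pulling_velocity * time", curve_id))
  structure(list(curve_id = as.character(curve_id), time = time,
                 tip_sample_distance = tip_sample_distance, force = force,
                 pulling_velocity = pulling_velocity,
                 spring_constant = spring_constant),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve '%s': %d samples, v = %.4g nm/s, k_c = %.3g pN/nm, F range [%.3g, %.3g] pN\n",
              x$curve_id, length(x$time), x$pulling_velocity, x$spring_constant,
              min(x$force), max(x$force)))
  invisible(x)
}

#' Configuration of a simulated pulling experiment
#'
#' The defaults emulate the experimental design of a cadherin single-molecule
#' study: six pulling velocities log-spaced over two decades, a soft contact
#' cantilever, MW-5000 PEG tethers in series, and a curve mixture dominated by
#' empty (no-interaction) traces with a small specific fraction, as dictated
#' by single-bond (~6% adhesion frequency) working conditions.
#'
#' @param kin Ground-truth [kinetic_params()] of the probed bond.
#' @param tether [tether_model()] of the series PEG tether; default two
#'   MW-5000 PEGs.
#' @param spring_constant Cantilever stiffness (pN/nm); default 10 (soft
#'   contact-mode lever).
#' @param velocities Pulling velocities (nm/s); default six log-spaced values
#'   from 100 to 10,000.
#' @param curves_per_velocity Curves simulated at each velocity.
#' @param fractions Named or positional numeric `(specific, nonspecific,
#'   empty)` mixture fractions summing to 1.
#' @param noise_sd Gaussian force noise (pN); default 5.
#' @param sampling_rate Samples per second. `NULL` (default) chooses an
#'   adaptive rate `max(5000, 5 * velocity)` so the trace always resolves at
#'   least ~5 samples per nm of travel; a fixed scalar is honoured as given.
#' @param nonspecific_lc_range Contour-length range (nm) of spurious
#'   short-tether adhesions.
#' @param lc_sd_frac Relative SD of the per-curve tether monomer count,
#'   emulating PEG polydispersity and attachment-point variation; this is the
#'   physical origin of the contour-length spread that the Gaussian Lc filter
#'   operates on. Default 4%.
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(kin, tether = tether_model(),
                              spring_constant = 10,
                              velocities = 10^seq(2, 4, length.out = 6),
                              curves_per_velocity = 100,
                              fractions = c(specific = 0.06,
                                            nonspecific = 0.02,
                                            empty = 0.92),
                              noise_sd = 5, sampling_rate = NULL,
                              nonspecific_lc_range = c(5, 40),
                              lc_sd_frac = 0.04, seed) {
  stopifnot(inherits(kin, "kinetic_params"), inherits(tether, "tether_model"))
  check_scalar(spring_constant, "spring_constant")
  if (length(velocities) < 1L || any(velocities <= 0))
    abort_domain("'velocities' must all be > 0")
  check_scalar(curves_per_velocity, "curves_per_velocity")
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-12)
    abort_domain("'fractions' must be 3 non-negative values (specific, nonspecific, empty) summing to 1")
  names(fractions) <- c("specific", "nonspecific", "empty")
  if (noise_sd < 0) abort_domain("'noise_sd' must be >= 0")
  if (!is.null(sampling_rate)) check_scalar(sampling_rate, "sampling_rate")
  if (length(nonspecific_lc_range) != 2L || any(nonspecific_lc_range <= 0) ||
      diff(nonspecific_lc_range) < 0)
    abort_domain("'nonspecific_lc_range' must be an increasing positive pair (nm)")
  if (lc_sd_frac < 0 || lc_sd_frac > 0.3)
    abort_domain("'lc_sd_frac' must lie in [0, 0.3]")
  seed <- check_seed(seed)
  structure(list(kin = kin, tether = tether, spring_constant = spring_constant,
                 velocities = velocities,
                 curves_per_velocity = as.integer(curves_per_velocity),
                 fractions = fractions, noise_sd = noise_sd,
                 sampling_rate = sampling_rate,
                 nonspecific_lc_range = nonspecific_lc_range,
                 lc_sd_frac = lc_sd_frac, seed = seed),
            class = "simulation_config")
}

sampling_rate_for <- function(config, velocity) {
  config$sampling_rate %||% max(5000, 5 * velocity)
}

# Noiseless force trajectory of a tether + cantilever in series pulled at
# constant velocity: solves z = x_tether(F) + F/k_c for each sampled z by
# interpolation off a dense table followed by vectorised Newton polish.
series_force_path <- function(z, tether, kc, f_cap = 500) {
  fg <- seq(0, f_cap, length.out = 1201L)
  zg <- fjc_extension(fg, tether) + fg / kc
  f <- stats::approx(zg, fg, xout = pmin(z, max(zg)), rule = 2)$y
  for (i in 1:3) {
    g <- fjc_extension(f, tether) + f / kc - z
    dg <- fjc_dxdf(f, tether) + 1 / kc
    f <- pmin(f_cap, pmax(0, f - g / dg))
  }
  if (any(!is.finite(f)))
    abort_simulation(sprintf("force root-find failed at time step %d",
                             which(!is.finite(f))[1L]))
  f
}

# Instantaneous loading rate dF/dt = v / (1/k_c + dx/dF) at a given force;
# the chain-rule reference value used by simulator tests.
instantaneous_loading_rate <- function(force, tether, kc, velocity) {
  velocity / (1 / kc + fjc_dxdf(force, tether))
}

#' Simulate one retraction curve with ground truth
#'
#' Tethered classes pull a two-state FJC in series with the cantilever at
#' constant velocity; for the `specific` class the bond survival decays with
#' the Bell-Evans hazard integrated (trapezoidally) along the sampled force
#' path, and rupture occurs where the integral first exceeds an exponential
#' variate. `nonspecific` curves use a short tether with Lc drawn from
#' `nonspecific_lc_range` and an exponential-tailed low-force detachment
#' (5-50 pN). `empty` curves are baseline plus noise. After rupture the force
#' returns to baseline; Gaussian noise of `noise_sd` is added throughout.
#'
#' @param config A [simulation_config()].
#' @param class One of `"specific"`, `"nonspecific"`, `"empty"`.
#' @param seed Integer seed for this curve.
#' @param velocity Pulling velocity (nm/s); default the first configured one.
#' @param curve_id Identifier; default derived from class and seed.
#' @return A list with elements `curve` ([force_curve()]) and `truth` (a
#'   one-row data frame: `curve_id, true_class, true_rupture_force,
#'   true_rupture_index, true_lc`; rupture fields are `NA` for empty curves).
#' @export
simulate_retract_curve <- function(config, class = c("specific", "nonspecific", "empty"),
                                   seed, velocity = config$velocities[1L],
                                   curve_id = NULL) {
  class <- match.arg(class)
  seed <- check_seed(seed)
  curve_id <- curve_id %||% sprintf("%s_%d", class, seed)
  with_seed(seed, sim_curve_engine(config, class, velocity, curve_id))
}

sim_curve_engine <- function(config, class, velocity, curve_id) {
  kc <- config$spring_constant
  fs <- sampling_rate_for(config, velocity)
  # travel far enough that a surviving specific tether reaches ~400 pN
  z_max <- 1.1 * (fjc_extension(400, config$tether) * (1 + 4 * config$lc_sd_frac) +
                    400 / kc)
  n <- max(2L, ceiling(z_max / velocity * fs))
  tt <- (0:(n - 1L)) / fs
  z <- velocity * tt

  f0 <- numeric(n)
  true_force <- NA_real_
  true_index <- NA_integer_
  true_lc <- NA_real_

  if (class != "empty") {
    if (class == "specific") {
      n_eff <- config$tether$n_monomers *
        max(0.5, 1 + stats::rnorm(1, 0, config$lc_sd_frac))
    } else {
      lc_ns <- stats::runif(1, config$nonspecific_lc_range[1L],
                            config$nonspecific_lc_range[2L])
      n_eff <- lc_ns / config$tether$l_planar
    }
    teth <- tether_with_n(config$tether, n_eff)
    true_lc <- contour_length(teth)
    f0 <- series_force_path(z, teth, kc)

    if (class == "specific") {
      haz <- bell_off_rate(f0, config$kin)
      cum <- cumtrapz0(tt, haz)
      ee <- stats::rexp(1)
      hit <- which(cum >= ee)
      true_index <- if (length(hit)) hit[1L] else n
    } else {
      # exponential-tailed detachment force in [5, 50] pN
      u <- stats::runif(1)
      f_det <- 5 + stats::qexp(u * stats::pexp(45, rate = 1 / 12), rate = 1 / 12)
      hit <- which(f0 >= f_det)
      true_index <- if (length(hit)) hit[1L] else n
    }
    true_force <- f0[true_index]
    if (true_index < n) f0[(true_index + 1L):n] <- 0
  }

  force <- f0
  if (config$noise_sd > 0) force <- force + stats::rnorm(n, 0, config$noise_sd)

  list(curve = force_curve(curve_id, tt, z, force, velocity, kc),
       truth = data.frame(curve_id = curve_id, true_class = class,
                          true_rupture_force = true_force,
                          true_rupture_index = true_index,
                          true_lc = true_lc, stringsAsFactors = FALSE))
}

#' Simulate a full pulling experiment
#'
#' Draws `curves_per_velocity` curves at each configured velocity with classes
#' sampled from the mixture `fractions`. One RNG stream (from `config$seed`)
#' assigns classes and per-curve sub-seeds up front, so each curve is
#' individually reproducible and the ensemble is invariant to evaluation
#' order.
#'
#' @param config A [simulation_config()].
#' @return A list with `curves` (list of [force_curve()]) and `truth`
#'   (data frame of per-curve ground truth, plus a `pulling_velocity` column).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nv <- length(config$velocities)
  total <- nv * config$curves_per_velocity
  plan <- with_seed(config$seed, {
    classes <- sample(c("specific", "nonspecific", "empty"), total,
                      replace = TRUE, prob = config$fractions)
    seeds <- sample.int(.Machine$integer.max - 1L, total, replace = FALSE)
    list(classes = classes, seeds = seeds)
  })
  curves <- vector("list", total)
  truth <- vector("list", total)
  idx <- 0L
  for (iv in seq_len(nv)) {
    v <- config$velocities[iv]
    for (ic in seq_len(config$curves_per_velocity)) {
      idx <- idx + 1L
      id <- sprintf("v%02d_c%05d", iv, ic)
      res <- simulate_retract_curve(config, plan$classes[idx],
                                    seed = plan$seeds[idx], velocity = v,
                                    curve_id = id)
      curves[[idx]] <- res$curve
      tr <- res$truth
      tr$pulling_velocity <- v
      truth[[idx]] <- tr
    }
  }
  list(curves = curves, truth = do.call(rbind, truth))
}

#' Simulate Bernoulli contact-trial outcomes
#'
#' The adhesion-frequency protocol: `n` independent tip-surface contact cycles
#' each of which produces a bond with probability `p`.
#'
#' @param p True binding probability in `[0, 1]`.
#' @param n Number of contact trials (>= 1).
#' @param seed Integer RNG seed.
#' @return Integer vector of 0/1 outcomes of length `n`.
#' @export
simulate_binding_outcomes <- function(p, n, seed) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    abort_domain("'p' must lie in [0, 1]")
  if (!is.numeric(n) || n < 1) abort_domain("'n' must be >= 1")
  seed <- check_seed(seed)
  with_seed(seed, stats::rbinom(as.integer(n), 1L, p))
}
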